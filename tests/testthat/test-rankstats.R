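# Core rank statistics: ranking, WMW test, MANOVA on ranks, scores, BH.

test_that("rank_transform assigns ascending ranks with mid-rank ties and conserves the rank sum", {
  expect_equal(as.numeric(rank_transform(c(10, 30, 20))), c(1, 3, 2))
  expect_equal(as.numeric(rank_transform(c(5, 5, 7))), c(1.5, 1.5, 3))
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:50, 1)
    v <- sample(round(rnorm(n), 1))  # rounding produces ties
    r <- rank_transform(v)
    expect_equal(sum(r), n * (n + 1) / 2)
    expect_true(all(r >= 1 & r <= n))
    perm <- sample.int(n)
    expect_equal(as.numeric(rank_transform(v[perm])),
                 as.numeric(r)[perm])  # permutation equivariance
  }
  expect_error(rank_transform(numeric(0)), "at least two")
  expect_error(rank_transform(5), "at least two")
  expect_error(rank_transform(c(1, NA, 3)), "missing")
})

test_that("wmw_test reproduces the exact small-sample p and is symmetric in mask complement", {
  r <- rank_transform(c(1, 2, 3, 4))
  res <- wmw_test(c(TRUE, TRUE, FALSE, FALSE), r)
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 3)
  expect_equal(res$stats$n1, 2)
  expect_equal(res$stats$R1_sum, 3)
  set.seed(7)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    v <- rnorm(n)
    m <- random_mask(n, sample(2:(n - 2), 1))
    rk <- rank_transform(v)
    expect_equal(wmw_test(m, rk)$p, wmw_test(!m, rk)$p)
  }
  expect_error(wmw_test(rep(TRUE, 4), r), "degenerate")
  expect_error(wmw_test(rep(FALSE, 4), r), "degenerate")
})

test_that("wmw_test matches exact enumeration (tie-free) and stays close under ties", {
  set.seed(21)
  for (i in 1:15) {
    n <- sample(6:12, 1)
    n1 <- sample(2:(n - 2), 1)
    m <- random_mask(n, n1)
    v <- rnorm(n)
    rk <- rank_transform(v)
    expect_equal(wmw_test(m, rk)$p, exact_wmw_p(m, rk))
    vt <- sample(rep(1:3, length.out = n))  # heavy ties
    rkt <- rank_transform(vt)
    expect_equal(wmw_test(m, rkt)$p, exact_wmw_p(m, rkt))
  }
})

test_that("wmw_test agrees with wilcox.test in both regimes and for one-sided alternatives", {
  set.seed(31)
  # exact regime, no ties
  for (i in 1:10) {
    n <- sample(8:25, 1)
    v <- rnorm(n)
    m <- random_mask(n, sample(2:6, 1))
    rk <- rank_transform(v)
    expect_equal(wmw_test(m, rk)$p, wilcox.test(v[m], v[!m])$p.value)
    expect_equal(wmw_test(m, rk, sides = "greater")$p,
                 wilcox.test(v[m], v[!m], alternative = "greater")$p.value)
    expect_equal(wmw_test(m, rk, sides = "less")$p,
                 wilcox.test(v[m], v[!m], alternative = "less")$p.value)
  }
  # normal-approximation regime with ties
  for (i in 1:10) {
    n <- sample(60:150, 1)
    v <- round(rnorm(n), 1)
    m <- random_mask(n, sample(10:30, 1))
    rk <- rank_transform(v)
    expect_equal(wmw_test(m, rk)$p,
                 suppressWarnings(wilcox.test(v[m], v[!m])$p.value))
  }
})

test_that("two-sided WMW p orders terms identically to a pooled t-test on the ranks", {
  set.seed(41)
  n <- 200
  v <- rnorm(n)
  rk <- rank_transform(v)
  p_wmw <- p_t <- numeric(50)
  for (i in 1:50) {
    m <- random_mask(n, sample(5:60, 1))
    p_wmw[i] <- wmw_test(m, rk)$p
    p_t[i] <- t.test(as.numeric(rk)[m], as.numeric(rk)[!m],
                     var.equal = TRUE)$p.value
  }
  expect_equal(cor(p_wmw, p_t, method = "spearman"), 1)
})

test_that("score_1d hits the extreme-rank identities and the worked value", {
  set.seed(51)
  for (i in 1:10) {
    n <- sample(5:100, 1)
    n1 <- sample(1:(n - 1), 1)
    top <- seq_len(n) > n - n1      # term occupies the top n1 ranks
    st <- wmw_test(top, rank_transform(seq_len(n)))$stats
    expect_equal(score_1d(st), 1)
    bottom <- seq_len(n) <= n1
    expect_equal(score_1d(wmw_test(bottom, rank_transform(seq_len(n)))$stats), -1)
  }
  # symmetric placement: ranks {1, 4} of 4
  st <- wmw_test(c(TRUE, FALSE, FALSE, TRUE), rank_transform(1:4))$stats
  expect_equal(score_1d(st), 0)
  # direct evaluation: n = 5, group ranks {3, 5} -> 2/3
  st <- wmw_test(c(FALSE, FALSE, TRUE, FALSE, TRUE), rank_transform(1:5))$stats
  expect_equal(score_1d(st), 2 / 3)
  # bounds everywhere
  for (i in 1:30) {
    n <- sample(4:60, 1)
    m <- random_mask(n, sample(1:(n - 1), 1))
    s <- score_1d(wmw_test(m, rank_transform(rnorm(n)))$stats)
    expect_lte(abs(s), 1)
  }
})

test_that("manova2d_test returns the null identity, is rank-invariant, and matches the brute-force quadratic form", {
  # both group mean-rank vectors identical -> statistic 0, p 1
  # (y is a different permutation, so the scatter stays non-singular)
  x <- 1:8
  y <- c(2, 1, 4, 3, 6, 5, 8, 7)
  m <- c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE)
  res <- manova2d_test(m, rank_transform(x), rank_transform(y))
  expect_equal(res$dx, 0)
  expect_equal(res$dy, 0)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  set.seed(61)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    m <- random_mask(n, sample(3:(n %/% 2), 1))
    xv <- rnorm(n); yv <- rnorm(n)
    rx <- rank_transform(xv); ry <- rank_transform(yv)
    res <- manova2d_test(m, rx, ry)
    expect_equal(res$statistic, brute_quadform(m, rx, ry), tolerance = 1e-10)
    # Cauchy-Schwarz and positivity invariants
    expect_gte(res$sxx, 0)
    expect_gte(res$syy, 0)
    expect_lte(res$sxy^2, res$sxx * res$syy)
    expect_gte(res$statistic, 0)
    # invariance under strictly monotone transform of the raw values
    res2 <- manova2d_test(m, rank_transform(exp(xv)), ry)
    expect_identical(res2$p_value, res$p_value)
  }
})

test_that("manova2d_test p-value equals the exact two-group Hotelling-Lawley MANOVA p", {
  set.seed(71)
  for (i in 1:10) {
    n <- sample(12:50, 1)
    m <- random_mask(n, sample(3:8, 1))
    rx <- rank_transform(rnorm(n)); ry <- rank_transform(rnorm(n))
    res <- manova2d_test(m, rx, ry)
    fit <- summary(manova(cbind(as.numeric(rx), as.numeric(ry)) ~ factor(m)),
                   test = "Hotelling-Lawley")
    expect_equal(res$p_value, fit$stats[1, 6], tolerance = 1e-12)
    expect_equal(res$F, fit$stats[1, 3], tolerance = 1e-12)
  }
})

test_that("manova2d_test reports singular scatter and degenerate groups as errors", {
  x <- rnorm(10)
  rx <- rank_transform(x)
  m <- random_mask(10, 4)
  expect_error(manova2d_test(m, rx, rx), class = "enrich2d_singular")
  expect_error(manova2d_test(m, rx, rx), "singular")
  ry <- rank_transform(rnorm(10))
  expect_error(manova2d_test(c(TRUE, rep(FALSE, 9)), rx, ry), "at least 2")
})

test_that("score_2d combines coordinate-wise scores and checks mask consistency", {
  n <- 20
  m <- seq_len(n) > n - 5          # top ranks in x ...
  rx <- rank_transform(seq_len(n))
  ry <- rank_transform(rev(seq_len(n)))  # ... bottom ranks in y
  sc <- score_2d(two_group_rank_stats(m, rx),
                 two_group_rank_stats(m, ry))
  expect_equal(unname(sc), c(1, -1))
  # symmetric placement about the median rank in both coordinates -> (0, 0)
  m0 <- c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE)
  sc0 <- score_2d(two_group_rank_stats(m0, rank_transform(1:8)),
                  two_group_rank_stats(m0, rank_transform(8:1)))
  expect_equal(unname(sc0), c(0, 0))
  # inconsistent group sizes rejected
  expect_error(
    score_2d(two_group_rank_stats(m, rx),
             two_group_rank_stats(!m, ry)),
    "inconsistent")
})

test_that("score pair is centred at zero under random membership of exchangeable data", {
  set.seed(81)
  n <- 60; n1 <- 12; B <- 5000
  rx <- rank_transform(rnorm(n))
  ry <- rank_transform(rnorm(n))
  sx <- sy <- numeric(B)
  for (b in seq_len(B)) {
    m <- random_mask(n, n1)
    sc <- score_2d(two_group_rank_stats(m, rx),
                   two_group_rank_stats(m, ry))
    sx[b] <- sc[["sx"]]; sy[b] <- sc[["sy"]]
  }
  expect_lt(abs(mean(sx)), 3 * sd(sx) / sqrt(B))
  expect_lt(abs(mean(sy)), 3 * sd(sy) / sqrt(B))
})

test_that("bh_fdr applies the step-up rule and matches a hand-rolled adjustment", {
  res <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(res$significant))  # largest p = 0.04 <= 4/4 * 0.05
  expect_equal(res$q_values, c(0.04, 0.04, 0.04, 0.04))
  expect_false(any(bh_fdr(rep(1, 10), q = 0.5)$significant))
  set.seed(91)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p, q = 0.1)$q_values, bh_manual(p))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, -0.1)), "\\[0, 1\\]")
  expect_error(bh_fdr(0.5, q = 1), "\\(0, 1\\)")
})
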