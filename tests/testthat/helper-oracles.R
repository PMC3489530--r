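# Independent oracles used to validate the analytical statistics. These are
# deliberately coded via different routes (enumeration, generic matrix
# algebra, Monte-Carlo permutation, hand-rolled step-up) than the package
# implementation.

# Exact two-sided WMW p by enumerating every assignment of the group labels
# over the fixed (possibly tied) ranks.
exact_wmw_p <- function(mask, ranks) {
  ranks <- as.numeric(ranks)
  n <- length(ranks)
  n1 <- sum(mask)
  combs <- utils::combn(n, n1)
  R1s <- colSums(matrix(ranks[combs], nrow = nrow(combs)))
  Us <- R1s - n1 * (n1 + 1) / 2
  u <- sum(ranks[mask]) - n1 * (n1 + 1) / 2
  p_le <- mean(Us <= u)
  p_ge <- mean(Us >= u)
  min(1, 2 * min(p_le, p_ge))
}

# Two-group quadratic form d' W^-1 d computed with generic matrix algebra.
brute_quadform <- function(mask, ranks_x, ranks_y) {
  X <- cbind(as.numeric(ranks_x), as.numeric(ranks_y))
  X1 <- X[mask, , drop = FALSE]
  X2 <- X[!mask, , drop = FALSE]
  d <- colMeans(X1) - colMeans(X2)
  W <- crossprod(scale(X1, scale = FALSE)) +
       crossprod(scale(X2, scale = FALSE))
  drop(t(d) %*% solve(W) %*% d)
}

# Monte-Carlo permutation p-value for the two-group MANOVA-on-ranks test:
# relabel group membership B times and compare the quadratic form. The
# statistic is computed from raw sums, independent of the package code.
mc_manova_p <- function(mask, ranks_x, ranks_y, B = 50000) {
  x <- as.numeric(ranks_x); y <- as.numeric(ranks_y)
  n <- length(x); n1 <- sum(mask); n2 <- n - n1
  Tx <- sum(x); Ty <- sum(y)
  Sxx <- sum(x^2); Syy <- sum(y^2); Sxy <- sum(x * y)
  qstat <- function(S1x, S1y) {
    m1x <- S1x / n1; m2x <- (Tx - S1x) / n2
    m1y <- S1y / n1; m2y <- (Ty - S1y) / n2
    sxx <- Sxx - n1 * m1x^2 - n2 * m2x^2
    syy <- Syy - n1 * m1y^2 - n2 * m2y^2
    sxy <- Sxy - n1 * m1x * m1y - n2 * m2x * m2y
    dx <- m1x - m2x; dy <- m1y - m2y
    (sxx * dy^2 + syy * dx^2 - 2 * sxy * dx * dy) / (sxx * syy - sxy^2)
  }
  obs <- qstat(sum(x[mask]), sum(y[mask]))
  idx <- replicate(B, sample.int(n, n1))
  S1x <- colSums(matrix(x[idx], nrow = n1))
  S1y <- colSums(matrix(y[idx], nrow = n1))
  (1 + sum(qstat(S1x, S1y) >= obs)) / (B + 1)
}

# Hand-rolled Benjamini-Hochberg step-up adjustment.
bh_manual <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- pmin(rev(cummin(rev(adj))), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Random membership terms over a set of row identifiers.
random_terms <- function(ids, n_terms, size_range = c(10, 100),
                         category = "null") {
  sizes <- sample(size_range[1]:size_range[2], n_terms, replace = TRUE)
  lapply(seq_len(n_terms), function(i) {
    term_set(sprintf("%s%04d", toupper(category), i), sample(ids, sizes[i]),
             category = category)
  })
}

random_mask <- function(n, n1) {
  m <- logical(n)
  m[sample.int(n, n1)] <- TRUE
  m
}
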