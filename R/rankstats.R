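# Core non-parametric statistics: ranking, the two-sample
# Wilcoxon-Mann-Whitney test, the two-group MANOVA on coordinate-wise
# ranks, directional position scores, and Benjamini-Hochberg FDR.

#' Rank-transform a numeric vector
#'
#' Replaces values by their ascending ranks. Tied values receive the mean of
#' the ranks they would jointly occupy (mid-ranks), so the sum of the ranks
#' is always `n(n+1)/2` exactly. All downstream enrichment statistics operate
#' on these ranks only, which makes every result invariant under strictly
#' monotone transformations of the input.
#'
#' @param values Numeric vector of length at least 2, without missing values.
#' @return A `rank_vector` object: the numeric ranks aligned to the input
#'   order, with attribute `n` (the number of ranked items).
#' @examples
#' rank_transform(c(10, 30, 20))   # 1 3 2
#' rank_transform(c(5, 5, 7))      # 1.5 1.5 3
#' @export
rank_transform <- function(values) {
  if (!is.numeric(values)) {
    stop("'values' must be numeric", call. = FALSE)
  }
  if (length(values) < 2L) {
    stop("at least two values are required for ranking", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("'values' must not contain missing entries; drop them first",
         call. = FALSE)
  }
  r <- rank(values, ties.method = "average")
  structure(as.numeric(r), n = length(r), class = "rank_vector")
}

#' @export
print.rank_vector <- function(x, ...) {
  cat("<rank_vector> n =", attr(x, "n"), "\n")
  print(as.numeric(x), ...)
  invisible(x)
}

#' Rank summaries of the two groups defined by a membership mask
#'
#' Computes the per-group sample sizes, the rank sum of the selected group,
#' and both mean ranks. These summaries feed the 1D test statistic (via the
#' rank sum) and the directional scores (via the mean-rank difference).
#'
#' @param in_term Logical mask aligned to `ranks`; must select between 1 and
#'   `n - 1` items.
#' @param ranks A [rank_transform()] result or plain numeric rank vector.
#' @return A `two_group_rank_stats` list: `n1`, `n2`, `n`, `R1_sum`,
#'   `R1_bar`, `R2_bar`.
#' @export
two_group_rank_stats <- function(in_term, ranks) {
  n <- length(ranks)
  if (!is.logical(in_term) || length(in_term) != n || anyNA(in_term)) {
    stop("'in_term' must be a complete logical mask aligned to the ranks",
         call. = FALSE)
  }
  n1 <- sum(in_term)
  n2 <- n - n1
  if (n1 < 1L || n2 < 1L) {
    stop("degenerate grouping: the mask must select between 1 and n-1 items",
         call. = FALSE)
  }
  r <- as.numeric(ranks)
  R1_sum <- sum(r[in_term])
  structure(
    list(n1 = n1, n2 = n2, n = n,
         R1_sum = R1_sum,
         R1_bar = R1_sum / n1,
         R2_bar = (n * (n + 1) / 2 - R1_sum) / n2),
    class = "two_group_rank_stats")
}

#' Two-sample Wilcoxon-Mann-Whitney test on precomputed ranks
#'
#' Tests whether the items selected by `in_term` tend to carry larger (or
#' smaller) values than the remaining items, using only the ranking of the
#' values. The test statistic is `U = R1 - n1(n1+1)/2`, where `R1` is the sum
#' of ranks in the selected group and `n1` its size.
#'
#' When `n1 * n2 <= 400` the p-value comes from the exact conditional null
#' distribution of the rank sum — equivalent to enumerating every assignment
#' of the group labels, ties included. Above that, a normal approximation
#' with tie correction and continuity correction is used, matching the
#' asymptotic regime of genome-scale tables while staying exact on small
#' inputs.
#'
#' @param in_term Logical mask aligned to `ranks`; must select at least one
#'   item and leave at least one item in the complement.
#' @param ranks A [rank_transform()] result (or a plain numeric rank vector).
#' @param sides `"two"` (default) for the two-sided test; `"greater"` /
#'   `"less"` test one-sided enrichment of the group at large / small values.
#' @return A list with elements `U`, `p`, and `stats` (the per-group rank
#'   summaries: `n1`, `n2`, `n`, `R1_sum`, `R1_bar`, `R2_bar`).
#' @examples
#' r <- rank_transform(c(1, 2, 3, 4))
#' wmw_test(c(TRUE, TRUE, FALSE, FALSE), r)$p  # exact two-sided 1/3
#' @export
wmw_test <- function(in_term, ranks, sides = c("two", "greater", "less")) {
  sides <- match.arg(sides)
  stats <- two_group_rank_stats(in_term, ranks)
  n1 <- stats$n1
  n2 <- stats$n2
  n <- stats$n
  U <- stats$R1_sum - n1 * (n1 + 1) / 2

  r <- as.numeric(ranks)
  tie_counts <- table(r)

  if (n1 * n2 <= 400) {
    p <- wmw_exact_p(r, in_term, sides)
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(tie_counts^3 - tie_counts) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    z <- U - mu
    correction <- switch(sides,
      two = sign(z) * 0.5,
      greater = 0.5,
      less = -0.5)
    z <- (z - correction) / sigma
    p <- switch(sides,
      two = 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z))
    p <- min(p, 1)
  }

  list(U = U, p = p, stats = stats)
}

# Exact conditional null distribution of the group rank sum, ties included:
# dynamic programming over the doubled (hence integer) mid-ranks counts the
# size-k subsets attaining each possible rank sum, i.e. full enumeration of
# all C(n, k) equally likely group assignments. Used when n1 * n2 <= 400;
# the DP runs on the smaller group, so k <= 20 there.
wmw_exact_p <- function(r, in_term, sides) {
  if (sum(in_term) > length(r) / 2) {
    # complement symmetry: swap the group and the tail
    in_term <- !in_term
    sides <- switch(sides, two = "two", greater = "less", less = "greater")
  }
  ranks2 <- as.integer(round(2 * r))
  n1 <- sum(in_term)
  S <- sum(ranks2)
  f <- matrix(0, nrow = n1 + 1L, ncol = S + 1L)
  f[1L, 1L] <- 1
  for (v in ranks2) {
    for (k in n1:1L) {
      idx <- seq_len(S + 1L - v)
      f[k + 1L, idx + v] <- f[k + 1L, idx + v] + f[k, idx]
    }
  }
  dist <- f[n1 + 1L, ]
  total <- sum(dist)
  obs <- as.integer(round(2 * sum(r[in_term])))
  p_le <- sum(dist[seq_len(obs + 1L)]) / total
  p_ge <- sum(dist[(obs + 1L):(S + 1L)]) / total
  switch(sides,
         two = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

#' Directional position score for a term (1D)
#'
#' The score `s = 2 * (R1_bar - R2_bar) / n` locates the centre of a term's
#' members within the rank distribution of all measured items: it is confined
#' to `[-1, 1]`, reaches `+1` exactly when the members occupy the top ranks,
#' `-1` when they occupy the bottom ranks, and `0` when member and complement
#' mean ranks coincide.
#'
#' @param stats Two-group rank summaries, as returned in the `stats` element
#'   of [wmw_test()].
#' @return A single numeric score in `[-1, 1]`.
#' @export
score_1d <- function(stats) {
  if (!inherits(stats, "two_group_rank_stats")) {
    stop("'stats' must be a two_group_rank_stats object", call. = FALSE)
  }
  2 * (stats$R1_bar - stats$R2_bar) / stats$n
}

# Condition constructor for degenerate within-group scatter, so callers can
# distinguish "untestable term" from programming errors.
singular_scatter_error <- function(detail) {
  structure(
    class = c("enrich2d_singular", "error", "condition"),
    list(message = paste0("singular rank scatter matrix: ", detail),
         call = NULL))
}

#' Two-group MANOVA test on coordinate-wise ranks (2D enrichment test)
#'
#' Tests whether the items selected by `in_term` deviate from the joint
#' distribution of two quantitative dimensions. Both dimensions are replaced
#' by their ranks separately; the two-group MANOVA statistic is the quadratic
#' form
#' \deqn{(s_{xx} d_y^2 + s_{yy} d_x^2 - 2 s_{xy} d_x d_y) /
#'       (s_{xx} s_{yy} - s_{xy}^2)}
#' where `dx`, `dy` are the differences of the group mean ranks and `sxx`,
#' `syy`, `sxy` the pooled within-group sums of squares and cross-products of
#' the ranks. With two groups the MANOVA reduces to Hotelling's two-sample
#' T-squared, `T2 = (n1 n2 / n) (n - 2) Q`, whose exact null reference is
#' `F = (n - 3) / (2 (n - 2)) T2` on an F(2, n - 3) distribution; the p-value
#' is taken from that mapping.
#'
#' @param in_term Logical mask aligned to both rank vectors; must select at
#'   least 2 items and leave at least 2 in the complement (each group needs
#'   within-group scatter).
#' @param ranks_x,ranks_y Coordinate-wise [rank_transform()] results aligned
#'   to the same items.
#' @return A `manova2d_stats` list: `dx`, `dy`, `sxx`, `syy`, `sxy`,
#'   `statistic` (the quadratic form), `T2`, `F`, `df` (the F degrees of
#'   freedom), `p_value`, `n1`, `n2`.
#' @seealso [score_2d()] for the accompanying directional score pair.
#' @export
manova2d_test <- function(in_term, ranks_x, ranks_y) {
  x <- as.numeric(ranks_x)
  y <- as.numeric(ranks_y)
  n <- length(x)
  if (length(y) != n) {
    stop("'ranks_x' and 'ranks_y' must be aligned to the same items",
         call. = FALSE)
  }
  if (!is.logical(in_term) || length(in_term) != n || anyNA(in_term)) {
    stop("'in_term' must be a complete logical mask aligned to the ranks",
         call. = FALSE)
  }
  n1 <- sum(in_term)
  n2 <- n - n1
  if (n1 < 2L || n2 < 2L) {
    stop("each group needs at least 2 items for within-group scatter",
         call. = FALSE)
  }

  x1 <- x[in_term]; x2 <- x[!in_term]
  y1 <- y[in_term]; y2 <- y[!in_term]
  m_x1 <- mean(x1); m_x2 <- mean(x2)
  m_y1 <- mean(y1); m_y2 <- mean(y2)
  dx <- m_x1 - m_x2
  dy <- m_y1 - m_y2
  sxx <- sum((x1 - m_x1)^2) + sum((x2 - m_x2)^2)
  syy <- sum((y1 - m_y1)^2) + sum((y2 - m_y2)^2)
  sxy <- sum((x1 - m_x1) * (y1 - m_y1)) + sum((x2 - m_x2) * (y2 - m_y2))

  det <- sxx * syy - sxy^2
  if (det <= 1e-12 * sxx * syy || det <= 0) {
    stop(singular_scatter_error(sprintf(
      "sxx*syy - sxy^2 = %.3g is not positive relative to sxx*syy = %.3g (x and y ranks are collinear within groups)",
      det, sxx * syy)))
  }

  Q <- (sxx * dy^2 + syy * dx^2 - 2 * sxy * dx * dy) / det
  T2 <- (n1 * n2 / n) * (n - 2) * Q
  Fstat <- (n - 3) / (2 * (n - 2)) * T2
  p <- stats::pf(Fstat, 2, n - 3, lower.tail = FALSE)

  structure(
    list(dx = dx, dy = dy, sxx = sxx, syy = syy, sxy = sxy,
         statistic = Q, T2 = T2, F = Fstat, df = c(2, n - 3),
         p_value = p, n1 = n1, n2 = n2),
    class = "manova2d_stats")
}

#' Directional score pair for a term (2D)
#'
#' The 2D analogue of [score_1d()]: the score is the number pair
#' `(sx, sy)`, each coordinate being the coordinate-wise difference of
#' average ranks scaled to `[-1, 1]`. The pair is confined to the square
#' `[-1, 1]^2`; concordant shifts fall near the diagonal, single-dimension
#' shifts near an axis, anti-correlated shifts in the off-diagonal quadrants.
#'
#' @param stats_x,stats_y Two-group rank summaries for the x and y
#'   dimensions, computed from the same membership mask.
#' @return Named numeric vector `c(sx = ..., sy = ...)`.
#' @export
score_2d <- function(stats_x, stats_y) {
  if (!inherits(stats_x, "two_group_rank_stats") ||
      !inherits(stats_y, "two_group_rank_stats")) {
    stop("both inputs must be two_group_rank_stats objects", call. = FALSE)
  }
  if (stats_x$n1 != stats_y$n1 || stats_x$n != stats_y$n) {
    stop("inconsistent group sizes: the two stats must come from the same membership mask",
         call. = FALSE)
  }
  c(sx = score_1d(stats_x), sy = score_1d(stats_y))
}

#' Benjamini-Hochberg FDR adjustment with a significance mask
#'
#' Step-up Benjamini-Hochberg adjustment of a p-value vector, plus the mask
#' of terms significant at the requested FDR threshold `q`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NA allowed; NA
#'   entries receive NA adjusted values and are never significant).
#' @param q FDR threshold in `(0, 1)`; the default 0.02 is the tool's default
#'   reporting threshold for 1D enrichment.
#' @return A list with `q_values` (BH-adjusted values) and `significant`
#'   (logical mask, `q_values <= q`).
#' @export
bh_fdr <- function(p_values, q = 0.02) {
  if (!is.numeric(p_values)) {
    stop("'p_values' must be numeric", call. = FALSE)
  }
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q >= 1) {
    stop("'q' must be a single value in (0, 1)", call. = FALSE)
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  sig <- !is.na(adj) & adj <= q
  list(q_values = adj, significant = sig)
}
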