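# Synthetic quantitative tables, annotations, and peptide-protein maps with
# planted, labelled structure, so every analysis path can be exercised and
# calibrated without external data.

#' Specify a synthetic quantitative table
#'
#' Describes a two-column (x, y) quantitative table emulating the shape of
#' genome-scale log-ratio / log-abundance clouds: a unimodal background with
#' optional x-y correlation, a set of random null terms, and planted terms
#' whose members are shifted by a known amount in each dimension.
#'
#' Defaults mirror a typical deep proteome run: 5,000 quantified protein
#' groups, term sizes between 10 and 100 (the bulk of GO/KEGG terms in that
#' range), and planted shifts expressed in within-distribution standard
#' deviations so power statements are distribution-free.
#'
#' @param n_rows Number of rows (protein groups).
#' @param n_terms Total number of annotation terms (null terms drawn with
#'   random membership; planted terms replace the first entries).
#' @param term_size_range Integer range from which null-term sizes are drawn
#'   uniformly.
#' @param planted Optional `data.frame` with columns `term_id`, `size`,
#'   `dx`, `dy`: each row plants one term whose members are shifted by
#'   `dx` / `dy` background SD units in x / y.
#' @param background `"normal"` (log-ratio-like, mean 0, SD 1) or
#'   `"lognormal"` (abundance-like; values reported on log10 scale, mean 7,
#'   SD 1).
#' @param rho Background correlation between x and y in `[-1, 1]`.
#' @param missing_frac Fraction of cells set missing, independently per cell.
#' @param seed Integer seed; specification plus seed fully determine the output.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_rows = 5000, n_terms = 100,
                     term_size_range = c(10, 100), planted = NULL,
                     background = c("normal", "lognormal"), rho = 0,
                     missing_frac = 0, seed = 1) {
  background <- match.arg(background)
  if (missing_frac < 0 || missing_frac > 1) {
    stop("'missing_frac' must be in [0, 1]", call. = FALSE)
  }
  if (abs(rho) > 1) stop("'rho' must be in [-1, 1]", call. = FALSE)
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("term_id", "size", "dx", "dy") %in% names(planted)))
    if (any(planted$size > n_rows)) {
      stop("planted term sizes must not exceed 'n_rows'", call. = FALSE)
    }
    if (nrow(planted) > n_terms) {
      stop("more planted terms than 'n_terms'", call. = FALSE)
    }
  }
  if (max(term_size_range) > n_rows) {
    stop("term sizes must not exceed 'n_rows'", call. = FALSE)
  }
  structure(list(n_rows = n_rows, n_terms = n_terms,
                 term_size_range = term_size_range, planted = planted,
                 background = background, rho = rho,
                 missing_frac = missing_frac, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate a quantitative table with planted term shifts
#'
#' Draws the background as i.i.d. bivariate values with correlation `rho`
#' (standard normal for log-ratios; for the abundance-like background the
#' values are normal on log10 scale), assigns random memberships to null
#' terms, and shifts the members of each planted term by `(dx, dy)` SD
#' units. A fixed spec and seed reproduce the output exactly.
#'
#' @param spec A [sim_spec()].
#' @return A list with `table` (`data.frame`, columns `x` and `y`, row names
#'   `G00001` ...), `terms` (list of [term_set()]), and `truth`
#'   (`data.frame`: `term_id`, `size`, `dx`, `dy`, `null`).
#' @export
simulate_table <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_rows
    ids <- sprintf("G%05d", seq_len(n))
    mu <- if (spec$background == "lognormal") 7 else 0
    x <- stats::rnorm(n)
    y <- spec$rho * x + sqrt(1 - spec$rho^2) * stats::rnorm(n)

    n_planted <- if (is.null(spec$planted)) 0L else nrow(spec$planted)
    n_null <- spec$n_terms - n_planted
    truth <- data.frame(
      term_id = character(0), size = integer(0),
      dx = numeric(0), dy = numeric(0), null = logical(0),
      stringsAsFactors = FALSE)
    terms <- list()

    if (n_planted > 0L) {
      for (i in seq_len(n_planted)) {
        p <- spec$planted[i, ]
        members <- sample(ids, p$size)
        rows <- match(members, ids)
        x[rows] <- x[rows] + p$dx
        y[rows] <- y[rows] + p$dy
        terms[[length(terms) + 1L]] <-
          term_set(p$term_id, members, category = "planted")
        truth <- rbind(truth, data.frame(
          term_id = p$term_id, size = p$size, dx = p$dx, dy = p$dy,
          null = FALSE, stringsAsFactors = FALSE))
      }
    }
    if (n_null > 0L) {
      sizes <- sample(spec$term_size_range[1]:spec$term_size_range[2],
                      n_null, replace = TRUE)
      for (i in seq_len(n_null)) {
        tid <- sprintf("NULL%04d", i)
        terms[[length(terms) + 1L]] <-
          term_set(tid, sample(ids, sizes[i]), category = "null")
        truth <- rbind(truth, data.frame(
          term_id = tid, size = sizes[i], dx = 0, dy = 0, null = TRUE,
          stringsAsFactors = FALSE))
      }
    }

    tab <- data.frame(x = mu + x, y = mu + y, row.names = ids)
    if (spec$missing_frac > 0) {
      for (col in c("x", "y")) {
        miss <- stats::runif(n) < spec$missing_frac
        tab[[col]][miss] <- NA_real_
      }
    }
    list(table = tab, terms = terms, truth = truth)
  })
}

#' Simulate a peptide-protein identification map
#'
#' Builds a peptide-to-protein map with known ground truth for exercising
#' [group_proteins()]: when at least four proteins are requested, proteins 1
#' and 2 are forced to have identical peptide sets and protein 3's set is
#' forced to be a strict subset of protein 4's; the remaining proteins get
#' private peptides plus, at `sharing_rate`, peptides shared with one other
#' protein.
#'
#' @param n_proteins Number of proteins (at least 1).
#' @param sharing_rate Probability in `[0, 1]` that a protein contributes a
#'   shared peptide.
#' @param seed Integer seed.
#' @return Named list mapping each peptide to its protein accessions, with
#'   attribute `truth` (`data.frame`: `accession`, `role` in
#'   `identical_pair`, `subset`, `superset`, `free`).
#' @export
simulate_peptide_map <- function(n_proteins = 12, sharing_rate = 0.2,
                                 seed = 1) {
  if (n_proteins < 1) stop("'n_proteins' must be at least 1", call. = FALSE)
  if (sharing_rate < 0 || sharing_rate > 1) {
    stop("'sharing_rate' must be in [0, 1]", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    accs <- sprintf("PROT%03d", seq_len(n_proteins))
    role <- rep("free", n_proteins)
    pep_of <- vector("list", n_proteins)
    names(pep_of) <- accs
    pep_counter <- 0L
    new_peps <- function(k) {
      p <- sprintf("pep%04d", pep_counter + seq_len(k))
      pep_counter <<- pep_counter + k
      p
    }
    forced <- n_proteins >= 4L
    if (forced) {
      shared_set <- new_peps(3L)
      pep_of[[1]] <- shared_set
      pep_of[[2]] <- shared_set
      role[1:2] <- "identical_pair"
      super <- new_peps(4L)
      pep_of[[4]] <- super
      pep_of[[3]] <- sort(sample(super, 2L))
      role[3] <- "subset"
      role[4] <- "superset"
    }
    start <- if (forced) 5L else 1L
    for (i in seq(from = start, length.out = max(0L, n_proteins - start + 1L))) {
      pep_of[[i]] <- new_peps(sample(3:8, 1L))
      if (stats::runif(1) < sharing_rate && i > start) {
        donor <- sample(seq(start, i - 1L), 1L)
        pep_of[[i]] <- c(pep_of[[i]], sample(pep_of[[donor]], 1L))
      }
    }
    peptides <- unlist(pep_of, use.names = FALSE)
    proteins <- rep(accs, lengths(pep_of))
    map <- lapply(split(proteins, peptides), unique)
    attr(map, "truth") <- data.frame(accession = accs, role = role,
                                     stringsAsFactors = FALSE)
    map
  })
}
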