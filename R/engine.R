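# Orchestration: run the 1D or 2D test over every term of every category,
# adjust for multiple testing, truncate, and emit result records.

#' Read a quantitative table from TSV
#'
#' Expects a tab-separated file whose first column holds unique protein-group
#' identifiers and whose remaining columns are numeric (log-scale) values;
#' empty cells and `NA`/`NaN` are treated as missing.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` of numeric columns with the identifiers as row names.
#' @export
read_quant_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           na.strings = c("", "NA", "NaN"))
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate row identifiers in %s", path), call. = FALSE)
  }
  tab <- tab[, -1, drop = FALSE]
  for (j in seq_along(tab)) tab[[j]] <- as.numeric(tab[[j]])
  rownames(tab) <- ids
  tab
}

#' Write a quantitative table to TSV
#'
#' @param table `data.frame` or matrix with row-name identifiers.
#' @param path Output path.
#' @param id_name Header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(table, path, id_name = "id") {
  out <- data.frame(rownames(table), as.data.frame(table),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[1] <- id_name
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Match each term's members against the retained (non-missing) rows once.
# Returns integer index vectors into the retained rows.
term_row_indices <- function(terms, ids) {
  lookup <- seq_along(ids)
  names(lookup) <- ids
  lapply(terms, function(ts) {
    idx <- lookup[ts$members]
    as.integer(idx[!is.na(idx)])
  })
}

finalize_records <- function(rec, fdr, adjust) {
  tested <- rec$status == "tested"
  rec$q <- NA_real_
  if (any(tested)) {
    if (adjust == "pooled") {
      rec$q[tested] <- bh_fdr(rec$p[tested], q = fdr)$q_values
    } else {
      for (cat in unique(rec$category[tested])) {
        sel <- tested & rec$category == cat
        rec$q[sel] <- bh_fdr(rec$p[sel], q = fdr)$q_values
      }
    }
  }
  rec[order(rec$p, rec$term, na.last = TRUE), , drop = FALSE]
}

#' 1D annotation enrichment
#'
#' Tests every annotation term for a systematic shift of its members within
#' the distribution of a single quantitative column, using the two-sided
#' Wilcoxon-Mann-Whitney test on ranks ([wmw_test()]) plus the directional
#' position score ([score_1d()]). Rows with a missing value in the column are
#' ignored; ranks are computed once on the retained rows, so the complement
#' of every term is always the measured population itself, never the whole
#' genome. p-values are Benjamini-Hochberg adjusted across all tested terms.
#'
#' @param table Numeric `data.frame`/matrix with row-name identifiers
#'   (see [read_quant_table()]).
#' @param column Name of the column to analyse.
#' @param terms List of [term_set()] objects; terms without any member in
#'   the table are dropped.
#' @param min_size Minimum number of members present among the retained rows
#'   for a term to be tested (default 2; 1 is allowed).
#' @param sides Sidedness of the test; `"two"` (default), `"greater"`,
#'   `"less"`.
#' @param fdr FDR threshold recorded with the run (default 0.02); used by
#'   [truncate_records()] downstream, not to drop rows here.
#' @param adjust `"pooled"` (default) adjusts across all categories jointly;
#'   `"per-category"` adjusts within each category.
#' @return `data.frame` with one row per term — `category`, `term`, `size`
#'   (members among retained rows), `p`, `q`, `s`, `status`
#'   (`"tested"` or `"skipped_small"`) — ordered by ascending `p`, then term.
#' @examples
#' set.seed(1)
#' tab <- data.frame(ratio = rnorm(60), row.names = sprintf("P%02d", 1:60))
#' tab$ratio[1:10] <- tab$ratio[1:10] + 3
#' ts <- list(term_set("shifted", sprintf("P%02d", 1:10), "demo"),
#'            term_set("null", sprintf("P%02d", 31:40), "demo"))
#' enrich_1d(tab, "ratio", ts)
#' @export
enrich_1d <- function(table, column, terms, min_size = 2,
                      sides = c("two", "greater", "less"), fdr = 0.02,
                      adjust = c("pooled", "per-category")) {
  sides <- match.arg(sides)
  adjust <- match.arg(adjust)
  if (min_size < 1) stop("'min_size' must be at least 1", call. = FALSE)
  table <- as.data.frame(table)
  if (!column %in% names(table)) {
    stop(sprintf("column '%s' not found in the table", column), call. = FALSE)
  }
  values <- as.numeric(table[[column]])
  keep <- !is.na(values)
  if (sum(keep) < 3L) {
    stop("fewer than 3 non-missing rows in the requested column",
         call. = FALSE)
  }
  ids <- rownames(table)[keep]
  ranks <- rank_transform(values[keep])
  n <- length(ids)

  terms <- filter_terms_to_measured(terms, rownames(table))
  if (length(terms) == 0L) {
    warning("no term has members among the table's row identifiers",
            call. = FALSE)
    return(data.frame(category = character(0), term = character(0),
                      size = integer(0), p = numeric(0), q = numeric(0),
                      s = numeric(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  idx_list <- term_row_indices(terms, ids)

  rec <- data.frame(
    category = vapply(terms, `[[`, character(1), "category"),
    term = vapply(terms, `[[`, character(1), "term_id"),
    size = lengths(idx_list),
    p = NA_real_, q = NA_real_, s = NA_real_,
    status = "skipped_small",
    stringsAsFactors = FALSE)

  for (i in seq_along(terms)) {
    n1 <- rec$size[i]
    if (n1 < min_size || n1 > n - 1L) next
    mask <- logical(n)
    mask[idx_list[[i]]] <- TRUE
    res <- wmw_test(mask, ranks, sides = sides)
    rec$p[i] <- res$p
    rec$s[i] <- score_1d(res$stats)
    rec$status[i] <- "tested"
  }
  finalize_records(rec, fdr, adjust)
}

#' 2D annotation enrichment
#'
#' Tests every annotation term for a deviation of its members from the joint
#' distribution of two quantitative columns (e.g. protein ratio versus mRNA
#' ratio), using the two-group MANOVA on coordinate-wise ranks
#' ([manova2d_test()]); each term receives a directional score pair
#' `(sx, sy)` ([score_2d()]). Rows missing in either column are dropped
#' (pairwise-complete) before ranking. FDR control is Benjamini-Hochberg, as
#' in the 1D case.
#'
#' @inheritParams enrich_1d
#' @param col_x,col_y Names of the two columns to analyse jointly.
#' @param min_size Minimum members among retained rows (default 2; the 2D
#'   test needs at least 2 per group, so values below 2 are rejected).
#' @return `data.frame` with columns `category`, `term`, `size`, `p`, `q`,
#'   `sx`, `sy`, `status` (`"tested"`, `"skipped_small"` or `"singular"`),
#'   ordered by ascending `p`, then term.
#' @export
enrich_2d <- function(table, col_x, col_y, terms, min_size = 2, fdr = 0.02,
                      adjust = c("pooled", "per-category")) {
  adjust <- match.arg(adjust)
  if (min_size < 2) {
    stop("'min_size' must be at least 2 for the 2D test", call. = FALSE)
  }
  table <- as.data.frame(table)
  for (col in c(col_x, col_y)) {
    if (!col %in% names(table)) {
      stop(sprintf("column '%s' not found in the table", col), call. = FALSE)
    }
  }
  x <- as.numeric(table[[col_x]])
  y <- as.numeric(table[[col_y]])
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 5L) {
    stop("fewer than 5 pairwise-complete rows in the requested columns",
         call. = FALSE)
  }
  ids <- rownames(table)[keep]
  ranks_x <- rank_transform(x[keep])
  ranks_y <- rank_transform(y[keep])
  n <- length(ids)

  terms <- filter_terms_to_measured(terms, rownames(table))
  if (length(terms) == 0L) {
    warning("no term has members among the table's row identifiers",
            call. = FALSE)
    return(data.frame(category = character(0), term = character(0),
                      size = integer(0), p = numeric(0), q = numeric(0),
                      sx = numeric(0), sy = numeric(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  idx_list <- term_row_indices(terms, ids)

  rec <- data.frame(
    category = vapply(terms, `[[`, character(1), "category"),
    term = vapply(terms, `[[`, character(1), "term_id"),
    size = lengths(idx_list),
    p = NA_real_, q = NA_real_, sx = NA_real_, sy = NA_real_,
    status = "skipped_small",
    stringsAsFactors = FALSE)

  for (i in seq_along(terms)) {
    n1 <- rec$size[i]
    if (n1 < min_size || n1 > n - 2L) next
    mask <- logical(n)
    mask[idx_list[[i]]] <- TRUE
    res <- tryCatch(manova2d_test(mask, ranks_x, ranks_y),
                    enrich2d_singular = function(e) e)
    if (inherits(res, "enrich2d_singular")) {
      rec$status[i] <- "singular"
      next
    }
    sc <- score_2d(two_group_rank_stats(mask, ranks_x),
                   two_group_rank_stats(mask, ranks_y))
    rec$p[i] <- res$p_value
    rec$sx[i] <- sc[["sx"]]
    rec$sy[i] <- sc[["sy"]]
    rec$status[i] <- "tested"
  }
  finalize_records(rec, fdr, adjust)
}

#' Truncate an enrichment result to the significant terms
#'
#' Terminates the list of hits either at a raw p-value threshold or at a
#' Benjamini-Hochberg FDR. The threshold is always a fraction in the open
#' interval (0, 1), never a percentage.
#'
#' @param records Result `data.frame` from [enrich_1d()] or [enrich_2d()].
#' @param mode `"fdr"` (keep `q <= threshold`, default) or `"pvalue"`
#'   (keep `p <= threshold`).
#' @param threshold Numeric threshold in (0, 1).
#' @return The filtered records (untested terms are dropped); idempotent.
#' @export
truncate_records <- function(records, mode = c("fdr", "pvalue"),
                             threshold = 0.02) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0 || threshold >= 1) {
    stop("'threshold' must be a single value strictly between 0 and 1",
         call. = FALSE)
  }
  crit <- if (mode == "fdr") records$q else records$p
  records[!is.na(crit) & crit <= threshold, , drop = FALSE]
}

#' Write enrichment records to TSV
#'
#' One row per term: `category`, `term`, `size`, `p`, `q`, the score
#' column(s), and `status`. Output ordering follows the record order
#' (ascending p), so identical runs produce byte-identical files.
#'
#' @param records Result `data.frame` from [enrich_1d()] or [enrich_2d()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Scatter plot of 2D enrichment score pairs
#'
#' Displays every significant term at its `(sx, sy)` score pair inside the
#' unit square: terms near the diagonal change concordantly in both
#' dimensions, terms near an axis change in one dimension only, and terms in
#' the off-diagonal quadrants change in opposite directions.
#'
#' @param records Result `data.frame` from [enrich_2d()], typically after
#'   [truncate_records()].
#' @param label Add term labels at the points (default `TRUE`).
#' @param file Optional path; when it ends in `.svg` and cairo is available
#'   the plot is also written as SVG.
#' @return A `ggplot` object, invisibly when `file` is given.
#' @export
plot_scores_2d <- function(records, label = TRUE, file = NULL) {
  records <- records[!is.na(records$sx) & !is.na(records$sy), , drop = FALSE]
  p <- ggplot2::ggplot(records, ggplot2::aes(x = .data$sx, y = .data$sy,
                                             colour = .data$category)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         colour = "grey90", linetype = 2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_cartesian(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "score x", y = "score y") +
    ggplot2::theme_minimal()
  if (label && nrow(records) > 0L) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$term),
                                vjust = -0.8, size = 3, show.legend = FALSE)
  }
  if (!is.null(file)) {
    if (!grepl("\\.svg$", file) || !isTRUE(capabilities("cairo"))) {
      stop("'file' must end in .svg and cairo must be available",
           call. = FALSE)
    }
    grDevices::svg(file, width = 7, height = 6)
    on.exit(grDevices::dev.off())
    print(p)
    return(invisible(p))
  }
  p
}
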