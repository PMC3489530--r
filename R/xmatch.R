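# Protein grouping by peptide parsimony and matching of protein groups to
# probe-level transcriptome and CGH data, plus log-transform preprocessing.

#' Construct a protein group
#'
#' @param group_id Group identifier (by convention the leading accession).
#' @param members `data.frame` with columns `accession` and `peptide_count`,
#'   sorted by descending peptide count (ties by accession).
#' @param peptides Character vector of all peptides identified in the group.
#' @param razor_peptides Character vector of peptides assigned to this group
#'   by the razor (parsimony) rule; a subset of `peptides`.
#' @return A `protein_group` object.
#' @export
protein_group <- function(group_id, members, peptides,
                          razor_peptides = peptides) {
  stopifnot(is.data.frame(members),
            all(c("accession", "peptide_count") %in% names(members)))
  ord <- order(-members$peptide_count, members$accession)
  members <- members[ord, , drop = FALSE]
  rownames(members) <- NULL
  structure(
    list(group_id = as.character(group_id), members = members,
         peptides = unique(as.character(peptides)),
         razor_peptides = unique(as.character(razor_peptides))),
    class = "protein_group")
}

#' @export
print.protein_group <- function(x, ...) {
  cat(sprintf("<protein_group> %s: %d proteins, %d peptides (%d razor)\n",
              x$group_id, nrow(x$members), length(x$peptides),
              length(x$razor_peptides)))
  invisible(x)
}

#' Collapse proteins into protein groups by peptide parsimony
#'
#' Proteins that cannot be distinguished by the identified peptides are
#' collapsed into protein groups: proteins with identical peptide sets are
#' merged, and a protein whose peptide set is completely contained in the
#' peptide set of another protein is merged into that protein's group.
#' Within a group, proteins are sorted by descending number of identified
#' peptides, the leading protein first. Peptides still shared between
#' distinct groups are then razor-assigned, by Occam's razor, to the group
#' that already has the most peptide identifications; ties are broken by
#' lexicographically smallest group id so runs are reproducible.
#'
#' @param peptide_map Named list mapping each peptide sequence to the
#'   character vector of protein accessions it matches.
#' @return A list of [protein_group()] objects, ordered by group id. Every
#'   input peptide appears in exactly one group's `razor_peptides`.
#' @export
group_proteins <- function(peptide_map) {
  if (length(peptide_map) == 0L || is.null(names(peptide_map))) {
    stop("'peptide_map' must be a non-empty named list (peptide -> proteins)",
         call. = FALSE)
  }
  # invert to protein -> peptide set
  peptides <- rep(names(peptide_map), lengths(peptide_map))
  proteins <- unlist(peptide_map, use.names = FALSE)
  pep_of <- lapply(split(peptides, proteins), unique)

  # 1. merge proteins with identical peptide sets
  set_key <- vapply(pep_of, function(p) paste(sort(p), collapse = "\r"),
                    character(1))
  clusters <- split(names(pep_of), set_key)
  clusters <- lapply(clusters, sort)
  cl_peps <- lapply(clusters, function(cl) pep_of[[cl[1]]])

  # 2. merge clusters whose peptide set is a subset of another cluster's set;
  #    when several supersets exist, take the largest (tie: smallest leading
  #    accession) for determinism
  sizes <- lengths(cl_peps)
  leads <- vapply(clusters, `[`, character(1), 1L)
  ord <- order(-sizes, leads)
  clusters <- clusters[ord]; cl_peps <- cl_peps[ord]; sizes <- sizes[ord]
  parent <- seq_along(clusters)
  for (i in seq_along(clusters)) {
    for (j in seq_len(i - 1L)) {
      if (sizes[j] > sizes[i] && all(cl_peps[[i]] %in% cl_peps[[j]])) {
        parent[i] <- j
        break  # clusters are sorted, so the first hit is the largest superset
      }
    }
  }
  groups <- lapply(which(parent == seq_along(parent)), function(root) {
    accs <- unlist(clusters[parent == root], use.names = FALSE)
    members <- data.frame(
      accession = accs,
      peptide_count = lengths(pep_of[accs]),
      stringsAsFactors = FALSE)
    peps <- unique(unlist(pep_of[accs], use.names = FALSE))
    protein_group(group_id = NA, members = members, peptides = peps)
  })
  for (i in seq_along(groups)) {
    groups[[i]]$group_id <- groups[[i]]$members$accession[1]
  }

  # 3. razor-assign every peptide to exactly one group
  group_ids <- vapply(groups, `[[`, character(1), "group_id")
  group_sizes <- vapply(groups, function(g) length(g$peptides), integer(1))
  ord <- order(group_ids)
  groups <- groups[ord]; group_ids <- group_ids[ord]
  group_sizes <- group_sizes[ord]
  owner <- character(0)
  for (i in seq_along(groups)) {
    for (pep in groups[[i]]$peptides) {
      cur <- owner[pep]
      if (is.na(cur) || length(cur) == 0L ||
          group_sizes[i] > group_sizes[match(cur, group_ids)]) {
        owner[pep] <- group_ids[i]
      }
      # on ties the earlier (lexicographically smaller) group id keeps it
    }
  }
  for (i in seq_along(groups)) {
    groups[[i]]$razor_peptides <-
      groups[[i]]$peptides[owner[groups[[i]]$peptides] == group_ids[i]]
  }
  groups
}

#' Read a peptide-protein map from a two-column TSV
#'
#' Expects a headerless `peptide <TAB> accession` table, one identification
#' per line.
#'
#' @param path Path to the TSV file.
#' @return Named list mapping each peptide to its protein accessions, as
#'   consumed by [group_proteins()].
#' @export
read_peptide_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           blank.lines.skip = TRUE)
  if (ncol(tab) < 2L) {
    stop(sprintf("peptide map %s must have two tab-separated columns", path),
         call. = FALSE)
  }
  lapply(split(tab[[2]], tab[[1]]), unique)
}

#' Log-transform quantitative values
#'
#' Expression values — ratios as well as abundances — should be analysed on
#' log scale: the arithmetic mean of a two-fold up- and a two-fold
#' down-regulation is `(2 + 1/2)/2 = 1.25`, not the expected no-change, while
#' the mean of the base-2 logarithms is exactly 0. The same argument applies
#' to medians, whose computation averages the two central values when the
#' count is even. Base 2 is customary for ratio data, base 2 or 10 for
#' abundances.
#'
#' @param values Numeric vector; non-positive or non-finite entries cannot be
#'   log-transformed and become `NA` (counted in a single warning).
#' @param base Logarithm base, 2 (default) or 10.
#' @return Numeric vector of logarithms, same length as the input.
#' @export
log_transform <- function(values, base = 2) {
  if (!base %in% c(2, 10)) {
    stop("'base' must be 2 or 10", call. = FALSE)
  }
  values <- as.numeric(values)
  bad <- !is.na(values) & (!is.finite(values) | values <= 0)
  if (any(bad)) {
    warning(sprintf("%d non-positive value(s) set to NA before log transform",
                    sum(bad)), call. = FALSE)
    values[bad] <- NA_real_
  }
  log(values, base = base)
}

#' Match a protein group to probe-level quantitative profiles
#'
#' Takes the protein-centric view: every probe whose annotated protein
#' identifiers intersect the group's member accessions is collected. With no
#' matching probe the group cannot be compared and `NULL` is returned; with
#' one probe its profile is used directly; with several, the point-wise
#' (column-wise) median of their profiles is taken. Profiles are expected on
#' log scale, so the median's averaging of two central values behaves
#' correctly.
#'
#' @param group A [protein_group()].
#' @param mapping A list with `probe_to_proteins` (named list: probe id ->
#'   protein identifiers) and `profiles` (numeric matrix, rows = probe ids,
#'   shared column schema).
#' @param strip_isoforms Strip isoform suffixes from group members before
#'   matching (default `TRUE`).
#' @return Named numeric vector (one value per profile column), or `NULL`
#'   when no probe matches.
#' @export
match_probesets <- function(group, mapping, strip_isoforms = TRUE) {
  stopifnot(inherits(group, "protein_group"),
            is.list(mapping$probe_to_proteins), is.matrix(mapping$profiles))
  accs <- group$members$accession
  if (strip_isoforms) accs <- strip_isoform(accs)
  hit <- vapply(mapping$probe_to_proteins,
                function(p) any(p %in% accs), logical(1))
  probes <- names(mapping$probe_to_proteins)[hit]
  probes <- probes[probes %in% rownames(mapping$profiles)]
  if (length(probes) == 0L) {
    return(NULL)
  }
  prof <- mapping$profiles[probes, , drop = FALSE]
  if (nrow(prof) == 1L) {
    return(prof[1, ])
  }
  apply(prof, 2, stats::median, na.rm = TRUE)
}

#' Collapse CGH probe copy numbers onto protein-coding genes
#'
#' Each array-CGH hybridization probe is associated with the closest
#' protein-coding gene on its chromosome: a probe falling inside a gene
#' interval is assigned to that gene; otherwise the gene whose interval
#' midpoint is nearest is used, with distance ties resolved toward the gene
#' at the lower coordinate. All copy numbers sharing a nearest gene are
#' combined by their median. Intervals are 0-based half-open.
#'
#' @param probes `data.frame` with columns `chrom`, `pos`, `value`.
#' @param genes `data.frame` with columns `chrom`, `start`, `end`, `gene_id`.
#' @return Named numeric vector: per-gene median copy number. Probes on
#'   chromosomes without any gene are dropped with a warning.
#' @export
collapse_cgh <- function(probes, genes) {
  stopifnot(all(c("chrom", "pos", "value") %in% names(probes)),
            all(c("chrom", "start", "end", "gene_id") %in% names(genes)))
  dropped <- 0L
  assign_gene <- character(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    g <- genes[genes$chrom == probes$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) {
      assign_gene[i] <- NA_character_
      dropped <- dropped + 1L
      next
    }
    pos <- probes$pos[i]
    inside <- g$start <= pos & pos < g$end
    cand <- if (any(inside)) g[inside, , drop = FALSE] else g
    mid <- (cand$start + cand$end) / 2
    d <- abs(pos - mid)
    best <- which(d == min(d))
    if (length(best) > 1L) {
      best <- best[which.min(cand$start[best])]
    }
    assign_gene[i] <- cand$gene_id[best]
  }
  if (dropped > 0L) {
    warning(sprintf("%d probe(s) dropped: no gene on their chromosome",
                    dropped), call. = FALSE)
  }
  keep <- !is.na(assign_gene)
  vapply(split(probes$value[keep], assign_gene[keep]), stats::median,
         numeric(1))
}
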