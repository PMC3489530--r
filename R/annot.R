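# Annotation sources: GMT and id->term tables, per-row categorical
# columns, and the rule deciding which terms a protein group carries.

#' Construct an annotation term
#'
#' @param term_id Term identifier, unique within its category.
#' @param members Character vector of member protein/gene identifiers;
#'   duplicates are removed.
#' @param category Annotation category the term belongs to (e.g. `"GOBP"`,
#'   `"GOCC"`, `"KEGG"`, `"Pfam"`, `"Corum"`, `"Chromosome"`).
#' @param description Optional free-text description.
#' @return A `term_set` object.
#' @export
term_set <- function(term_id, members, category = "Annotation",
                     description = "") {
  members <- unique(as.character(members))
  members <- members[!is.na(members) & nzchar(members)]
  if (length(members) == 0L) {
    stop("a term must have at least one member", call. = FALSE)
  }
  structure(
    list(term_id = as.character(term_id), category = as.character(category),
         description = as.character(description), members = members),
    class = "term_set")
}

#' @export
print.term_set <- function(x, ...) {
  cat(sprintf("<term_set> %s [%s]: %d members\n",
              x$term_id, x$category, length(x$members)))
  invisible(x)
}

#' Read annotation terms from a GMT file
#'
#' Parses the Broad GMT dialect: one term per line, tab-separated as
#' `term <TAB> description <TAB> member1 <TAB> member2 ...`. Duplicate member
#' identifiers within a line are removed.
#'
#' @param path Path to the GMT file.
#' @param category Category label attached to every term from this file;
#'   defaults to the file name without extension.
#' @return A list of [term_set()] objects (empty list for an empty file).
#' @export
parse_gmt <- function(path, category = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("annotation file not found: %s", path), call. = FALSE)
  }
  if (is.null(category)) {
    category <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (length(fields) < 3L || !nzchar(fields[1]) || length(members) == 0L) {
      stop(sprintf("malformed GMT line %d in %s: need term, description and at least one member",
                   i, path), call. = FALSE)
    }
    out[[i]] <- term_set(fields[1], members, category = category,
                         description = fields[2])
  }
  out
}

#' Write annotation terms to a GMT file
#'
#' Inverse of [parse_gmt()]; a parse -> write -> parse round trip preserves
#' term ids, descriptions and member sets.
#'
#' @param terms List of [term_set()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(terms, function(ts) {
    paste(c(ts$term_id, ts$description, ts$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read annotation terms from a two-column id/term table
#'
#' Accepts a headerless tab-separated file with one `identifier <TAB> term`
#' pair per line and inverts it into term member sets.
#'
#' @param path Path to the TSV file.
#' @param category Category label for all terms; defaults to the file name.
#' @return A list of [term_set()] objects.
#' @export
parse_id_term_tsv <- function(path, category = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("annotation file not found: %s", path), call. = FALSE)
  }
  if (is.null(category)) {
    category <- sub("\\.[^.]*$", "", basename(path))
  }
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           blank.lines.skip = TRUE)
  if (ncol(tab) < 2L) {
    stop(sprintf("id/term table %s must have two tab-separated columns", path),
         call. = FALSE)
  }
  parse_categorical_column(tab[[1]], tab[[2]], category = category)
}

#' Invert a per-row categorical column into term member sets
#'
#' Matrix-style annotation: each row (identifier) carries a
#' semicolon-separated list of terms; this inverts the row-to-terms mapping
#' into one member set per term. Empty cells contribute nothing.
#'
#' @param ids Character vector of row identifiers.
#' @param column Character vector of semicolon-separated term strings,
#'   aligned to `ids`.
#' @param category Category label for the resulting terms.
#' @return A list of [term_set()] objects, ordered by term id.
#' @export
parse_categorical_column <- function(ids, column, category = "Annotation") {
  ids <- as.character(ids)
  column <- as.character(column)
  if (length(ids) != length(column)) {
    stop("'ids' and 'column' must have the same length", call. = FALSE)
  }
  column[is.na(column)] <- ""
  per_row <- strsplit(column, ";", fixed = TRUE)
  terms <- trimws(unlist(per_row, use.names = FALSE))
  row_of <- rep(ids, lengths(per_row))
  keep <- nzchar(terms)
  terms <- terms[keep]
  row_of <- row_of[keep]
  if (length(terms) == 0L) {
    return(list())
  }
  members_by_term <- split(row_of, terms)
  lapply(names(members_by_term)[order(names(members_by_term))], function(tid) {
    term_set(tid, members_by_term[[tid]], category = category)
  })
}

#' Normalize protein identifiers for annotation lookup
#'
#' Strips UniProt isoform suffixes (`"P12345-2"` becomes `"P12345"`) so that
#' isoform-level accessions hit gene-level annotation entries.
#'
#' @param ids Character vector of accessions.
#' @return Character vector with isoform suffixes removed.
#' @export
strip_isoform <- function(ids) {
  sub("-[0-9]+$", "", as.character(ids))
}

#' Select the annotation terms carried by a protein group
#'
#' A protein group mixes proteins supported by many peptides with proteins
#' that joined the group on a single shared peptide. Taking only the leading
#' protein's annotation can miss terms carried by a shorter or activated
#' form; taking every member's annotation picks up spurious terms from
#' weakly supported members. The compromise implemented here is to pool the
#' annotation of every member whose peptide count is at least half that of
#' the leading protein (the member with the maximal count), using real-valued
#' comparison: a 5-peptide member passes against a 10-peptide leader.
#'
#' @param group A [protein_group()] (members sorted by descending peptide
#'   count; the leading protein first).
#' @param per_protein_terms Named list mapping a protein accession to the
#'   character vector of terms it carries (any encoding, e.g.
#'   `"GOCC:ribosome"`).
#' @param strip_isoforms If `TRUE` (default), isoform suffixes are stripped
#'   from group member accessions before lookup.
#' @return A `group_annotation` list with `group_id` and the pooled sorted
#'   character vector `terms`.
#' @export
select_group_terms <- function(group, per_protein_terms,
                               strip_isoforms = TRUE) {
  if (!inherits(group, "protein_group")) {
    stop("'group' must be a protein_group", call. = FALSE)
  }
  counts <- group$members$peptide_count
  if (length(counts) == 0L) {
    stop("empty protein group", call. = FALSE)
  }
  threshold <- max(counts) / 2
  use <- group$members$accession[counts >= threshold]
  keys <- if (strip_isoforms) strip_isoform(use) else use
  terms <- unique(unlist(per_protein_terms[unique(keys)], use.names = FALSE))
  terms <- sort(terms[!is.na(terms)])
  structure(list(group_id = group$group_id, terms = terms),
            class = "group_annotation")
}

#' Drop terms without members in a measured table
#'
#' Enrichment is based entirely on the measured population: terms from the
#' annotation source that have no member among the table's row identifiers
#' carry no information and are removed before testing.
#'
#' @param terms List of [term_set()] objects.
#' @param ids Character vector of measured row identifiers.
#' @return The filtered term list.
#' @export
filter_terms_to_measured <- function(terms, ids) {
  ids <- as.character(ids)
  Filter(function(ts) any(ts$members %in% ids), terms)
}
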