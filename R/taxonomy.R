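# Ranked-lineage handling for GTDB-style taxonomy strings
# (d__Domain;p__Phylum;c__Class;o__Order;f__Family;g__Genus).

GTDB_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")
GTDB_PREFIXES <- c("d__", "p__", "c__", "o__", "f__", "g__")

new_ranked_lineage <- function(values) {
  stopifnot(is.character(values), length(values) == length(GTDB_RANKS))
  names(values) <- GTDB_RANKS
  structure(values, class = "ranked_lineage")
}

#' Parse a GTDB-style lineage string
#'
#' Parses a semicolon-delimited, rank-prefixed taxonomy string into a
#' `ranked_lineage`: a named character vector over the six ranks
#' domain, phylum, class, order, family, genus, with `NA` for absent ranks.
#' Ranks must be filled contiguously from domain downward; an empty suffix
#' after a prefix (e.g. `"g__"`) yields a missing rank. Names are compared as
#' exact strings after whitespace trimming throughout the package; GTDB
#' placeholder codes (e.g. `"UBA7541"`) are ordinary names.
#'
#' @param text A single non-empty character string, e.g.
#'   `"d__Bacteria;p__Acidobacteriota;c__Terriglobia"`.
#' @return A `ranked_lineage` object.
#' @examples
#' lin <- parse_lineage("d__Bacteria;p__Acidobacteriota;c__Terriglobia")
#' lineage_at_rank(lin, "class")
#' format(lin)
#' @export
parse_lineage <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("lineage string must be a single non-empty character value",
         call. = FALSE)
  }
  tokens <- trimws(strsplit(text, ";", fixed = TRUE)[[1L]])
  if (!length(tokens)) {
    stop("lineage string contains no rank tokens", call. = FALSE)
  }
  idx <- match(substr(tokens, 1L, 3L), GTDB_PREFIXES)
  if (anyNA(idx)) {
    stop(sprintf("unknown rank prefix in token '%s'",
                 tokens[which(is.na(idx))[1L]]), call. = FALSE)
  }
  if (anyDuplicated(idx)) {
    stop(sprintf("duplicate rank in token '%s'",
                 tokens[which(duplicated(idx))[1L]]), call. = FALSE)
  }
  if (is.unsorted(idx, strictly = TRUE)) {
    bad <- which(diff(idx) < 0)[1L] + 1L
    stop(sprintf("out-of-order rank token '%s'", tokens[bad]), call. = FALSE)
  }
  if (!identical(idx, seq_along(idx))) {
    skipped <- setdiff(seq_len(max(idx)), idx)[1L]
    offending <- tokens[which(idx > skipped)[1L]]
    stop(sprintf("rank '%s' skipped before token '%s'",
                 GTDB_RANKS[skipped], offending), call. = FALSE)
  }
  vals <- rep(NA_character_, length(GTDB_RANKS))
  nm <- trimws(substring(tokens, 4L))
  nm[!nzchar(nm)] <- NA_character_
  vals[idx] <- nm
  filled <- which(!is.na(vals))
  if (!length(filled)) {
    stop("lineage has no named ranks", call. = FALSE)
  }
  if (!identical(filled, seq_along(filled))) {
    stop(sprintf("rank '%s' is filled below a missing rank",
                 GTDB_RANKS[max(filled)]), call. = FALSE)
  }
  new_ranked_lineage(vals)
}

#' @export
format.ranked_lineage <- function(x, ...) {
  v <- unclass(x)
  d <- sum(!is.na(v))
  paste0(GTDB_PREFIXES[seq_len(d)], v[seq_len(d)], collapse = ";")
}

#' @export
print.ranked_lineage <- function(x, ...) {
  cat("<ranked_lineage> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.ranked_lineage <- function(x, ...) format(x)

#' Depth of a ranked lineage
#'
#' Number of filled ranks, counting from domain (contiguity guaranteed by
#' [parse_lineage()]).
#' @param lin A `ranked_lineage`.
#' @return Integer in 1..6.
#' @export
lineage_depth <- function(lin) {
  stopifnot(inherits(lin, "ranked_lineage"))
  sum(!is.na(unclass(lin)))
}

#' Extract the name at a given rank
#'
#' @param lin A `ranked_lineage`.
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return The taxon name at that rank, or `NA_character_` if the rank is not
#'   filled.
#' @export
lineage_at_rank <- function(lin, rank) {
  stopifnot(inherits(lin, "ranked_lineage"))
  if (!is.character(rank) || length(rank) != 1L || !rank %in% GTDB_RANKS) {
    stop(sprintf("unrecognized rank '%s'; must be one of %s",
                 as.character(rank)[1L],
                 paste(GTDB_RANKS, collapse = ", ")), call. = FALSE)
  }
  unname(unclass(lin)[[rank]])
}

# Parse a character vector of lineage strings once per unique string and
# return an n x 6 character matrix of rank names (NA = missing).
lineage_matrix <- function(lineages) {
  stopifnot(is.character(lineages))
  u <- unique(lineages)
  parsed <- vapply(u, function(s) unclass(parse_lineage(s)),
                   character(length(GTDB_RANKS)))
  m <- t(parsed)
  colnames(m) <- GTDB_RANKS
  m[match(lineages, u), , drop = FALSE]
}

#' Names at a rank for a vector of lineage strings
#'
#' Vectorized projection used by the table-level statistics: every unique
#' string is parsed (and validated) once.
#'
#' @param lineages Character vector of GTDB-style lineage strings.
#' @param rank Target rank name.
#' @return Character vector of names at `rank` (`NA` where the lineage is
#'   shallower than `rank`).
#' @export
lineage_names_at_rank <- function(lineages, rank) {
  if (!rank %in% GTDB_RANKS) {
    stop(sprintf("unrecognized rank '%s'", rank), call. = FALSE)
  }
  if (!length(lineages)) return(character(0))
  lineage_matrix(lineages)[, rank]
}

# Render lineage strings truncated at `rank` from a lineage matrix.
render_truncated <- function(m, rank) {
  ridx <- match(rank, GTDB_RANKS)
  cols <- lapply(seq_len(ridx), function(j) paste0(GTDB_PREFIXES[j], m[, j]))
  do.call(paste, c(cols, sep = ";"))
}

#' Validate a detection table
#'
#' A detection table has one row per (metagenomic dataset, taxon) detection:
#' columns `dataset_id`, `habitat`, `lineage` (GTDB-style string) and
#' `relative_abundance_pct` in (0, 100]. A row's existence *is* the
#' detection, so abundances must be strictly positive; `(dataset_id,
#' lineage)` pairs must be unique and each dataset must carry exactly one
#' habitat label.
#'
#' @param table A data.frame.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_detection_table <- function(table) {
  need <- c("dataset_id", "habitat", "lineage", "relative_abundance_pct")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop(sprintf("detection table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(table)) {
    if (any(!is.finite(table$relative_abundance_pct)) ||
        any(table$relative_abundance_pct <= 0) ||
        any(table$relative_abundance_pct > 100)) {
      stop("relative_abundance_pct must lie in (0, 100]", call. = FALSE)
    }
    key <- paste(table$dataset_id, table$lineage, sep = "\r")
    if (anyDuplicated(key)) {
      stop(sprintf("duplicate (dataset_id, lineage) pair: %s",
                   sub("\r", " / ", key[duplicated(key)][1L])), call. = FALSE)
    }
    hab_per_ds <- tapply(table$habitat, table$dataset_id,
                         function(h) length(unique(h)))
    if (any(hab_per_ds > 1L)) {
      stop(sprintf("dataset '%s' carries more than one habitat label",
                   names(hab_per_ds)[hab_per_ds > 1L][1L]), call. = FALSE)
    }
  }
  invisible(table)
}

#' Aggregate a detection table to a coarser rank
#'
#' Re-expresses a detection table at class, order or family (or any other)
#' resolution: one row per (dataset, name-at-rank), with relative abundance
#' summed over the child rows of that dataset. A taxon is detected at rank
#' `r` in dataset `d` iff at least one descendant row exists, which the
#' summed row encodes (abundance sums of positive terms stay positive).
#'
#' @param table A detection table (see [validate_detection_table()]).
#' @param rank Target rank; every row's lineage must be at least this deep.
#' @return A detection table whose `lineage` strings are truncated at `rank`.
#' @examples
#' tab <- data.frame(
#'   dataset_id = "X", habitat = "soil",
#'   lineage = c("d__B;p__P;c__C;o__O;f__F1", "d__B;p__P;c__C;o__O;f__F2"),
#'   relative_abundance_pct = c(1.2, 0.8))
#' aggregate_to_rank(tab, "order")$relative_abundance_pct  # 2.0
#' @export
aggregate_to_rank <- function(table, rank) {
  validate_detection_table(table)
  if (!rank %in% GTDB_RANKS) {
    stop(sprintf("unrecognized rank '%s'", rank), call. = FALSE)
  }
  if (!nrow(table)) return(table)
  m <- lineage_matrix(table$lineage)
  shallow <- which(is.na(m[, rank]))
  if (length(shallow)) {
    stop(sprintf(
      "%d row(s) are shallower than rank '%s' (first offending rows: %s)",
      length(shallow), rank,
      paste(utils::head(shallow, 5L), collapse = ", ")), call. = FALSE)
  }
  trunc <- render_truncated(m, rank)
  key <- paste(table$dataset_id, trunc, sep = "\r")
  agg <- rowsum(table$relative_abundance_pct, group = key, reorder = TRUE)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  ds <- vapply(parts, `[[`, character(1L), 1L)
  lin <- vapply(parts, `[[`, character(1L), 2L)
  hab_map <- table$habitat[!duplicated(table$dataset_id)]
  names(hab_map) <- table$dataset_id[!duplicated(table$dataset_id)]
  out <- data.frame(
    dataset_id = ds,
    habitat = unname(hab_map[ds]),
    lineage = lin,
    relative_abundance_pct = as.numeric(agg[, 1L]),
    stringsAsFactors = FALSE)
  out <- out[order(out$dataset_id, out$lineage), , drop = FALSE]
  rownames(out) <- NULL
  out
}
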