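# Habitat breadth (generalist vs specialist) from detection or genome
# evidence, with evidence-count exclusions for rarely sampled taxa.

breadth_record <- function(taxon, rank, detected, possible, n_evidence,
                           evidence) {
  data.frame(taxon = taxon, rank = rank,
             evidence = evidence,
             n_habitats_detected = as.integer(detected),
             n_habitats_possible = as.integer(possible),
             n_evidence = as.integer(n_evidence),
             stringsAsFactors = FALSE)
}

#' Habitat breadth of a taxon from a detection table
#'
#' Counts the distinct habitat labels in which the taxon is detected at the
#' stated rank, and the distinct datasets supporting it.
#'
#' @param table A detection table.
#' @param taxon Taxon name at `rank`.
#' @param rank Rank at which to match `taxon`.
#' @param habitat_universe Declared habitat labels; defaults to the distinct
#'   labels present in `table`. Labels in `table` outside the universe are an
#'   error.
#' @return One-row data.frame: `taxon`, `rank`, `evidence` ("detections"),
#'   `n_habitats_detected`, `n_habitats_possible`, `n_evidence` (distinct
#'   datasets).
#' @export
habitat_breadth_from_detections <- function(table, taxon, rank,
                                            habitat_universe = NULL) {
  validate_detection_table(table)
  if (is.null(habitat_universe)) habitat_universe <- unique(table$habitat)
  stray <- setdiff(unique(table$habitat), habitat_universe)
  if (length(stray)) {
    stop(sprintf("unknown habitat label(s): %s",
                 paste(stray, collapse = ", ")), call. = FALSE)
  }
  if (nrow(table)) {
    at <- lineage_names_at_rank(table$lineage, rank)
    sub <- table[!is.na(at) & at == taxon, , drop = FALSE]
  } else {
    sub <- table
  }
  breadth_record(taxon, rank,
                 detected = length(unique(sub$habitat)),
                 possible = length(habitat_universe),
                 n_evidence = length(unique(sub$dataset_id)),
                 evidence = "detections")
}

#' Habitat breadth of a taxon from genome provenance
#'
#' Counts the distinct source habitats among a taxon's genomes and the
#' genome count supporting it.
#'
#' @param genomes A genome table with columns `genome_id`, `lineage`,
#'   `habitat`.
#' @inheritParams habitat_breadth_from_detections
#' @return One-row data.frame as for [habitat_breadth_from_detections()],
#'   `evidence` = "genomes", `n_evidence` = genome count.
#' @export
habitat_breadth_from_genomes <- function(genomes, taxon, rank,
                                         habitat_universe = NULL) {
  need <- c("genome_id", "lineage", "habitat")
  miss <- setdiff(need, names(genomes))
  if (length(miss)) {
    stop(sprintf("genome table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (is.null(habitat_universe)) habitat_universe <- unique(genomes$habitat)
  stray <- setdiff(unique(genomes$habitat), habitat_universe)
  if (length(stray)) {
    stop(sprintf("unknown habitat label(s): %s",
                 paste(stray, collapse = ", ")), call. = FALSE)
  }
  if (nrow(genomes)) {
    at <- lineage_names_at_rank(genomes$lineage, rank)
    sub <- genomes[!is.na(at) & at == taxon, , drop = FALSE]
  } else {
    sub <- genomes
  }
  breadth_record(taxon, rank,
                 detected = length(unique(sub$habitat)),
                 possible = length(habitat_universe),
                 n_evidence = nrow(sub),
                 evidence = "genomes")
}

#' Classify a breadth record as generalist / specialist
#'
#' A record below the evidence cutoff is `indeterminate` (rarely sampled
#' taxa are otherwise erroneously called specialists). Otherwise, under
#' `"strict-all-habitats"` a generalist must be detected in every declared
#' habitat; under `"at-least-k"` in at least `k` habitats. A taxon confined
#' to exactly one habitat is a `specialist`; anything between is reported as
#' `intermediate-breadth` rather than forced into a binary. Records with
#' zero supporting evidence are `indeterminate`.
#'
#' @param rec One-row breadth record (see
#'   [habitat_breadth_from_detections()]).
#' @param mode `"strict-all-habitats"` (detection-evidence default) or
#'   `"at-least-k"` (genome-evidence default, k = 2).
#' @param k Minimum breadth for a generalist under `"at-least-k"`; must be
#'   >= 2.
#' @param min_evidence Minimum supporting datasets/genomes; defaults: 250
#'   for detection evidence, 5 for genome evidence; 0 disables the filter.
#' @return One-row data.frame: the record plus `label`.
#' @export
classify_niche <- function(rec,
                           mode = c("strict-all-habitats", "at-least-k"),
                           k = 2L,
                           min_evidence = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(rec), nrow(rec) == 1L)
  if (mode == "at-least-k" && k < 2L) {
    stop("k must be >= 2 under mode 'at-least-k'", call. = FALSE)
  }
  if (is.null(min_evidence)) {
    min_evidence <- if (rec$evidence == "genomes") 5L else 250L
  }
  b <- rec$n_habitats_detected
  label <- if (rec$n_evidence < min_evidence || b == 0L) {
    "indeterminate"
  } else if (b == 1L) {
    "specialist"
  } else if (mode == "strict-all-habitats") {
    if (b == rec$n_habitats_possible) "generalist" else "intermediate-breadth"
  } else {
    if (b >= k) "generalist" else "intermediate-breadth"
  }
  out <- rec
  out$label <- label
  out$min_evidence <- min_evidence
  out
}

#' Habitat-breadth profile of all taxa at a rank
#'
#' Batch driver over [habitat_breadth_from_detections()] /
#' [habitat_breadth_from_genomes()] and [classify_niche()].
#'
#' @param x A detection table (`evidence = "detections"`) or genome table
#'   (`evidence = "genomes"`).
#' @param rank Rank of the profile.
#' @param evidence Which evidence base `x` is.
#' @param habitat_universe Declared habitat labels (default: labels in `x`).
#' @inheritParams classify_niche
#' @return data.frame with one classified breadth record per taxon
#'   (lexicographic by taxon name).
#' @export
profile_niche_breadth <- function(x, rank,
                                  evidence = c("detections", "genomes"),
                                  habitat_universe = NULL,
                                  mode = NULL, k = 2L,
                                  min_evidence = NULL) {
  evidence <- match.arg(evidence)
  if (is.null(mode)) {
    mode <- if (evidence == "genomes") "at-least-k" else "strict-all-habitats"
  }
  if (is.null(habitat_universe)) habitat_universe <- unique(x$habitat)
  taxa <- sort(unique(stats::na.omit(lineage_names_at_rank(x$lineage, rank))))
  fn <- if (evidence == "detections") habitat_breadth_from_detections else
    habitat_breadth_from_genomes
  out <- lapply(taxa, function(tx) {
    classify_niche(fn(x, tx, rank, habitat_universe = habitat_universe),
                   mode = mode, k = k, min_evidence = min_evidence)
  })
  res <- if (length(out)) do.call(rbind, out) else data.frame()
  rownames(res) <- NULL
  res
}
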