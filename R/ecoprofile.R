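# Ubiquity, soil-preference and relative-abundance profiling of taxa from a
# habitat-labelled detection table, and SPL/NSPL/intermediate/rare calls.

#' Default classification thresholds
#'
#' The cutoffs used throughout the preference classification: a lineage is
#' ubiquitous in a habitat above 75% occurrence, soil-preferring above a
#' soil:non-soil occurrence ratio of 4, relatively more abundant in soil
#' above an abundance ratio of 1, and rare below 4% occurrence in every
#' habitat. `family_ubiquity` (25%) is the alternative family-level
#' soil-ubiquity screen. All comparisons are strict (`>`, `<`); boundary
#' values fall to "intermediate".
#'
#' @param ubiquity Soil-ubiquity cutoff (percent) for the SPL call.
#' @param ratio Soil:non-soil ubiquity ratio cutoff.
#' @param abundance_ratio Soil:non-soil mean-abundance ratio cutoff.
#' @param rare Maximum-ubiquity-anywhere cutoff (percent) below which a taxon
#'   is called rare.
#' @param family_ubiquity Family-level soil-ubiquity screen (percent).
#' @return A named list of thresholds.
#' @export
preference_thresholds <- function(ubiquity = 75, ratio = 4,
                                  abundance_ratio = 1, rare = 4,
                                  family_ubiquity = 25) {
  th <- list(ubiquity = ubiquity, ratio = ratio,
             abundance_ratio = abundance_ratio, rare = rare,
             family_ubiquity = family_ubiquity)
  if (any(!vapply(th, function(x) is.numeric(x) && length(x) == 1L && x > 0,
                  logical(1L)))) {
    stop("all thresholds must be positive scalars", call. = FALSE)
  }
  th
}

# Normalise a census (data.frame habitat/n_datasets or named numeric) to a
# named integer vector. The census is supplied separately from the detection
# table because undetected datasets leave no rows.
as_census <- function(census) {
  if (is.data.frame(census)) {
    need <- c("habitat", "n_datasets")
    if (!all(need %in% names(census))) {
      stop("census data.frame needs columns habitat and n_datasets",
           call. = FALSE)
    }
    v <- setNames(as.numeric(census$n_datasets), census$habitat)
  } else if (is.numeric(census) && !is.null(names(census))) {
    v <- census
  } else {
    stop("census must be a data.frame(habitat, n_datasets) or a named numeric",
         call. = FALSE)
  }
  if (anyDuplicated(names(v))) stop("duplicate habitat in census", call. = FALSE)
  if (any(v < 0) || any(!is.finite(v))) {
    stop("census counts must be finite and non-negative", call. = FALSE)
  }
  v
}

#' Ubiquity and mean abundance of a taxon within a habitat group
#'
#' Ubiquity is the percentage of the habitat group's total datasets (from the
#' census) in which the taxon was detected at the stated rank:
#' `100 * n_detected / n_datasets`. Mean relative abundance averages, by
#' default, over the datasets where the taxon *is* detected; set
#' `include_zeros = TRUE` to average the detected abundance mass over all
#' censused datasets of the group instead.
#'
#' @param table A detection table (see [validate_detection_table()]).
#' @param taxon Taxon name at `rank`.
#' @param rank Rank at which to match `taxon`.
#' @param habitat_group Character vector of habitat labels to pool.
#' @param census Habitat census: data.frame(habitat, n_datasets) or named
#'   numeric vector of dataset totals per habitat.
#' @param include_zeros Average abundance over all censused datasets rather
#'   than detected ones only.
#' @return One-row data.frame: `taxon`, `habitat` (group label), `n_datasets`,
#'   `n_detected`, `ubiquity`, `mean_abundance`.
#' @export
compute_ubiquity <- function(table, taxon, rank, habitat_group, census,
                             include_zeros = FALSE) {
  validate_detection_table(table)
  census <- as_census(census)
  miss <- setdiff(habitat_group, names(census))
  if (length(miss)) {
    stop(sprintf("census does not cover habitat(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  stray <- setdiff(unique(table$habitat), names(census))
  if (length(stray)) {
    stop(sprintf("detections from uncensused habitat(s): %s",
                 paste(stray, collapse = ", ")), call. = FALSE)
  }
  n_total <- sum(census[habitat_group])
  if (n_total == 0) {
    stop(sprintf("undefined ubiquity: habitat group '%s' has zero datasets",
                 paste(habitat_group, collapse = "+")), call. = FALSE)
  }
  sub <- table[table$habitat %in% habitat_group, , drop = FALSE]
  if (nrow(sub)) {
    hit <- !is.na(lineage_names_at_rank(sub$lineage, rank)) &
      lineage_names_at_rank(sub$lineage, rank) == taxon
    sub <- sub[hit, , drop = FALSE]
  }
  if (nrow(sub)) {
    per_ds <- rowsum(sub$relative_abundance_pct, group = sub$dataset_id)
    n_det <- nrow(per_ds)
    mean_ab <- if (include_zeros) sum(per_ds) / n_total else mean(per_ds)
  } else {
    n_det <- 0L
    mean_ab <- 0
  }
  if (n_det > n_total) {
    stop(sprintf(
      "census inconsistency: %d detected datasets exceed census total %d",
      n_det, n_total), call. = FALSE)
  }
  data.frame(taxon = taxon,
             habitat = paste(habitat_group, collapse = "+"),
             n_datasets = n_total, n_detected = n_det,
             ubiquity = 100 * n_det / n_total,
             mean_abundance = mean_ab,
             stringsAsFactors = FALSE)
}

#' Partition habitat labels into soil and non-soil groups
#'
#' The non-soil group is every non-soil label minus the exclusion set; by
#' default host-associated datasets are excluded from all soil vs non-soil
#' comparisons (they dominate public archives and the taxa of interest are
#' established to be scarce there).
#'
#' @param habitats Character vector of habitat labels; must contain "soil".
#' @param exclude Labels to drop from the non-soil group.
#' @return `list(soil = "soil", nonsoil = <labels>)`.
#' @export
soil_nonsoil_partition <- function(habitats, exclude = "host-associated") {
  if (!"soil" %in% habitats) {
    stop("habitat set does not contain 'soil'", call. = FALSE)
  }
  list(soil = "soil",
       nonsoil = setdiff(habitats, c("soil", exclude)))
}

#' Soil-preference metrics for one taxon
#'
#' Computes soil and pooled non-soil ubiquity and mean relative abundance and
#' their soil:non-soil ratios. The preference ratio is the ratio of ubiquity
#' *percentages* (not raw dataset counts, which unequal habitat census sizes
#' would distort). Zero denominators yield `Inf`, never an error; a taxon
#' absent from both groups yields all-zero metrics with `absent = TRUE`.
#'
#' @inheritParams compute_ubiquity
#' @param exclude Habitat labels excluded from the non-soil group.
#' @return One-row data.frame: `taxon`, `soil_ubiquity`, `nonsoil_ubiquity`,
#'   `preference_ratio`, `soil_mean_abundance`, `nonsoil_mean_abundance`,
#'   `abundance_ratio`, `absent`.
#' @export
compute_preference_metrics <- function(table, taxon, rank, census,
                                       exclude = "host-associated",
                                       include_zeros = FALSE) {
  census <- as_census(census)
  part <- soil_nonsoil_partition(names(census), exclude = exclude)
  if (!length(part$nonsoil)) {
    stop("undefined preference ratio: non-soil habitat group is empty",
         call. = FALSE)
  }
  s <- compute_ubiquity(table, taxon, rank, part$soil, census,
                        include_zeros = include_zeros)
  ns <- compute_ubiquity(table, taxon, rank, part$nonsoil, census,
                         include_zeros = include_zeros)
  ratio_of <- function(num, den) {
    if (den > 0) num / den else if (num > 0) Inf else 0
  }
  data.frame(
    taxon = taxon,
    soil_ubiquity = s$ubiquity,
    nonsoil_ubiquity = ns$ubiquity,
    preference_ratio = ratio_of(s$ubiquity, ns$ubiquity),
    soil_mean_abundance = s$mean_abundance,
    nonsoil_mean_abundance = ns$mean_abundance,
    abundance_ratio = ratio_of(s$mean_abundance, ns$mean_abundance),
    absent = s$n_detected == 0L && ns$n_detected == 0L,
    stringsAsFactors = FALSE)
}

#' Classify a taxon's soil preference
#'
#' Applies the classification rule: rare if the taxon's maximum ubiquity in
#' any single habitat is below the rarity cutoff; else SPL (soil-preferring
#' lineage) if soil ubiquity exceeds the ubiquity cutoff *and* the preference
#' ratio exceeds the ratio cutoff; else NSPL (non-soil-preferring) if the
#' preference ratio is below the ratio cutoff *and* the abundance ratio is
#' below the abundance-ratio cutoff; else intermediate. Infinite ratios
#' (zero non-soil denominator) compare as greater than any finite threshold.
#'
#' @param metrics One-row data.frame from [compute_preference_metrics()].
#' @param max_ubiquity_any_habitat The taxon's maximum per-habitat ubiquity
#'   (percent) across all censused habitats.
#' @param thresholds See [preference_thresholds()].
#' @return One-row data.frame: `taxon`, `label`, followed by the metrics.
#' @export
classify_preference <- function(metrics, max_ubiquity_any_habitat,
                                thresholds = preference_thresholds()) {
  stopifnot(is.data.frame(metrics), nrow(metrics) == 1L)
  label <- if (max_ubiquity_any_habitat < thresholds$rare) {
    "rare"
  } else if (metrics$soil_ubiquity > thresholds$ubiquity &&
             metrics$preference_ratio > thresholds$ratio) {
    "SPL"
  } else if (metrics$preference_ratio < thresholds$ratio &&
             metrics$abundance_ratio < thresholds$abundance_ratio) {
    "NSPL"
  } else {
    "intermediate"
  }
  cbind(data.frame(taxon = metrics$taxon, label = label,
                   max_ubiquity_any_habitat = max_ubiquity_any_habitat,
                   stringsAsFactors = FALSE),
        metrics[, setdiff(names(metrics), "taxon"), drop = FALSE])
}

#' Profile every taxon at a rank
#'
#' Batch driver: aggregates nothing itself but matches each distinct name at
#' `rank`, computes the per-habitat ubiquity/abundance grid, the soil
#' preference metrics and the SPL/NSPL/intermediate/rare call. Degenerate
#' taxa never abort the batch; their error message is carried in the `flag`
#' column.
#'
#' @inheritParams compute_preference_metrics
#' @param thresholds See [preference_thresholds()].
#' @return `list(calls = <one row per taxon, lexicographic>, grid = <taxon x
#'   habitat summary>)` of class `"ecoprofile"`.
#' @export
profile_all_taxa <- function(table, rank, census,
                             thresholds = preference_thresholds(),
                             exclude = "host-associated",
                             include_zeros = FALSE) {
  validate_detection_table(table)
  census <- as_census(census)
  taxa <- sort(unique(stats::na.omit(
    lineage_names_at_rank(table$lineage, rank))))
  habitats <- names(census)[census > 0]
  grid_rows <- list()
  call_rows <- list()
  for (tx in taxa) {
    g <- do.call(rbind, lapply(habitats, function(h) {
      compute_ubiquity(table, tx, rank, h, census,
                       include_zeros = include_zeros)
    }))
    grid_rows[[tx]] <- g
    row <- tryCatch({
      m <- compute_preference_metrics(table, tx, rank, census,
                                      exclude = exclude,
                                      include_zeros = include_zeros)
      cl <- classify_preference(m, max(g$ubiquity), thresholds)
      cl$flag <- if (m$absent) "absent-from-comparison-groups" else ""
      cl
    }, error = function(e) {
      data.frame(taxon = tx, label = NA_character_,
                 max_ubiquity_any_habitat = max(g$ubiquity),
                 soil_ubiquity = NA_real_, nonsoil_ubiquity = NA_real_,
                 preference_ratio = NA_real_, soil_mean_abundance = NA_real_,
                 nonsoil_mean_abundance = NA_real_, abundance_ratio = NA_real_,
                 absent = NA, flag = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    call_rows[[tx]] <- row
  }
  calls <- if (length(call_rows)) do.call(rbind, call_rows) else
    data.frame()
  grid <- if (length(grid_rows)) do.call(rbind, grid_rows) else data.frame()
  rownames(calls) <- NULL
  rownames(grid) <- NULL
  structure(list(calls = calls, grid = grid, rank = rank,
                 thresholds = thresholds),
            class = "ecoprofile")
}

#' @export
print.ecoprofile <- function(x, ...) {
  cat(sprintf("<ecoprofile> %d taxa at rank '%s'\n",
              nrow(x$calls), x$rank))
  if (nrow(x$calls)) print(table(x$calls$label, useNA = "ifany"))
  invisible(x)
}
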