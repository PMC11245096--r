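# Genomic-investment life-history classification. Two indices summarise a
# genome's investment tradeoff: regulatory flexibility (transcription
# factors per gene) and resource acquisition (secreted degradative enzymes
# plus biosynthetic gene clusters per membrane transporter). Genomes are
# assigned one of three strategies -- Scarcity, Ruderal, Competitor -- by
# nearest centroid in z-scored index space, with centroids fitted from a
# labelled training set.

STRATEGY_LABELS <- c("Scarcity", "Ruderal", "Competitor")

#' Regulatory-flexibility index
#'
#' Transcription-factor gene count divided by total gene count.
#'
#' @param n_tf Number of predicted transcription factors.
#' @param n_genes_total Total number of genes (> 0).
#' @return `n_tf / n_genes_total`, in [0, 1].
#' @export
regulatory_flexibility_index <- function(n_tf, n_genes_total) {
  if (any(n_genes_total <= 0)) {
    stop("n_genes_total must be positive", call. = FALSE)
  }
  if (any(n_tf < 0) || any(n_tf > n_genes_total)) {
    stop("n_tf must lie in [0, n_genes_total]", call. = FALSE)
  }
  n_tf / n_genes_total
}

#' Resource-acquisition index
#'
#' Secreted CAZyme + secreted protease + secreted lipase gene counts plus
#' biosynthetic gene cluster count, divided by membrane-transporter count.
#' Secretion status is decided upstream (signal-peptide prediction); the
#' inputs here are already-secreted counts.
#'
#' @param n_secreted_cazymes,n_secreted_proteases,n_secreted_lipases
#'   Secreted enzyme counts.
#' @param n_bgc Biosynthetic gene cluster count.
#' @param n_transporters Membrane transporter count (> 0).
#' @return Non-negative index value.
#' @export
resource_acquisition_index <- function(n_secreted_cazymes,
                                       n_secreted_proteases,
                                       n_secreted_lipases,
                                       n_bgc, n_transporters) {
  counts <- c(n_secreted_cazymes, n_secreted_proteases, n_secreted_lipases,
              n_bgc)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(n_transporters <= 0)) {
    stop("n_transporters must be positive", call. = FALSE)
  }
  (n_secreted_cazymes + n_secreted_proteases + n_secreted_lipases + n_bgc) /
    n_transporters
}

#' Investment indices for every genome in a table
#'
#' Computes both indices from the annotation-count columns. Genomes with
#' zero transporters cannot be placed in index space; they are returned with
#' `NA` indices and `excluded = TRUE` (with a message) rather than erroring,
#' and are dropped by [classify_strategy()].
#'
#' @param genomes Genome table with columns `genome_id`, `n_tf`,
#'   `n_genes_total`, `n_secreted_cazymes`, `n_secreted_proteases`,
#'   `n_secreted_lipases`, `n_bgc`, `n_transporters`.
#' @return data.frame: `genome_id`, `regulatory_flexibility`,
#'   `resource_acquisition`, `excluded`.
#' @export
investment_indices <- function(genomes) {
  need <- c("genome_id", "n_tf", "n_genes_total", "n_secreted_cazymes",
            "n_secreted_proteases", "n_secreted_lipases", "n_bgc",
            "n_transporters")
  miss <- setdiff(need, names(genomes))
  if (length(miss)) {
    stop(sprintf("genome table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  bad <- genomes$n_transporters <= 0
  if (any(bad)) {
    message(sprintf(
      "investment_indices: excluding %d genome(s) with zero transporters",
      sum(bad)))
  }
  rf <- ifelse(genomes$n_genes_total > 0,
               genomes$n_tf / genomes$n_genes_total, NA_real_)
  ra <- ifelse(bad, NA_real_,
               (genomes$n_secreted_cazymes + genomes$n_secreted_proteases +
                  genomes$n_secreted_lipases + genomes$n_bgc) /
                 genomes$n_transporters)
  data.frame(genome_id = genomes$genome_id,
             regulatory_flexibility = rf,
             resource_acquisition = ra,
             excluded = bad | is.na(rf),
             stringsAsFactors = FALSE)
}

#' Fit strategy centroids from a labelled training set
#'
#' Z-scores both index dimensions using the mean and sd of *all* training
#' points, then sets each strategy's centroid to the mean of its labelled
#' points in scaled space. Deterministic; no random initialisation. The
#' scaling makes classification invariant to any common rescaling of the
#' raw index units.
#'
#' @param training data.frame with columns `regulatory_flexibility`,
#'   `resource_acquisition`, `label` (each of Scarcity, Ruderal, Competitor
#'   present at least once).
#' @return A `strategy_centroids` object: `centroids` (3 x 2 matrix in
#'   scaled space), `center`, `scale`.
#' @export
fit_centroids <- function(training) {
  need <- c("regulatory_flexibility", "resource_acquisition", "label")
  miss <- setdiff(need, names(training))
  if (length(miss)) {
    stop(sprintf("training set is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  absent <- setdiff(STRATEGY_LABELS, unique(training$label))
  if (length(absent)) {
    stop(sprintf("training set has no points for label(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(unique(training$label), STRATEGY_LABELS)
  if (length(extra)) {
    stop(sprintf("unknown strategy label(s): %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  X <- as.matrix(training[, c("regulatory_flexibility",
                              "resource_acquisition")])
  if (anyNA(X)) stop("training indices contain NA", call. = FALSE)
  ctr <- colMeans(X)
  # population (1/n) sd: duplicating the training set leaves the fitted
  # scaling, hence the centroids, unchanged
  scl <- sqrt(colMeans(sweep(X, 2L, ctr)^2))
  if (any(scl == 0)) {
    stop("zero standard deviation in a training dimension", call. = FALSE)
  }
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  cen <- t(vapply(STRATEGY_LABELS, function(lb) {
    colMeans(Z[training$label == lb, , drop = FALSE])
  }, numeric(2L)))
  structure(list(centroids = cen, center = ctr, scale = scl),
            class = "strategy_centroids")
}

#' @export
print.strategy_centroids <- function(x, ...) {
  cat("<strategy_centroids> (z-scored index space)\n")
  print(round(x$centroids, 3))
  invisible(x)
}

#' Assign life-history strategies by nearest centroid
#'
#' Scales each genome's indices with the training-set scaling and assigns
#' the label of the nearest centroid (Euclidean distance in scaled space).
#' Exact ties are broken by the fixed label order Scarcity < Ruderal <
#' Competitor and flagged. Genomes with `NA` indices (zero-transporter
#' exclusions) receive `NA` labels.
#'
#' @param idx data.frame from [investment_indices()] (or any frame with
#'   `genome_id`, `regulatory_flexibility`, `resource_acquisition`).
#' @param centroids A `strategy_centroids` object from [fit_centroids()].
#' @return data.frame: `genome_id`, both indices, `label`, `d_scarcity`,
#'   `d_ruderal`, `d_competitor`, `tie_flag`.
#' @export
classify_strategy <- function(idx, centroids) {
  stopifnot(inherits(centroids, "strategy_centroids"))
  X <- cbind(idx$regulatory_flexibility, idx$resource_acquisition)
  Z <- sweep(sweep(X, 2L, centroids$center), 2L, centroids$scale, "/")
  D <- vapply(seq_len(nrow(centroids$centroids)), function(k) {
    sqrt((Z[, 1L] - centroids$centroids[k, 1L])^2 +
           (Z[, 2L] - centroids$centroids[k, 2L])^2)
  }, numeric(nrow(Z)))
  D <- matrix(D, nrow = nrow(Z))
  ok <- !is.na(D[, 1L])
  pick <- rep(NA_integer_, nrow(Z))
  tie <- rep(FALSE, nrow(Z))
  for (i in which(ok)) {
    d <- D[i, ]
    k <- which.min(d)  # first minimum = fixed label order on ties
    pick[i] <- k
    tie[i] <- sum(abs(d - d[k]) <= 1e-12 * max(1, d[k])) > 1L
  }
  data.frame(genome_id = idx$genome_id,
             regulatory_flexibility = idx$regulatory_flexibility,
             resource_acquisition = idx$resource_acquisition,
             label = STRATEGY_LABELS[pick],
             d_scarcity = D[, 1L], d_ruderal = D[, 2L],
             d_competitor = D[, 3L],
             tie_flag = tie,
             stringsAsFactors = FALSE)
}

#' Synthetic stand-in training set
#'
#' The labelled reference points used to fit strategy centroids are not
#' redistributable, so the packaged default is a clearly synthetic stand-in:
#' 27 points (9 per strategy) drawn around well-separated archetype
#' coordinates with a fixed seed. Replace with a user-supplied training TSV
#' (`id  regulatory_flexibility  resource_acquisition  label`) for real
#' analyses.
#'
#' @param seed Integer seed.
#' @param n_per_label Points per strategy.
#' @return data.frame: `id`, `regulatory_flexibility`,
#'   `resource_acquisition`, `label`.
#' @export
synthetic_training_set <- function(seed = 1042L, n_per_label = 9L) {
  arch <- default_archetypes()
  with_seed(stream_seed(seed, 10007L), {
    rows <- lapply(seq_len(nrow(arch)), function(k) {
      data.frame(
        id = sprintf("train_%s_%02d", arch$label[k], seq_len(n_per_label)),
        regulatory_flexibility = pmax(
          rnorm(n_per_label, arch$rf[k], arch$rf_sd[k]), 1e-4),
        resource_acquisition = pmax(
          rnorm(n_per_label, arch$ra[k], arch$ra_sd[k]), 0),
        label = arch$label[k],
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
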