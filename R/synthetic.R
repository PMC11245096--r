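# Seeded generators for detection tables and genome tables with known
# ground truth. Every downstream statistic in the package is validated
# against tables built here, so the generators are first-class, tested
# code, not fixtures.

# Evaluate `code` under a temporary RNG state; the caller's state is
# restored afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stream sub-seed below 2^31, so that one global seed
# drives independent streams (adding taxa at the end of a config never
# perturbs earlier taxa's draws).
stream_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(stream) * 30269
  as.integer(s %% 2147483647)
}

#' Ecosystem simulation configuration
#'
#' Describes a stated world of habitats and family-level taxa: how many
#' metagenomic datasets each habitat contributes, and for each (taxon,
#' habitat) pair the detection probability and the log-normal relative
#' abundance model. Detections are independent across taxa within a dataset
#' (the simplest null; no downstream statistic here uses co-occurrence
#' structure). Abundances are log-normal truncated to (0, 100] percent:
#' strictly positive and right-skewed, as read-fraction data are.
#'
#' @param habitats data.frame with columns `habitat`, `n_datasets`
#'   (unique names, counts >= 0).
#' @param taxa data.frame with columns `lineage` (family-depth GTDB string),
#'   `habitat`, `p_detect` in [0, 1], `meanlog`, `sdlog` (>= 0). Omitted
#'   (taxon, habitat) pairs have detection probability 0.
#' @param seed Integer seed driving all draws.
#' @return An `ecosystem_sim_config` object.
#' @export
ecosystem_sim_config <- function(habitats, taxa, seed = 1L) {
  stopifnot(is.data.frame(habitats), is.data.frame(taxa))
  if (!all(c("habitat", "n_datasets") %in% names(habitats))) {
    stop("habitats needs columns habitat, n_datasets", call. = FALSE)
  }
  if (!all(c("lineage", "habitat", "p_detect", "meanlog", "sdlog") %in%
           names(taxa))) {
    stop("taxa needs columns lineage, habitat, p_detect, meanlog, sdlog",
         call. = FALSE)
  }
  if (anyDuplicated(habitats$habitat)) {
    stop("habitat names must be unique", call. = FALSE)
  }
  if (any(habitats$n_datasets < 0)) {
    stop("dataset counts must be >= 0", call. = FALSE)
  }
  if (any(taxa$p_detect < 0 | taxa$p_detect > 1)) {
    stop("detection probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(taxa$sdlog < 0)) stop("sdlog must be >= 0", call. = FALSE)
  stray <- setdiff(unique(taxa$habitat), habitats$habitat)
  if (length(stray)) {
    stop(sprintf("taxa reference undeclared habitat(s): %s",
                 paste(stray, collapse = ", ")), call. = FALSE)
  }
  fams <- lineage_names_at_rank(unique(taxa$lineage), "family")
  if (anyNA(fams) || anyDuplicated(fams)) {
    stop("taxa lineages must be family-deep with unique family names",
         call. = FALSE)
  }
  if (anyDuplicated(paste(taxa$lineage, taxa$habitat))) {
    stop("duplicate (lineage, habitat) row in taxa", call. = FALSE)
  }
  structure(list(habitats = habitats, taxa = taxa, seed = as.integer(seed)),
            class = "ecosystem_sim_config")
}

#' Generate a synthetic detection table
#'
#' For each habitat and each of its datasets, every configured taxon is
#' detected independently with its (taxon, habitat) probability; detected
#' rows carry a log-normal relative abundance (percent), truncated at 100.
#' Reproducible for a fixed seed; each taxon consumes its own RNG stream.
#'
#' @param cfg An [ecosystem_sim_config()].
#' @return A detection table (`dataset_id`, `habitat`, `lineage`,
#'   `relative_abundance_pct`), sorted by dataset then lineage.
#' @export
generate_detection_table <- function(cfg) {
  stopifnot(inherits(cfg, "ecosystem_sim_config"))
  hab <- cfg$habitats
  ids <- lapply(seq_len(nrow(hab)), function(i) {
    if (hab$n_datasets[i] == 0) return(character(0))
    sprintf("%s_%05d", gsub("[^A-Za-z0-9]+", "_", hab$habitat[i]),
            seq_len(hab$n_datasets[i]))
  })
  names(ids) <- hab$habitat
  lineages <- unique(cfg$taxa$lineage)
  rows <- list()
  for (i in seq_along(lineages)) {
    lin <- lineages[i]
    tl <- cfg$taxa[cfg$taxa$lineage == lin, , drop = FALSE]
    rows[[i]] <- with_seed(stream_seed(cfg$seed, i), {
      sub <- list()
      for (j in seq_len(nrow(tl))) {
        h <- tl$habitat[j]
        n <- length(ids[[h]])
        if (n == 0 || tl$p_detect[j] == 0) next
        det <- runif(n) < tl$p_detect[j]
        m <- sum(det)
        if (m == 0) next
        ab <- pmin(rlnorm(m, tl$meanlog[j], tl$sdlog[j]), 100)
        sub[[j]] <- data.frame(dataset_id = ids[[h]][det], habitat = h,
                               lineage = lin,
                               relative_abundance_pct = ab,
                               stringsAsFactors = FALSE)
      }
      if (length(sub)) do.call(rbind, sub) else NULL
    })
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dataset_id = character(0), habitat = character(0),
               lineage = character(0), relative_abundance_pct = numeric(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$dataset_id, out$lineage), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Seven-habitat default ecosystem configuration
#'
#' The stated world used throughout the package's validation: the seven
#' standard habitat groups at 500 datasets each, and eight families whose
#' detection probabilities construct the classification outcomes by design
#' -- three soil-preferring families (p = 0.9 in soil, 0.05 elsewhere, with
#' higher soil abundance; two of them sharing an order to exercise rank
#' aggregation), two non-soil-preferring families (p = 0.05 in soil, 0.5 in
#' the non-host non-soil habitats, with lower soil abundance), one
#' moderately soil-preferring low-abundance family, and two rare families
#' (p = 0.02 everywhere).
#'
#' @param seed Integer seed.
#' @param n_datasets_per_habitat Dataset count per habitat.
#' @return An [ecosystem_sim_config()].
#' @export
default_ecosystem_config <- function(seed = 1L,
                                     n_datasets_per_habitat = 500L) {
  habs <- c("soil", "engineered", "freshwater", "host-associated", "marine",
            "non-marine saline and alkaline", "terrestrial non-soil")
  habitats <- data.frame(habitat = habs,
                         n_datasets = n_datasets_per_habitat,
                         stringsAsFactors = FALSE)
  lin <- function(c_, o_, f_) {
    sprintf("d__Bacteria;p__Acidobacteriota;c__%s;o__%s;f__%s", c_, o_, f_)
  }
  spl <- c(lin("ClassSoilA", "OrderSoilA1", "FamSoilA1"),
           lin("ClassSoilA", "OrderSoilA1", "FamSoilA2"),
           lin("ClassSoilB", "OrderSoilB1", "FamSoilB1"))
  nspl <- c(lin("ClassAquaA", "OrderAquaA1", "FamAquaA1"),
            lin("ClassAquaB", "OrderAquaB1", "FamAquaB1"))
  inter <- lin("ClassMidA", "OrderMidA1", "FamMidA1")
  rare <- c(lin("ClassRareA", "OrderRareA1", "FamRareA1"),
            lin("ClassRareB", "OrderRareB1", "FamRareB1"))
  nonsoil_habs <- setdiff(habs, c("soil", "host-associated"))
  rowset <- function(lineage, habitat, p, meanlog, sdlog) {
    data.frame(lineage = lineage, habitat = habitat, p_detect = p,
               meanlog = meanlog, sdlog = sdlog, stringsAsFactors = FALSE)
  }
  taxa <- rbind(
    # soil-preferring: ubiquitous and abundant in soil, sparse elsewhere
    do.call(rbind, lapply(spl, function(l) rbind(
      rowset(l, "soil", 0.9, log(5), 0.6),
      do.call(rbind, lapply(c(nonsoil_habs, "host-associated"), function(h)
        rowset(l, h, 0.05, log(0.5), 0.6)))))),
    # non-soil-preferring: common in non-host non-soil habitats, sparse and
    # lean in soil
    do.call(rbind, lapply(nspl, function(l) rbind(
      rowset(l, "soil", 0.05, log(0.2), 0.6),
      do.call(rbind, lapply(nonsoil_habs, function(h)
        rowset(l, h, 0.5, log(2), 0.6)))))),
    # soil-preferring by occurrence but not abundant there
    rbind(rowset(inter, "soil", 0.3, log(0.3), 0.6),
          do.call(rbind, lapply(nonsoil_habs, function(h)
            rowset(inter, h, 0.05, log(1), 0.6)))),
    # rare everywhere
    do.call(rbind, lapply(rare, function(l)
      do.call(rbind, lapply(habs, function(h)
        rowset(l, h, 0.02, log(0.1), 0.6)))))
  )
  ecosystem_sim_config(habitats, taxa, seed = seed)
}

#' Default life-history archetype coordinates
#'
#' Index-space archetypes the simulators and the synthetic training set
#' draw from: `rf` is transcription factors per gene, `ra` secreted
#' degradative enzymes plus BGCs per transporter. Scarcity invests little
#' on either axis, Ruderal in regulatory flexibility, Competitor in
#' resource acquisition.
#'
#' @return data.frame: `label`, `rf`, `ra`, `rf_sd`, `ra_sd`.
#' @export
default_archetypes <- function() {
  data.frame(label = STRATEGY_LABELS,
             rf = c(0.020, 0.080, 0.035),
             ra = c(0.25, 0.60, 1.50),
             rf_sd = c(0.004, 0.004, 0.004),
             ra_sd = c(0.08, 0.08, 0.08),
             stringsAsFactors = FALSE)
}

#' Genome simulation configuration
#'
#' Describes the generating model the variance-partitioning machinery
#' assumes: each genome's continuous feature is
#' class baseline + habitat offset + interaction offset + Gaussian noise;
#' binary traits are Bernoulli draws from a logit-linear model; life-history
#' annotation counts are constructed so the two investment indices land on
#' the genome's archetype coordinates plus Gaussian jitter.
#'
#' @param classes Character vector of class names.
#' @param habitats Character vector of habitat names.
#' @param n_per_cell Integer matrix (classes x habitats) of genome counts.
#' @param class_baseline Numeric matrix (classes x features).
#' @param habitat_offset Numeric matrix (habitats x features); default all
#'   zero.
#' @param interaction_offset Numeric array (classes x habitats x features);
#'   default all zero.
#' @param residual_sd Named numeric vector, one sd per feature (>= 0).
#' @param integer_features Features rounded to non-negative integers after
#'   simulation (counts).
#' @param binary_traits Optional list with `baseline` (named logit vector,
#'   one per trait), `class_offset` (classes x traits), `habitat_offset`
#'   (habitats x traits).
#' @param aerobe_logit Optional list with `baseline` scalar, `class_offset`
#'   and `habitat_offset` named vectors, generating a 0/1 `pred_aerobe`
#'   column.
#' @param archetypes data.frame with columns `label` (exactly Scarcity,
#'   Ruderal, Competitor), `rf`, `ra`, `rf_sd`, `ra_sd`.
#' @param archetype_prob Matrix (classes x 3) of per-class strategy
#'   probabilities; default uniform.
#' @param n_transporters Transporter count given to every genome when
#'   constructing life-history counts.
#' @param seed Integer seed.
#' @return A `genome_sim_config` object.
#' @export
genome_sim_config <- function(classes, habitats, n_per_cell,
                              class_baseline,
                              habitat_offset = NULL,
                              interaction_offset = NULL,
                              residual_sd,
                              integer_features = character(0),
                              binary_traits = NULL,
                              aerobe_logit = NULL,
                              archetypes = default_archetypes(),
                              archetype_prob = NULL,
                              n_transporters = 200L,
                              seed = 1L) {
  classes <- as.character(classes)
  habitats <- as.character(habitats)
  feats <- colnames(class_baseline)
  if (is.null(feats)) stop("class_baseline needs feature column names",
                           call. = FALSE)
  n_per_cell <- as.matrix(n_per_cell)
  if (!identical(dim(n_per_cell), c(length(classes), length(habitats)))) {
    stop("n_per_cell must be classes x habitats", call. = FALSE)
  }
  if (any(n_per_cell < 0)) stop("genome counts must be >= 0", call. = FALSE)
  if (is.null(habitat_offset)) {
    habitat_offset <- matrix(0, length(habitats), length(feats),
                             dimnames = list(habitats, feats))
  }
  if (is.null(interaction_offset)) {
    interaction_offset <- array(0, dim = c(length(classes), length(habitats),
                                           length(feats)),
                                dimnames = list(classes, habitats, feats))
  }
  if (!all(feats %in% names(residual_sd))) {
    stop("residual_sd must name every feature", call. = FALSE)
  }
  if (any(residual_sd < 0)) stop("residual sd must be >= 0", call. = FALSE)
  if (!setequal(archetypes$label, STRATEGY_LABELS) ||
      nrow(archetypes) != 3L) {
    stop("archetypes must have exactly the three strategy labels",
         call. = FALSE)
  }
  if (is.null(archetype_prob)) {
    archetype_prob <- matrix(1 / 3, length(classes), 3L,
                             dimnames = list(classes, STRATEGY_LABELS))
  }
  structure(list(classes = classes, habitats = habitats,
                 n_per_cell = n_per_cell, features = feats,
                 class_baseline = class_baseline,
                 habitat_offset = habitat_offset,
                 interaction_offset = interaction_offset,
                 residual_sd = residual_sd[feats],
                 integer_features = integer_features,
                 binary_traits = binary_traits,
                 aerobe_logit = aerobe_logit,
                 archetypes = archetypes[match(STRATEGY_LABELS,
                                               archetypes$label), ],
                 archetype_prob = archetype_prob,
                 n_transporters = as.integer(n_transporters),
                 seed = as.integer(seed)),
            class = "genome_sim_config")
}

#' Generate a synthetic genome table with ground truth
#'
#' @param cfg A [genome_sim_config()].
#' @return A `genome_sim` list: `genomes` (genome table with lineage,
#'   habitat, continuous features, optional `pred_aerobe`, and the
#'   life-history count columns), `traits` (genome x trait 0/1 data.frame or
#'   NULL), `truth` (the generating effects plus each genome's archetype).
#' @export
generate_genome_table <- function(cfg) {
  stopifnot(inherits(cfg, "genome_sim_config"))
  feats <- cfg$features
  cells <- which(cfg$n_per_cell > 0, arr.ind = TRUE)
  with_seed(stream_seed(cfg$seed, 1L), {
    cls <- character(0); habs <- character(0)
    for (r in seq_len(nrow(cells))) {
      n <- cfg$n_per_cell[cells[r, 1L], cells[r, 2L]]
      cls <- c(cls, rep(cfg$classes[cells[r, 1L]], n))
      habs <- c(habs, rep(cfg$habitats[cells[r, 2L]], n))
    }
    n_gen <- length(cls)
    ci <- match(cls, cfg$classes)
    hi <- match(habs, cfg$habitats)
    gmat <- matrix(NA_real_, n_gen, length(feats),
                   dimnames = list(NULL, feats))
    for (f in seq_along(feats)) {
      mu <- cfg$class_baseline[ci, f] + cfg$habitat_offset[hi, f] +
        cfg$interaction_offset[cbind(ci, hi, f)]
      gmat[, f] <- mu + rnorm(n_gen, 0, cfg$residual_sd[f])
    }
    for (f in intersect(cfg$integer_features, feats)) {
      gmat[, f] <- pmax(round(gmat[, f]), 0)
    }
    genomes <- data.frame(
      genome_id = sprintf("G%06d", seq_len(n_gen)),
      lineage = sprintf("d__Bacteria;p__Acidobacteriota;c__%s", cls),
      habitat = habs, stringsAsFactors = FALSE)
    genomes <- cbind(genomes, as.data.frame(gmat))

    if (!is.null(cfg$aerobe_logit)) {
      al <- cfg$aerobe_logit
      eta <- al$baseline +
        unname(al$class_offset[cls]) + unname(al$habitat_offset[habs])
      eta[is.na(eta)] <- al$baseline
      genomes$pred_aerobe <- rbinom(n_gen, 1L, plogis(eta))
    }

    # Life-history counts constructed so the indices land on the archetype
    # coordinates plus jitter.
    arch <- cfg$archetypes
    labs <- vapply(seq_len(n_gen), function(i) {
      sample(STRATEGY_LABELS, 1L, prob = cfg$archetype_prob[ci[i], ])
    }, character(1L))
    ai <- match(labs, arch$label)
    rf <- pmin(pmax(rnorm(n_gen, arch$rf[ai], arch$rf_sd[ai]), 1e-4), 0.5)
    ra <- pmax(rnorm(n_gen, arch$ra[ai], arch$ra_sd[ai]), 0)
    n_genes_total <- if ("n_genes" %in% feats) {
      pmax(round(genomes$n_genes), 500L)
    } else rep(4000L, n_gen)
    n_tf <- pmin(round(rf * n_genes_total), n_genes_total)
    total_sec <- round(ra * cfg$n_transporters)
    caz <- round(0.5 * total_sec)
    prot <- round(0.3 * total_sec)
    lip <- round(0.1 * total_sec)
    bgc <- pmax(total_sec - caz - prot - lip, 0L)
    genomes$n_tf <- n_tf
    genomes$n_genes_total <- n_genes_total
    genomes$n_secreted_cazymes <- caz
    genomes$n_secreted_proteases <- prot
    genomes$n_secreted_lipases <- lip
    genomes$n_bgc <- bgc
    genomes$n_transporters <- rep(cfg$n_transporters, n_gen)

    traits <- NULL
    if (!is.null(cfg$binary_traits)) {
      bt <- cfg$binary_traits
      tnames <- names(bt$baseline)
      tm <- matrix(NA_integer_, n_gen, length(tnames),
                   dimnames = list(genomes$genome_id, tnames))
      for (t in seq_along(tnames)) {
        eta <- bt$baseline[t] + bt$class_offset[ci, t] +
          bt$habitat_offset[hi, t]
        tm[, t] <- rbinom(n_gen, 1L, plogis(eta))
      }
      traits <- as.data.frame(tm)
    }

    truth <- list(class_baseline = cfg$class_baseline,
                  habitat_offset = cfg$habitat_offset,
                  interaction_offset = cfg$interaction_offset,
                  residual_sd = cfg$residual_sd,
                  archetype = data.frame(genome_id = genomes$genome_id,
                                         label = labs,
                                         stringsAsFactors = FALSE))
    structure(list(genomes = genomes, traits = traits, truth = truth),
              class = "genome_sim")
  })
}

#' Labelled training points drawn from the configured archetypes
#'
#' Emulates a labelled reference set of the size used to train the
#' life-history classifier (9 per strategy = 27 points by default).
#'
#' @param cfg A [genome_sim_config()] (only its archetypes and seed are
#'   used).
#' @param n_per_label Points per strategy label (>= 1).
#' @return data.frame: `id`, `regulatory_flexibility`,
#'   `resource_acquisition`, `label`.
#' @export
generate_training_set <- function(cfg, n_per_label = 9L) {
  stopifnot(inherits(cfg, "genome_sim_config"), n_per_label >= 1L)
  arch <- cfg$archetypes
  with_seed(stream_seed(cfg$seed, 10007L), {
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

#' Per-class genome counts by source habitat
#'
#' Reads the packaged table of genome counts per (class, habitat) for the
#' six classes in the comparative-genomics cohort (classes with at least
#' 100 genomes, recovered from at least 5 of the 7 habitats).
#'
#' @return data.frame: `class` plus one count column per habitat.
#' @export
class_habitat_counts <- function() {
  path <- system.file("extdata", "acido_class_habitat_genome_counts.tsv",
                      package = "habpref", mustWork = TRUE)
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Default genome simulation configuration
#'
#' The stated world for the comparative-genomics stage: the six classes of
#' the published cohort with their genome counts per source habitat, class
#' baselines chosen so soil-preferring classes have larger, GC-richer,
#' gene-denser-in-number genomes with expanded secretory arsenals, modest
#' soil habitat offsets on the features reported habitat-responsive
#' (more peptidases, lower coding density, more and shorter genes, lower
#' predicted growth temperature and pH), and default archetype mixing
#' biased toward Competitor in the dominant soil class.
#'
#' @param seed Integer seed.
#' @return A [genome_sim_config()].
#' @export
default_genome_config <- function(seed = 1L) {
  counts <- class_habitat_counts()
  classes <- counts$class
  habitats <- setdiff(names(counts), "class")
  n_per_cell <- as.matrix(counts[, habitats])
  rownames(n_per_cell) <- classes

  feats <- c("genome_size", "gc", "coding_density", "n_genes",
             "mean_gene_length", "n_crisprs", "n_viral_contigs",
             "n_cazymes", "n_peptidases", "n_bgcs", "pred_ogt", "pred_ph")
  baseline <- rbind(
    Blastocatellia      = c(4.5e6, 61, 88.5, 4100, 970, 1.0, 3.2, 180, 110, 6, 28, 6.8),
    Terriglobia         = c(5.2e6, 60, 87.5, 4600, 950, 1.5, 4.0, 220, 130, 8, 26, 5.0),
    Thermoanaerobaculia = c(4.2e6, 62, 88.8, 3900, 980, 1.4, 3.0, 170, 105, 6, 32, 6.6),
    Vicinamibacteria    = c(4.8e6, 63, 88.0, 4300, 960, 1.2, 3.5, 200, 120, 7, 27, 6.5),
    Aminicenantia       = c(3.4e6, 55, 90.5, 3100, 1010, 0.8, 2.0, 110, 80, 4, 34, 7.0),
    Holophagae          = c(3.6e6, 56, 90.0, 3300, 1000, 0.9, 2.2, 120, 85, 4, 24, 6.9))
  colnames(baseline) <- feats
  baseline <- baseline[classes, , drop = FALSE]

  hab_off <- matrix(0, length(habitats), length(feats),
                    dimnames = list(habitats, feats))
  hab_off["soil", c("n_peptidases", "coding_density", "n_genes",
                    "mean_gene_length", "pred_ogt", "pred_ph")] <-
    c(10, -0.5, 150, -15, -1.5, -0.3)

  res_sd <- c(genome_size = 4e5, gc = 2, coding_density = 1, n_genes = 350,
              mean_gene_length = 30, n_crisprs = 1, n_viral_contigs = 1.5,
              n_cazymes = 25, n_peptidases = 15, n_bgcs = 2, pred_ogt = 2,
              pred_ph = 0.4)

  spl <- c("Blastocatellia", "Terriglobia", "Thermoanaerobaculia",
           "Vicinamibacteria")
  aerobe <- list(baseline = 0,
                 class_offset = setNames(
                   ifelse(classes %in% spl, 1.5, -1.0), classes),
                 habitat_offset = setNames(rep(0, length(habitats)),
                                           habitats))

  arch_prob <- matrix(c(0.40, 0.35, 0.25), length(classes), 3L,
                      byrow = TRUE,
                      dimnames = list(classes, STRATEGY_LABELS))
  arch_prob["Terriglobia", ] <- c(0.20, 0.30, 0.50)

  # presence/absence metabolic traits on the logit scale: two enriched in
  # the soil-preferring classes, two in the non-soil-preferring classes
  tnames <- c("o2_respiration_high_affinity", "trehalose_biosynthesis",
              "nitrate_to_ammonium", "polyamine_biosynthesis")
  cls_off <- matrix(0, length(classes), length(tnames),
                    dimnames = list(classes, tnames))
  cls_off[, c(1, 2)] <- ifelse(classes %in% spl, 1.5, -1.5)
  cls_off[, c(3, 4)] <- ifelse(classes %in% spl, -1.5, 1.5)
  binary_traits <- list(
    baseline = setNames(rep(0, length(tnames)), tnames),
    class_offset = cls_off,
    habitat_offset = matrix(0, length(habitats), length(tnames),
                            dimnames = list(habitats, tnames)))

  genome_sim_config(
    classes = classes, habitats = habitats, n_per_cell = n_per_cell,
    class_baseline = baseline, habitat_offset = hab_off,
    residual_sd = res_sd,
    integer_features = c("n_genes", "n_crisprs", "n_viral_contigs",
                         "n_cazymes", "n_peptidases", "n_bgcs"),
    binary_traits = binary_traits,
    aerobe_logit = aerobe,
    archetype_prob = arch_prob,
    seed = seed)
}
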