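# Shared fixtures and independent oracles. Oracles here deliberately use a
# different computational route than the package (exhaustive row iteration,
# SVD pseudoinverse projections) so agreement is evidence, not tautology.

# A tiny hand-written detection table spanning two classes / three families.
tiny_detection_table <- function() {
  lin <- c(
    F1 = "d__Bacteria;p__Acidobacteriota;c__C1;o__O1;f__F1",
    F2 = "d__Bacteria;p__Acidobacteriota;c__C1;o__O1;f__F2",
    F3 = "d__Bacteria;p__Acidobacteriota;c__C2;o__O2;f__F3")
  data.frame(
    dataset_id = c("s1", "s1", "s2", "m1", "m2", "e1"),
    habitat = c("soil", "soil", "soil", "marine", "marine", "engineered"),
    lineage = lin[c("F1", "F2", "F1", "F3", "F1", "F3")],
    relative_abundance_pct = c(1.2, 0.8, 2.0, 0.5, 0.1, 3.0),
    stringsAsFactors = FALSE)
}

tiny_census <- function() {
  c(soil = 3, marine = 2, engineered = 1, "host-associated" = 0)
}

# Brute-force ubiquity / mean abundance by exhaustive row iteration.
brute_ubiquity <- function(table, taxon, rank, habitat_group, census) {
  census <- if (is.data.frame(census)) {
    setNames(census$n_datasets, census$habitat)
  } else census
  hit_ds <- character(0)
  ab_by_ds <- list()
  for (i in seq_len(nrow(table))) {
    if (!table$habitat[i] %in% habitat_group) next
    nm <- habpref::lineage_at_rank(
      habpref::parse_lineage(table$lineage[i]), rank)
    if (is.na(nm) || nm != taxon) next
    ds <- table$dataset_id[i]
    hit_ds <- union(hit_ds, ds)
    ab_by_ds[[ds]] <- sum(c(ab_by_ds[[ds]], 0),
                          table$relative_abundance_pct[i])
  }
  n_tot <- sum(census[habitat_group])
  list(n_detected = length(hit_ds),
       ubiquity = 100 * length(hit_ds) / n_tot,
       mean_abundance = if (length(ab_by_ds))
         mean(unlist(ab_by_ds)) else 0)
}

# RSS of the least-squares projection of y onto col(X), via SVD
# pseudoinverse (independent of the package's QR route).
svd_proj_rss <- function(X, y) {
  s <- svd(X)
  keep <- s$d > max(dim(X)) * max(s$d) * 1e-12
  U <- s$u[, keep, drop = FALSE]
  fit <- U %*% (t(U) %*% y)
  sum((y - fit)^2)
}

indicator <- function(f) {
  f <- factor(f)
  m <- outer(f, levels(f), "==") + 0
  colnames(m) <- levels(f)
  m
}

# Sequential SS oracle from successive projections onto nested design
# spaces built from raw indicator matrices.
seq_ss_oracle <- function(y, a, b) {
  n <- length(y)
  one <- matrix(1, n, 1)
  Xa <- cbind(one, indicator(a))
  Xab <- cbind(Xa, indicator(b))
  Xfull <- indicator(interaction(a, b, drop = TRUE))
  r0 <- sum((y - mean(y))^2)
  ra <- svd_proj_rss(Xa, y)
  rab <- svd_proj_rss(Xab, y)
  rf <- svd_proj_rss(Xfull, y)
  c(a = r0 - ra, b = ra - rab, ab = rab - rf, res = rf)
}

# Balanced one-feature genome-sim config whose class factor explains a
# stated share of the population variance (residual sd 1, no habitat or
# interaction effects).
share_config <- function(share, n_per_cell = 50L, seed = 1L) {
  classes <- paste0("C", 1:6)
  z <- 1:6 - mean(1:6)
  z <- z / sqrt(mean(z^2))  # population variance 1
  baseline <- matrix(sqrt(share / (1 - share)) * z, ncol = 1,
                     dimnames = list(classes, "feat"))
  habpref::genome_sim_config(
    classes = classes, habitats = c("soil", "other"),
    n_per_cell = matrix(n_per_cell, 6, 2),
    class_baseline = baseline,
    residual_sd = c(feat = 1),
    seed = seed)
}
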