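test_that("ubiquity agrees with exhaustive row iteration on small tables", {
  tab <- tiny_detection_table()
  census <- tiny_census()
  for (tx in c("F1", "F2", "F3")) {
    for (grp in list("soil", "marine", c("marine", "engineered"))) {
      got <- compute_ubiquity(tab, tx, "family", grp, census)
      ref <- brute_ubiquity(tab, tx, "family", grp, census)
      expect_equal(got$n_detected, ref$n_detected)
      expect_equal(got$ubiquity, ref$ubiquity)
      expect_equal(got$mean_abundance, ref$mean_abundance)
    }
  }
  # class-level ubiquity via aggregation also matches brute force
  cls <- aggregate_to_rank(tab, "class")
  got <- compute_ubiquity(cls, "C1", "class", "soil", census)
  expect_equal(got$ubiquity, brute_ubiquity(cls, "C1", "class", "soil",
                                            census)$ubiquity)
  expect_equal(got$ubiquity, 100 * 2 / 3)
})

test_that("ubiquity reproduces the published phylum-level arithmetic", {
  # 9,814 detected of 10,250 soil datasets -> 95.7% at one decimal
  det <- data.frame(dataset_id = sprintf("soil_%05d", 1:9814),
                    habitat = "soil",
                    lineage = "d__Bacteria;p__Acidobacteriota",
                    relative_abundance_pct = 10,
                    stringsAsFactors = FALSE)
  census <- c(soil = 10250)
  u <- compute_ubiquity(det, "Acidobacteriota", "phylum", "soil", census)
  expect_equal(round(u$ubiquity, 1), 95.7)
  expect_equal(u$n_detected, 9814L)
  # a taxon with zero rows in the group
  z <- compute_ubiquity(det, "Nothing", "phylum", "soil", census)
  expect_equal(z$ubiquity, 0)
  expect_equal(z$mean_abundance, 0)
})

test_that("ubiquity error contracts hold", {
  tab <- tiny_detection_table()
  expect_error(compute_ubiquity(tab, "F1", "family", "host-associated",
                                tiny_census()),
               "zero datasets")
  expect_error(compute_ubiquity(tab, "F1", "family", "soil",
                                c(soil = 3, marine = 2)),
               "uncensused")
  expect_error(compute_ubiquity(tab, "F1", "family", "desert",
                                tiny_census()),
               "census does not cover")
  # detections exceeding the census are inconsistent
  expect_error(compute_ubiquity(tab, "F1", "family", "soil",
                                c(soil = 1, marine = 2, engineered = 1,
                                  "host-associated" = 0)),
               "inconsistency")
})

test_that("soil/non-soil partition applies the default exclusion", {
  p <- soil_nonsoil_partition(c("soil", "marine", "host-associated"))
  expect_equal(p$nonsoil, "marine")
  p2 <- soil_nonsoil_partition(c("soil", "marine", "host-associated"),
                               exclude = character(0))
  expect_setequal(p2$nonsoil, c("marine", "host-associated"))
  expect_error(soil_nonsoil_partition(c("marine", "engineered")), "soil")
  # excluding every non-soil label leaves nothing to compare against
  tab <- tiny_detection_table()
  expect_error(
    compute_preference_metrics(tab, "F1", "family", tiny_census(),
                               exclude = c("marine", "engineered",
                                           "host-associated")),
    "non-soil habitat group is empty")
})

test_that("preference metrics divide ubiquities and mark zero denominators", {
  tab <- tiny_detection_table()
  census <- tiny_census()
  m <- compute_preference_metrics(tab, "F1", "family", census)
  # soil 2/3, non-soil (marine+engineered) 1/3
  expect_equal(m$soil_ubiquity, 100 * 2 / 3)
  expect_equal(m$nonsoil_ubiquity, 100 * 1 / 3)
  expect_equal(m$preference_ratio, 2)
  # the published phylum ubiquities imply a ratio just over 2.5
  expect_equal(95.7 / 37.6, 2.545, tolerance = 1e-3)
  # taxon only in soil: infinite marker, no exception
  m2 <- compute_preference_metrics(tab, "F2", "family", census)
  expect_identical(m2$preference_ratio, Inf)
  # equal ubiquity both sides gives ratio 1
  eq <- data.frame(dataset_id = c("s1", "m1"),
                   habitat = c("soil", "marine"),
                   lineage = "d__B;p__P;c__C;o__O;f__Fq",
                   relative_abundance_pct = c(1, 1),
                   stringsAsFactors = FALSE)
  meq <- compute_preference_metrics(eq, "Fq", "family",
                                    c(soil = 2, marine = 2))
  expect_equal(meq$preference_ratio, 1)
  # absent taxon: all-zero metrics with a flag, never a crash
  ab <- compute_preference_metrics(tab, "Ghost", "family", census)
  expect_true(ab$absent)
  expect_equal(ab$soil_ubiquity, 0)
  expect_equal(ab$preference_ratio, 0)
})

test_that("classification follows the published rule at its cutoffs", {
  mk <- function(su, pr, ar) {
    data.frame(taxon = "t", soil_ubiquity = su, nonsoil_ubiquity = su / pr,
               preference_ratio = pr, soil_mean_abundance = 1,
               nonsoil_mean_abundance = 1 / ar, abundance_ratio = ar,
               absent = FALSE)
  }
  th <- preference_thresholds()
  # the four published exemplars
  expect_equal(classify_preference(mk(92.61, 6, 5.2), 92.61, th)$label, "SPL")
  expect_equal(classify_preference(mk(11.5, 0.5, 0.4), 30, th)$label, "NSPL")
  expect_equal(classify_preference(mk(33.47, 6, 0.8), 33.47, th)$label,
               "intermediate")
  expect_equal(classify_preference(mk(3.2, 2, 0.5), 3.2, th)$label, "rare")
  # boundaries are strict: exactly 75 / exactly 4 fall to intermediate
  expect_equal(classify_preference(mk(75, 10, 2), 75, th)$label,
               "intermediate")
  expect_equal(classify_preference(mk(90, 4, 2), 90, th)$label,
               "intermediate")
  # infinite ratio compares above any threshold
  expect_equal(classify_preference(mk(80, Inf, Inf), 80, th)$label, "SPL")
})

test_that("classification is monotone in soil ubiquity and preference ratio", {
  th <- preference_thresholds()
  mk <- function(su, pr, ar) {
    data.frame(taxon = "t", soil_ubiquity = su, nonsoil_ubiquity = 10,
               preference_ratio = pr, soil_mean_abundance = 1,
               nonsoil_mean_abundance = 1, abundance_ratio = ar,
               absent = FALSE)
  }
  set.seed(21)
  for (i in 1:200) {
    su <- runif(1, 0, 100); pr <- runif(1, 0, 10); ar <- runif(1, 0, 3)
    base <- classify_preference(mk(su, pr, ar), pmax(su, 5), th)$label
    if (base == "SPL") {
      up1 <- classify_preference(mk(min(su * 1.2, 100), pr, ar),
                                 pmax(min(su * 1.2, 100), 5), th)$label
      up2 <- classify_preference(mk(su, pr * 1.5, ar), pmax(su, 5),
                                 th)$label
      expect_equal(up1, "SPL")
      expect_equal(up2, "SPL")
    }
  }
})

test_that("profile_all_taxa recovers the constructed labels and partitions", {
  expect_equal(nrow(profile_all_taxa(
    tiny_detection_table()[0, ], "family", tiny_census())$calls), 0L)

  cfg <- default_ecosystem_config(seed = 31L, n_datasets_per_habitat = 200L)
  det <- generate_detection_table(cfg)
  prof <- profile_all_taxa(aggregate_to_rank(det, "family"), "family",
                           cfg$habitats)
  calls <- prof$calls
  expect_true(all(calls$label %in% c("SPL", "NSPL", "intermediate",
                                     "rare")))
  expect_equal(anyDuplicated(calls$taxon), 0L)
  # constructed soil family (p_soil = 0.9, p_else = 0.05): ratio ~ 18 > 4
  expect_equal(calls$label[calls$taxon == "FamSoilA1"], "SPL")
  # deterministic lexicographic order
  expect_equal(calls$taxon, sort(calls$taxon))
  # grid rows: one per (taxon, habitat)
  expect_equal(nrow(prof$grid),
               length(unique(calls$taxon)) * nrow(cfg$habitats))
})
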