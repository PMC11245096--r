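test_that("sequential SS matches the closed-form balanced example", {
  y <- c(1, 1, 1, 1, 3, 3, 3, 3)
  a <- rep(c("A1", "A2"), each = 4)
  b <- rep(c("B1", "B2"), 4)
  at <- twoway_anova_sequential(y, a, b)
  expect_equal(at$ss, c(8, 0, 0, 0))
  expect_equal(at$df, c(1L, 1L, 1L, 4L))
  pct <- percent_contribution(at)
  expect_equal(pct$pct, c(100, 0, 0, 0))
})

test_that("constant response degrades gracefully", {
  at <- twoway_anova_sequential(rep(2, 8), rep(c("x", "y"), each = 4),
                                rep(c("u", "v"), 4))
  expect_equal(at$ss, rep(0, 4))
  expect_true(all(is.na(at$f)))
  expect_true(all(is.na(at$p)))
  expect_true(all(is.na(percent_contribution(at)$pct)))
  expect_error(twoway_anova_sequential(rnorm(6), rep("a", 6),
                                       rep(c("u", "v"), 3)),
               "fewer than 2 levels")
})

test_that("sequential SS matches both independent oracles on unbalanced data", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(20:50, 1)
    a <- sample(paste0("a", 1:3), n, replace = TRUE)
    b <- sample(paste0("b", 1:3), n, replace = TRUE)
    y <- rnorm(n) + as.integer(factor(a)) * 0.5
    at <- twoway_anova_sequential(y, a, b)
    # oracle 1: successive SVD-pseudoinverse projections on raw indicators
    orc <- seq_ss_oracle(y, a, b)
    expect_equal(at$ss, unname(orc), tolerance = 1e-8)
    # oracle 2: R's own sequential ANOVA
    ref <- anova(lm(y ~ factor(a) * factor(b)))
    expect_equal(at$ss, ref[["Sum Sq"]], tolerance = 1e-10)
    expect_equal(at$df, ref[["Df"]])
    expect_equal(at$f[1:3], ref[["F value"]][1:3], tolerance = 1e-10)
    expect_equal(at$p[1:3], ref[["Pr(>F)"]][1:3], tolerance = 1e-10)
    # SS additivity
    expect_equal(sum(at$ss), attr(at, "total_ss"), tolerance = 1e-8)
  }
})

test_that("entry order matters exactly when the design is unbalanced", {
  set.seed(33)
  # unbalanced: order changes the A/B split
  n <- 40
  a <- sample(c("a1", "a2"), n, replace = TRUE, prob = c(0.7, 0.3))
  b <- ifelse(runif(n) < ifelse(a == "a1", 0.8, 0.2), "b1", "b2")
  y <- rnorm(n) + (a == "a1") + 0.5 * (b == "b1")
  ab <- twoway_anova_sequential(y, a, b)
  ba <- twoway_anova_sequential(y, a, b, order = "ba")
  expect_false(isTRUE(all.equal(ab$ss[1], ba$ss[2])))
  expect_equal(sum(ab$ss), sum(ba$ss))  # total is order-invariant
  # balanced: decomposition is order-invariant
  a2 <- rep(c("a1", "a2"), each = 20)
  b2 <- rep(c("b1", "b2"), 20)
  y2 <- rnorm(40) + (a2 == "a1")
  ab2 <- twoway_anova_sequential(y2, a2, b2)
  ba2 <- twoway_anova_sequential(y2, a2, b2, order = "ba")
  expect_equal(ab2$ss[1:2], ba2$ss[2:1], tolerance = 1e-10)
})

test_that("empty cells reduce the interaction df", {
  set.seed(44)
  # 3 x 2 design with the (a3, b2) cell empty: interaction df drops 2 -> 1
  a <- c(rep("a1", 10), rep("a2", 10), rep("a3", 10))
  b <- c(rep(c("b1", "b2"), 5), rep(c("b1", "b2"), 5), rep("b1", 10))
  y <- rnorm(30)
  at <- twoway_anova_sequential(y, a, b)
  expect_equal(at$df, c(2L, 1L, 1L, 25L))
  ref <- anova(lm(y ~ factor(a) * factor(b)))
  expect_equal(at$ss, ref[["Sum Sq"]], tolerance = 1e-10)
  expect_equal(at$df, ref[["Df"]])

  # fully confounded design: habitat and interaction get 0 df, 0 SS,
  # residual matches the cell-means fit
  b_conf <- c(rep("b1", 10), rep("b2", 10), rep("b1", 10))
  at2 <- twoway_anova_sequential(y, a, b_conf)
  expect_equal(at2$df, c(2L, 0L, 0L, 27L))
  expect_equal(at2$ss[2:3], c(0, 0))
  ref2 <- anova(lm(y ~ factor(a) * factor(b_conf)))
  expect_equal(at2$ss[4], ref2[["Sum Sq"]][nrow(ref2)], tolerance = 1e-10)
})

test_that("percent contribution is plain SS arithmetic over the full total", {
  at <- twoway_anova_sequential(c(1, 2, 3, 4, 6, 8, 9, 12),
                                rep(c("p", "q"), each = 4),
                                rep(c("u", "v"), 4))
  at$ss <- c(45, 45, 5, 5)  # forced arithmetic identity
  pct <- percent_contribution(at)
  expect_equal(pct$pct, c(45, 45, 5, 5))
})

test_that("Tukey HSD matches its closed-form and reference oracles", {
  # identical groups: difference 0, p ~ 1
  tk0 <- tukey_hsd(c(1, 2, 3, 1, 2, 3), rep(c("g1", "g2"), each = 3))
  expect_equal(tk0$diff, 0)
  expect_gt(tk0$p_adj, 0.999)

  # k = 2: adjusted p equals the pooled two-sample t-test p to 1e-6
  set.seed(5)
  y <- c(rnorm(7, 0), rnorm(11, 1))
  g <- rep(c("g1", "g2"), c(7, 11))
  tk <- tukey_hsd(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-6)

  # 3 unbalanced groups vs the reference implementation
  set.seed(8)
  y3 <- c(rnorm(5, 0), rnorm(9, 0.8), rnorm(6, 2))
  g3 <- factor(rep(c("a", "b", "c"), c(5, 9, 6)))
  tk3 <- tukey_hsd(y3, g3)
  ref <- TukeyHSD(aov(y3 ~ g3))$g3
  expect_equal(tk3$diff, unname(ref[, "diff"]), tolerance = 1e-10)
  expect_equal(tk3$lwr, unname(ref[, "lwr"]), tolerance = 1e-8)
  expect_equal(tk3$upr, unname(ref[, "upr"]), tolerance = 1e-8)
  expect_equal(tk3$p_adj, unname(ref[, "p adj"]), tolerance = 1e-8)

  # zero residual variance is flagged, not fatal
  tkz <- tukey_hsd(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_true(all(tkz$degenerate))
  expect_equal(tkz$p_adj, 0)
  expect_error(tukey_hsd(c(1, 2), c("a", "b")), "residual degree")
})

test_that("screen_features flags constructed effects and only those", {
  classes <- paste0("C", 1:3)
  cfg <- genome_sim_config(
    classes = classes, habitats = c("soil", "other"),
    n_per_cell = matrix(40L, 3, 2),
    class_baseline = matrix(c(50, 60, 70, 0, 0, 0), 3, 2,
                            dimnames = list(classes, c("gc", "flat"))),
    residual_sd = c(gc = 2, flat = 2), seed = 19L)
  sim <- generate_genome_table(cfg)
  scr <- screen_features(sim$genomes, c("gc", "flat"))
  expect_true(scr$gc$significant[["class"]])
  expect_false(scr$gc$significant[["habitat"]])
  expect_false(scr$flat$significant[["class"]])
  # Tukey ran only for the significant term
  expect_named(scr$gc$tukey, "class")
  expect_length(scr$flat$tukey, 0L)
  # summary flattening
  s <- summary(scr)
  expect_equal(nrow(s), 8L)
  expect_error(screen_features(sim$genomes, "nope"), "nope")
  expect_length(screen_features(sim$genomes, character(0)), 0L)
})

test_that("SPL-vs-NSPL grouping drops unmapped classes and needs a map", {
  cfg <- share_config(0.4, n_per_cell = 30L, seed = 29L)
  sim <- generate_genome_table(cfg)
  expect_error(screen_features(sim$genomes, "feat",
                               grouping = "SPL-vs-NSPL"),
               "spl_map")
  spl_map <- setNames(c("SPL", "SPL", "SPL", "NSPL", "NSPL", NA),
                      paste0("C", 1:6))
  scr <- screen_features(sim$genomes, "feat", grouping = "SPL-vs-NSPL",
                         spl_map = spl_map)
  expect_equal(scr$feat$anova$term[1], "preference")
})

test_that("binary traits run through the same machinery, constants skipped", {
  classes <- c("Cspl", "Cnspl")
  bt <- list(baseline = c(t_present = 50, t_split = 0),
             class_offset = matrix(c(0, 0, 2.2, -2.2), 2, 2,
                                   dimnames = list(classes,
                                                   c("t_present",
                                                     "t_split"))),
             habitat_offset = matrix(0, 2, 2,
                                     dimnames = list(c("soil", "other"),
                                                     c("t_present",
                                                       "t_split"))))
  cfg <- genome_sim_config(
    classes = classes, habitats = c("soil", "other"),
    n_per_cell = matrix(150L, 2, 2),
    class_baseline = matrix(0, 2, 1, dimnames = list(classes, "f")),
    residual_sd = c(f = 1), binary_traits = bt, seed = 37L)
  sim <- generate_genome_table(cfg)
  expect_message(
    ts <- binary_trait_screen(sim$traits, sim$genomes$lineage,
                              sim$genomes$habitat),
    "skipped 1 constant")
  expect_true(isTRUE(ts$t_present$skipped))
  # Bernoulli p 0.9 vs 0.1 split by class at n = 600: class term passes 1e-5
  expect_true(ts$t_split$significant[["class"]])
  expect_false(ts$t_split$significant[["habitat"]])
  expect_error(binary_trait_screen(data.frame(x = c(0, 2)), "d__B", "soil"),
               "0 or 1")
})

test_that("within-lineage soil contrasts flag only simulated offsets", {
  classes <- c("Coff", "Cnull")
  hoff <- matrix(0, 2, 2, dimnames = list(c("soil", "other"),
                                          c("n_peptidases", "quiet")))
  ioff <- array(0, dim = c(2, 2, 2),
                dimnames = list(classes, c("soil", "other"),
                                c("n_peptidases", "quiet")))
  ioff["Coff", "soil", "n_peptidases"] <- 30
  cfg <- genome_sim_config(
    classes = classes, habitats = c("soil", "other"),
    n_per_cell = matrix(60L, 2, 2),
    class_baseline = matrix(100, 2, 2,
                            dimnames = list(classes,
                                            c("n_peptidases", "quiet"))),
    interaction_offset = ioff, habitat_offset = hoff,
    residual_sd = c(n_peptidases = 10, quiet = 10), seed = 41L)
  sim <- generate_genome_table(cfg)
  res <- within_lineage_tests(sim$genomes, "Coff",
                              c("n_peptidases", "quiet"))
  expect_true(res$significant[res$feature == "n_peptidases"])
  expect_false(res$significant[res$feature == "quiet"])
  res_null <- within_lineage_tests(sim$genomes, "Cnull",
                                   c("n_peptidases", "quiet"))
  expect_false(any(res_null$significant))
  # a class with no soil genomes is indeterminate, not an error
  nosoil <- sim$genomes[sim$genomes$habitat != "soil", ]
  res_ind <- within_lineage_tests(nosoil, "Coff", "quiet")
  expect_true(all(res_ind$indeterminate))
  expect_true(all(is.na(res_ind$p)))
})
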