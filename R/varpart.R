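# Two-way sequential (Type-I) ANOVA variance partitioning of genomic
# features into lineage, habitat and interaction components, percent
# contributions, a hard significance screen, and Tukey-Kramer HSD post hoc
# comparisons. The sequential decomposition is computed from scratch by
# successive least-squares projections onto nested design spaces.

rss_rank <- function(X, y) {
  q <- qr(X)
  r <- qr.resid(q, y)
  list(rss = sum(r * r), rank = q$rank)
}

#' Two-way ANOVA with sequential (Type-I) sums of squares
#'
#' Decomposes the variance of `y` into factor A, factor B (fitted after A),
#' their interaction, and residual, by successive least-squares projections
#' onto the nested design spaces {1} < {1,A} < {1,A,B} < {cells of A x B}.
#' Each term's SS is the drop in residual SS when the term enters; degrees
#' of freedom are rank differences, so empty cells reduce the interaction df
#' automatically. On unbalanced data the decomposition depends on entry
#' order — the lineage factor enters first by convention here; pass
#' `order = "ba"` to reverse. F statistics are tested against the residual
#' mean square. A constant response yields all-zero SS with `NA` F and p
#' (no error).
#'
#' @param y Numeric response vector (no NAs).
#' @param a First factor (e.g. lineage/class labels).
#' @param b Second factor (e.g. habitat labels).
#' @param term_labels Labels used for the two factors in the output.
#' @param order `"ab"` (default, A first) or `"ba"`.
#' @return An `anova_table`: data.frame with columns `term`
#'   (A, B, interaction, residual), `df`, `ss`, `f`, `p`, `pct` (filled by
#'   [percent_contribution()]); attributes `total_ss` and `n`.
#' @examples
#' y <- c(1, 1, 1, 1, 3, 3, 3, 3)
#' a <- rep(c("A1", "A2"), each = 4)
#' b <- rep(c("B1", "B2"), 4)
#' twoway_anova_sequential(y, a, b)
#' @export
twoway_anova_sequential <- function(y, a, b,
                                    term_labels = c("class", "habitat"),
                                    order = c("ab", "ba")) {
  order <- match.arg(order)
  if (order == "ba") {
    tmp <- a; a <- b; b <- tmp
    term_labels <- rev(term_labels)
  }
  y <- as.numeric(y)
  if (anyNA(y) || any(!is.finite(y))) {
    stop("response contains non-finite values", call. = FALSE)
  }
  a <- droplevels(factor(a))
  b <- droplevels(factor(b))
  n <- length(y)
  if (length(a) != n || length(b) != n) {
    stop("y, a and b must have equal length", call. = FALSE)
  }
  if (nlevels(a) < 2L) {
    stop(sprintf("factor '%s' has fewer than 2 levels", term_labels[1L]),
         call. = FALSE)
  }
  if (nlevels(b) < 2L) {
    stop(sprintf("factor '%s' has fewer than 2 levels", term_labels[2L]),
         call. = FALSE)
  }
  cells <- droplevels(interaction(a, b, drop = TRUE))

  ybar <- mean(y)
  ss_tot <- sum((y - ybar)^2)
  fit_a <- rss_rank(model.matrix(~a), y)
  fit_ab <- rss_rank(model.matrix(~ a + b), y)
  fit_full <- rss_rank(model.matrix(~ 0 + cells), y)

  ss <- c(max(ss_tot - fit_a$rss, 0),
          max(fit_a$rss - fit_ab$rss, 0),
          max(fit_ab$rss - fit_full$rss, 0),
          max(fit_full$rss, 0))
  df <- c(fit_a$rank - 1L,
          fit_ab$rank - fit_a$rank,
          fit_full$rank - fit_ab$rank,
          n - fit_full$rank)

  degenerate <- ss_tot <= 1e-12 * max(1, sum(y * y))
  mse <- if (df[4L] > 0L) ss[4L] / df[4L] else NA_real_
  fstat <- rep(NA_real_, 4L)
  pval <- rep(NA_real_, 4L)
  if (!degenerate && !is.na(mse) && mse > 0) {
    for (i in 1:3) {
      if (df[i] > 0L) {
        fstat[i] <- (ss[i] / df[i]) / mse
        pval[i] <- pf(fstat[i], df[i], df[4L], lower.tail = FALSE)
      }
    }
  }
  out <- data.frame(
    term = c(term_labels[1L], term_labels[2L], "interaction", "residual"),
    df = df, ss = ss, f = fstat, p = pval, pct = NA_real_,
    stringsAsFactors = FALSE)
  structure(out, class = c("anova_table", "data.frame"),
            total_ss = ss_tot, n = n, degenerate = degenerate)
}

#' Fill percent contributions into an ANOVA table
#'
#' A term's percent contribution is its share of the *total* sum of squares,
#' residual included: `100 * SS(term) / sum(SS)`. The residual is part of
#' the denominator so that contributions of different responses are
#' comparable (a term explaining nothing contributes 0%, not NA). A
#' zero-variance response yields `NA` percentages.
#'
#' @param t An `anova_table` from [twoway_anova_sequential()].
#' @return The table with `pct` filled.
#' @export
percent_contribution <- function(t) {
  stopifnot(inherits(t, "anova_table"))
  total <- sum(t$ss)
  degenerate <- isTRUE(attr(t, "degenerate")) || total <= 0
  t$pct <- if (degenerate) NA_real_ else 100 * t$ss / total
  t
}

#' @export
print.anova_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$ss <- signif(df$ss, 6)
  df$f <- signif(df$f, 5)
  df$p <- signif(df$p, 4)
  df$pct <- round(df$pct, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tukey-Kramer HSD multiple comparisons of group means
#'
#' All pairwise differences of group means with simultaneous confidence
#' intervals and adjusted p-values from the studentized-range distribution.
#' Unequal group sizes use the Tukey-Kramer standard error
#' `sqrt(MSE/2 * (1/n_i + 1/n_j))`. With exactly two groups the adjusted p
#' equals the pooled two-sample t-test p (q = sqrt(2)|t|). Zero residual
#' variance is flagged: p is 0 or 1 by whether the means differ and the
#' interval is degenerate.
#'
#' @param y Numeric response.
#' @param g Group labels (>= 2 non-empty groups, >= 1 residual df).
#' @param alpha Level for the simultaneous confidence intervals.
#' @return data.frame, one row per pair: `pair`, `diff` (second minus first
#'   in sorted label order, reported as "lvl2-lvl1"), `lwr`, `upr`, `p_adj`,
#'   `degenerate`; attributes `df_res`, `mse`.
#' @export
tukey_hsd <- function(y, g, alpha = 0.05) {
  y <- as.numeric(y)
  g <- droplevels(factor(g))
  n <- length(y)
  if (length(g) != n) stop("y and g must have equal length", call. = FALSE)
  kk <- nlevels(g)
  if (kk < 2L) stop("need at least 2 groups", call. = FALSE)
  ni <- tabulate(g, nbins = kk)
  if (any(ni == 0L)) stop("a group has size 0", call. = FALSE)
  df_res <- n - kk
  if (df_res < 1L) {
    stop("need at least one residual degree of freedom", call. = FALSE)
  }
  means <- tapply(y, g, mean)
  ss_w <- sum((y - means[g])^2)
  mse <- ss_w / df_res
  lev <- levels(g)
  pairs <- utils::combn(kk, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(idx) {
    i <- pairs[1L, idx]; j <- pairs[2L, idx]
    d <- means[[j]] - means[[i]]
    se <- sqrt(mse / 2 * (1 / ni[i] + 1 / ni[j]))
    if (mse > 0) {
      qobs <- abs(d) / se
      p <- ptukey(qobs, nmeans = kk, df = df_res, lower.tail = FALSE)
      hw <- qtukey(1 - alpha, nmeans = kk, df = df_res) * se
      degen <- FALSE
    } else {
      p <- if (d == 0) 1 else 0
      hw <- 0
      degen <- TRUE
    }
    data.frame(pair = paste0(lev[j], "-", lev[i]),
               diff = d, lwr = d - hw, upr = d + hw,
               p_adj = p, degenerate = degen,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "df_res") <- df_res
  attr(out, "mse") <- mse
  out
}

# Derive the lineage factor used by the screens.
screen_factor_a <- function(genomes, grouping, spl_map) {
  cls <- lineage_names_at_rank(genomes$lineage, "class")
  if (grouping == "by-class") {
    cls
  } else {
    if (is.null(spl_map)) {
      stop("grouping 'SPL-vs-NSPL' requires spl_map (class -> SPL/NSPL)",
           call. = FALSE)
    }
    unname(spl_map[cls])
  }
}

screen_factor_b <- function(habitat, habitat_mode) {
  if (habitat_mode == "soil-vs-nonsoil") {
    ifelse(habitat == "soil", "soil", "non-soil")
  } else {
    habitat
  }
}

#' Screen genomic features for lineage / habitat / interaction effects
#'
#' Runs [twoway_anova_sequential()] on each requested feature with lineage
#' (class, or the SPL/NSPL dichotomy) as the first factor and habitat
#' (soil vs non-soil by default, or the full source label) as the second,
#' fills percent contributions, flags terms passing the hard significance
#' screen, and runs [tukey_hsd()] on the significant main factors only.
#'
#' @param genomes Genome table: `genome_id`, `lineage`, `habitat` and one
#'   numeric column per feature.
#' @param features Character vector of feature column names.
#' @param grouping `"by-class"` or `"SPL-vs-NSPL"`.
#' @param spl_map Named character vector mapping class names to `"SPL"` /
#'   `"NSPL"` (required for `"SPL-vs-NSPL"`; unmapped classes are dropped).
#' @param habitat_mode `"soil-vs-nonsoil"` (default) or `"source"` (use the
#'   habitat labels as-is).
#' @param alpha Significance screen on the F-test p-value (default 1e-5).
#' @param run_tukey Run post hoc comparisons on significant main terms.
#' @param order Factor entry order, see [twoway_anova_sequential()].
#' @return A list of class `"feature_screen"`, one element per feature:
#'   `feature`, `anova` (with `pct`), `significant` (named logical per
#'   term), `tukey` (list with entries for significant main factors).
#' @export
screen_features <- function(genomes, features,
                            grouping = c("by-class", "SPL-vs-NSPL"),
                            spl_map = NULL,
                            habitat_mode = c("soil-vs-nonsoil", "source"),
                            alpha = 1e-5, run_tukey = TRUE,
                            order = "ab") {
  grouping <- match.arg(grouping)
  habitat_mode <- match.arg(habitat_mode)
  miss <- setdiff(features, names(genomes))
  if (length(miss)) {
    stop(sprintf("feature column(s) missing from genome table: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  a_all <- screen_factor_a(genomes, grouping, spl_map)
  b_all <- screen_factor_b(genomes$habitat, habitat_mode)
  keep <- !is.na(a_all)
  term_labels <- c(if (grouping == "by-class") "class" else "preference",
                   "habitat")
  out <- lapply(features, function(feat) {
    y <- as.numeric(genomes[[feat]])[keep]
    at <- percent_contribution(twoway_anova_sequential(
      y, a_all[keep], b_all[keep], term_labels = term_labels, order = order))
    sig <- setNames(!is.na(at$p) & at$p < alpha, at$term)
    tk <- list()
    if (run_tukey) {
      if (isTRUE(sig[[term_labels[1L]]])) {
        tk[[term_labels[1L]]] <- tukey_hsd(y, a_all[keep])
      }
      if (isTRUE(sig[[term_labels[2L]]])) {
        tk[[term_labels[2L]]] <- tukey_hsd(y, b_all[keep])
      }
    }
    list(feature = feat, anova = at, significant = sig, tukey = tk)
  })
  names(out) <- features
  structure(out, class = "feature_screen", alpha = alpha,
            grouping = grouping, habitat_mode = habitat_mode)
}

#' Flatten a feature screen into one data.frame
#'
#' @param object A `"feature_screen"` from [screen_features()] or
#'   [binary_trait_screen()].
#' @param ... Unused.
#' @return data.frame with columns `feature`, `term`, `df`, `ss`, `f`, `p`,
#'   `pct`, `significant` (skipped constant traits carry NA rows).
#' @export
summary.feature_screen <- function(object, ...) {
  rows <- lapply(object, function(e) {
    if (isTRUE(e$skipped)) {
      return(data.frame(feature = e$feature, term = NA_character_,
                        df = NA_integer_, ss = NA_real_, f = NA_real_,
                        p = NA_real_, pct = NA_real_, significant = NA,
                        stringsAsFactors = FALSE))
    }
    a <- as.data.frame(e$anova)
    a$feature <- e$feature
    a$significant <- unname(e$significant[a$term])
    a[, c("feature", "term", "df", "ss", "f", "p", "pct", "significant")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.feature_screen <- function(x, ...) {
  cat(sprintf("<feature_screen> %d feature(s), alpha = %g\n",
              length(x), attr(x, "alpha")))
  print(utils::head(summary(x), 12L))
  invisible(x)
}

#' Screen binary metabolic traits
#'
#' Applies the same two-way sequential ANOVA machinery to 0/1
#' presence/absence trait columns (a linear-probability ANOVA on the
#' dichotomous response, exactly as one would after recoding a
#' presence/absence matrix numerically). Traits constant across all genomes
#' are skipped with a log entry rather than an error.
#'
#' @param traits Genome x trait matrix or data.frame with entries in {0, 1};
#'   rows align with `lineage` / `habitat`.
#' @param lineage Character vector of GTDB-style lineage strings, one per
#'   genome row.
#' @param habitat Habitat label per genome row.
#' @inheritParams screen_features
#' @return A `"feature_screen"` list, one entry per trait; skipped constant
#'   traits have `skipped = TRUE` and a `reason`.
#' @export
binary_trait_screen <- function(traits, lineage, habitat,
                                grouping = c("by-class", "SPL-vs-NSPL"),
                                spl_map = NULL,
                                habitat_mode = c("soil-vs-nonsoil", "source"),
                                alpha = 1e-5, order = "ab") {
  grouping <- match.arg(grouping)
  habitat_mode <- match.arg(habitat_mode)
  traits <- as.data.frame(traits)
  vals <- unlist(traits, use.names = FALSE)
  if (length(vals) && !all(vals %in% c(0, 1))) {
    stop("trait matrix entries must all be 0 or 1", call. = FALSE)
  }
  if (nrow(traits) != length(lineage) || nrow(traits) != length(habitat)) {
    stop("traits rows must align with lineage and habitat vectors",
         call. = FALSE)
  }
  genomes <- data.frame(genome_id = seq_len(nrow(traits)),
                        lineage = lineage, habitat = habitat,
                        stringsAsFactors = FALSE)
  a_all <- screen_factor_a(genomes, grouping, spl_map)
  b_all <- screen_factor_b(habitat, habitat_mode)
  keep <- !is.na(a_all)
  term_labels <- c(if (grouping == "by-class") "class" else "preference",
                   "habitat")
  out <- lapply(names(traits), function(tr) {
    y <- as.numeric(traits[[tr]])[keep]
    if (length(unique(y)) < 2L) {
      return(list(feature = tr, skipped = TRUE,
                  reason = "constant trait (present or absent in all genomes)"))
    }
    at <- percent_contribution(twoway_anova_sequential(
      y, a_all[keep], b_all[keep], term_labels = term_labels, order = order))
    sig <- setNames(!is.na(at$p) & at$p < alpha, at$term)
    list(feature = tr, anova = at, significant = sig, tukey = list())
  })
  names(out) <- names(traits)
  n_skip <- sum(vapply(out, function(e) isTRUE(e$skipped), logical(1L)))
  if (n_skip) {
    message(sprintf("binary_trait_screen: skipped %d constant trait(s)",
                    n_skip))
  }
  structure(out, class = "feature_screen", alpha = alpha,
            grouping = grouping, habitat_mode = habitat_mode,
            n_skipped = n_skip)
}

oneway_anova <- function(y, g) {
  g <- droplevels(factor(g))
  kk <- nlevels(g)
  n <- length(y)
  means <- tapply(y, g, mean)
  gm <- mean(y)
  ni <- tabulate(g, nbins = kk)
  ss_b <- sum(ni * (means - gm)^2)
  ss_w <- sum((y - means[g])^2)
  df_b <- kk - 1L
  df_w <- n - kk
  if (df_w > 0L && ss_w > 0) {
    f <- (ss_b / df_b) / (ss_w / df_w)
    p <- pf(f, df_b, df_w, lower.tail = FALSE)
  } else {
    f <- NA_real_
    p <- NA_real_
  }
  list(ss_between = ss_b, ss_within = ss_w, df_between = df_b,
       df_within = df_w, f = f, p = p)
}

#' Within-lineage soil vs non-soil comparisons
#'
#' Restricted to the genomes of one class, tests each feature for a
#' difference between soil-derived and non-soil-derived genomes (one-way
#' ANOVA, equivalent to a pooled t-test) with the same hard significance
#' screen. If either side has fewer than 2 genomes every feature is flagged
#' indeterminate rather than raising an error.
#'
#' @param genomes Genome table.
#' @param class_name Class whose genomes to test.
#' @param features Feature column names.
#' @param alpha Significance screen (default 1e-5).
#' @return data.frame: `class`, `feature`, `n_soil`, `n_nonsoil`,
#'   `mean_soil`, `mean_nonsoil`, `f`, `p`, `significant`, `indeterminate`.
#' @export
within_lineage_tests <- function(genomes, class_name, features,
                                 alpha = 1e-5) {
  miss <- setdiff(features, names(genomes))
  if (length(miss)) {
    stop(sprintf("feature column(s) missing from genome table: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  cls <- lineage_names_at_rank(genomes$lineage, "class")
  sub <- genomes[!is.na(cls) & cls == class_name, , drop = FALSE]
  is_soil <- sub$habitat == "soil"
  n_s <- sum(is_soil)
  n_ns <- sum(!is_soil)
  indet <- n_s < 2L || n_ns < 2L
  rows <- lapply(features, function(feat) {
    y <- as.numeric(sub[[feat]])
    if (indet) {
      return(data.frame(class = class_name, feature = feat,
                        n_soil = n_s, n_nonsoil = n_ns,
                        mean_soil = if (n_s) mean(y[is_soil]) else NA_real_,
                        mean_nonsoil = if (n_ns) mean(y[!is_soil]) else NA_real_,
                        f = NA_real_, p = NA_real_, significant = NA,
                        indeterminate = TRUE, stringsAsFactors = FALSE))
    }
    aw <- oneway_anova(y, ifelse(is_soil, "soil", "non-soil"))
    data.frame(class = class_name, feature = feat,
               n_soil = n_s, n_nonsoil = n_ns,
               mean_soil = mean(y[is_soil]),
               mean_nonsoil = mean(y[!is_soil]),
               f = aw$f, p = aw$p,
               significant = !is.na(aw$p) && aw$p < alpha,
               indeterminate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
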