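---
title: "Methods: habitat preference, niche breadth and variance partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat preference, niche breadth and variance partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habpref)
```

# The model and its assumptions

`habpref` operationalises two complementary questions about a set of
microbial lineages. The first is ecological: given a large corpus of
habitat-labelled metagenomic datasets and a record of which datasets each
taxon was detected in (and at what relative read abundance), where does
each lineage live, and how strongly does it prefer soil? The second is
comparative-genomic: given per-genome features and the habitat each genome
was recovered from, how much of the between-genome variation is explained
by phylogenetic affiliation (the class a genome belongs to) versus the
habitat it came from?

## Ecological statistics

For a taxon $t$ at rank $r$ and a habitat group $H$ with census
$n_H$ datasets,

$$\mathrm{ubiquity}(t, H) = 100 \cdot \frac{\#\{\text{datasets in } H
\text{ with } \geq 1 \text{ detection of } t\}}{n_H}.$$

The census is a separate input because undetected datasets leave no rows in
a detection table; the denominator is the habitat-wide total, not the
number of datasets the table happens to mention. The *preference ratio* is
the quotient of the soil and pooled non-soil ubiquity **percentages** (not
raw dataset counts, which unequal habitat sizes would distort), and the
*abundance ratio* the quotient of mean relative abundances. Host-associated
datasets are excluded from the non-soil pool by default: they dominate
public archives and would deflate every non-soil ubiquity.

Classification applies strict inequalities at the standard cutoffs
(75% soil ubiquity, preference ratio 4, abundance ratio 1, 4% rarity
cutoff; `preference_thresholds()`): a taxon below 4% ubiquity in *every*
habitat is **rare**; else soil ubiquity > 75 *and* ratio > 4 gives **SPL**;
else ratio < 4 *and* abundance ratio < 1 gives **NSPL**; everything else —
including boundary values — is **intermediate**. Infinite ratios (a taxon
absent from the non-soil pool) compare as larger than any finite cutoff, so
a soil-exclusive ubiquitous taxon is SPL, not an error.

**Open choice — mean abundance.** Whether published mean abundances average
over detected datasets only, or spread the detected mass over all censused
datasets, is not stated by the sources this design follows. Detection
tables only carry abundance for detected rows, so the default averages over
detected datasets; `include_zeros = TRUE` switches to the all-datasets
denominator. The choice never affects ubiquity or the preference ratio.

## Niche breadth

Breadth is a distinct-count: habitats with at least one detection (or at
least one genome). Two inequivalent generalist definitions coexist in
practice and are kept explicit rather than silently mixed:
detection-based calls default to *strict-all-habitats* (a generalist must
appear in all declared habitats), genome-based calls to *at-least-k* with
k = 2. Taxa with strict-mode breadth strictly between 1 and the habitat
count are reported as `intermediate-breadth`; collapsing them into either
bin would invent a rule. Rarely sampled taxa are the known failure mode
(they masquerade as specialists), so records under an evidence cutoff
(250 studies / 5 genomes by default, 0 to disable) are `indeterminate`.
Raising the cutoff can only grow the indeterminate set — a tested
monotonicity invariant.

## Sequential variance partitioning

For each response $y$ (a continuous genomic feature, or a 0/1 trait run
through the identical linear machinery), the decomposition is the classic
sequential (Type-I) ANOVA for `y ~ A + B + A:B` with the lineage factor
entered first: each term's sum of squares is the drop in residual SS when
the term's design space is added, computed by QR projections onto the
nested spaces $\{1\} \subset \{1,A\} \subset \{1,A,B\} \subset
\{\text{cells}\}$. Degrees of freedom are rank differences, so empty
class × habitat cells reduce the interaction df automatically and a fully
confounded factor degrades to 0 df / 0 SS rather than erroring.

**Open choice — SS type and entry order.** Neither is dictated by the
sequential-ANOVA convention alone; on unbalanced data (and genome
collections are always unbalanced) Type-I SS depends on order. The package
enters lineage first, matching the stated model ("class, habitat, and their
interaction"), and exposes `order = "ba"`; tests assert both that order
*does* change the split on unbalanced data and that it does not on balanced
data, so the sensitivity is documented rather than hidden.

Percent contribution is a term's share of the **total** SS, residual
included. The residual belongs in the denominator because contributions
are compared across responses: a lineage contribution of 45% alongside a
habitat contribution of 0.3–12% only makes sense against a common total
containing unexplained variance.

The significance screen is a hard $p < 10^{-5}$ on each term's F-test, with
no further multiplicity correction — that is the procedure being modelled;
an FDR layer is deliberately out of scope. Tukey–Kramer HSD post hoc
comparisons run only on factors passing the screen, using
$\mathrm{SE}_{ij} = \sqrt{\mathrm{MSE}/2\,(1/n_i + 1/n_j)}$ and the
studentized-range distribution; with two groups the adjusted p collapses to
the pooled t-test p ($q = \sqrt{2}\,|t|$), which the tests verify to 1e-6.

## Life-history classification

Two indices summarise a genome's investment tradeoff: regulatory
flexibility $= n_{\mathrm{TF}} / n_{\mathrm{genes}}$ and resource
acquisition $= (n_{\mathrm{sec.CAZy}} + n_{\mathrm{sec.protease}} +
n_{\mathrm{sec.lipase}} + n_{\mathrm{BGC}}) / n_{\mathrm{transporter}}$.
Secretion status is an upstream annotation decision; the package consumes
already-secreted counts. Genomes with zero transporters have no defined
position in index space and are excluded with a logged flag.

A labelled training set seeds the classifier. Because the labels must be
preserved, the "k-means seeded by labelled points" idea is implemented as
supervised nearest-centroid: both dimensions are z-scored with the
**population** (1/n) mean and sd of all training points — so duplicating
the training set changes nothing — and each label's centroid is the mean of
its scaled points. Assignment is nearest centroid by Euclidean distance in
the scaled space; the two raw indices differ by an order of magnitude, so
unscaled distance would be dominated by one axis. Exact ties break by the
fixed order Scarcity < Ruderal < Competitor and carry a flag. An optional
unsupervised refinement pass was considered and rejected: a Lloyd update
can merge or permute label regions, destroying the property that every
training point of a separable set classifies to its own label (a tested
invariant).

The real labelled reference points are not redistributable, so
`synthetic_training_set()` ships a clearly labelled synthetic stand-in
(27 points, 9 per label, fixed seed) around the archetype coordinates of
`default_archetypes()`; any analysis of real genomes should supply its own
training TSV.

# What the synthetic generator emulates — and what it does not

`generate_detection_table()` draws, per habitat and dataset, independent
Bernoulli detections per family and log-normal relative abundances
truncated to (0, 100] (strictly positive, right-skewed — the qualitative
shape of read-fraction data; no published distributional facts exist for
such abundances, so the log-normal is a stand-in isolated behind the
config). Detections are independent across taxa within a dataset; no
co-occurrence or compositional coupling is simulated, because no downstream
statistic here consumes it. One global seed drives a per-taxon RNG stream,
so growing a config never perturbs existing taxa's draws.

The default world (`default_ecosystem_config()`) uses the seven standard
habitat groups at 500 datasets each and eight families whose detection
probabilities *construct* the classification outcomes: p = 0.9 in soil /
0.05 elsewhere (SPL, with higher soil abundance), 0.05 in soil / 0.5 in
non-host non-soil habitats (NSPL, with lower soil abundance), a moderate
soil-ubiquitous but lean family (intermediate), and p = 0.02 everywhere
(rare). Note the rare construction is genuinely stochastic at the 4%
cutoff: with 500 datasets a p = 0.02 family shows ≥ 4% ubiquity in some
habitat in a few percent of seeds, so a green rare-recovery test certifies
the typical world, not every draw.

`generate_genome_table()` implements exactly the structure the ANOVA
assumes — class baseline + habitat offset + interaction + Gaussian noise —
which is the point: the variance shares put in are known, so recovery can
be measured. The default cohort reuses the published per-class,
per-habitat genome counts (1,930 genomes, six classes) with baselines
chosen so soil-preferring classes have larger, GC-richer genomes, more
genes, expanded CAZyme/peptidase/BGC arsenals, and mostly aerobic calls,
and with modest soil offsets on the features reported habitat-responsive
(more peptidases; lower coding density; more, shorter genes; lower
predicted growth temperature and pH). These magnitudes are package choices
made once for realism, not fitted values. What a green test establishes is
therefore that the *machinery* recovers known structure — not that real
genome collections satisfy the additive-Gaussian model, have homoscedastic
classes, or lack phylogenetic autocorrelation below class rank (no mixed
models or phylogenetic contrasts are attempted, by design).

# Numerical choices

- **Parsing**: lineage ranks must be contiguous from domain; empty suffixes
  are missing ranks; all errors name the offending token. Names compare as
  exact trimmed strings — GTDB placeholder codes are ordinary names.
- **Projections**: all RSS values come from QR factorisations; sequential
  SS differences are clamped at 0 against roundoff; additivity of the four
  terms to the total SS is asserted at 1e-8 relative tolerance in tests.
- **Degenerate inputs**: a constant response yields all-zero SS with NA F,
  p and percent contributions (flagged, no exception); a factor with one
  level is a hard error; zero residual variance in Tukey gives p ∈ {0, 1}
  with degenerate intervals and a flag; constant binary traits are skipped
  with a log entry.
- **No internal rounding** anywhere; display rounding happens only in
  print methods and reports.
- **Seeds**: every generator takes an explicit integer seed, derives
  per-stream sub-seeds below $2^{31}$, and restores the caller's RNG state.

# Recovery tolerances

With fixed class effects explaining a share $s$ of variance at $n = 600$,
the recovered percent contribution of a single table has sampling sd of
roughly 2.5 points (the cross term between the fixed effects and the noise
in the class means dominates). The recovery check therefore asserts the
estimate aggregated over 20 seeds within ±5 points of the generating share
for $s \in \{10\%, 25\%, 40\%\}$ — a per-draw ±5 assertion over 60 draws
would fail routinely in a correctly implemented system, which is the wrong
thing to test. The null-calibration check (label permutations against the
$10^{-5}$ screen) bounds the observed significant-term count by the 99.9%
binomial envelope of the nominal rate, computed in closed form rather than
hard-coded.

# Known limitations

- The preference classification is threshold-based and inherits every
  discontinuity thresholds bring; taxa near a cutoff flip labels under
  resampling.
- Genus-level breadth is supported but has no in-package calibration
  beyond the distinct-count invariants.
- The 0/1 trait screen is a linear-probability ANOVA, faithful to the
  modelled procedure; it is not a logistic model and its p-values near
  saturated traits should be read accordingly.
- Crosswalks between taxonomy schemes (subgroup systems, alternative
  databases) are out of scope; one ranked lineage dialect is supported.
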