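# habpref

Habitat preference, niche breadth and lineage-versus-habitat variance
partitioning for microbial taxa.

## What problem this solves

Metagenomic read-mapping surveys (e.g. SingleM/Sandpiper-style searches over
hundreds of thousands of public datasets) tell you, for every dataset, which
taxa were detected and at what relative abundance. Comparative-genomics
pipelines tell you, for every genome, its lineage, its source habitat, and a
stack of annotation-derived features. `habpref` turns those two kinds of
table into the ecological statistics a microbial biogeography study needs:

- **Ecological profile** — per-habitat *ubiquity*
  (`100 · n_detected / n_datasets`), *soil preference* (the ratio of soil to
  pooled non-soil ubiquity percentages, host-associated datasets excluded)
  and *relative abundance* ratios, with taxa classified as **SPL**
  (soil-preferring: soil ubiquity > 75% and preference ratio > 4), **NSPL**
  (preference ratio < 4 and abundance ratio < 1), **intermediate**, or
  **rare** (< 4% ubiquity in every habitat).
- **Niche breadth** — habitat generalist/specialist calls from detection
  evidence (strict all-habitats rule, taxa under 250 supporting studies
  excluded) or genome provenance (≥ 2 habitats rule, lineages under
  5 genomes excluded).
- **Variance partitioning** — for each genomic feature or 0/1 metabolic
  trait, a two-way sequential (Type-I) ANOVA `y ~ class + habitat +
  class:habitat`, percent contribution of each term as its share of the
  total sum of squares (residual included), a hard `p < 1e-5` screen, and
  Tukey–Kramer HSD post hoc comparisons on significant factors.
- **Life history** — the regulatory-flexibility index (transcription
  factors / genes) and resource-acquisition index (secreted CAZymes +
  proteases + lipases + BGCs, per transporter), with genomes assigned
  Scarcity / Ruderal / Competitor by nearest trained centroid in z-scored
  index space.
- **Synthetic data** — seeded generators for both table types with known
  ground truth (detection probabilities, effect sizes, archetypes), so
  every statistic above is testable offline.

All ranks follow GTDB-style lineage strings
(`d__...;p__...;c__...;o__...;f__...;g__...`), and any statistic can be
computed at any rank via `aggregate_to_rank()`.

## Worked example

```r
library(habpref)

# a stated world: 7 habitats x 500 datasets, families constructed as
# soil-preferring, non-soil-preferring, intermediate and rare
cfg <- default_ecosystem_config(seed = 7, n_datasets_per_habitat = 500)
det <- generate_detection_table(cfg)
prof <- profile_all_taxa(aggregate_to_rank(det, "family"), "family", cfg$habitats)
prof$calls[, c("taxon", "label", "soil_ubiquity", "preference_ratio")]
#>       taxon        label soil_ubiquity preference_ratio
#> 1 FamAquaA1         NSPL           6.8           0.1365
#> 2 FamAquaB1         NSPL           5.0           0.0988
#> 3  FamMidA1 intermediate          32.0           5.9701
#> 4 FamRareA1         rare           1.4           0.7143
#> 5 FamRareB1         rare           2.4           1.1538
#> 6 FamSoilA1          SPL          88.2          17.5000
#> 7 FamSoilA2          SPL          91.4          18.1349
#> 8 FamSoilB1          SPL          90.2          16.3406
```

The three families seeded with `p_soil = 0.9, p_else = 0.05` come back SPL
(ubiquity ≈ 90 > 75, ratio ≈ 18 > 4); the two seeded into non-soil habitats
come back NSPL; the `p = 0.02` families are rare.

```r
# variance partitioning over a synthetic 1,930-genome cohort
sim <- generate_genome_table(default_genome_config(seed = 7))
summary(screen_features(sim$genomes, c("gc", "n_peptidases")))
#>        feature        term   df       ss       f         p      pct significant
#> 1           gc       class    5 9.10e+03 437.921 5.77e-314 53.25739        TRUE
#> 2           gc     habitat    1 6.11e+00   1.472  2.25e-01  0.03580       FALSE
#> ...
#> 9  n_peptidases       class    5 6.69e+05 574.750  0.00e+00 57.87687        TRUE
#> 10 n_peptidases     habitat    1 3.95e+04 169.731  3.07e-37  3.41836        TRUE
```

GC content was generated with class structure only: its class term passes
the `1e-5` screen and habitat does not. Peptidase counts carry a soil
offset by construction, so both terms register, with the lineage
contribution (57.9%) dwarfing habitat (3.4%) — the pattern this machinery
is designed to quantify.

```r
# life-history calls against the packaged synthetic training stand-in
cen <- fit_centroids(synthetic_training_set())
calls <- classify_strategy(investment_indices(sim$genomes), cen)
table(calls$label)
#> Competitor    Ruderal   Scarcity
#>        742        630        558
```

## Command line

```sh
Rscript exec/habpref simulate   --seed 11 --out run/
Rscript exec/habpref ecoprofile --detection run/detection.tsv --census run/census.tsv --rank family --out run/
Rscript exec/habpref nicherange --detection run/detection.tsv --census run/census.tsv --genome run/genomes.tsv --rank class --out run/
Rscript exec/habpref varpart    --genome run/genomes.tsv --traits run/traits.tsv --out run/
Rscript exec/habpref lifehistory --genome run/genomes.tsv --training run/training.tsv --out run/
Rscript exec/habpref report     --out run/
```

Every stage writes a JSON manifest (inputs, thresholds, seed, versions, row
counts, exclusions) next to its outputs; identical config + seed gives
byte-identical outputs.

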