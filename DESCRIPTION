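Package: habpref
Title: Habitat Preference, Niche Breadth and Lineage-versus-Habitat
    Variance Partitioning for Microbial Taxa
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Profiles the ecological distribution of microbial lineages from
    habitat-labelled metagenomic detection tables: per-habitat ubiquity,
    soil-preference and relative-abundance metrics with classification of
    lineages as soil-preferring, non-soil-preferring, intermediate or rare;
    habitat-breadth (generalist/specialist) calls from detection or genome
    evidence with rarity exclusions; two-way sequential (Type-I) ANOVA
    partitioning of genomic features and binary metabolic traits into
    lineage, habitat and interaction components with Tukey HSD post hoc
    comparisons; genomic-investment life-history classification (Scarcity,
    Ruderal, Competitor) by nearest trained centroid; and seeded synthetic
    detection- and genome-table generators with known ground truth for
    end-to-end validation. Includes a small command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
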