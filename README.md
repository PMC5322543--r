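# mirdiverge

Tools for studying how plant microRNA (miRNA) binding sites are conserved
or diverge between duplicated genes. After a gene duplicates — by
whole-genome duplication (WGD), tandem duplication (TD) or other
mechanisms — the two paralogs may keep the same miRNA regulation, lose a
binding site in one copy, or gain a new site, often for an evolutionarily
young miRNA born after the duplication. This package implements the full
analysis chain for that question and a seeded synthetic-data generator so
every stage can be exercised end-to-end with known ground truth.

The package is aimed at researchers in plant comparative genomics and
regulatory evolution who want a self-contained, testable re-implementation
of this style of analysis.

## What it computes

**Target scanning.** Plant miRNAs recognize targets through near-perfect
complementarity. A candidate site of miRNA length *L* is scored by the
standard weighted-mismatch scheme: miRNA position *i* (from the 5′ end)
pairs antiparallel with window position *L* + 1 − *i*; Watson–Crick pairs
score 0, each G:U wobble 0.5 points, each other mismatch 1 point, and a
site is called when the total score *S* ≤ *C* (cutoff ~3–3.5 points).
Three configurable scoring profiles (unweighted; seed-weighted, penalties
×2 at positions 2–13; strict-wobble, G:U = 1.0 inside the seed) emulate
running several predictors, and an interaction is accepted when at least
*k* = 2 of the 3 profiles agree (`consensus_rule()`).

**Duplicate catalog.** From all-vs-all protein similarity hits, a gene is a
*duplicate* if it has a nonself hit with E < 1e-10 and query coverage
> 50%, a *singleton* if it has no nonself hit with E < 1e-3, and
*unclassified* in between. A 2×2 chi-square test asks whether miRNA
targets are enriched among duplicates.

**Divergence classification.** A paralog pair or triplet is *same* when all
members are targeted by identical miRNA family sets, *divergent* when at
least one member is targeted but the sets differ (only one member
targeted, or different miRNAs). miRNAs are *young* when they have no
qualifying homolog (E < 1e-10, coverage > 50%) outside the ingroup genus;
divergence is attributed to young miRNAs through the symmetric difference
of the members' target sets.

**Statistics.** Pearson expression correlation between paralogs over
condition panels, a Mann–Whitney contrast of same vs divergent groups,
Ka/Ks by Nei–Gojobori (1986) counting with Jukes–Cantor correction
(d = −¾ ln(1 − 4p/3)), and Fitch small parsimony for mapping site
presence/absence gains and losses on gene-family trees (Dollo mode
available).

## Worked example

```r
library(mirdiverge)

cfg <- gen_config(seed = 11, n_pairs_wgd = 40, n_pairs_td = 20,
                  n_triplets = 10, n_singletons = 20,
                  n_mirnas = 12, n_families = 8)
bundle <- generate_dataset(cfg)   # sequences, hits, expression + ground truth
report <- run_pipeline(bundle)

report$summary$by_class
#>   dup_class n_same n_divergent n_total n_not_applicable pct_divergent
#> 1       WGD      6          34      40                0            85
#> 2        TD      1          19      20                0            95
#> 3   triplet      2           8      10                0            80
#> 4     Total      9          61      70                0            87

head(report$target_table$sites[, c("gene_id","mirna_id","start","end","score","n_agreeing")])
#>     gene_id    mirna_id start end score n_agreeing
#> 1 SYNG00001 syn-miR004b   481 501   0.0          3
#> 2 SYNG00002 syn-miR002b    18  38   2.5          3
#> 3 SYNG00002 syn-miR004b   481 501   0.0          3
#> 4 SYNG00003 syn-miR005a   395 415   0.0          3
#> 5 SYNG00004 syn-miR001b   209 229   2.5          3
#> 6 SYNG00004 syn-miR005a   395 415   0.0          3
```

Of the 70 duplicate groups, 61 (87%) diverged in their binding-site
patterns — the generator's defaults plant an ancestral site in every group
and then ablate it in one member or add a young-miRNA site, so most
groups diverge, as in real *Arabidopsis* cohorts. The sites table shows
each consensus call with its transcript coordinates (1-based, closed),
plain score in points, and how many profiles agreed. Downstream:

```r
report$attribution        # 29 of 61 divergent groups (48%) young-attributed
report$expression$contrast
#> median r same = 0.80, divergent = 0.20, Mann-Whitney p = 1.5e-06
report$enrichment$table   # duplicates 118/150 targeted, singletons 0/20
```

Every number above can be checked against `bundle$truth`, and
`verify_truth(bundle)` re-scans the emitted sequences to prove the planted
and ablated sites behave as recorded.

## Package layout

- `R/sequences.R` — FASTA I/O, miRNA/transcript records, family keys
- `R/target_scan.R` — duplex scoring, window scan, k-of-n consensus
- `R/dup_catalog.R` — duplicate/singleton classification, enrichment
- `R/divergence.R` — same/divergent verdicts, miRNA ages, attribution
- `R/evo_stats.R` — correlation/rank/chi-square tests, codon alignment, NG86 Ka/Ks
- `R/phylo_map.R` — presence/absence mapping, Fitch/Dollo parsimony
- `R/synthdata.R` — seeded generator + ground-truth verification
- `R/pipeline.R` — end-to-end orchestration and report writing
- `vignettes/mirna-duplicate-divergence.Rmd` — methods and design notes
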