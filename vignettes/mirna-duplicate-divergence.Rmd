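---
title: "Methods: miRNA binding-site divergence between duplicated genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA binding-site divergence between duplicated genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdiverge)
```

# The scientific question

Gene duplication creates redundant copies whose regulation can then drift
apart. In plants, miRNAs repress targets through near-perfect
complementarity, usually within coding sequence, so a paralog can lose an
ancestral binding site through a handful of point mutations, or gain a new
one — in particular for a *young* miRNA born after the duplication.
`mirdiverge` implements the analysis chain for quantifying this process:
scan transcripts for miRNA binding sites, catalog duplicates and
singletons, classify paralog groups as having the same or divergent
binding-site patterns, attribute divergence to young versus ancient
miRNAs, and relate divergence to expression correlation and to Ka/Ks.

# The duplex scoring model

A candidate site is a transcript window of miRNA length $L$, read 5′→3′ on
the sense strand. miRNA position $i$ (from its 5′ end) pairs antiparallel
with window position $L + 1 - i$. The score is

$$S = \sum_{i=1}^{L} w_i \, \pi(m_i, t_{L+1-i}),$$

where $\pi$ assigns 0 to Watson–Crick pairs, 0.5 points to G:U wobbles and
1 point to anything else (an `N` counts as a mismatch), and $w_i$ is an
optional positional weight. A window is a hit when $S \le C$.

Assumptions worth stating plainly:

* **No gaps or bulges.** The duplex is strictly ungapped over the full
  miRNA length. The point scheme defines only mismatch classes; target
  bulges would need an alignment model the scheme does not provide.
* **RNA alphabet throughout.** DNA inputs are converted on read so one
  scoring path serves everything.
* **Coordinates** are 1-based, fully closed, on the transcript sense
  strand, everywhere.

## The three profiles and the 2-of-3 consensus

Published analyses of this kind combine several prediction tools and keep
interactions supported by at least two of three programs. The external
tools share the wobble/mismatch point scheme and cutoffs around 3–3.5
points but weight the 5′ "seed" region differently, and their internals
are not reproducible from their descriptions. We therefore emulate the
ensemble as three *configurations* of the one scoring engine:

| profile | cutoff | weighting |
|---|---|---|
| `plain` | 3.0 | none |
| `seed` | 3.5 | all penalties ×2 at miRNA positions 2–13 |
| `wobble_strict` | 3.0 | G:U costs 1.0 inside positions 2–13, 0.5 outside |

A site is consensus-positive when ≥ `k` (default 2) profiles report a hit
with ≥ 50% reciprocal window overlap. Because all windows have length
$L$, 50% reciprocal overlap reduces to start positions within
$\lfloor L/2 \rfloor$; overlapping hits are clustered by single linkage on
that criterion. Each cluster is reported at one *representative* window of
exactly length $L$ — the member window with the lowest unweighted score,
ties toward the smallest start — so that every reported site has
`end - start + 1 = L` and a well-defined plain score. (Reporting the union
of member windows was the alternative; it was rejected because it breaks
the fixed-length site contract and makes per-site scores ambiguous.)
These profiles are declared emulations: passing tests shows the consensus
machinery behaves correctly, not that any external tool's output is
reproduced bit-for-bit.

# Duplicate catalog

From all-vs-all protein similarity hits (12-column tabular format):
duplicate ⇔ some nonself hit has $E < 10^{-10}$ **and** query coverage
$> 0.5$; singleton ⇔ no nonself hit has $E < 10^{-3}$. The inequalities
are strict, as printed in the sources that use these thresholds. The two
rules do not partition the gene universe, so genes between them form an
explicit `unclassified` class excluded from enrichment tests rather than
being forced into either set. Coverage is evaluated in the query direction
(aligned query length / query length), the common tabular-output
convention; the choice is recorded in the catalog metadata since hit files
do not disambiguate it.

# Divergence classification

For each pair or triplet we compare the *sets of miRNA families* targeting
each member (family key = miRNA id with arm suffix `-3p/-5p` and a single
trailing variant letter stripped, e.g. `ath-miR842a-5p → ath-miR842`):

* `not_applicable` — no member targeted;
* `same` — all members targeted by identical family sets;
* `divergent` — otherwise; subtype `asymmetric` when a member is
  untargeted, `different_mirnas` when all are targeted but by different
  families.

Family-set comparison, rather than coordinate comparison, is the default
because the biological tally is *which miRNAs regulate each paralog*, and
comparing coordinates across paralogs would require a cross-paralog
alignment the data do not include. A coordinate-aware mode
(`target_sets(..., coordinate_aware = TRUE)`) appends a position bin to
each family key, so the same family bound at distant positions counts as
divergent; for pairs targeted by one family at different loci the default
mode says `same` and the flagged mode `divergent`, and both results can be
produced side by side.

Triplets with any untargeted member are divergent — "same" is only defined
when all retained copies are targeted, matching how triplicate cohorts are
tabulated by number of targeted members (1, 2 or 3).

## miRNA ages and attribution

A miRNA is *young* when it has no homolog hit outside the ingroup (default
*A. thaliana* + *A. lyrata*) with $E < 10^{-10}$ and coverage $> 0.5$, and
is not overridden by annotation; otherwise *ancient*. A divergent group is
*young-attributed* when the generalized symmetric difference of its
members' family sets (families not shared by every member — i.e. the
divergence-causing families) contains a young family. The symmetric
difference is used because a shared ancient family should not mask a
young-miRNA-driven difference; for `same`-verdict groups, where there is
no difference to attribute, the tally is instead "any involved family
young".

Percentages in all table-shaped outputs are round-half-up to integers
(`pct_half_up()`), matching the printed style of such tables.

# Statistics

* **Expression.** Pearson correlation per paralog pair across the
  condition panel (default 63 columns), pairwise deletion of missing
  values, pairs with < 3 complete observations or zero variance excluded
  with a warning. Same-vs-divergent groups are compared with a two-sided
  Mann–Whitney U test — exact enumeration when both groups have ≤ 20
  values and no ties, otherwise the normal approximation with tie
  correction. The original analyses state significance without naming the
  test; Mann–Whitney is our choice (logged, not asserted as the original),
  appropriate for bounded, non-normal correlation coefficients.
* **Enrichment.** Pearson chi-square on 2×2 tables, 1 df, Yates correction
  off by default because all tables of interest have large expected
  counts; available by flag. Zero marginals are an error, not a silent 0.
* **No multiple-testing correction**: the pipeline performs ≤ 4 planned
  tests and reports them individually with this note.

## Ka/Ks: NG86 with Jukes–Cantor correction

The original workflow used PAML's yn00; that is an external program, so
the package implements Nei–Gojobori (1986) counting in full instead — a
deliberate, documented substitution (`kaks_method` in report metadata).
Group-level conclusions rest on *relative* Ks between cohorts, which NG86
preserves. Details:

* synonymous sites per codon = fraction of the 9 single-base neighbours
  preserving the amino acid, summed per position as thirds; mutations to
  stop codons count as nonsynonymous; site totals are averaged over the
  two sequences;
* differences in multi-hit codons are averaged over all orderings of the
  changed positions, excluding pathways through stop codons unless all are
  blocked;
* $p \to d$ by $d = -\tfrac34 \ln(1 - \tfrac43 p)$; $p \ge 3/4$ is flagged
  saturated and yields `NA` rather than a number.

Codon alignments come from translating the two CDSs, aligning the proteins
globally (BLOSUM62, affine gaps, `Biostrings::pairwiseAlignment` — a
substitution for an external aligner) and expanding each protein gap to a
3-nt gap. Columns with gaps or ambiguity are dropped; internal stops are
an error. The implementation is verified against an independently coded
brute-force NG86 oracle to $10^{-9}$.

# Parsimony mapping

Binding-site presence/absence per miRNA family is mapped onto gene-family
trees (newick input via `ape`). `min_changes()` runs Fitch small parsimony
(bottom-up intersection/union, top-down resolution) and returns the
minimal number of state changes plus one most-parsimonious labeling,
deterministically resolved toward absence at ties. Fitch (reversible) is
the default because both gains and losses of sites are biologically
expected; a Dollo mode (single gain, losses only) is available for
comparison. Multifurcations are resolved arbitrarily with zero-length
branches before the pass. Tests assert scores (verified against exhaustive
enumeration of all internal labelings), not labelings, since
most-parsimonious labelings are generally not unique. The parsimony count
is this package's explicit formalization of "multiple gains and losses";
the original analyses describe the pattern qualitatively.

# The synthetic-data generator

`generate_dataset()` emulates every real input from one seed:

* **Sequences**: uniform-composition transcripts (default GC 0.4, mean
  length 500 nt ± 10%), 21-nt miRNAs grouped into families with lettered
  variants.
* **Planted sites**: each duplicate group inherits one ancestral site for
  an ancient family, the same window at the same position in every member.
  The window is the exact reverse complement of the miRNA, then damaged to
  a scheduled plain score drawn from `site_score_dist` (default: half the
  sites perfect, tail to 2.5 points). All scheduled damage sits outside
  miRNA positions 2–13, so a planted site of score ≤ 2.5 is called by all
  three default profiles and is always a consensus site.
* **Divergence mechanisms**: with probability `p_site_loss` the site in
  one member takes ≥ 4 points of additional mismatch damage (past every
  cutoff); otherwise with probability `p_young_gain` one member gains an
  extra site for a young family. Expected divergent fraction:
  `p_site_loss + (1 - p_site_loss) * p_young_gain`.
* **Defaults** `p_site_loss = 0.45`, `p_young_gain = 0.84` were set so the
  targeted cohort resembles the published one: expected divergence
  0.45 + 0.55·0.84 ≈ 0.91 and young-attributed share ≈ 0.51.
* **Similarity hits** encode true duplicates at E = 1e-50 / coverage 0.9
  and singletons with self-hits only; **homolog hit tables** give ancient
  families qualifying outgroup hits (E = 1e-20, coverage 0.8) and young
  families at most weak ones (E = 1e-4) that fail the cutoff;
  **expression** rows per group are drawn from a multivariate normal
  (mean 8, sd 2, compound-symmetric correlation `rho_same` = 0.8 or
  `rho_div` = 0.2 by intended verdict, shifted nonnegative — a constant
  shift preserves Pearson r).

What the generator does *not* emulate: codon structure and realistic codon
usage, introns and UTR architecture, genome synteny, sequence similarity
between paralogs outside the planted windows, mechanistic miRNA repression
of expression (the correlation coupling is a group-contrast model only),
and background site composition biases. Consequently, passing recovery
tests demonstrates that the machinery is correct and well-calibrated under
the stated model — not that the scanner's false-positive behaviour on real
genomes is characterized. Background false sites *are* possible in random
sequence and are deliberately left in; at the default cutoffs a random
21-nt window passes with negligible probability, so recovery is ~100% and
deviations would indicate a defect, not noise.

# Numerical and degenerate-input choices

* Hits and sites are sorted by (gene, start, miRNA); reruns on identical
  inputs are byte-identical — the pipeline itself has no randomness.
* Transcripts shorter than the miRNA scan to an empty result with a
  warning; empty hit lists classify every gene as a singleton; cohorts
  with no targeted group skip the expression and enrichment tests with an
  explanatory note instead of erroring.
* Fitch ties resolve toward absence; chi-square refuses zero marginals;
  Ka/Ks flags saturation instead of extrapolating.
* Problem sizes in the shipped tests — 200 scanner-oracle pairs, 50
  hundred-codon Ka/Ks alignments, 100 eight-leaf parsimony trees, three
  500-pair pipeline cohorts, 100 power-simulation runs — were chosen as
  the smallest sizes at which the statistical checks (3-binomial-SE
  recovery bands, ≥ 95% rejection power) are stable across seeds.

# Known limitations

* The scoring profiles are emulations of an ensemble, not reproductions of
  any named predictor; absolute interaction counts on real data will
  differ from any specific tool.
* NG86 underestimates high divergences relative to codon-model methods
  (no transition/transversion or codon-frequency weighting); saturated
  pairs are flagged rather than estimated.
* Family-set divergence ignores site multiplicity: a paralog pair bound by
  the same family once versus twice is `same` in the default mode.
* Tree inference, domain identification and similarity searching are out
  of scope; trees, family membership and hit tables are inputs.
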