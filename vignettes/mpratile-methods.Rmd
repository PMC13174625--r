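---
title: "Models and methods behind mpratile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mpratile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpratile)
library(dplyr)
```

`mpratile` implements the computational core of a tiling motif-shuffle
massively parallel reporter assay (MPRA) study of the *MECP2*
cis-regulatory landscape: library design, activity estimation, hotspot
calling, k-mer attribution, and the X-linked private-variant filter,
together with a seeded synthetic-data generator that makes the whole
pipeline testable without any sequencing data. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
synthetic data can and cannot tell you about real experiments.

## Coordinates and orientation

CRE regions are stored with 1-based inclusive genomic coordinates (the
convention of the printed target intervals). *MECP2* is on the minus
strand, so MPRA positions count 0-based from the region's *higher*
genomic coordinate:

$$\text{offset} = \text{end} - \text{pos}.$$

This single formula is over-determined by two independent anchors — the
CRE A variant chrX:154046133 at MPRA position 824 and the promoter
variant chrX:154097837 at position 901 — and both are asserted in the
test suite. Library sequences are represented 5'→3' on the gene strand
(the reverse complement of the plus-strand slice), so that string index
`i + 1` is MPRA offset `i`. Whether physical oligos were synthesised on
this strand or the plus strand is not determinable from the coordinate
anchors alone; the choice is isolated in `orient_sequence()` and can be
flipped with `reverse = FALSE`. All internal intervals are half-open
`[a, b)` in MPRA offsets.

## Library design

Each CRE is divided into 270 bp tiles offset by 70 bp (200 bp overlap);
a 970 bp CRE yields 11 tiles, a 690 bp CRE yields 7. Lengths that do not
land on the 70 bp grid get one extra end-anchored tile, flagged in the
tile table, so every base is always covered.

TF binding sites are found with a FIMO-style scan: log-odds scores
against an iid uniform background,

$$s(w) = \sum_i \log_2 \frac{p_i(w_i) + 0.1/4}{1.1 \cdot 0.25},$$

with p-values computed *exactly* by dynamic programming over scores
discretised into 0.001-bit bins. Because the scan and the DP share the
same integer binning, the reported p-value equals brute-force
enumeration over all $4^w$ words exactly (tested for widths 4–6); the
binning is the only approximation, and it affects scores by at most
half a bin per column. The default reporting threshold is p ≤ 1e-4, the
common scan default; the study did not print the threshold it used, so
it is exposed as a parameter.

Each motif hit fully contained in a tile is shuffled twice (a uniform
random permutation of the bases in the hit interval — a linear, k = 1
shuffle that exactly conserves base composition), and each shuffle
replicate becomes one library element next to the tile's reference
element. A motif spanning several overlapping tiles is shuffled
independently in each, which is what later allows comparing the same
disruption in different flanking contexts. Hits crossing a tile edge
are excluded (the study does not say how it handled them). Permutations
that reproduce the input (inevitable for homopolymers) are retried up
to 20 times and then flagged `unchanged`. Element seeds are a stable
hash of (master seed, tile, motif, interval, replicate), so adding
elements never changes existing sequences. Single-nucleotide variants
are substituted into every tile containing their offset, with a hard
error if the expected reference base does not match — the cheapest
guard against orientation bugs. Final oligos are
15 bp handle + 270 bp insert + 15 bp handle = 300 bp.

## Activity and effect testing

Activity per element and replicate is the depth-normalised log2 ratio

$$a = \log_2 \frac{(\sum \text{RNA} + 1)/R_{tot}}{(\sum \text{DNA} + 1)/D_{tot}},$$

summing counts over the element's barcodes, with replicate-wide totals
and +1 pseudocounts. Elements with fewer than 10 unique barcodes in a
replicate are dropped from that replicate. The upstream pipeline that
produced the study's count tables defines its own normalisation; this
package declares the summed-count form above as its estimator because
it is deterministic, robust at ~135 barcodes per element, and unbiased
for the simulator's generative model. Per-barcode median ratios could be
added behind the same interface.

Shuffle effects are tested with a one-way-ANOVA Dunnett many-to-one
procedure: within a family, each group's mean is compared with the
matched reference tile's mean using the pooled error variance, and
two-sided p-values are adjusted over the $m$ correlated statistics,

$$p_i = P\!\left(\max_j |T_j| \ge |t_i|\right),$$

estimated by seeded Monte Carlo over the joint null (shared control
mean, common scaled chi-square variance; 1e5 draws by default, giving
p-value noise well under ±0.005). With $m = 1$ this reduces to the
unadjusted pooled t test, and the whole procedure is cross-checked in
the tests against the multivariate-t implementation in `multcomp`.
Unbalanced replicate counts enter through per-group $n_i$ rather than
by dropping elements. The family definition is one family per (tile,
element kind): all motif shuffles of a tile are one family against that
tile's reference, and the tile's variants form a separate family — the
study states that variants were tested in separate ANOVAs, but not the
exact family grouping, so per-tile is this package's choice (it matches
"compared to its matched reference sequence" most directly). Null
samples are cached across families with identical designs, which changes
no p-value but makes whole-library testing fast.

## Hotspot calling

Every mutated nucleotide is labelled with its CRE position and sorted
into fixed 50 bp bins (`[0,50), [50,100), ...`; bin phase is not stated
in the study, so bins are anchored at 0 and a trailing short bin is
kept). A bin qualifies as a TF hotspot when it has at least 50 mutated
nucleotides of coverage and at least 10% of its shuffle datapoints
significantly change activity in one direction — decreased activity
marks an activator-binding site, increased a repressor-binding site,
both directions at once is reported `ambiguous`. The 10% is read as a
fraction of datapoints (not nucleotides), per direction, with inclusive
thresholds. Adjacent qualifying bins of one class merge. Sub-bin
hotspot boundaries are a downstream refinement (alignment and k-mer
analysis), not a property of the caller.

## k-mer attribution

For a family of tested sequences, all 8–14 bp k-mers are extracted
(forward orientation — all library sequences share the MPRA
orientation) and filtered to the informative band: present in at least
20% *and* absent in at least 20% of sequences (the disjunctive reading
of "found or missing in at least 20%" would retain everything, so the
conjunctive reading is implemented). Presence is associated with
activity by the Brunner–Munzel test of stochastic superiority
$\hat p = P(X < Y) + \tfrac12 P(X = Y)$, with placement-based variances,
Satterthwaite degrees of freedom, and a two-sided p from the t
distribution; degenerate variances (complete separation, all ties) fall
back to a seeded permutation test (exhaustive when feasible). The
stringent raw threshold p < 1e-3 stands in for multiple-testing
correction, as in the study. A calibration caveat that matters for
small data: the t approximation is anticonservative in the extreme tail
for families of a few dozen sequences (empirically ~5× nominal at
p = 1e-3 with groups of 9 vs 31), and approaches nominal only at the
dense-tile family sizes (hundreds of elements) the method targets. The
package's null-calibration test therefore runs at a 200-element family;
conclusions from much smaller families should rely on the permutation
fallback instead.

Significant k-mers are matched to PWMs by ungapped sliding alignment on
both strands with at least 4 overlapping columns, scored as the *sum*
of per-column Pearson correlations between the k-mer's pseudocount
probability matrix and the motif's columns. Summing (rather than
averaging) makes a full-width agreement outrank a chance 4-column
overlap, without which the exact consensus of a sharp PWM is
indistinguishable from noise under the column-shuffle null. Match
p-values come from a seeded Monte Carlo null — the same k-mer scored
against column-order-shuffled database motifs (1,000 draws by default);
reproducing the exact analytic null of the original motif-comparison
tool is a non-goal. Significant k-mers are then refined to the
*smallest* k-mer that still optimises the match: terminal bases are
deleted greedily (both ends tried each round, left preferred on ties)
while the (p-value, score) objective does not worsen, stopping at
length 6. Matched TFs are cross-referenced against an expression table;
motifs without a gene mapping are kept but flagged.

## Variant pipeline

The transmission filter for private inherited variants (PIVs) requires,
with one flag per criterion: position inside a target region; exactly
one carrier family; an unaffected heterozygous mother in that family;
at least one affected male child hemizygous for the alternate allele;
site QUAL strictly above 50; and depth of at least 20 (inclusive) in
both mother and proband. A male recorded as diploid on chrX, or a
genotyped sample missing from the pedigree, is a data-integrity error
rather than a filter failure. Allele frequency counts one allele per
parent — 1 carrier among 16,490 unrelated parents gives 6.06e-5, which
rounds to the printed ~6.1e-5; per-X-copy counting (mothers contribute
two) is available behind a switch. Variant MPRA calls are calibrated
against population controls: the control threshold is the largest
significant absolute control effect (0 if no control is significant,
as at the promoter where controls were inert), and a variant is
`candidate_functional` only when significant in at least two tiles —
or in its only testable tile — with a strongest significant effect
beyond that threshold; significance in one of several tiles, or below
the threshold, is `indeterminate`. Promoter-level signal percentiles
use ascending midranks, $100 \cdot \text{rank}/N$ per replicate, and
are invariant under monotone transforms of the signal.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated. A 970 bp CRE is drawn iid uniform with two planted motifs —
an activator (multiplier 4) and a repressor (multiplier 0.25),
symmetric ±2 in log2 — and the background is rejection-resampled until
each planted consensus occurs only at its own site. True element
activity is multiplicative: baseline × the multipliers of all planted
motifs intact and fully inside the element's tile; a shuffle or variant
touching a motif removes its factor, so destroying the activator has a
true effect of −2 log2 units. Counts follow the assay's stated scale —
four replicates, ~135 barcodes per element (negative binomial, floored
at 10 so the barcode filter is exercised through designated low-barcode
elements instead), DNA negative binomial (mean 50 per barcode, size 5),
and RNA Poisson given DNA times activity times a replicate scale
({1.0, 0.9, 1.1, 1.0}). RNA-given-DNA Poisson was chosen over
independent negative binomials because it is the simplest model under
which the log2(RNA/DNA) estimand is unbiased; overdispersion lives in
the DNA draw. The default fixture spaces neutral decoy shuffle
intervals every 7 bp, yielding on the order of 1,100 shuffle elements
per CRE — the saturation regime the study reports (over 1,000 mutations
per CRE) and the coverage regime the 50-nucleotide/10% hotspot rule
presumes; at a few hundred mutations per CRE the rule becomes fragile
to family-correlated false positives, which is visible if the density
is lowered.

The synthetic cohort plants maternally transmitted X-linked variants in
trios (QUAL in (50, 99], DP in [20, 60]) alongside one distractor per
failure mode — a two-family variant, QUAL exactly 50, proband depth 19,
an affected daughter instead of a son, a homozygous-reference mother,
and an out-of-region variant — so the filter's flags can be checked
one-to-one. All generators are deterministic given the master seed.

What the simulations do *not* emulate: barcode-to-insert
misassignment, UMI artefacts, sequence-dependent synthesis or cloning
bias, chromatin context (the assay is episomal), correlated noise
between neighbouring elements, and real TF binding energetics (planted
effects are step functions of motif integrity). Passing the planted
recovery tests therefore demonstrates that the statistics recover the
truth of this generative model at realistic depth and effect sizes —
not that the laboratory assay is free of those artefacts.

## Problem sizes and determinism

The test suite and the acceptance script run end to end on one CPU:
twenty seeded fixture pipelines for planted-motif recovery, 2,000
simulated null families for the Dunnett familywise-error check (with a
shared 1e5-draw null per design), exhaustive permutation oracles for
the rank test at n, m ≤ 8, full enumeration of all words for PWM widths
4–6, and a six-round, ~3,000-k-mer null calibration. Every random step
takes an explicit seed, and derived seeds are stable hashes, so all
results are byte-reproducible.

## A worked example

```{r example}
fx <- make_fixture(seed = 1)
activities <- compute_activity(fx$counts)
effects <- test_shuffle_effects(activities, fx$manifest, seed = 1)
datapoints <- summarize_effects(effects)
bins <- bin_mutations(datapoints, 970)
call_hotspots(bins)
```

The two calls recover the planted activator (offsets 300–310, shuffles
*decrease* activity) and repressor (620–630, shuffles *increase* it) in
their 50 bp bins. `autoplot(datapoints, hotspots = call_hotspots(bins))`
draws the per-mutation effect track with hotspot shading.

## Known limitations

- The Brunner–Munzel t-approximated p-value disagrees with its own
  exact permutation distribution by up to ~0.06 at n = m ≤ 8; at those
  sizes the permutation fallback is the trustworthy path.
- The Dunnett adjustment is Monte Carlo, so adjusted p-values carry
  ~1/√draws noise; exact multivariate-t quadrature could replace it.
- Hotspot intervals are bin-resolution (50 bp); precise boundaries come
  from the k-mer/alignment step.
- The motif-match null shuffles database columns; it is a practical
  calibration, not the analytic null of the original comparison tool.
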