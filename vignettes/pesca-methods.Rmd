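---
title: "Models and methods behind pesca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pesca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pesca analyses pooled enhancer screens read out by single-nucleus
RNA-seq: a library of candidate gene regulatory elements (GREs), each
driving a reporter transcript tagged with three distinct 10-base
barcodes in its 3'UTR, is delivered virally to a tissue; droplet
snRNA-seq then yields, per nucleus, a cell-type label (from the
non-viral transcriptome, upstream of this package) and a handful of
viral barcode UMIs. The statistical task is to decide which GREs drive
expression specifically in a designated target cell type. This
vignette records the models, parameter choices, numerical decisions and
limitations; the README shows the surface-level workflow.

## GRE selection from ATAC-seq signal

Selection starts from a merged, non-redundant peak list
(`merge_intervals()`; BED convention, 0-based half-open; intervals that
merely abut are kept separate, because adjacent but distinct peak calls
are distinct regulatory hypotheses). Conservation filtering needs a
cutoff on per-peak mean phyloP-style scores, which is calibrated from
the data itself rather than fixed: each peak is paired with a
same-length **distal control** shifted +100 kb (mirrored to −100 kb at
chromosome ends; peaks admitting neither placement are dropped and
reported), and the cutoff is the 95th percentile of the control score
distribution. We use the **nearest-rank** percentile (the
`ceiling(p/100 · n)`-th order statistic): it is exact on small inputs
and testable as an order statistic, and any interpolation scheme would
differ by a negligible amount at realistic *n*. Whether controls should
additionally be forced to avoid overlapping other peaks is left open;
they are not, and with peaks covering a few percent of the genome the
contamination of the control distribution is small.

Signal columns (one per cell population, replicate-averaged upstream)
are scaled to a common total of 10^7 so that specificity compares
shapes, not sequencing depth. Each peak is scored as

    (s_target + 0.5) / (mean over other populations of s + 0.5)

with the pseudocount damping ratios at barely-open regions. With more
than two non-target populations the denominator generalises to their
arithmetic mean. Ranking is by score with deterministic tie-breaks
(higher target signal, then input order), and the top *k* = 287 form
the default panel.

## Barcode design

Barcodes must tolerate sequencing errors: all pairs in a set are at
edit distance ≥ 3, so any single error leaves the true barcode the
unique neighbour within one mismatch. Both plain Levenshtein and
**sequence-Levenshtein** distances are offered; the latter minimises
over the last row and column of the DP table, modelling fixed-length
reads where an indel shifts the frame at the end of the window. It is
never larger than Levenshtein, so a sequence-Levenshtein-3 set is the
stricter guarantee; which metric governed the original screen's final
pool is ambiguous, so neither is asserted as canonical and the set's
metric travels with it as metadata.

Sets are built by a **seeded greedy closure**: candidates are visited
in a reproducible shuffled order of the 4^L sequence space and accepted
when ≥ 3 from everything accepted so far. We deliberately do not use an
evolutionary search: what matters downstream is only that the pairwise
constraint holds (it is verified exhaustively, O(n²), by
`validate_barcode_set()`), determinism matters for reproducibility, and
greedy closures reach the required 861 barcodes easily at L = 10
(maximal set sizes are not guaranteed and not claimed). For L > 11 the
space is streamed with revisit-skipping rather than fully permuted; the
draw budget then bounds runtime, and exhaustion raises a capacity error
reporting the count achieved. Each GRE receives 3 barcodes drawn
without replacement across the whole map.

## Deconvolution policy

Observed sequences are compared to the designed set by **Hamming**
distance over the fixed 10-base window — the mapping constraint of the
original pipeline was "at most one mismatch" against a fixed contig,
i.e. substitutions only; indel-tolerant matching is out of scope. The
policy reconciles two constraints stated at different layers of that
pipeline (map within 1 mismatch; unique within 2): a read is *assigned*
iff exactly one barcode lies within 1 mismatch **and** no second
barcode lies within radius 2; two barcodes within radius 2 make it
*ambiguous*; otherwise *unassigned*. For a valid distance-3 set a tie
within 1 mismatch is impossible — the matcher asserts this instead of
assuming it, so a corrupted barcode set fails loudly. Note that a read
one error away from its true barcode can still be ambiguous when the
error happens to step toward another barcode's radius-2 shell; at the
default error rate this puts the not-uniquely-assignable fraction near
1%, a conservative policy that discards rather than guesses.
Deduplication collapses exact `(cell, UMI, barcode)` triples; UMI error
correction is deliberately not attempted, matching the exact-condense
convention of the upstream pipeline.

## Enrichment statistics

**Fold-enrichment.** For feature *f* the score is
`(mean_target(x_f) + 0.01) / (mean_rest(x_f) + 0.01)`. The expression
scale matters more than it looks. On log1p-normalized values
(`ln(1 + CP10K)`, the display convention of droplet data) the ratio of
means cannot estimate an expression fold: concavity compresses any
fold toward the ratio of detection probabilities, badly so at this
assay's depth (≈15.6 viral UMIs spread over 287 GREs). And on raw
per-cell counts the rest-group mean (≈0.05) is comparable to the 0.01
pseudocount, which alone shrinks a true 8-fold signal by ~15%. The
default therefore computes the score on **linear relative expression**
(counts per 10,000, no log): there the pseudocount is negligible
relative to typical values and the ratio-of-means estimator is
consistent for the generated fold — which is also what makes the
generator-vs-estimator recovery checks in the test suite meaningful.
`expr_scale = "lognorm"` and `"raw"` are exposed for comparison, and
log2 of the pseudocounted fold is reported for display. Cells with zero
viral counts carry no relative-expression information and are excluded
(flagged); totals are computed over whatever feature columns are
supplied, so callers with a full transcriptome can normalise against
it.

**Triplet consistency.** Per-barcode log2 folds are arranged into one
vector per barcode slot (length = number of GREs) and all pairwise
Pearson correlations computed. The null shuffles the value-to-position
assignment of the whole GRE × slot matrix and recomputes the mean
pairwise r, 1000 times; exchangeability forces the null mean to 0, and
the spread of a single-pair null scales as 1/√(G−1) (the mean over the
three pairs is tighter by about √3). Zero-variance slots yield an NA
correlation with a warning rather than an error.

**NB likelihood-ratio test.** Counts for GRE *f* in cell *i* are
modelled as negative binomial with mean `s_i · m_g(i)` where `s_i` is a
per-cell size factor (per-cell totals centred to geometric mean 1 by
default; median-of-ratios optional) and `g(i)` indexes target vs rest.
The full model has two group means, the reduced one; twice the
log-likelihood difference is referred to χ²(1). Because the covariate
is a single binary indicator, the GLM collapses to two scalar means:
they are fitted by a fixed-point iteration on the score equation from
the exact Poisson closed form, and the per-feature dispersion by 1-D
profile maximum likelihood over log θ (method-of-moments fallback;
features with no overdispersion get a large fixed size, the Poisson
limit), alternated for two rounds. The reduced model reuses the
full-model dispersion so the models are nested. Unlike differential
expression toolkits that pool a dispersion trend across features, the
dispersion here is strictly per-feature — the safer choice for a few
hundred features of very different abundance with no shared
mean-variance structure to borrow. All-zero features carry no information (p = 1);
non-convergent features get NA and are excluded from the
Benjamini–Hochberg denominator. A GRE is called enriched when
BH q < 0.01 **and** fold > 1, so depleted features cannot be reported
as hits.

**Power by binomial thinning.** Every count c is replaced by a
Binomial(c, p) draw for p in {0.5, 0.25, 0.125, 0.0625}, ten replicates
each, and the NB test rerun; the report carries per-replicate q-values
and thinned totals, plus per-feature detection rates. Detection is
non-increasing in thinning severity in expectation, not per replicate,
which is how the tests assert it.

## The synthetic screen generator

The generator defines the conditions under which everything above is
validated: ten cell types with cortical-like proportions (50%
excitatory, the Sst target at 5%, the remainder split across
interneuron and glial classes), infection probability 0.86 per cell,
per-infected-cell viral UMI totals drawn negative-binomially around
15.6 (dispersion 0.3 — unconstrained by the emulated screen; chosen as
moderate snRNA-seq-like overdispersion, and small enough that virtually
no infected cell draws zero, keeping the infected fraction observable),
and multinomial allocation of each cell's UMIs across the 861 barcodes
with weights proportional to each GRE's `true_fold` in target cells and
uniform otherwise. Reads then carry i.i.d. per-base substitution errors
(default 0.005) and an optional per-UMI duplication factor to exercise
deduplication. UMI tags are deterministic base-4 encodings of the
per-cell molecule index: unique within a cell by construction, which is
what makes the error-free round trip (deconvolved matrix == generator
truth) an exact identity instead of a birthday-collision lottery.

Because each cell's total is fixed before allocation, boosting some
GREs in target cells necessarily depresses the others there: one GRE at
`true_fold` 8.3 among 287 realises an expected target/rest count ratio
of 8.3·G/(G−1+8.3) ≈ 8.09, and the 286 background GREs sit at ≈0.97.
This compositional coupling is a real feature of reporter pools, not an
artefact, and the tests account for it.

What the generator does **not** emulate: the non-viral transcriptome
(cell-type labels are inputs — clustering is upstream), ambient RNA,
doublets, droplet chemistry, cell-calling, or per-animal batch
structure. Passing tests therefore demonstrate the correctness and
calibration of the statistics under a clean NB/multinomial world, not
robustness to those artefacts.

## Numerical and testing choices

Problem sizes in the test-suite were chosen to make each statistical
property measurable rather than marginal: screens of 10,000 cells where
a contract is stated at that depth (depth and infection recovery, fold
recovery within 10–15%, significance of ≥7-fold hits), 1,200–4,000
cells for calibration and pipeline checks. Monte-Carlo tolerances are
set several standard errors wide of the quantity being asserted — e.g.
the 0.05 ± 0.02 type-I band is asserted on the mean over five label
permutations because a single 287-feature fraction has binomial sd
≈ 0.013; the planted-peak recovery threshold of the selection pipeline
was measured over ten generator seeds (range 0.70–0.90 at boost 6)
before being frozen at mean ≥ 0.70. The triplet-consistency signal
check uses twenty enriched GREs at 4,000 cells, where the observed mean
r (≈0.45–0.55) clears the null's 99th percentile several-fold; with
only a handful of enriched GREs the observed r is honestly small, as
the README example shows. Seeded routines (`design_barcodes()`,
`simulate_screen()`, `shuffle_null()`, `subsample_power()`,
`run_pipeline()`) restore the caller's RNG state and derive per-stage
substreams from one master seed, so identical seeds give byte-identical
outputs at every stage.

## Limitations

Enrichment folds are estimated per screen without shrinkage across
GREs; at very low abundance they are noisy, which is exactly what the
thinning analysis quantifies. The NB test treats cells as exchangeable
within target/rest — animal- or library-level structure must be handled
by running on subsets. The deconvolution assumes a fixed-position
barcode window after flank trimming; indel-bearing reads are lost, a
known cost of the Hamming policy. Capacity of the greedy barcode
designer degrades for min-distance constraints near the barcode length;
it reports what it achieved rather than searching exhaustively.
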