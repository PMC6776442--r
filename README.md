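# pesca

Analysis toolkit for **paralleled enhancer single-cell assays** —
pooled screens in which hundreds of candidate gene regulatory elements
(GREs, putative enhancers) each drive a barcoded reporter transcript
from a viral vector, and a single-nucleus RNA-seq readout measures, for
every element at once, how specifically it drives expression in a
target cell type (for example somatostatin-expressing cortical
interneurons, a rare population of roughly 5% of cells).

The package covers the full computational path of such a screen:

1. **GRE panel selection** — merge BED-like ATAC-seq peak lists into a
   non-redundant reference, calibrate a conservation cutoff as the 95th
   percentile of phyloP-style scores of distal control sequences placed
   100 kb from each peak, scale each cell population's signal to a
   common total (10^7), score each peak by the pseudocounted
   specificity ratio
   `(s_target + 0.5) / (mean(s_other) + 0.5)`,
   and take the top *k* (287 by default).
2. **Barcode design** — DNA barcode sets (10-mers by default) with a
   guaranteed minimum pairwise edit distance of 3 (Levenshtein or
   sequence-Levenshtein), built by a seeded greedy closure, exhaustively
   verifiable, and randomly paired 3-per-GRE without reuse.
3. **Barcode deconvolution** — reads `(cell barcode, UMI, sequence)`
   are matched to barcodes by Hamming distance (assigned iff exactly one
   barcode within 1 mismatch and no second within 2), deduplicated on
   the `(cell, UMI, barcode)` key, and aggregated to a sparse
   cell × GRE UMI count matrix.
4. **Enrichment statistics** — per-feature target-cell fold-enrichment
   `(mean_target + 0.01) / (mean_rest + 0.01)` on per-cell relative
   expression; pairwise Pearson consistency of the three barcodes per
   GRE with a value-shuffling null; a per-GRE negative-binomial GLM
   likelihood-ratio test (log link, size-factor offset, per-feature ML
   dispersion) with Benjamini–Hochberg FDR; and a binomial-thinning
   power analysis (probabilities 0.5, 0.25, 0.125, 0.0625 × 10
   replicates by default).
5. **Synthetic screens** — a generator with known ground truth
   (cell-type mixture, infection fraction 0.86, negative-binomial viral
   UMI totals with mean 15.6 per infected cell, multinomial barcode
   allocation scaled by each GRE's true fold in target cells, per-base
   sequencing errors), so that every stage is testable end-to-end with
   no external data.

## Worked example

Simulate a screen with three truly enriched GREs, deconvolve its reads,
and test every GRE for target-cell enrichment:

```r
library(pesca)

truth <- screen_truth(seed = 1,
                      true_fold = c(GRE012 = 8.3, GRE019 = 9.1,
                                    GRE022 = 7.2))
scr <- simulate_screen(truth, n_cells = 4000)
res <- count_umis(scr$reads, scr$barcode_set)
res
#> pesca_counts: 3410 cells x 861 barcodes, 52609 molecules
#>   reads: 53239 total, 52609 assigned, 593 ambiguous, 37 unassigned, 0 rejected
#>   not uniquely assignable: 1.18%

fit <- enrich_screen(res$counts, scr$map, scr$labels, target = "Sst",
                     seed = 1)
summary(fit)
#> Top 10 GREs by q-value (target 'Sst'):
#>  feature    fold log2_fold lrt_stat        p        q enriched
#>   GRE012 10.2982     3.364   176.46 2.87e-40 8.25e-38     TRUE
#>   GRE019  9.2879     3.215   132.67 1.07e-30 1.53e-28     TRUE
#>   GRE022  6.3262     2.661    76.83 1.87e-18 1.79e-16     TRUE
#>   GRE278  0.0915    -3.451     9.85 1.69e-03 1.22e-01    FALSE
#>   ...
```

The three planted elements are recovered as the only GREs with
BH q < 0.01, with estimated folds near their generated values (10.3,
9.3 and 6.3 for true 8.3, 9.1 and 7.2 at this depth). `fit$null` holds
the shuffle null of barcode-triplet consistency (mean ≈ 0), and
`plot(fit)` draws the ranked log2 fold-enrichment of all 287 GREs with
significant ones highlighted. `subsample_power()` then shows how
detection of these hits degrades as counts are binomially thinned.

A command-line wrapper over the same functions is installed at
`inst/cli/pesca.R`
(`pesca.R {simulate|select|barcodes|count|enrich|power|run}`), driven
by a YAML configuration; `run_pipeline()` is the equivalent R entry
point and writes a manifest with per-file checksums for reproducible
reruns.

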