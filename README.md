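# diffarch

Differential analysis of two-condition 3D chromatin architecture in R.

Chemotherapy resistance, differentiation and other cell-state transitions
reorganize the genome's spatial architecture at every scale: megabase A/B
compartments switch between open and closed states, topologically
associating domains (TADs) split or merge, and focal chromatin loops —
including enhancer–promoter contacts — are gained or lost. `diffarch` takes
binned Hi-C contact matrices for two conditions, plus matched ATAC-seq
coverage and an expression table, and quantifies that reorganization
end-to-end. It is aimed at computational genomicists who want a
self-contained, testable implementation of the standard differential
3D-genome workflow rather than a chain of external binaries.

## The models at the core

* **Balancing.** ICE: find weights `w` with
  `corrected[i,j] = raw[i,j] * w_i * w_j` such that all retained row sums are
  equal (marginal CV < 1e-5), after masking bins whose log marginal deviates
  more than 3 MAD from the median.
* **Compartments.** PC1 of the Pearson correlation matrix of the
  observed/expected matrix at 100 kb; sign oriented by ATAC coverage
  (top-quartile bins must average PC1 > 0); A where PC1 > 0, B where
  PC1 < 0; per-bin switch categories `A->A`, `B->B`, `A->B`, `B->A`.
* **TAD boundaries.** Multi-window diamond insulation score
  (mean per-window z of the cross-boundary diamond means, windows
  15–75 kb in 7.5-kb steps at 5-kb bins); boundaries are windowed score
  minima at least `delta = 0.01` below their flanking maxima whose
  distance-normalized diamond pixels are lower than those at the flanks
  (one-sided Mann–Whitney, BH-FDR < 0.01). Stable = found in both
  conditions; gained = condition-2-only with stronger condition-2
  insulation; lost = condition-1-only with weaker condition-2 insulation.
* **Loops.** Candidates = pixels ≥ 2× distance expectation and above the
  per-stratum 95th percentile, within 1 Mb; kept if the 3×3 peak-window sum
  clears a negative-binomial background (method-of-moments per distance
  stratum, BH-FDR < 0.05) and the peak O/E beats the surrounding 11×11
  ring — including its within-domain quadrant — by 2× and a one-sided
  rank-sum test. APA score = center O/E of the stacked 21×21 loop
  neighborhood over its far corner.
* **EPIs.** Loops with one anchor overlapping a TSS and the other an
  enhancer by ≥ 1 bp (half-open coordinates), classes inherited from the
  loop comparison.
* **Flanking condensed regions.** On the boundary ATAC metaprofile, maximal
  runs below 75% of the per-side baseline within ±30 kb, at least 10 kb wide.

A full synthetic-data generator (`generate_synthetic()`) plants all of these
structures with exported ground truth, so every stage is validated by
recovery rather than by fixture matching.

## Worked example

```r
library(diffarch)
res <- run_demo(outdir = "demo_out", seed = 1)

res$switches$summary
#>      category   n pct_non_na pct_all
#> A->A     A->A 117   29.39698   29.25
#> B->B     B->B 156   39.19598   39.00
#> A->B     A->B  63   15.82915   15.75
#> B->A     B->A  62   15.57789   15.50

res$recovery$boundary_confusion
#>        stable gained lost unclassified missed
#> stable     45      0    0            0      0
#> gained      0     24    0            0      0
#> lost        0      0   11            0      0

sapply(res$apa, function(a) round(a$score, 2))
#> stable_cond1 stable_cond2 gained_cond1 gained_cond2   lost_cond1   lost_cond2
#>         4.49         4.88         1.10         4.59         4.54         1.13

res$flank_dips$cond1
#>    side detected center_offset width     depth baseline
#> 1  left     TRUE        -22500 15000 0.3948016 1.012646
#> 2 right     TRUE         22500 15000 0.4286128 1.006134
```

Reading the output: about 31% of the synthetic genome switches compartment
(planted: ~16% per direction); all 35 planted splits/merges are classified
correctly; gained loops score APA ≈ 4.6 in the condition that carries them
versus ≈ 1.1 in the other — the signature of condition-specific looping;
and the accessibility profile around boundaries shows the two condensed
flanking regions (~40% depth, centered ±22.5 kb) on both sides.

For real data, assemble the same input bundle from files —
`read_contact_matrix()` (sparse triplet text), `read_bedgraph()`,
`read_bed()`, `read_expression()` — and call
`run_pipeline(bundle, run_config(outdir = "out"))`. Every stage is also
exposed as a plain function (`ice_correct()`, `compartment_pc1()`,
`separation_score()`, `call_boundaries()`, `detect_loops()`, `apa()`,
`identify_epis()`, `metaprofile()`, `detect_flank_dips()`, ...).

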