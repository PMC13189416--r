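# tempoNMF

Temporal-behavior decomposition of dense time-series bulk RNA-seq by
non-negative matrix factorization.

## The problem

Dense differentiation time courses — here the two-condition design of a
PU.1-inducible myeloid progenitor sampled at 27 post-induction timepoints
per condition over seven days (every hour to 4 h, every 4 h to 24 h, every
8 h to 168 h), toward the neutrophil fate after GCSF pre-treatment and
toward the macrophage fate in IL3 — contain thousands of genes whose
expression changes only *transiently*. Endpoint differential-expression
comparisons miss them. `tempoNMF` classifies genes by their entire
trajectory instead: the gene × timepoint matrix $X_{gt}$ (GCSF block
concatenated before IL3) is factored as

$$X_{gt} \approx (WH)_{gt} = \sum_{m=1}^{M} W_{gm} H_{mt}, \qquad W, H \ge 0,$$

where the rows of $H$ are a small number of shared temporal patterns
("behaviors" or metagenes — typically pulses with distinct onsets and
offsets, early drops and late rises) and $W_{gm}$ weights each gene on
each behavior. The fit uses the multiplicative updates

$$W \leftarrow W \circ \frac{XH^\top}{WHH^\top}, \qquad
  H \leftarrow H \circ \frac{W^\top X}{W^\top W H},$$

from uniform random starts, stopping when the Frobenius residual
$F^k = \lVert X - W^kH^k \rVert_F$ changes by less than θ (default 0.05).
The number of behaviors is chosen at the interior local minimum of the
RMSE between reconstructions at successive ranks, robustness is assessed
by comparing restarts with each other versus with the data, and genes are
grouped and ordered by their *dominant* (highest-weight) behavior.

Around that core the package provides the full pipeline: median-of-ratios
size factors, low-expression filtering, replicate averaging and per-gene
max-scaling; replicate outlier screening by z-scores on principal-component
scores; 1 − r hierarchical clustering of timepoints and transcription
factors; per-behavior top-gene lists for ontology tools; thresholding of
external DEG tables; and enrichment of TF-binding peaks in proximal
(±1 kb) and distal (±50 kb minus proximal) TSS windows with a one-sided
exact test. A synthetic-data generator reproduces the study's statistical
structure (sampling grid, pulsatile behaviors, sparse weights, replicate
noise, planted outliers, toy peak/TSS geometry) so every stage is testable
without sequencing data. It is aimed at computational biologists analysing
dense multi-condition expression time courses.

## Worked example

```r
library(tempoNMF)

# simulate the study-condition fixture: 2,000 genes, 5 planted behaviors,
# 3 replicates per timepoint, replicate CV 0.1
ds <- default_fixture(seed = 20240101)
dim(ds$expression)
#> [1] 2000  171

# normalize (median of ratios), filter, average replicates, scale
s    <- size_factors(ds$expression)
filt <- filter_low_expressed(normalize_counts(ds$expression, s), floor = 5)
tm   <- max_scale(average_replicates(filt, ds$sheet))
tm
#> timepoint_matrix: 1999 genes x 57 timepoints (GCSF 29 + IL3 28), max-scaled

# choose the number of behaviors
sel <- sweep_rank(tm, M_range = 2:10, seed = 2, theta = 0.01)
round(sel$rmse_successive, 4)
#>      2      3      4      5      6      7      8      9
#> 0.1205 0.1252 0.0964 0.0056 0.0077 0.0078 0.0094 0.0111
sel$local_minima
#> [1] 5
```

The successive-approximation RMSE stays high while each added behavior
captures real structure, collapses at the planted rank 5, then creeps up
as extra behaviors fit noise — the local minimum selects M = 5. (The
minimum occasionally lands at 6 for an individual seed; across panels of
seeds it concentrates on 5.)

```r
fit <- nmf_fit(tm, M = 5, seed = 42, theta = 0.01)
fit
#> nmf_model: 1999 genes x 5 behaviors x 57 timepoints; 116 iterations (converged); final F = 9.997

ord <- order_behaviors(fit)      # display order: GCSF peaks before IL3
ord
#>   behavior peak_condition peak_time_h
#> 1        1           GCSF          12
#> 2        2           GCSF         168
#> 3        5            IL3           3
#> 4        4            IL3          16
#> 5        3            IL3         128
table(dominant_behavior(fit)$dominant_behavior)
#>   1   2   3   4   5
#> 400 400 401 411 387

# outlier screen: z > 2 on the top four PCs within each replicate group
replicate_zscores(pca_scores(filt), ds$sheet)
#> outlier_report: 684 sample/PC rows, threshold z > 2, 0 flagged

# TSS-window binding enrichment on the toy peak fixture
toy <- make_peaks_and_annotation(2000, bound_fraction_fg = 0.4,
                                 bound_fraction_bg = 0.1, seed = 5)
bound <- assign_windows(toy$peaks, toy$tss)
binding_enrichment(bound, toy$foreground, toy$tss$gene_id, window = "proximal")
#>     window T_p T_n A_p  A_n    ratio      p_value
#> 1 proximal  38 100 224 2000 3.392857 4.852857e-13
```

The enrichment row reads: 38 of the 100 foreground genes are proximally
bound versus 224 of the 2,000 background genes, an enrichment ratio of
(38/100)/(224/2000) ≈ 3.4 with one-sided exact p ≈ 5 × 10⁻¹³. Each gene's
roughly 400-gene block recovers its planted behavior — matched to truth by
best correlation, >99% of genes land on their designated behavior — and
the clean fixture flags no replicate outliers.

The whole pipeline can also be driven in one call (or from the thin
CLI wrapper in `inst/cli/temponmf.R`):

```r
run_pipeline("all", pipeline_config(M = 5, M_range = 2:6,
                                    robustness_runs = 20, theta = 0.01),
             outdir = "tempoNMF_out")
```

which simulates the fixture when no inputs are configured and writes every
stage artifact plus a manifest (config echo, seed, checksums).

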