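# osemeat

Ordered-subset EM CT reconstruction and epicardial fat analytics.

`osemeat` is an R package for two linked problems in cardiac CT research:

1. **Low-dose CT image formation.** Iterative maximum-likelihood
   reconstruction from parallel-beam sinograms: the classical MLEM
   algorithm and its ordered-subset acceleration (OSEM) with
   angular-distance-optimized subset ordering, on top of a sparse Siddon
   ray-tracing system matrix, plus a Shepp-Logan phantom bench to measure
   convergence and error.
2. **Cardiac risk analysis.** Epicardial adipose tissue (EAT) volumetry
   from CT volumes by Hounsfield-unit windowing, Gensini coronary stenosis
   scoring with stenosed-vessel (NSCV) classification, and cohort
   statistics relating EAT to coronary heart disease (logistic risk model,
   Spearman correlation, ROC analysis), driven by a calibrated synthetic
   cohort generator.

It is aimed at researchers who want a transparent, fully tested reference
implementation of the OSEM update chain and of the downstream clinical
scoring/statistics, with every step exposed as a composable function.

## The algorithms in brief

With ray-pixel intersection lengths $q_{ij}$ (the system matrix), image
$g_j$ and measurements $y_i$, the EM update over an angle subset $S_m$ is

$$ g_j^{(k,m+1)} = g_j^{(k,m)} \cdot
   \frac{\sum_{i \in S_m} q_{ij}\; y_i / \hat y_i}{\sum_{i \in S_m} q_{ij}},
   \qquad \hat y_i = \sum_j q_{ij}\, g_j^{(k,m)} . $$

MLEM uses a single subset (all angles); OSEM partitions the angles into
$L$ balanced, interleaved subsets and sweeps them in an order that
maximizes the angular distance between consecutive subsets, converging
roughly $L$ times faster per pass over the data. The Gensini score is
$\sum_{\text{lesions}} \text{points}(\text{stenosis}\%) \times
\text{segment coefficient}$ with the doubling point scale 1–32; EAT volume
is (voxels in the −150…−50 HU window) × voxel volume.

See `vignettes/osem-eat-methods.Rmd` for the full model description,
parameter choices and limitations.

## Worked example

Reconstruction bench at reduced scale (64×64 phantom, 60 projections at
3°, 10 subsets of 6):

```r
library(osemeat)
ph   <- generate_shepp_logan(64)
geom <- make_geometry(3, 180, default_detector_count(64))
sm   <- build_system_matrix(geom, ph)
y    <- forward_project(sm, ph)
part <- partition_subsets(60, 6, "optimized")
os   <- osem_reconstruct(y, sm, part, recon_config(10), truth = ph)
ml   <- mlem_reconstruct(y, sm, recon_config(12), truth = ph)
round(os$error_history, 4)
#> 0.4630 0.2670 0.1807 0.1344 0.1065 0.0882 0.0755 0.0662 0.0591 0.0536
round(ml$error_history, 4)
#> 0.9200 0.8623 0.8022 0.7441 0.6897 0.6396 0.5941 0.5531 0.5163 0.4832 0.4534 0.4266
```

The histories are relative RMSE against the phantom: one full OSEM
iteration (0.463) is matched by MLEM only around iteration 10–11 — the
$L$-fold acceleration at $L = 10$. At the full bench scale (256×256, 180
angles, 30 subsets) OSEM reaches an error floor of ≈ 0.026 within 20
iterations, and MLEM needs ≈ 27 iterations to match OSEM's first.

Coronary scoring and cohort statistics:

```r
les <- data.frame(segment = c("LM", "LAD_MID"), stenosis_pct = c(100, 80))
gensini_score(les)$per_lesion
#>   segment stenosis_pct points coefficient contribution
#> 1      LM          100     32         5.0          160
#> 2 LAD_MID           80      8         1.5           12
classify_nscv(les)$category      # left main counts as two vessels
#> [1] double

coh <- generate_cohort(cohort_params(n_control = 2000, n_chd = 2000, seed = 7))
logistic_fit(coh, covariates = c("eat_ml", "age", "smoking"))
#> <logistic_result> n = 4000, converged in 4 IRLS iterations
#>         term        B       SE  wald        OR  ci_lower ci_upper          p
#>  (Intercept) -7.66092 0.388883 388.1 0.0004709 0.0002197 0.001009  2.165e-86
#>       eat_ml  0.03281 0.001276 661.5 1.0333527 1.0307724 1.035939 6.947e-146
#>          age  0.04404 0.005384  66.9 1.0450216 1.0340520 1.056107  2.850e-16
#>      smoking  1.01992 0.078714 167.9 2.7729684 2.3765222 3.235549  2.139e-38
chd <- coh[coh$chd == 1, ]
spearman_cor(chd$eat_ml, chd$gensini)
#> <spearman_result> r = 0.362, p = 6.639e-63, n = 2000
roc_analysis(coh$eat_ml, coh$chd)
#> <roc_result> AUC = 0.776; Youden threshold 146.2 (sens 0.651, spec 0.788)
```

Here each mL of EAT carries log-odds 0.033 (OR 1.033) for CHD after
adjustment, EAT correlates positively with Gensini severity in the CHD
group, and EAT alone separates the groups with AUC 0.78 at an optimal
cutoff of ≈ 146 mL.

A command-line front end over the same functions lives at
`inst/cli/osemeat.R` (subcommands `phantom`, `project`, `reconstruct`,
`eat`, `gensini`, `cohort`, `stats`; run it with `Rscript` and `--help`
style options as documented in its header).

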