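# driftpainter

Haplotype painting with drift-aware comparison statistics, for asking a
deceptively simple population-genetic question: when two groups look
genetically distinct, is that distinctness *ancient structure* (they split
long ago and have remained separate — a "remnants" history) or *recent
isolation* (they split recently and one of them went through a strong
bottleneck that exaggerates every distance — a "marginalisation" history)?
Classical summaries such as F_ST, model-based clustering and raw
chromosome-painting profiles cannot tell these apart, because a bottleneck
inflates all of them. This package implements an analysis strategy that
can: repaint each group under donor sets that exclude the focal groups,
clean the copying vectors into ancestry proportions, and scale
between-group differences by the drift each group shows *within* itself
across chromosomes.

It is aimed at statistical/population geneticists working with phased
SNP data (or coalescent simulations) who want the full pipeline — from
simulation through painting to drift-scaled tests and admixture dating —
as ordinary R functions returning tibbles.

## What is inside

* **Copying model** — a Li & Stephens haplotype-copying HMM
  (ChromoPainter-style): each recipient haploid is modelled as a mosaic
  of donor haploids, with switch probability `1 − exp(−n·d)` over `d`
  Morgans and per-site miscopy probability θ. Forward–backward gives
  per-site copy posteriors, expected copied cM per donor group (the
  copying vector `f`), expected chunk counts, sampled copy-paths, and
  E-M estimates of `n` and θ (`paint_panel()`, `sample_paintings()`,
  `fit_copy_model_em()`).
* **Ancestry cleaning** — non-negative least squares under a sum-to-one
  constraint expresses a group's copying vector as a mixture of other
  groups' vectors plus a self-copying term,
  `f^j ≈ Σ_k β_k f^k + β_SELF f^{j*}`, with delete-one-chromosome
  weighted block-jackknife standard errors (`ancestry_profile()`).
* **Drift-scaled statistics** — total variation distance
  `TVD_XY = ½Σ_k |f_k^X − f_k^Y|`; its within-recipient,
  between-chromosome analogue `TVD~_X`; the ratio
  `F_XY = TVD_XY / ½(TVD~_X + TVD~_Y)` which discounts differences that
  drift alone would produce; the within-group exceedance proportion
  `P(X)`; and Hudson's F_ST for calibration (`compare_profiles()`,
  `p_statistic()`, `hudson_fst()`).
* **Clustering** — a fixed-C Dirichlet-multinomial Gibbs sampler over
  copied-length vectors with empty-cluster refill, coincidence matrices
  and label-separation summaries (`run_gibbs()`).
* **Local ancestry** — two-surrogate per-SNP posteriors (per-chromosome
  E-M, or Bayes recalibration through the surrogates' own confusion
  rates), contiguous-segment calling, allele-match similarity within
  segments and the introgressed/ancestral similarity-ratio test
  (`persite_posteriors_em()`, `call_segments()`,
  `pairwise_similarity()`, `introgression_ratio()`).
* **Admixture dating** — coancestry curves built from sampled
  copy-paths (capped chunk-size products binned by genetic distance, as
  observed/expected ratios) and one- or two-exponential decay fits whose
  rates are dates in generations, converted to calendar years with
  `y = 1950 − (g + 1)·28` (`build_curves()`, `fit_admixture_date()`).
* **Synthetic data** — coalescent panels under the study demographies
  (msprime back-end): the 13-population marginalisation/remnants worlds
  and the 7-population simplified grid, SNP ascertainment to a target
  MAF spectrum, and two-source admixture mosaics with exponential
  segment lengths and known truth (`build_demography()`,
  `simulate_panel()`, `ascertain_snps()`, `simulate_admixed_mosaic()`).

## Worked example

Simulate the marginalisation world at desk scale, paint the two focal
groups, and compare them with and without each other as donors:

```r
library(driftpainter)

model <- build_demography("MA_full")
panel <- simulate_panel(model, c(Pop5 = 20, Pop5b = 10, Pop6 = 12, Pop7 = 12),
                        regions = rep(3e6, 6), seed = 11)
panel <- ascertain_snps(panel, target_spectrum = rep(1, 100),
                        n_per_region = 1000, seed = 12)

fst <- hudson_fst(panel, "Pop5", "Pop5b")
prof_out <- paint_panel(panel, donor_set("exclude_groups", c("Pop5", "Pop5b")),
                        params = copy_model_params(170.068, 0.001))
cmp <- dplyr::filter(compare_profiles(prof_out, "group"),
                     x_group == "Pop5", y_group == "Pop5b")
round(c(fst = fst, tvd = cmp$tvd, f_xy = cmp$f_xy), 3)
#>   fst   tvd  f_xy
#> 0.030 0.007 0.360
```

F_ST between the two groups is substantial (0.030 — entirely
bottleneck-driven here, since they split only 20 generations ago), yet
once neither group can be painted by the other their ancestry profiles
are nearly identical (TVD 0.007) and the drift-scaled `F_XY` of 0.36 is
far below what anciently split pairs show (values of 3–7 in the bundled
tests): the marginalisation signature. Cleaned ancestry proportions with
jackknife errors come from `ancestry_profile(prof_out, "Pop5b")`, and
`autoplot()` methods draw the standard figures.

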