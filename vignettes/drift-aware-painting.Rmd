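---
title: "Drift-aware chromosome painting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift-aware chromosome painting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(driftpainter)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, and the choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The scientific problem

Two groups sampled from the same region can appear strongly
differentiated — elevated F_ST, separate clusters, distinct painting
profiles — either because their ancestors separated long ago
("remnants" history) or because they separated recently and one group
subsequently went through a strong bottleneck ("marginalisation"
history). Drift during a bottleneck inflates every distance-like summary,
so the two histories are confounded for F_ST, ADMIXTURE-style clustering
and raw copying vectors alike. The package's strategy is to (i) repaint
each group under donor sets that *exclude* the focal groups, so neither
can absorb the other's drift; (ii) clean painting profiles into ancestry
proportions with honest chromosome-level uncertainty; and (iii) scale
between-group profile distances by the within-group, between-chromosome
variability that drift alone produces.

## The copying model

Each recipient haploid is modelled as an imperfect mosaic of donor
haploids (the Li & Stephens approximation). Between adjacent sites
separated by `d` Morgans the copied donor switches with probability
`1 − exp(−n d)`; after a switch the new donor is drawn from the landing
distribution (uniform over donor haploids by default, or weighted by
per-group copying priors when those are being estimated). At each site
the recipient's allele equals the donor's with probability `1 − θ`.

* `switch_rate` (`n`, per Morgan): controls chunk granularity. The
  conventional default is `400000 / H` with `H` the number of donor
  haploids, which is calibrated for panels of hundreds to thousands of
  donors at chip SNP density. At the reduced panel sizes used in the
  bundled simulations this formula over-switches badly (tens of switches
  per cM against tens of SNPs per cM), so the simulation fixtures fix
  moderate explicit values (170–400 per Morgan) instead; users painting
  real-scale panels should keep the default rule or estimate `n` by E-M.
* `emission_rate` (`θ`, per site, in `[0, 0.5)`): the miscopy
  probability. Default 0.00771 (the conventional default for human chip
  data); coalescent-simulated panels are cleaner than real data and the
  fixtures use 0.001.

Recursions run forward–backward with per-site rescaling, accumulating
the log-likelihood from the scaling constants — the numerically stable
equivalent of a log-space recursion. A scaling constant underflowing to
zero raises an error naming the site; nothing is silently clamped. Zero
genetic distances between adjacent sites are clamped to 1e-8 cM so
transitions stay defined. Expected chunk counts are the posterior
expectation of donor-change events plus the first chunk, computed from
pairwise transition posteriors; the per-site cM weight of a site is half
the distance to each neighbour (terminal sites take half the single
adjacent gap). Diploid individuals are painted one haploid at a time
with both own haploids always excluded from the donor set; group-level
exclusions are a separate, explicit donor-set choice.

E-M for `(n, θ)` runs independently per recipient haploid and
chromosome; the M-step for `n` maximises the expected complete-data
log-likelihood by 1-D optimisation on the log scale, and estimates are
combined SNP-count-weighted within recipients, then averaged across
recipients. The per-group copying prior (used by the local-ancestry
E-M) is updated from the posterior copied mass; this keeps the update
simple at the cost of exact monotonicity, so monotonicity is only
guaranteed (and only asserted in tests) for switch/emission E-M.

## Ancestry cleaning and uncertainty

A target group's genome-wide copying vector is regressed onto the other
groups' copying vectors under non-negativity and a sum-to-one
constraint, with an optional self-copying design vector that is zero
except at the target's own donor-axis entry. The constraint is imposed
simultaneously by an augmented heavily weighted row in the least-squares
system (weight 1000 — large enough that the constraint holds to ~1e-8,
small enough that the augmented design stays well conditioned for the
active-set solver, which is retried at smaller weights on numerical
failure). Coefficients at or below 0.001 are zeroed once and the
remainder rescaled; thresholding is applied jointly to the surrogate and
self terms. Standard errors come from delete-one-chromosome re-fits
combined with the weighted-jackknife variance formula (block weights =
chromosome SNP counts), which respects independent drift across
chromosomes — the property the whole analysis leans on.

## Comparison statistics

`TVD_XY = ½ Σ_k |f_k^X − f_k^Y|` compares two copying vectors;
`TVD~_X = ½ Σ_i (L_i/L) Σ_k |f_ik^X − f_k^X|` measures how much a single
recipient's profile moves from chromosome to chromosome (weights
`L_i` = SNP counts); and `F_XY = TVD_XY / ½(TVD~_X + TVD~_Y)` scales the
former by the latter. When both within terms are zero the ratio is
undefined and is returned as a flagged missing value, never an infinity.
`P(X)` is the proportion of within-X *unordered* individual pairs whose
`F` is at least the mean between-group `F̂_XY`; ties count as exceeding.
The normalisation question (ordered pairs with an indicator, divided by
`choose(n_X, 2)`) is resolved as the unordered-pair proportion, which the
tests verify equals the ordered sum halved whenever `F` is symmetric —
the only reading that keeps the statistic in `[0, 1]`.

F_ST uses the Hudson ratio-of-averages estimator (per-site numerator
`(p_a − p_b)² − p_a(1−p_a)/(n_a−1) − p_b(1−p_b)/(n_b−1)` over denominator
`p_a(1−p_b) + p_b(1−p_a)`, summed before dividing), chosen over
Weir–Cockerham for its robustness to unequal sample sizes at desk scale.

## Clustering

Individuals are clustered on genome-wide copied-length vectors under a
fixed-C Dirichlet-multinomial mixture: real-valued cM lengths enter the
multinomial log-likelihood directly. One iteration refills empty
clusters with one random distinct individual each, draws each cluster's
emission vector from its conjugate Dirichlet posterior (entries clamped
to `[1e-7, 1 − 1e-7]` then renormalised — clamping before
renormalisation, the stabler of the two orders), and redraws assignments
categorically. Defaults are `M = 200000`, burn-in 100000, thinning 1000,
ten pooled chains — a ten-fold reduction of the full-scale settings
(`M = 2,000,000`, thinning 10,000), which remain available in the
configuration. `delta` sets the prior concentration; because the
"counts" are genetic lengths, the data-to-prior balance depends on the
genetic length painted, which is why the simulated fixtures compress
full-chromosome genetic lengths into short physical regions (below).

## Local ancestry and the similarity-ratio test

Two-surrogate painting gives per-SNP posteriors of copying each source.
The "E-M" route re-estimates switch, emission and copying priors within
each chromosome (50 iterations by default) and uses the final posteriors
directly. The "NNLS" route recalibrates raw copy posteriors through
Bayes' rule using the surrogates' own copying behaviour:
`Pr(D | copy X) = f_X^D β_D / Σ_j f_X^j β_j`, then mixes over `X`
per SNP. Segments are maximal runs of SNPs with posterior strictly above
the threshold (ties excluded), discarded below a minimum SNP count;
coordinates are 0-based half-open SNP indices, converted to bp/cM only
at the I/O boundary. Similarity between two individuals pools the
overlapping same-source segment SNPs of all four haploid pairings into a
single matching proportion; an empty overlap is flagged missing, not
scored zero. The ratio of introgressed-segment to ancestral-segment
similarity, compared between groups, orders the split relative to the
admixture: a bottleneck *after* admixture homogenises both segment
classes equally (ratios overlap), a split *before* admixture depresses
the ratio in the bottlenecked group.

## Coancestry curves and dating

Sampled copy-paths (backward sampling from the posterior) are chopped
into chunks; for designated pairs of paths, each same-chromosome chunk
pair contributes the product of its cM sizes (capped at 1 cM) to the
0.1 cM bin of its midpoint separation, credited to the donor-group pair,
out to 50 cM. The curve value is the per-bin observed/expected ratio —
joint ordered weight times bin total over the product of marginal
shares. The ratio form matters: a raw per-pair mean confounds chunk-size
geometry with ancestry correlation and carries no usable decay, whereas
the ratio decays to 1 at rate `t/100` per cM for an admixture pulse `t`
generations ago. Pairings are all distinct sampled paths within and
between an individual's two haploids; a path is never paired with
itself (the same-sample diagonal would contribute pure identity).
Fitting profiles out per-curve intercepts and amplitudes by weighted
least squares (weights = chunk-pair counts) while sharing the
exponential rate(s) across curves; the default fit range starts at 1 cM
because shorter-range bins are dominated by painting noise. A fit whose
exponential explains under 1% of the weighted variance beyond a constant
is flagged "no admixture signal". Ancestry-coefficient reweighting of
curves is a per-surrogate multiplicative factor with sub-0.001
surrogates dropped. Dates convert to calendar years as
`y = 1950 − (g + 1)·28` (28-year generations anchored at 1950, one
generation added for the sampled individuals), rendered CE/BCE by sign.

## The synthetic-data generator

The generator drives a standard backward-in-time coalescent engine (the
bundled msprime script) — the demographies are engine-independent, so
re-implementing an approximate sequential-Markov simulator would add
nothing. Presets encode the study demographies: the 13-population world
with splits at 100–4000 generations, an out-of-Africa bottleneck and an
East-Asian bottleneck, a symmetric migration ramp between the two East
Asian-like populations (+0.00025 per generation over 375 generations,
encoded as piecewise-constant rates on a 25-generation grid), and
one-way pulses from the unsampled out-of-Africa population (0.02/gen
over generations 100–110); the marginalisation variant splits Pop5b from
Pop5 at 20 generations with an instantaneous 20,000 → 200 bottleneck,
the remnants variants split it at 1700 generations with 0.005 or
0.008/gen pulses into Pop5 (and 0.002 into Pop6) over generations
200–300. The simplified 7-population grid pairs Pop5b split times
\{750, …, 1700\} with bottleneck starts \{40, …, 20\} (to 5,000
diploids) and pulse fractions \{50, 75, 90\}% spread uniformly over the
100-generation window. Migration pulses are encoded exactly as printed
per-generation fractions; a 0.005/gen pulse over 100 generations
realises `1 − exp(−0.5) ≈ 39%` migrant ancestry, and the package reports
realised ancestry rather than asserting any nominal total. Sizes not
pinned down by the stated histories (ancestral sizes, the out-of-Africa
and East-Asian bottleneck depths) are fixed once, mirroring the
simplified-history values (10,000 ancestral; 2,000 during bottlenecks),
and are not tuning knobs.

Ascertainment mimics SNP arrays: exactly `n_per_region` sites per region
allocated across 100 half-open folded-MAF bins `[x, x + 0.005)` on
`[0, 0.5]` proportionally to a target spectrum, deficits filled at
random. The default target is the panel's own spectrum (pure thinning);
the test fixtures use a flat spectrum as a chip-array stand-in, since
painting informativeness per SNP, and hence every downstream signature,
depends on common variants being enriched the way array data are.
Admixture mosaics concatenate stretches whose cM lengths are
`Exponential(gens/100)`, each taken from a random haploid of source 1
with the stated probability; truth intervals tile each chromosome
exactly and every simulated allele equals its source haploid's allele.

## Desk-scale choices and what the tests do (and do not) show

The full study scale — hundreds of donors, ~660k SNPs, ~3500 cM — is far
beyond a test suite, so the fixtures scale down deliberately:

* F_ST calibrations use ten 5 Mb regions, 50 diploids per relevant
  population, five seeds.
* The marginalisation signature fixture uses ten 3 Mb regions with the
  genetic map compressed four-fold (recombination 5e-8/bp, i.e. 15 cM
  per region), 1200 flat-ascertained SNPs per region, 12 diploids per
  donor group with 23 + 10 in the focal pair, and painting at switch
  rate 400, emission 0.001, over five seeds.
* Dating uses three 40 Mb regions (50 cM each), 20 mosaic haploids,
  ten path samples per haploid, three seeds.
* The similarity-ratio ordering experiment emulates the two event
  orderings with mosaics directly: a bottleneck *after* admixture is two
  founder mosaics recombined into the group, a bottleneck *before*
  admixture draws the ancestral background from a single founder while
  the introgressed side stays diverse; three seeds pooled.

At this scale the categorical signatures reproduce cleanly and
deterministically: clustering separates the bottlenecked pair under
all-donors painting in essentially every retained sample and never once
both groups are excluded as donors; the drift-scaled `F_XY` of the focal
pair sits several-fold below every anciently split pair; cleaned
analysis-B ancestry profiles of the two groups agree within joint
jackknife error; and the 50-generation mosaic date is recovered on the
seed average. The graded statistic `P(X)` is the exception: its
bottleneck contrast rests on chromosome-level drift exceeding painting
noise, and at desk scale the two are comparable, so the tests assert the
seed-averaged ordering `P(Pop5) > P(Pop5b)` rather than the near-zero
`P(Pop5b)` magnitude that full-scale data produce. Passing tests
demonstrate internal correctness (all core recursions are checked
against exhaustive oracles) and qualitative reproduction of the
simulated signatures; they do not demonstrate power on real-scale chip
data, phasing-error robustness, or behaviour under ascertainment schemes
other than MAF-spectrum matching.

## Known limitations

* The painting model is a deliberate simplification: no per-region
  recombination-rate re-estimation, no unlinked/haploid modes, and no
  region-based normalisation parameter for downstream tree building.
* Coancestry dating reports rates and amplitudes only — no bootstrap
  confidence intervals, no null-individual standardisation, no
  multi-way source composition; two-exponential fits are reported
  without a formal significance test between one and two pulses.
* Three-source local ancestry is out of scope; phasing error is not
  modelled (simulated panels are perfectly phased).
* Significance testing of TVD/F_XY differences is deliberately absent;
  the statistics are descriptive, scaled summaries.
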