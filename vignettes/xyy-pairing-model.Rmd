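---
title: "The 2+1 pairing model for XYY Drosophila males: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The 2+1 pairing model for XYY Drosophila males: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xyypair)
```

## The biological problem

In Drosophila male meiosis I the X and Y chromosomes pair through their
ribosomal DNA (rDNA) arrays. An XYY male has three sex chromosomes that
must resolve to two spindle poles, which makes segregation a *competitive*
assay for pairing: if rDNA copy number modulates pairing efficacy, a Y
with a deleted rDNA array should lose pairing contests against a
full-length competitor, and the loss should be visible in the progeny.

The package models this with the **2+1 model**: two of the three
chromosomes pair and disjoin faithfully while the third segregates at
random. Writing the full-length Y as `1` and the deletion-series Y as
`2`, the configurations are

* **L** — X pairs Y1; Y2 free,
* **M** — X pairs Y2; Y1 free,
* **N** — Y1 pairs Y2; X free,

with population frequencies `(pL, pM, pN)` on the simplex. Each
configuration produces four equiprobable sperm karyotypes (the paired
chromosomes disjoin, the free chromosome joins either pole with
probability 1/2), and the six possible sperm classes — in the canonical
order `X, 12, X1, 2, X2, 1` used everywhere in the package — have
expected frequencies

$$
P(X) = P(12) = \frac{p_L + p_M}{4},\qquad
P(X1) = P(2) = \frac{p_M + p_N}{4},\qquad
P(X2) = P(1) = \frac{p_L + p_N}{4}.
$$

Two limiting predictions anchor the model: an equal mixture gives six
equal zygote classes, and exclusive L pairing eliminates the `X1` and `2`
classes entirely. Because every configuration sends the X to each pole
with probability 1/2, the expected sex ratio is exactly 1:1 for *every*
mixture — a deviation therefore indicates differential zygote viability,
never pairing bias.

```{r}
zygote_distribution(pairing_mixture(1, 0, 0))
expected_sex_ratio(pairing_mixture(0.9, 0.05, 0.05))
```

## Estimation and identifiability

The three complementary-pair sums invert the model linearly:
`pL = 1 - 2(f_X1 + f_2)`, `pM = 1 - 2(f_X2 + f_1)`,
`pN = 1 - 2(f_X + f_12)`. `estimate_mixture_moments()` applies this to
pooled class frequencies; `pairing_fit()` wraps it in the usual modelling
interface and adds vial-bootstrap percentile intervals (resampling whole
vials, the natural exchangeable unit).

The estimator **assumes unit viability** of all six zygote classes. With
six observed frequencies and five free parameters beyond the mixture
(relative viabilities up to scale), mixture and viability are jointly
unidentifiable, so no joint fit is offered. Instead the fit reports the
complementary-pair differences `f_X - f_12`, `f_X1 - f_2`, `f_X2 - f_1`,
which are zero in expectation under any mixture when viability is uniform
and hence isolate the viability signal; the tests demonstrate that a
class-12 (XYY-male) viability of 0.6 biases the moments estimate
detectably. Sampling noise can push a raw estimate off the simplex;
negative components are clipped to zero with renormalization and the
estimate is flagged `projected` — an out-of-model warning, not silently
absorbed.

```{r}
tab <- simulate_xyy_vials(pairing_mixture(0.2, 0.3, 0.5),
                          design = vial_design(n_vials = 30), seed = 7)
fit <- pairing_fit(tab, boot = 300, seed = 7)
summary(fit)
```

## The statistical toolkit

**Difference-of-means intervals.** Replicate-vial and transfer-time
subsets are compared with the noninformative-prior posterior interval for
a difference of normal means with unequal variances, which coincides with
the Welch *t* interval: center `mean_a - mean_b`, scale
`sqrt(sd_a^2/n_a + sd_b^2/n_b)`, Welch–Satterthwaite degrees of freedom.
A "0.975 interval" is two-sided, i.e. the 0.9875 quantile. Exclusion of
zero is the significance criterion, and no multiple-testing correction is
applied across the 72-comparison scan — the analysis is deliberately
anti-conservative in that respect, which strengthens its negative
conclusion. This reading was chosen over a plain normal-quantile interval
because only the Welch form singles out exactly one significant pair in
the packaged subset table (the X2 class, first versus third transfer, in
the full-length-Y2 cross); the normal approximation flags more.

A calibration caveat the package documents and tests rather than hides:
with only three vials per subset, the Welch interval is *conservative* —
its measured null exclusion rate is below the nominal 2.5% (roughly
1.5–2% in simulation), converging to nominal by around thirty vials per
group. The package's implementation agrees with `stats::t.test`'s Welch
interval to numerical precision, so this is a property of the procedure
at that group size, not of the code.

**Required sample size.** The power analysis asks how many vials per
group would make two observed class frequencies statistically separable:
`n = ceil(t²(1-α/2, df) (sd_a² + sd_b²) / (mean_a - mean_b)²)` with
α = 0.05 and df fixed at 1000 (effectively a normal quantile). There is
no power term beyond the α threshold: this is a detectability criterion,
not a 1-β design. Because its inputs are the one-decimal rounded means
and SDs of the summary tables, reproduction of the reported vial numbers
is expected only to a few percent.

**Regression and qPCR.** Class frequency is regressed on relative rDNA
copy number by ordinary least squares with `r² = cor(x, y)²`, mirroring
the spreadsheet SLOPE/INTERCEPT/CORREL workflow of the original analysis.
Relative rDNA copy number is quantified by `2^(-ΔΔCt)` against a
multicopy tRNA normalizer and a reference genotype, with amplification
efficiency taken as 100% (the underlying assay protocol reports none);
replicate SEMs of sample and reference are pooled root-sum-of-squares on
the ΔCt scale (the scale on which the noise is approximately normal) and
transferred to the percent scale by the delta method,
`sem% = ln(2) · fraction% · sem(ΔΔCt)`. The mean-ΔCt-first convention is
used (ΔΔCt from mean ΔCts, not a mean of per-replicate ratios); the two
differ only at second order in the noise. Replicate outliers are not
removed.

## The synthetic-data generators

The generators produce every input the pipeline consumes, with the
statistical structure the analysis assumes:

* `simulate_xyy_vials()` — vial sizes from a negative-binomial-shaped
  integer distribution (defaults: 32 vials, mean 105, SD 44 flies, the
  scale of the largest real cross; vials are overdispersed relative to
  Poisson, and any overdispersed integer family matching the mean/SD
  would do); class counts multinomial within each vial at the model
  distribution, optionally perturbed per vial by a symmetric Dirichlet
  draw with concentration κ, giving the closed-form between-vial variance
  `p(1-p)(n+κ)/(n(1+κ))` used as the test oracle. Empty vials are
  redrawn.
* `simulate_control_cross()` — four-class XY control progeny;
  exceptional flies binomial at the nondisjunction/loss rate, split
  50/50 between XXY females and X0-like males because the phenotypic
  assay cannot distinguish loss from nondisjunction, so the simulator
  does not either.
* `simulate_qpcr()` — replicate Ct pairs with
  `Ct = baseline - log2(template)/log2(1 + efficiency)` plus Gaussian
  cycle noise (default SD 0.2 cycles, a typical replicate spread for
  this assay).

All generators derive per-generator substreams deterministically from one
integer seed and are bit-reproducible. What they deliberately do **not**
emulate: position-effect variegation expressivity (the X1-versus-X12
scoring ambiguity is modelled only as a flag), gynandromorphs, larval
lethality timing, nullo-XY sperm, meiosis-II errors, and trivalent
pairing. Passing tests therefore show that the estimators are correct
*under the model's closed six-class world*, not that real crosses satisfy
it — the viability diagnostic exists precisely because real data do not.

## Numerical choices and problem sizes

Mixtures within 1e-9 of the simplex are renormalized, farther ones
rejected; viability vectors are canonicalized to max 1; frequencies
passed to the moments estimator must sum to 1 within 1e-6 (pooled table
rows are renormalized from their rounded percentages first). Degenerate
inputs fail loudly: zero-variance groups collapse the interval to a
point, a constant regression abscissa and single-vial SDs are errors or
flagged `NA`s rather than silent zeros.

The test suite's simulation sizes were chosen to keep the full run around
half a minute while leaving comfortable statistical margins: parameter
recovery uses 20 random mixtures at 30 vials × 120 flies (RMSE bound
0.05 per component), interval calibration uses 4,000–10,000 simulated
null pairs, Dirichlet-multinomial variance checks use 2,000 vials, and
bootstrap coverage uses 60 replicates of 200 resamples at a 4-SE guard
band.

## Known limitations

* The moments estimator is biased whenever viability is non-uniform —
  which the real crosses show it is (aneuploid subviability); its output
  says so, and the complementary-pair diagnostic quantifies the
  asymmetry, but the package deliberately offers no joint
  mixture-viability fit.
* Partial pairing failure (a paired pair that sometimes nondisjoins) is
  not parameterized; the 2+1 model's paired pair disjoins with
  probability 1.
* The qPCR module reports relative copy number only; no absolute
  calibration is attempted.
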