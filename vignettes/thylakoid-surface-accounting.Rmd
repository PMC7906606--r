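---
title: "Modelling thylakoid membrane expansion during de-etiolation"
author: "ThylakoidExpansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thylakoid membrane expansion during de-etiolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ThylakoidExpansion)
```

## The problem

When a dark-grown *Arabidopsis* seedling first sees light, its etioplasts
differentiate into chloroplasts and the thylakoid membrane network is
built almost from scratch within days. Two independent routes estimate
how much membrane is made:

* a **molecular** route, which converts absolute amounts of the main
  membrane constituents — the galactolipids MGDG and DGDG, and the three
  photosynthetic complexes PSII, cytochrome b6f and PSI — into membrane
  area via molecular footprints; and
* a **morphometric** route, which scales the per-chloroplast thylakoid
  surface measured on 3D electron-microscopy reconstructions up to the
  whole seedling.

This package implements both routes, a four-parameter logistic (4PL)
growth model of surface versus time, the comparison of the two
estimates, and a seeded synthetic generator of de-etiolation time
courses used throughout the tests.

## Units

All functions use one canonical unit system: time in hours of light
exposure, amounts in nmol per seedling, molecular footprints in
nm²/molecule, membrane surfaces in µm² per seedling (1 µm² = 1e6 nm²),
and volumes in µm³.

## The molecular surface model

For any membrane component, surface per seedling is

$$ S = n \cdot N_A \cdot a $$

with $n$ the amount (mol/seedling), $N_A$ the Avogadro constant and $a$
the footprint (area per molecule). Each photosynthetic complex is
quantified through one marker subunit (PsbA for PSII-LHCII, PetC for
cytochrome b6f, PsaC for PSI) at an assumed 1:1 subunit:complex
stoichiometry; the complex footprints (494, 49.5 and 300 nm²) are
stroma-exposed areas, so proteins receive no further correction.

Lipids receive two corrections:

* **bilayer division**: a membrane has two leaflets, so the
  stroma-exposed surface is half the summed molecular area (divide by
  2); and
* **envelope subtraction**: galactolipids also populate the chloroplast
  envelope. Given the measured thylakoid-to-envelope surface ratio $R$,
  the envelope's share of the galactolipid pool is taken as
  $f = 1/(1+R)$ and removed. $R$ is only measured at 4, 24 and 96 h
  (1.02, 7.37, 6.83); `envelopeFractionAt()` interpolates it linearly
  between those times and holds it constant outside them, since nothing
  is known about intermediate behaviour. The envelope's two membranes
  are not modelled separately — the measured ratio already refers to a
  single envelope surface, and resolving outer versus inner membrane
  would require data the tables do not contain.

The total,

$$ S_{thylakoid}(t) = S_{MGDG}(t) + S_{DGDG}(t) + \sum_c S_c(t) +
\varepsilon, $$

carries an explicit $\varepsilon$ term for everything not quantified
(SQDG, plastoquinone, ATP synthase, NDH, FtsH, ...). $\varepsilon$
defaults to 0 and is always reported as its own column of the
`SurfaceBreakdown`, so the accounting identity
`total = sum(components) + epsilon` can be (and is) enforced by the
class validity at 1e-9 relative tolerance.

## The morphometric route

3D reconstructions yield the stroma-exposed thylakoid surface per
chloroplast; grana lamellae add surface beyond it, handled as
`stroma_surface * (1 + grana_percent/100)`. When no grana percentage is
available it defaults to 0 and results describe the stroma-exposed
surface only. Scaling to the seedling multiplies by chloroplasts per
cell and cells per seedling; the cell count defaults to a constant 3000
(mesophyll plus palisade, about half the cotyledon volume divided by
the mean cell volume), constant across time because cotyledon cell
number does not change during this window. Counts are reported rounded
but propagated as reals so repeated multiplication does not compound
rounding.

## The growth model

Surface versus time is summarized by the four-parameter logistic

$$ S(t) = a + \frac{d - a}{1 + \exp((t_{mid} - t)/\tau)} $$

with lower asymptote $a$, upper asymptote $d$, inflection time
$t_{mid}$ (where $S = (a+d)/2$ exactly) and timescale $\tau > 0$. This
parameterization is self-documenting and standard for S-shaped growth.
Fitting uses Levenberg–Marquardt least squares with a deterministic
self-start: $a$ and $d$ from the data range, $t_{mid}$ from the first
linear-interpolated crossing of the half range, $\tau$ a quarter of the
time span. Optimizer tolerances are 1e-15 on relative change with up to
1000 iterations; there are no stochastic restarts, so fits are
reproducible by construction. Flat input and optimizer failure return a
flagged degenerate result (with $d = a$) instead of raising, and a fit
whose $d < a$ is re-expressed through the exact symmetry
$(a, d, \tau) \to (d, a, -\tau)$ so the increasing branch is always
reported.

The mixed-effects variant places replicate-level random effects on
three parameters, by default $d$, $t_{mid}$ and $\tau$ — the asymptote
and timing are what plausibly varies between biological replicates; the
choice is configurable because nothing in the data pins down which
three. Two estimators are provided. The default, and the reference
implementation, is a **two-stage** estimator: an unconstrained 4PL fit
per replicate, fixed effects as the per-replicate means,
between-replicate SDs as the sample SDs of the randomized parameters.
It is deterministic, cannot fail where the per-replicate fits succeed,
and reduces *exactly* to the pooled fit when replicates are identical —
a contract the tests enforce. The joint `nlme` estimator is also
offered and falls back to the two-stage one when it does not converge,
which is routine when the between-replicate variance is near zero.
Either per-replicate or replicate-mean series can be fitted; both modes
exist because the original analysis does not state which was used.

## Comparing the two routes

`compareModelMorpho()` evaluates the fitted 4PL at the morphometric
time points and flags each one. The series spans two orders of
magnitude, so a pure ratio criterion misbehaves at both ends: at early
times both estimates are tiny and a large ratio is biologically
meaningless, while at the final time a ratio of ~0.77 would pass a
[0.5, 2] band even though the absolute shortfall is large. Agreement is
therefore judged on the absolute residual relative to the scale of the
series (the largest morphometric value), with a default threshold of
10%; the ratio and a ratio-band flag are still reported as secondary
descriptors. On the packaged reference tables this yields agreement at
4 and 24 h and divergence at 96 h, where the molecular model
undershoots — consistent with unquantified components
($\varepsilon$) contributing mostly late in de-etiolation.

## Absolute quantification

Immunoblot and lipidomics signals are converted to amounts through
ordinary least-squares calibration lines fitted to external standards.
The intercept is left free (forcing through the origin is an assumption
the standards do not justify); a signal below the fitted intercept
yields a negative concentration, which is clipped to 0 and flagged
rather than raised, since blot background routinely puts weak signals
there.

## The synthetic generator

`simulateTimecourse()` emulates the statistical structure of the study
design so every stage is testable without any raw data: 8 time points
(0–96 h), 3 replicates, 12 galactolipid species and 3 marker subunits.
Each analyte follows its own 4PL kinetic law; the class defaults encode
the observed temporal structure — ER-pathway lipids (18-carbon sn2
chain) rise around 10 h with a 2 h timescale, producing the
characteristic leap between 8 and 12 h; plastid-pathway lipids
(16-carbon sn2) rise around 30 h with a 4 h timescale, so their
pre-onset tail stays within replicate noise at 12 h; PsbA rises before
PetC and PsaC. Baselines and amplitudes are set so noise-free totals
sit at the measured scale (≈0.3 nmol total galactolipid in the dark,
≈2.2 nmol at 96 h, MGDG/DGDG ≈ 3 at 96 h). Replicate noise is
multiplicative lognormal, mean-preserving, with a default CV of 15%
(the reference dispersions run 10–30%); amounts are positive and their
dispersions scale with the mean, which is exactly what a lognormal
gives. A Gaussian alternative (truncated at zero) exists for
sensitivity checks.

Kinetics deliberately reuse the 4PL family rather than a mechanistic
synthesis model: the recovery tests ask whether the fitting machinery
recovers the generating family's parameters, and a mechanistic model
would conflate generator misspecification with estimator error. Note
one consequence: the *total* surface is a sum of 4PLs with different
midpoints, which is not itself a 4PL, so the fitted upper asymptote
recovers the truth's asymptote only approximately even without noise
(within about 1% under the defaults).

The generator always emits a truth record with every generating
parameter, so tests never re-derive truth from output. The morphometric
table is produced by running the surface model forward on the
noise-free truth and dividing back through the chloroplast-per-cell and
cell-per-seedling factors, guaranteeing internal consistency between
the two routes at zero noise.

What the generator does *not* emulate: absolute-quantification error in
the calibration step, between-time-point correlation of replicates
(each sample's noise is independent), detection limits (every analyte
is reported at every time), or any proteome beyond the three marker
subunits. Passing recovery tests therefore demonstrates correctness of
the estimation machinery under the stated noise model, not robustness
to every failure mode of real lipidomics or immunoblot data.

## Problem sizes used in the tests

The test-suite simulations are sized to characterize the estimators
while staying quick: 20 generator seeds for the CV-15% asymptote
recovery, 25 seeds per noise level for the bias-versus-noise sweep, 50
small generations for the empirical-CV calibration, and 25-case
property sweeps for the accounting invariants. All run in well under a
minute in total.

## Known limitations

* Printed input tables carry 2 significant figures; quantities
  recomputed from them inherit a few percent of quantization error.
* The envelope correction treats the envelope as a single surface and
  interpolates $R$ through unmeasured time points.
* The grana contribution enters only as an explicit percentage; no
  grana geometry is modelled.
* $\varepsilon$ is a free additive term, not a model of the
  unquantified components; the late divergence between the two routes
  is attributed to it but not decomposed.
* The mixed model's randomized-parameter set is a modelling choice, not
  an identified quantity.

## A worked example

```{r example, warning = FALSE}
ae <- readAmountTable(thylakoidDataFile("subunit_amounts.csv"))
m <- amountMeans(ae)

## PSII surface at 0 and 96 h (um2/seedling)
complexSurface(m["PsbA", "0"], "PsbA")
complexSurface(m["PsbA", "96"], "PsbA")

## morphometric scaling at 96 h, in mm2/seedling
morpho <- readMorphometricTable(thylakoidDataFile("morphometrics.csv"))
morphometricSurfaceTable(morpho)

## fit the 4PL to the published component-surface series and compare
ref <- referenceComponentSurfaces()
fit <- fitLogistic4P(timePoints(ref), unname(surfaceTotal(ref)))
coef(fit)
compareModelMorpho(fit, morphometricSurfaceTable(morpho))
```
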