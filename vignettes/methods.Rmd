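---
title: "Estimating retinal ganglion cell counts from structure and function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating retinal ganglion cell counts from structure and function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgcest)
```

## The problem

Retinal ganglion cells (RGCs) die throughout glaucoma, but standard
automated perimetry (SAP) only registers the loss late: its decibel scale
compresses early deficits, and 25–50% of RGCs can be gone before the
24-2 mean deviation (MD) moves. Structural imaging (OCT nerve fiber layer
thickness, ARNFLT) and RGC electrophysiology (steady-state pattern ERG
amplitudes Mag and MagD) each see part of the picture. This package
implements a pipeline that fuses them into per-eye RGC count estimates and
the cohort-level statistics used to evaluate such estimates in glaucoma
suspects (GS) and preperimetric glaucoma (PPG).

## The CSFI count

The combined structure–function index estimates an eye's RGC count twice
and blends the two by disease stage.

**Perimetry route.** Each of the 52 non-blind-spot 24-2 locations maps its
sensitivity $s$ (dB) to a local log-scaled ganglion cell quantity through
a linear function whose slope and intercept depend on eccentricity $ec$
(degrees, Euclidean distance of the location's center from fixation):

$$m = 0.054\,ec^{1.32} + 0.9,\qquad b = -1.5\,ec^{1.32} - 14.8,$$
$$gc = \frac{(s-1)-b}{m} + 4.7,\qquad SAP_{rgc} = \sum 10^{0.1\,gc}.$$

RGC density is treated as uniform over each location's 6°×6° patch, so no
sub-location integration is performed. Sensitivities below 1 dB are
allowed: $gc$ goes negative and the contribution decays smoothly toward
zero rather than erroring, which is the right behaviour for deep defects.

**OCT route.** ARNFLT is converted to an axon count via an age-dependent
axonal density $d$ (axons/µm²) and corrected for nerve fiber layer
remodeling through the MD-dependent factor $c$:

$$d = -0.007\,\mathrm{age} + 1.4,\quad c = -0.26\,MD + 0.12,\quad
a = ARNFLT \cdot 10870 \cdot d,$$
$$OCT_{rgc} = 10^{0.1(10\log_{10} a - c)} = a\,10^{-c/10}.$$

The logarithm must be base 10: the $10^{0.1(\cdot)}$ inversion only
returns $a$'s scale under $\log_{10}$, and any other base shifts counts by
orders of magnitude.

**Blend.** $eRGC_{CSFI} = (1 + MD/30)\,OCT_{rgc} + (-MD/30)\,SAP_{rgc}$.
At MD = 0 the estimate is purely structural, at MD = −30 purely
functional, mirroring where each modality is reliable.

### The two coefficient variants

Printed transcriptions of the perimetry/OCT chains circulate in two forms
that differ in three places: `0.54(ec*1.32)` vs $0.054\,ec^{1.32}$ in $m$,
`-1.5(ec+1.32)` vs $-1.5\,ec^{1.32}$ in $b$, and `(-0.007+age)` vs
$-0.007\cdot age$ in $d$. Only the power-law/product forms produce counts
on the physiologic ~10⁶ scale (a 50-year-old healthy eye: ~1.1 million);
the literal forms yield per-location counts of ~10¹ and densities of ~50
axons/µm², both impossible. We therefore default to the `corrected` forms
and keep the literal chain available as `variant = "as_printed"` so the
transcription can be reproduced verbatim; every result object carries its
variant tag. The constants 4.7 and 0.1 are used as given in both variants.

A floating-point note: the two blend weights are stored so that
`w_oct + w_sap == 1` holds *exactly* in double precision. One weight is
computed as the literal expression and the other as its complement from 1,
ordered by MD regime so the subtraction is either exact by the Sterbenz
lemma (operands within a factor of two) or rounds back to 1; a naive
independent evaluation of both weights misses exactness on a measurable
fraction of MD values.

## The affine eRGC estimators and the mixed model

The CSFI needs 52 perimetry points plus OCT per eye. The package's second
estimator family needs three numbers: age, ARNFLT, and one ssPERG
amplitude. `builtin_rgc_models()` returns the two published models
(intercept 401,341.71 / 405,528.50 etc.) at full precision; the familiar
rounded formulas are derived for display only, using half-away-from-zero
rounding, the convention of the reported tables (base R's `round()` is
half-to-even and would print 405,528).

`fit_rgc_glmm()` refits models of this form on any bilateral cohort. The
model is a linear mixed model with fixed effects {age, ARNFLT, PERG} and a
random intercept shared by the two eyes of each subject, estimated by
REML via `lme4::lmer`. With at most two eyes per subject, a random
intercept is the identifiable reading of "repeated measures with
within-subject correlation": it induces a compound-symmetric within-pair
covariance, and richer structures are not estimable from pairs.
Rank-deficient designs are rejected before fitting; convergence and
singularity messages from the optimizer are captured on the returned
object rather than thrown, because degenerate-but-exact fits (zero noise)
still recover coefficients to machine precision.

**Cross-validation.** `split_cohort()` partitions eyes (default) or
subjects at a given fraction; splitting by eye reproduces the 30/20 counts
of a 60% split of 50 eyes, while `unit = "subject"` avoids placing fellow
eyes on opposite sides of the split. `cross_validate()` returns the
squared Pearson correlation between predictions and outcomes. Predictions
are fixed-effects-only (marginal): validation subjects are unseen, so no
random-intercept estimate exists for them, and using marginal predictions
for the training set as well keeps the two R² values comparable.

**Loss accounting.** `proportional_loss()` reports
$100(\bar{x}_{healthy}-\bar{x}_{group})/\bar{x}_{healthy}$ rounded
half-away-from-zero to integer percent; `annual_loss_rate()` reports
$100\,|\beta_{age}|/\bar{x}_{healthy}$ to two decimals. Unrounded values
ride along as attributes so rounding happens only at render time.

## Cohort statistics

* `one_way_anova()` — classical decomposition via `aov`, with
  $\eta^2 = SS_{between}/SS_{total}$ as the effect size (the magnitude
  range of the reference tables is consistent with $\eta^2$; the tables do
  not label their effect-size column, so this is a documented choice).
* `games_howell()` — for unequal variances and group sizes. Per pair:
  Welch SE, Welch–Satterthwaite df, and
  $q = |\Delta\bar{x}|\sqrt{2}/se$ referred to the studentized-range
  distribution (`ptukey`) with the total number of groups. With two
  groups this reduces exactly to the Welch t-test, a identity the test
  suite checks numerically. An optional `subject` argument first averages
  fellow eyes within subject and group, giving an analysis whose units are
  independent subjects; the default eye-level analysis matches per-eye
  group sizes.
* `roc_auc()` — AUC as the Mann–Whitney concordance fraction with
  half-weight ties; p-value from the normal approximation to U with tie
  correction. Orientation is normalized so the reported AUC is ≥ 0.5 with
  the direction recorded. Degenerate inputs (one class, all-tied scores
  with zero U-variance) are handled explicitly.
* `welch_t()`, `pearson_r2()` — thin, validated wrappers over the base
  tests; two zero-variance samples are rejected as degenerate.

## What the simulator emulates — and what it does not

`simulate_cohort()` reproduces the *statistical structure* the analysis
assumes: three diagnostic groups (default 15/5/5 subjects → 30/10/10 eyes
when no subject is discordant) whose measurement means and SDs default to
the reference cohort profiles; bilateral eyes sharing subject age; a
configurable fraction of discordant subjects (default 0.2, i.e. 5 of 25)
whose fellow eyes fall in *adjacent* groups; and a shared subject-level
deviate giving each measurement an inter-eye correlation of $\rho$
(default 0.6 — a typical value for ocular structural measures; the true
value is unreported, so it is a parameter, not an assertion). Marginals
are truncated normals (ARNFLT 40–130 µm, Mag/MagD ≥ 0, MD ∈ [−35, 3] dB,
age 20–80). The latent outcome is the Mag estimator's prediction plus
subject-level (SD 50,000) and eye-level (SD 40,000) Gaussian noise,
chosen to put outcome SDs near the reference cohort's ~1.3×10⁵ scale.

What it does **not** emulate: the joint correlation structure *between*
different measurements within an eye (ARNFLT and Mag are conditionally
independent given group here, but correlated ~0.5 in real eyes), floor
effects of advanced disease, measurement-device noise spectra, or disease
progression. Passing tests on these cohorts therefore demonstrates that
the estimators and tests are *implemented correctly* (parameter recovery,
coverage, invariances) — not that they would achieve any particular R² or
AUC on real patients, which is exactly why real-cohort fit statistics are
not asserted anywhere in the suite.

`simulate_visual_field()` draws sensitivities from a linear normative
surface (33 dB at the innermost ring, 4.24°, declining to 27 dB at 27°,
noise SD 1.5 dB) and shifts the field to hit a target MD within 0.05 dB;
targets that clipping to [0, 50] dB makes unreachable raise an error. The
surface is a test fixture: CSFI results are tagged by coefficient variant
and do not depend on it.

## Problem sizes and numerical tolerances

The test suite runs at desk scale: parameter-recovery properties use 50
replicate cohorts of 200 subjects (400 eyes), which bounds the mean
coefficient bias below 5% while keeping a full run around half a minute;
marginal-mean checks use 1000 eyes per group against 3-standard-error
bands; ROC results are verified against exhaustive pair enumeration on
instances of ≤ 30 observations, and Games-Howell p-values against an
independent double-quadrature evaluation of the studentized-range
distribution to 10⁻⁴. Vectorised CSFI sums agree with per-location loops
to 10⁻⁹ relative tolerance. Seeded runs are bitwise reproducible; RNG
state is saved and restored around every seeded helper.

## Limitations

The CSFI inherits the Harwerth ganglion-cell model's known tendency to
overestimate absolute counts; these are staging quantities, not
histological truths. The affine estimators are calibrated to healthy, GS
and PPG eyes and should not be extrapolated to moderate or severe
glaucoma, where floor effects break linearity. The simulator's
independence of covariates given group means synthetic cross-validation
R² values are typically below those reported for real cohorts, where
strong ARNFLT–PERG–CSFI correlations inflate fit.
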