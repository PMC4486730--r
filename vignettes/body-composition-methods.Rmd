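---
title: "Estimating pinniped body composition: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating pinniped body composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinnicomp)
library(dplyr)
```

Field physiologists estimate the fat and adipose tissue mass of seals with
two techniques that never open the animal: geometric reconstruction of the
blubber layer from girths, lengths and ultrasound depths (the truncated
cones method), and isotope dilution of labeled water (total body water,
TBW). Both are indirect, both lean on literature constants, and both carry
uncertainty that matters when body condition feeds demographic or
management models. `pinnicomp` implements the two pipelines, the Bayesian
regressions that calibrate them, Monte Carlo error propagation, and
one-at-a-time sensitivity analysis, together with a synthetic-data
generator that makes every stage testable against a known truth.

## The truncated-cones model

The body is approximated as a stack of conical frusta between eight
landmark girth stations (ankles, pelvis, umbilicus, mid, sternum, axilla,
neck, ears), plus an end cone from the tail to the ankles and from the ears
to the nose tip. Hauled-out seals flatten under gravity, so cross-sections
are modelled as ellipses with horizontal semi-axis $a = W/2$ (half the
width) and vertical semi-axis $b = H/2$ (half the height); the traditional
variant assumes circles with $r = G/2\pi$ from the girth $G$.

The volume of a frustum whose elliptical ends have semi-axes
$(a_1, b_1)$ and $(a_2, b_2)$ and whose axial length is $L_S$ is

$$V = \frac{\pi L_S}{6}\left(2a_1b_1 + a_2b_1 + a_1b_2 + 2a_2b_2\right),$$

which is the exact integral of the cross-sectional area
$\pi\,a(t)\,b(t)$ when both semi-axes vary linearly along the segment; the
test suite checks this against Simpson quadrature, which is exact for the
quadratic integrand and therefore an independent oracle. The end cones use
$V = \pi L_S a b / 3$. Because lengths are taped along the animal's
curved surface, the axial length of each segment is recovered as
$L_S = \sqrt{L_C^2 - (r_1 - r_2)^2}$ from the curvilinear length $L_C$ and
the radius difference at the two ends.

**One axial length for all shells.** Tissue boundaries are generated by
eroding the outer surface inward (skin depth off both semi-axes for the
skin boundary; lateral sculp depth off $a$ and dorsal sculp depth off $b$
for the blubber--muscle boundary, matching where the probes sit). The
straight segment lengths are computed once, from the outer surface, and
reused for every concentric shell: the body axis does not move when a
boundary is eroded, and recomputing lengths per shell would make the three
volumes geometrically inconsistent. This choice also makes the synthetic
generator's forward model exactly invertible.

**Shells.** With $V_{\text{outer}}$, $V_{-\text{skin}}$ and
$V_{\text{inner}}$ the volumes inside the three surfaces,
$V_{\text{skin}} = V_{\text{outer}} - V_{-\text{skin}}$,
$V_{\text{blubber}} = V_{-\text{skin}} - V_{\text{inner}}$ and
$V_{\text{core}} = V_{\text{inner}}$; additivity is exact by construction.
At the ears and ankles (no ultrasound) the inner boundary coincides with
the skin boundary, so blubber tapers to zero beyond the instrumented
sites and the end cones hold skin and core only. Degenerate draws are
handled deterministically: an eroded semi-axis is clamped at zero with a
warning (so extreme Monte Carlo draws survive rather than abort), and the
inner boundary is never allowed outside the skin boundary, which keeps all
shells non-negative even when a noisy sculp reading is shallower than the
skin depth.

**Traditional vs modified.** The traditional estimator is circular,
trunk-only (pelvis to neck), subtracts the mean of the available sculp
depths from the radius, treats the whole sculp as blubber at
0.94 g/mL and 90.3% fat. The modified estimator is elliptical, nose to
tail, separates a skin shell of uniform depth 1.32 cm, and uses newly
measured tissue properties: blubber 0.89 ± 0.03 g/mL with fat fraction
0.853 ± 0.026 (early molt) or 0.823 ± 0.031 (late molt), skin
1.17 ± 0.13 g/mL with fat fraction 0.161 ± 0.007. All of these ship as a
YAML-backed `tissue_properties()` object so other species or phases can be
swapped in. "Proportion adipose" from the cones side is blubber mass over
total mass -- skin is not adipose tissue -- while the dilution side
estimates whole-body adipose, so the two are reported side by side rather
than conflated.

Skin density can also be derived from a blubber-plus-skin biopsy core via
the two-layer mass balance
$\rho_D = \rho_T + (\rho_T - \rho_B)(d_T - d_D)/d_D$
(`skin_density_from_core()`).

## Labeled water

The injectate stock is too hot to count directly, so standards dilute a
small aliquot (about 0.01 mL) into roughly a litre of water; each
replicate count is scaled back by its dilution factor and the stock's
specific activity is summarised as a normal distribution over replicates.
TBW follows from tracer conservation,
$\mathrm{TBW} = \mathrm{CPM}_{\text{inj}} / (\mathrm{CPM\,mL}^{-1}_{\text{eq}} - \mathrm{CPM\,mL}^{-1}_{\text{bg}})$,
with the injected activity taken as injected mass times stock activity at
1 g/mL for the saline (the syringe is weighed, not pipetted, and the
mass-to-volume convention is ours since none is stated in the field
protocol). Proportion water is TBW over body mass at 1 g/mL.

Three conversions from proportion water to composition are provided:

* **Heteroscedastic logit.** With water ratio $x = P_{H_2O}/(1-P_{H_2O})$,
  $\mathrm{logit}(P_{fat}) = \alpha_0 + \alpha_1 x + x\varepsilon$,
  $\varepsilon \sim N(0, \sigma^2)$. The inverse logit bounds fat strictly
  inside (0, 1), and the residual scaled by $x$ lets error expand at higher
  water ratios. The sign of $\alpha_1$ is deliberately not hard-coded: the
  printed magnitude (0.86 ± 0.14, intercept −1.6 ± 0.16) is accompanied in
  its source by a verbal description of a curve that *decreases* and
  asymptotes to zero, which requires $\alpha_1 < 0$ under this
  parameterization. `fit_logit_water_fat()` lets the data set the sign;
  the synthetic generator's default is $\alpha_1 = -0.86$ (decreasing, the
  printed magnitude). Predictive draws add $x\varepsilon$ on top of the
  joint parameter posterior, controlled by a flag.
* **Linear rule.** $P_{fat} = 1 - 1.37\,P_{H_2O}$. Negative outputs above
  $P_{H_2O} = 1/1.37 \approx 0.73$ are flagged, never clamped, so the
  divergence between the linear and logit rules at high water content
  stays visible.
* **Tissue-water bookkeeping.** With water fractions $w_A$ (adipose) and
  $w_L$ (lean, $w_L > w_A$) and fat fraction $f_A$ of adipose tissue,
  proportion adipose interpolates linearly between the all-lean and
  all-adipose limits after the dilution-vs-desiccation bias adjustment
  (0.967): $P_{adip} = (w_L - 0.967\,P_{H_2O})/(w_L - w_A)$,
  $P_{fat} = P_{adip} f_A$. The classical parameter values live in
  supplementary material we do not ship; the defaults
  ($w_A = 0.144$, $w_L = 0.732$ -- the classical lean-tissue hydration
  constant -- and $f_A = 0.90$, each with a small SD, beta-matched when
  uncertainty is requested) are documented synthetic stand-ins, and the
  operation is generic in its parameters.

## Bayesian calibration by Metropolis-within-Gibbs

Three regressions calibrate the pipelines: a simple linear model relating
traditional to modified blubber volume; an instrument calibration with one
slope shared across body sites and site-specific intercepts, mapping
non-imaging ultrasound depths to image-equivalent depths; and the logit
water-to-fat curve above. All are fitted by one-parameter-at-a-time
Gaussian random-walk Metropolis with uniform priors on every parameter and
a uniform prior on the *inverse* variance. The reference program that
originally fitted these models is not available, so equivalence is claimed
distributionally, not bitwise: with flat priors the posterior means must
match least squares (checked within two Monte Carlo standard errors), 95%
intervals must cover generating parameters at close to the nominal rate in
simulation, and the slope--intercept posterior correlation must carry the
analytic negative sign when $\bar{x} > 0$.

Numerical choices: prior bounds are centred on the least-squares solution
with half-width `prior_scale` (default 100) times the larger of the
estimate's magnitude and its standard error -- wide enough to be
effectively flat, finite so that the uniform prior is proper. The
precision upper bound sits four orders of magnitude above the
least-squares precision so that noiseless data can push $\sigma^2$ toward
zero (the exact-fit limit is a test). Proposal step sizes adapt toward a
0.3--0.5 acceptance rate in 50-iteration windows during burn-in only, then
freeze, keeping the kept draws a valid Markov chain. Chains start from the
least-squares solution, with later chains jittered. Draws are thinned
(default every 5th) because single-site random walks on correlated
coefficients mix slowly; diagnostics report lag-1 autocorrelation per
chain per parameter (a constant chain scores 1, i.e. stuck) and the
largest between-chain mean gap in pooled posterior-SD units, with
thresholds 0.5 and 0.2.

## Uncertainty propagation and sensitivity

`propagate()` pushes joint draws of all declared inputs through an
estimator: normal for tape measurements, lognormal for ultrasound depth
readings (strictly positive, multiplicative error; parameters are the mean
and SD of the log readings, and zero readings are rejected before
fitting), beta (moment-matched) for proportions, plus point masses and a
uniform index family that lets an estimator address rows of a joint
posterior-draw table -- how the water-to-fat conversion's correlated
$(\alpha_0, \alpha_1)$ pair enters the dilution pipeline without being
torn apart. The replicate structure (three observers) is deliberately
flattened to independent values when building distributions, mirroring the
small-sample practice of the field study; a hierarchical decomposition is
a possible extension but is off by default. Draws on which an estimator
fails are excluded and counted, and more than 1% failures aborts the run.

`sensitivity_oat()` varies one input over its distribution while pinning
every other input at its mean and records the output SD per input -- the
one-at-a-time design, not a variance-based (Sobol) analysis. For linear
estimators the per-input SDs recover the coefficients and their squares
sum to the joint variance; both are tests.

## The synthetic generator

`seal_truth()` defines a piecewise-frustum body -- deliberately inside the
estimator's model class -- with nested outer/skin/blubber surfaces,
tissue densities and fat fractions, from which exact volumes, masses, and
TBW (via $w_A$, $w_L$) follow. The default body is sized to a molting
adult female elephant seal: roughly 400 kg, about 385 L, sculp depths of
6--9 cm, around a third of body mass in the sculp, proportion water near
0.53. `make_seal()` emits triplicate observer measurements (additive
normal noise on tapes, default SDs 0.5--1.5 cm; multiplicative lognormal
on ultrasound, log-SD 0.06); curvilinear stations are constructed from the
axial geometry so that at zero noise the whole modified pipeline recovers
the truth to machine precision -- the model-closure test. `make_dilution()`
inverts the tracer arithmetic (equilibrium concentration equals injected
activity over TBW plus background) with a count-level coefficient of
variation, and `make_regression()` draws datasets exactly under each
regression's likelihood, including the $x$-scaled logit residuals.

What passing these tests does *not* show: real seals are not piecewise
frusta (an optional check against smooth bodies would probe model error,
not estimator correctness), skin depth varies over the body while the
model holds it uniform, fat slumping under gravity is not simulated, and
gut water or hydration state can bias TBW low-level inputs in ways no
synthetic experiment here represents. The generator validates the
arithmetic and the statistics, not the anatomy.

## Problem sizes and defaults used in checks

The shipped checks run at the study's scale: 14 animals for the volume
comparison; 13 seals with 3 replicate depths per site and residual SD
0.05 cm for the ultrasound calibration; 9 carcass points for the
water-to-fat curve; Monte Carlo at N = 15,000 draws; calibration coverage
at 100 seeded datasets per model with 2 chains of 1,000 kept draws each
(burn-in 800, thinning 4). Larger chains sharpen the diagnostics but do
not change any conclusion; these sizes are the package's chosen balance of
precision against runtime.

## Known limitations

* Uniform skin depth; the study itself flags within-body variation as
  future work.
* No girth-to-ellipse perimeter inversion: elliptical mode requires
  heights and widths, and the generator's girths (Ramanujan perimeter) are
  consumed only by the circular mode.
* The intercept units of the ultrasound calibration table are taken as cm;
  the source does not state them.
* Single-site random-walk sampling is robust but slow-mixing for highly
  correlated coefficients; thinning and the diagnostics make this visible
  rather than hiding it.
* The tissue-water conversion's default beta parameters are stand-ins (see
  above), clearly labelled, and meant to be replaced from a config when
  the measured values are at hand.
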