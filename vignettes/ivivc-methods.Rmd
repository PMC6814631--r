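---
title: "Level A IVIVC for extended-release formulations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Level A IVIVC for extended-release formulations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A level A in vitro–in vivo correlation (IVIVC) is a point-to-point map
between the cumulative fraction of drug *dissolved* in a standardized in
vitro test and the cumulative fraction *absorbed* in vivo.  Once validated,
it lets a dissolution test stand in for a bioavailability study: the plasma
concentration profile of a modified formulation can be predicted by
convolution instead of being measured in volunteers.  `ivivcr` implements
the complete two-stage workflow for extended-release (ER) oral
formulations studied against an immediate-release (IR) reference in a
single-dose crossover design, together with a synthetic study generator so
that every stage can be exercised against known ground truth.

## The models

**Dissolution (stage 0).**  Cumulative fraction dissolved is fitted per
formulation by unweighted least squares to either a Hill curve
$$F_\mathrm{diss}(t) = \frac{F_\mathrm{inf}\,t^b}{\mathrm{MDT}^b + t^b}$$
or a Weibull curve
$$F_\mathrm{diss}(t) = F_\mathrm{inf}\left(1 - e^{-(t/\mathrm{MDT})^b}\right),$$
with $F_\mathrm{inf}$ fixed to 1 by default (complete release; a switch
frees it).  MDT is the mean dissolution time in hours — the 50% release
time for the Hill curve and the 63.2% release time for the Weibull — and
$b$ a dimensionless slope factor.  The family is selected by the
least-squares AIC, $n\log(\mathrm{SSE}/n) + 2k$; ties go to the Weibull.
Profile similarity uses the regulatory $f_2$ factor with the conventional
truncation one point past 85% reference dissolution and exclusion of
$t = 0$.

**Unit impulse response (stage 1).**  Each subject's IR profile is fitted
with an $n$-exponential disposition model plus first-order absorption and a
lag,
$$C(t) = \sum_{i=1}^{n} A_i\left[e^{-\alpha_i (t - t_\mathrm{lag})} -
e^{-k_a (t - t_\mathrm{lag})}\right],\qquad n \le 3,$$
by unweighted least squares, selecting $n$ by AIC.  The absorption rate is
then *stripped*: the stored unit impulse response (UIR)
$$U(t) = \sum_i \frac{A_i}{D_\mathrm{ref}}\, e^{-\alpha_i t}$$
is the disposition-only response to an instantaneous unit-mass input and
serves as the convolution kernel.  Everything downstream is therefore
*relative to the IR formulation*.

**Deconvolution (stage 2).**  For each ER arm the cumulative amount
absorbed is estimated by numerically inverting $C = U * r$ (input rate
$r$).  The rate is parameterized on the sampling grid and solved by
nonnegative least squares, which makes the cumulative fraction absorbed
$F_a$ nondecreasing by construction.  Because the kernel is a sum of
exponentials the convolution operator has closed-form entries, so
convolution and deconvolution are exact adjoints and a noiseless
round trip closes to solver precision.

**Correlation (stage 3).**  The level A relation is the nonlinear Emax
time scaling with intercept,
$$T_\mathrm{vitro} = \frac{A_1\,T_\mathrm{vivo}}{A_2 + T_\mathrm{vivo}} - B_2,
\qquad F_a(t) \approx F_\mathrm{diss}\big(\max(0,\ T_\mathrm{vitro}(t))\big),$$
with one common $(A_1, A_2, B_2)$ for all formulations and *no*
absorption-scale factor.  Negative mapped times are clamped to zero — the
$B_2$ intercept makes early in vivo times map before the in vitro clock
starts, where nothing has dissolved; this is the only self-consistent
reading.  The asymptotic in vitro time is $A_1 - B_2$ and the absorption
onset is at $T_\mathrm{vivo} = A_2 B_2/(A_1 - B_2)$.  Conventional linear
alternatives (absorption scale, time scale, time shift) are provided for
comparison; on data generated with a nonlinear time scale they
systematically under-predict Cmax.

**Prediction and validation (stage 4).**  For every formulation the fitted
correlation converts its dissolution curve into a predicted $F_a$, which is
convolved with each subject's own UIR to give individual predicted plasma
profiles.  Observed and predicted Cmax, AUClast and AUCinf are computed by
noncompartmental analysis on the same sampling grid, summarized as
geometric means across subjects, and compared by the percent prediction
error $\%PE = 100\,(\mathrm{pred} - \mathrm{obs})/\mathrm{obs}$.  The
FDA/EMA rules are applied: internally, average $|\%PE| \le 10\%$ for Cmax
and AUCinf and every individual formulation $\le 15\%$; externally,
$|\%PE| \le 10\%$.  Leave-one-out cross-validation refits the correlation
with each ER formulation held out and validates it externally.

## Numerical design choices

Several choices were genuinely open; this section records what the package
does and why.

**Deconvolution basis.**  The classic point-area scheme (piecewise-constant
rate per interval) is provided (`basis = "step"`), but the default is a
*continuous piecewise-linear* rate with the rate pinned to 0 at $t = 0$.
On the sparse late sampling times of a 72-h study the staircase carries a
first-order discretization bias in the cumulative input (about $-2\%$ at
the plateau under the default design, which propagates to roughly 10%
biases in $A_2$ and $B_2$); the linear basis is second-order and reduces
this by an order of magnitude.  Both bases use closed-form operator
entries and are exact adjoints of the matching convolution.

**Stage-2 fitting span.**  The correlation is fitted over grid times up to
the span of the in vitro dissolution data (24 h by default).  Beyond the
mapped asymptote both the dissolution curve and the deconvolved tail are
extrapolations, and the late deconvolution nodes are the least reliable;
including them mostly injects tail noise into $A_1 - B_2$.  The span is a
control (`ivivc_control(time_limit = )`).

**Operator-consistent bias correction.**  Even the linear basis leaves a
small systematic discretization bias.  After the plain stage-2 fit, the
pipeline applies an indirect-inference correction: for the fitted
constants, noiseless model curves are pushed through *exactly* the
operator chain applied to the data (fine-grid convolution with every
subject's UIR, then the same nonnegative-least-squares deconvolution),
the plain objective is refitted to those filtered curves, and the
estimated mapping bias is subtracted, solving $b(p) = \hat p$ by fixed
point.  The correction is a smooth deterministic function of the plain
estimate — it does not re-match the noisy data, so it adds essentially no
variance — and on noiseless data the pipeline then recovers the
generating constants to better than 0.2%.  The fine grid is made very
dense around the absorption onset, where the input rate rises with
unbounded curvature.  Disable with `ivivc_control(refine = FALSE)`.

**UIR identifiability guards.**  The stripped kernel's scale and tail drive
every deconvolution, and three degeneracies can wreck them while fitting
the concentrations perfectly well: $k_a$ drifting onto a disposition rate
(the $A_i/(k_a - \alpha_i)$ cancellation inflates the kernel), absorption
becoming effectively instantaneous (the kernel collapses onto the raw oral
curve), and spurious very slow or very fast exponentials.  The fit
therefore (i) anchors the slowest exponential to the terminal log-linear
regression (slope and intercept bands of ±10% and ±15% — the tail of an
oral curve *is* the stripped kernel's slow term, and log-scale regression
estimates it far more reliably than absolute-scale least squares under
proportional error); (ii) screens candidates by the implied self-absorption
fraction $\phi = 1 - (\sum A_i/k_a)/(\sum A_i/\alpha_i)$, which must lie in
(0.55, 0.97); and (iii) floors disposition rates at $0.35/t_\mathrm{last}$
and caps them at $2/t_\mathrm{first}$, with $k_a \le 20$/h.  The
exponential order is selected by AIC on *unconstrained* fits (the anchor
restricts the parameter space unevenly across orders) while the kernel
itself comes from the anchored fit of the winning order.  If no candidate
is physical, the least implausible adequate fit is kept with a warning.

**Optimizer conventions.**  All nonlinear fits use Levenberg–Marquardt
least squares on log-transformed positive parameters with multi-start
ladders: dissolution starts from the interpolated characteristic release
time and $b \in \{0.5, 1, 2\}$; the UIR from curve stripping crossed with
an absorption-rate grid; the Emax constants from the two conventional
start sets $(15, 5, 8)$ and $(16, 6, 10)$ h plus grid perturbations.  For
model selection on noiseless data, the SSE entering the AIC is floored at
$(10^{-8}\times$ data scale$)^2$ per point so that parsimony, not the
vagaries of machine-zero residuals, decides.

**NCA conventions.**  $\lambda_z$ uses the best adjusted-$R^2$ window among
all suffixes of at least 3 points strictly after Tmax, preferring more
points on ties (within $10^{-4}$); AUC is linear trapezoidal;
AUCinf extrapolates with the observed last concentration.  Samples below
the LLOQ are flagged, never dropped: leading BLQ values count as zero,
embedded and trailing ones are excluded.  Cmax/Tmax/AUClast are reported
for any profile with a quantifiable point; the terminal parameters are
`NA` when no valid slope exists.

## The synthetic study generator

`study_spec()`/`simulate_study()` emulate the study design this
methodology targets: N = 20 healthy subjects in a five-period crossover, a
24-mg IR reference and four 30-mg ER formulations with 10/15/20/35%
release-controlling polymer, plasma sampled at 0–72 h (17 times), in vitro
dissolution at 0–24 h (11 times), LLOQ 0.05 ng/mL.  Formulation Weibull
MDTs (4.04, 5.38, 6.73, 10.76 h at $b = 1.2$) order the release to reach
80% dissolved near 6/8/10/16 h.  The true time scale defaults to
$(A_1, A_2, B_2) = (11.6, 2.66, 3.49)$ h.  Disposition is two-compartment
(CL 47 L/h, V1 110 L, Q 15 L/h, V2 170 L, $k_a$ 3.25/h), chosen so the IR
arm reproduces the reference summary statistics of such a study — Cmax
near 150 ng/mL, Tmax under 1 h, AUC about 510 ng·h/mL, terminal half-life
10–11 h — with about 30% of the kernel AUC in the terminal phase and a
stripped-kernel inflation of ~1.16 (so ER/IR exposure ratios land near
1.1).  Between-subject variability is lognormal with 25% CV on every
parameter; residual error is 10% proportional, truncated at zero.
Formulation-level relative bioavailability defaults to 1: the correlation
model carries no absorption-scale factor, so unit relative F is the
condition under which parameter recovery is well-posed (it is a spec
field, `rel_f`, for sensitivity work).

The generator composes in vivo absorption exactly as the correlation
assumes — the dissolution curve warped by the Emax map — and convolves it
with the same absorption-stripped kernel convention the UIR fit stores, so
the noiseless pipeline is exactly self-consistent.  A two-stage absorption
mode (`absorption = "two_stage"`, fast until a 4.5-h change point, slower
after) provides a model-misspecification stress test.

What passing tests on this generator do *not* show: real dissolution assays
drift and real absorption is not an exact warp of an in vitro curve; real
disposition is not exactly biexponential; BLQ censoring here is almost
inactive.  Recovery results on the generator are a necessary, not a
sufficient, indication of field performance.

## Problem sizes used by the test suite

The packaged tests run the full pipeline at the design size (20 subjects)
for the parameter-recovery checks, and at 1–8 subjects for structural and
layout checks; model-selection consistency uses 50–100 simulated
replicates per case.  A full 20-subject pipeline run takes a few seconds.

## Known limitations

* The deconvolution grid defaults to the observation times; super-resolved
  grids are rejected as underdetermined rather than regularized (the
  second-difference smoothing penalty is available but off by default).
* Stage-2 fitting uses the per-formulation mean absorption profile;
  per-subject fitting is available (`per_subject = TRUE`) but the reported
  standard errors always come from the pooled Gauss–Newton approximation.
* The strip-Ka convention assumes truly first-order absorption from the
  reference; subjects violating it are caught only insofar as the
  physicality screens fire.
* About one synthetic study in ten at the default noise level fails the
  internal 10% average rule — a reminder that the FDA criteria test the
  study as much as the model.
* No in vivo cutoff-time (t_cutoff) linear variant is implemented; the
  nonlinear map is the supported route to nonlinearity.
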