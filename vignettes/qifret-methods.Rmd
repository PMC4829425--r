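---
title: "Quantitative imaging FRET: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative imaging FRET: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qifret)
```

## The measurement problem

Receptor tyrosine kinases signal by lateral dimerization in the plasma
membrane, and the strength of that dimerization is a two-dimensional
equilibrium: it depends on receptor surface density, not bulk concentration.
Quantitative imaging FRET (QI-FRET) measures it by imaging individual
plasma-membrane-derived vesicles in three channels — donor, acceptor, and a
"FRET" channel (donor excitation, acceptor emission) — and converting the
per-vesicle intensities into donor and acceptor surface concentrations plus a
FRET efficiency. Scanning expression levels across hundreds of vesicles
traces out the dimerization curve, from which a two-dimensional dissociation
constant, a dimerization free energy, and a structural parameter (the
Intrinsic FRET of the dimer) are extracted.

`qifret` implements the full chain: calibration, per-vesicle quantification,
stochastic ("proximity") FRET correction, equilibrium or constitutive-dimer
inference, image-based intensity extraction, and a synthetic-data generator
with known ground truth so every stage can be validated by parameter
recovery.

## From intensities to concentrations and efficiency

Five calibration constants link raw intensities to physical quantities: the
channel scale factors $i_D$, $i_A$ (intensity per receptor $\mu m^{-2}$,
from through-origin regressions on solution standards of known
concentration), the bleed-through coefficients $\beta_D$, $\beta_A$
(fractions of donor and directly excited acceptor signal leaking into the
FRET channel, from single-fluorophore samples), and the gauge factor $G_F$,
which converts sensitized acceptor emission into the equivalent lost donor
intensity. $G_F$ is derived from a construct in which every donor is linked
to one acceptor with known efficiency $E$: since the reconstructed donor
intensity must be $I_D/(1-E)$, $G_F$ is the through-origin slope of
$I_D\,E/(1-E)$ on the sensitized emission. The linked construct's efficiency
is an explicit input rather than a hard-coded constant, because it is a
property of the standard, not of the instrument.

Per vesicle,
$$C_A = I_A/i_A,\qquad
  I_{SEN} = I_{FRET} - \beta_A I_A - \beta_D I_D,\qquad
  I_{D,corr} = I_D + G_F\, I_{SEN},$$
$$C_D = I_{D,corr}/i_D,\qquad E = 1 - I_D/I_{D,corr},$$
with $T = C_D + C_A$ and acceptor fraction $x_A = C_A/T$.

The $I_{SEN}$ subtraction can go slightly negative from noise when a vesicle
has little FRET. Values within $3\sigma_{bg}$ of zero are clipped to zero;
values below $-3\sigma_{bg}$ are flagged and excluded from fitting. By
default $\sigma_{bg}$ is estimated from the negative tail of the observed
$I_{SEN}$ distribution (a reflected half-normal estimate,
$\sqrt{\mathrm{mean}(I_{SEN}^2\,|\,I_{SEN}<0)}$): a fixed strict cut at zero
would discard about half of all genuinely FRET-free vesicles and bias the
subsequent fit toward stronger dimerization. Intensities are assumed
background-free; background removal belongs to the imaging stage.

## Proximity FRET

Even non-interacting donors and acceptors confined to a membrane transfer
energy when they pass within roughly 100 Å of each other. This stochastic
background must be subtracted before any interaction can be inferred. The
package estimates it by Monte Carlo: each simulated donor sees acceptors
from a homogeneous spatial Poisson process at the vesicle's acceptor
density, restricted to an annulus between an exclusion radius (default 10 Å,
a hard-core minimum approach for two fluorescent-protein barrels) and a
cutoff (default 300 Å, where a single pair contributes $<3\times10^{-5}$
efficiency at $R_0 = 53.1$ Å). The per-donor efficiency is $S/(1+S)$ with
$S=\sum_j (R_0/r_j)^6$, the kinetic superposition of transfer rates; donors
do not quench each other, so each donor is the origin of its own acceptor
field and donor density never enters.

The curve is tabulated on a density grid (default 0–2000 receptors
$\mu m^{-2}$, $10^4$ donors and 5 replicates per point, one seed per grid
point) and linearly interpolated. Monte-Carlo jitter is removed by isotonic
regression, so the stored curve is non-decreasing as the physics requires;
linear interpolation preserves that monotonicity. The correction is a plain
subtraction of the curve at each vesicle's own $C_A$:
$E_D = \max(0,\,E - E_{prox}(C_A))$, with records falling below the
stochastic floor by more than a tolerance (default 0.05) flagged rather than
silently clipped. Subtraction is applied in full, not weighted by the
monomeric fraction: such a weighting would require the dimeric fraction,
which is only known after the fit the correction feeds — making the
correction circular — and for the dilute-to-moderate densities of interest
the difference is well inside the per-vesicle noise.

The exclusion radius and cutoff are honest defaults, not claimed matches to
any particular published curve; both are configurable and recorded in the
curve's serialization.

## The monomer–dimer model

Mass action in two dimensions with association constant $K$ gives the
dimeric fraction at total concentration $T$:
$$f_D(T;K) = \frac{1}{T}\Bigl(T - \frac{\sqrt{1+8TK}-1}{4K}\Bigr)
           = 1 - \frac{2}{1+\sqrt{1+8TK}},$$
where the second form is algebraically identical but numerically stable at
small $TK$ (no cancellation) and exact at $T=0$. A dimer containing a donor
and an acceptor transfers with the Intrinsic FRET $\tilde E$, a purely
structural parameter, so the corrected efficiency normalized by the acceptor
fraction satisfies $E_D/x_A = f_D(T;K)\,\tilde E$.

The fit minimizes the unweighted sum of squares of $E_D/x_A$ residuals over
usable vesicles, with $K$ parameterized as $\log K$ (positivity) and
$\tilde E$ box-constrained to $(0,1)$, starting from a coarse profile over
$\log K$ with $\tilde E$ profiled analytically at each grid value. Standard
errors come from the Hessian of the sum of squares at the optimum with
residual variance $SSR/(n-2)$; 67% confidence intervals are $\pm1$ standard
error, applied on the log scale for $K_{diss} = 1/K$ (hence mildly
asymmetric, as for any positive parameter). At least 10 usable vesicles and
3 distinct concentrations are required; data with no concentration
dependence drive $K$ to its bound and trigger a warning pointing to the
constitutive analysis.

The free energy uses a standard state of one receptor per nm$^2$:
$$\Delta G = -RT\,\ln(10^6/K_{diss}),$$
with $RT = 0.596$ kcal mol$^{-1}$ ($T = 300$ K) as the default thermal
energy; it is configurable, and $\Delta G$ is exactly linear in $\log K$, so
its standard error is $RT\cdot se(\log K)$. Distances between the
fluorescent proteins in the dimer come from the Förster relation
$d = R_0((1-\tilde E)/\tilde E)^{1/6}$ with $R_0 = 53.1$ Å for the
YFP/mCherry pair, under the assumption of free fluorophore rotation;
orientation effects are not modeled. Report formatting follows the field's
convention of one decimal for $\Delta G$, and one decimal below 50 Å /
nearest Å above.

## Constitutive dimers and mode selection

Saturating ligand (or an activating mutation) can drive a receptor fully
dimeric across the whole observed range. Then $f_D \equiv 1$ and each
vesicle reports the Intrinsic FRET directly as $\tilde E = E_D/x_A$. The
package histograms the per-vesicle values (default bin width 0.02) and fits
a single Gaussian by least squares; the center is the population
$\tilde E$, and both the Gaussian $\sigma$ and the standard error of the
mean are reported, since either can be quoted as the uncertainty. Vesicles
with $x_A$ outside $[0.05, 0.95]$ are excluded — dividing by an extreme
acceptor fraction amplifies noise disproportionately. A secondary histogram
mode above 50% of the main peak (measured on a lightly smoothed histogram,
and only when separated by a genuine valley) triggers a multimodality
warning rather than a silent unimodal fit.

The two regimes are distinguished by regressing $E_D/x_A$ on $\log_{10} T$:
a slope significantly different from zero (default $\alpha = 0.05$) implies
a concentration-dependent equilibrium; otherwise the population is treated
as constitutively dimeric. With fewer than 10 usable vesicles or less than
half a decade of spread in $T$, the test reports "undecidable" instead of
guessing. The pipeline's auto mode branches on this decision and, when the
p-value is within a factor of two of $\alpha$, retains both analyses.

## The synthetic generator

The generator emulates a measurement campaign: total concentrations drawn
log-uniform over 1–1000 receptors $\mu m^{-2}$ (transient transfection
covers about three decades), acceptor fractions uniform on $[0.2, 0.8]$
(co-transfection scatters the donor:acceptor ratio broadly), 300 vesicles
per campaign (200–500 is typical for a construct). Per vesicle it computes
$f_D$ from mass action (or sets $f_D = 1$ in constitutive mode), forms
$E_D = f_D x_A \tilde E$, optionally adds the proximity background at the
vesicle's $C_A$, inverts the quantification equations with a ground-truth
calibration into raw intensities, and applies noise: additive Gaussian on
the efficiency ($\sigma_E = 0.05$ by default, the per-vesicle scatter seen
in single-vesicle FRET) plus multiplicative lognormal on each intensity
($\sigma_{rel} = 0.02$, shot and quantification noise). Efficiency draws
landing outside $[0,1)$ are resampled rather than clipped, so the emitted
table never contains impossible efficiencies and carries no point mass at
the boundary. Every generator takes an explicit seed and touches no global
state beyond `set.seed`; noisy output is always accompanied by a row-matched
noise-free truth table.

What the generator does *not* emulate: photobleaching and blinking,
vesicle-to-vesicle calibration drift, clustered (non-Poisson) bystander
distributions, and ligand-binding kinetics. Recovery tests on this generator
therefore validate the inference machinery, not those instrumental effects.

A consequence of the bounded support deserves emphasis. For vesicles whose
true efficiency is within $\sim\!2\sigma_E$ of zero (the lowest
concentrations), resampling truncates the noise distribution at zero and
shifts its mean upward — as does, more mildly, the zero-clipping of
$I_{SEN}$ in quantification. The unweighted least-squares fit then sees
slightly too much FRET at low $T$ and overestimates dimer stability: at the
default campaign scale ($K_{diss} = 35$, $\tilde E = 0.82$,
$\sigma_E = 0.05$) the recovered $\Delta G$ runs about 0.1–0.2 kcal
mol$^{-1}$ too negative, and because the fit's confidence intervals
(half-width $\approx 0.08$ kcal mol$^{-1}$ at $n = 300$) do not account for
this bias, their empirical coverage collapses well below the nominal 67%.
Feeding the same fit unbounded noise restores near-zero bias and $\sim$70%
coverage, which localizes the effect entirely in the bounded-support noise
model, not the estimator. At lower noise ($\sigma_E \le 0.02$) the bias is
negligible. Real measurements, whose corrected efficiencies can
legitimately scatter below zero, are not subject to this particular
truncation.

## Image quantification

Vesicles imaged at the equator appear as rings. The ring center is the
intensity-weighted centroid of above-background pixels (exact for a
symmetric ring), the radius is the peak of the 1-px-binned radial profile
with parabolic sub-bin refinement, and the center is polished by a local
grid search maximizing the on-ring mean. Detection fails on blank or
ringless images via a contrast threshold.

Membrane intensity is read from the averaged cross-membrane profile along
72 rays (sampled at 0.25 px by bilinear interpolation), after subtracting
the median intensity of an annulus outside the vesicle, and fitting a
Gaussian. The readout is the *integral* $A\sigma\sqrt{2\pi}$ rather than
the peak amplitude: defocus and interpolation blur trade amplitude against
width but conserve the area, so the integral stays proportional to
fluorophores per membrane area (bilinear sampling attenuates the fitted
amplitude by $\approx 2\%$ at a 2-px-wide membrane while the integral moves
by $\approx 0.1\%$). Non-convergent or high-residual fits flag the vesicle.
The geometry is strictly equatorial; out-of-plane membrane contributions
are not modeled.

## Problem sizes and numerical choices

The shipped tests and examples run at deliberately desk-friendly sizes:
$10^4$ donors and 5 replicates per proximity grid point (Monte-Carlo
standard errors $\sim10^{-4}$ on $E_{prox}$), 200–500 vesicles per
synthetic campaign, 20-seed recovery ensembles, and $121^2$-pixel synthetic
images — small enough that the whole suite completes in well under a
minute, large enough that every recovery tolerance is dominated by the
science, not the simulation. Ties and degeneracies are handled explicitly:
$f_D$ uses the cancellation-free algebraic form; the optimizer's
$\log K$-grid initialization makes the two-parameter fit deterministic;
`T_range` inputs are normalized to increasing order; empty histogram or
concentration bins are omitted, never zero-filled.

## Known limitations

* The proximity model is a transparent Monte-Carlo estimator with documented
  defaults; its exclusion radius and cutoff are plausible, not fitted to any
  published curve.
* Only monomer–dimer equilibria are modeled. Populations forming higher-order
  oligomers are expected to *fail* the fit (non-convergence or boundary
  diagnostics), which is the supported behavior, not an oversight.
* Unweighted least squares matches the conventional analysis but ignores the
  $1/x_A$ heteroscedasticity of the normalized response; confidence
  intervals are accordingly approximate.
* The bounded-support efficiency noise of the generator biases recovery at
  high noise levels, as quantified above.
* Distances assume free fluorophore rotation ($\kappa^2 = 2/3$ implicit in
  $R_0$); orientational constraints would shift them.
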