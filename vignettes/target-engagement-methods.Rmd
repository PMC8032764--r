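---
title: "Quantifying CNS target engagement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CNS target engagement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropkpd)
```

This package implements the quantitative chain by which a
receptor-subtype-selective CNS drug's target engagement is established, from
in vitro affinity through rodent ex vivo occupancy and human PET to a
pharmaco-EEG signature. Every stage has a synthetic-data generator with known
ground truth, so the whole chain is testable without access to subject-level
data. This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic studies do and do not demonstrate.

## Concentration–response and affinity

Binding and electrophysiology concentration–response data are described by
the four-parameter Hill equation

$$y = A + \frac{B - A}{1 + (C/x)^D},$$

where $x$ is the modulator concentration (nM), $A$ the response as
$x \to 0$, $B$ the asymptotic response, $C$ the midpoint (IC50/EC50) and $D$
the Hill coefficient. `fit_hill()` estimates the free parameters by least
squares; any subset can be fixed, covering the two constrained uses that
recur in practice: $A = 0$ for oocyte modulation curves (no modulation at
zero concentration) and $D = 1$ for exposure–occupancy curves (one binding
site, no cooperativity).

The equation is badly conditioned on the linear concentration scale, so the
optimizer works on $\log C$ with box constraints
($C \in [\min x/100,\ \max x \cdot 100]$, $D \in [0.1, 10]$), multi-starts
from three initial midpoints, and finishes with a damped Gauss–Newton polish
(quadratic convergence near the optimum, which is what makes noise-free
round trips exact to near machine precision). Replicates all enter the loss;
per-concentration means are used only for starting values. A flat response
carries no information about $C$ and is flagged non-converged rather than
returning an arbitrary estimate.

Competition-binding midpoints are converted to equilibrium inhibition
constants with the Cheng–Prusoff correction
$K_i = \mathrm{IC}_{50} / (1 + L/K_d)$ for radioligand concentration $L$ and
affinity $K_d$. Subtype selectivity is summarized as
$K_i^{(s)}/K_i^{(\mathrm{ref})}$ ratios; a "no binding above $X$"
observation enters as a censored lower bound $X/K_i^{(\mathrm{ref})}$ rather
than being dropped, because it is the bound, not the point estimate, that
supports a selectivity claim.

## Rat ex vivo occupancy

Autoradiography signals mix three components: target-specific binding,
binding to off-target receptor subtypes (the radioligand is selective but
not perfectly so), and classical nonspecific binding. The latter two are
estimated jointly from a cohort given a saturating dose of a selective
blocker; `specific_binding()` subtracts the blocker-group regional mean from
every animal, and occupancy is the fractional loss of specific binding
relative to the vehicle group:

$$y = 100\,\bigl(1 - S_{\mathrm{drug}}/\bar S_{\mathrm{vehicle}}\bigr).$$

Negative $S$ values (possible under noise) are kept and flagged, and
occupancies are returned unclipped — clipping would bias the downstream
fit. The exposure–occupancy relation is fitted per animal against plasma
concentration with the Hill equation, $A = 0$ and $D = 1$ fixed, asymptote
$B$ free: with a partially selective radioligand the apparent plateau sits
below 100%, and `rescale_to_asymptote` (default on for the rat arm)
re-expresses occupancancies as a fraction of that plateau, treating it as
100% of the drug-accessible sites. Total plasma converts to free molar
exposure as $\mathrm{nM} = \mathrm{ng/mL} \times 1000 / \mathrm{MW} \times
f_u$; the molecular weight (445.469 g/mol) and free fractions (14% rat,
5.5% primate) are explicit inputs, not constants buried in code, because
published free-concentration pairs are not always exactly consistent with a
single free fraction.

The cohort generator draws per-animal plasma levels lognormally (CV 30%)
around dose-proportional medians of 12.7 ng/mL per mg/kg, chosen once so
that the top 100 mg/kg group sits near 70% occupancy when the EC50 is
544 ng/mL — the regime the rat study operated in. Measurement noise is
additive on the signal scale with SD 18 fmol/mg, i.e. about 6% of the
hippocampal specific density (304 fmol/mg over a 100 fmol/mg
non-displaceable plateau).

## Human PET: SRTM and occupancy

Regional time–activity curves (TACs) are analyzed with the simplified
reference tissue model,

$$C_T(t) = R_1 C_R(t) + \bigl(k_2 - R_1 k_{2a}\bigr)
\int_0^t C_R(u)\, e^{-k_{2a}(t-u)}\,du, \qquad
k_{2a} = \frac{k_2}{1 + BP_{ND}},$$

with the cerebellum as reference region. `srtm_fit_basis()` uses the
basis-function approach: for each candidate $k_{2a} = \theta$ on a
logarithmic grid (100 values in 0.006–0.6 min⁻¹) the convolution basis is
precomputed and the two remaining coefficients solved by weighted linear
least squares; the grid minimum is then polished by a continuous
one-dimensional search between its neighbours, so recovery on noise-free
data is limited only by floating point, not by grid resolution. Fits at the
grid boundary and negative $BP_{ND}$ are flagged, not silently accepted.
Frame weights default to frame duration, the usual count-statistics proxy.

Two numerical choices matter on the 26-frame 90-minute schedule (8×15 s,
3×60 s, 5×120 s, 5×300 s, 5×600 s). First, the continuous reference curve
is reconstructed from framed values as piecewise linear through frame
midpoints and the exponential convolution is integrated *exactly* on each
linear segment — naive rectangular discretization biases the late 600-s
frames. Second, the delivery term $R_1 C_R$ uses the observed framed
reference values directly (they are already frame averages), so a target
identical to its reference fits to exactly $R_1 = 1$, $BP_{ND} = 0$.
One genuine degeneracy deserves mention: when $k_2 = R_1 k_{2a}$ the basis
coefficient vanishes and $\theta$ is unidentifiable, although $R_1$ and
$BP_{ND}$ remain exact; the test suite avoids that line deliberately.

Occupancy is the fractional reduction of binding potential between paired
scans, $(BP^{\mathrm{base}}_{ND} - BP^{\mathrm{drug}}_{ND}) /
BP^{\mathrm{base}}_{ND}$, and the exposure–occupancy relation is fitted
with the Emax model $E = E_{\max} C / (EC_{50} + C)$. For fixed $EC_{50}$
the model is linear in $E_{\max}$, so the $EC_{50}$ profile likelihood is
computed exactly on a log grid and the 95% interval read off the usual
$F$-based cutoff; whether $E_{\max}$ is fixed at 100% is left configurable,
since near-complete occupancy at high exposure cannot distinguish the two.

The PET generator produces the reference TAC as a difference of
exponentials (bolus-like rise, slow washout), forward-simulates target
regions through the same SRTM machinery, scales $BP_{ND}$ by
$1 - \mathrm{occupancy}$ in the post-dose scan, and adds Gaussian frame
noise with SD $\propto 1/\sqrt{\text{frame duration}}$.

## Pharmaco-EEG

Resting EEG is transformed to power spectra on a log-frequency grid:
41 center frequencies $2^{1 + k/8}$, $k = 0..40$ (2–64 Hz in eighth-octave
steps), with Morlet wavelets of constant spectral quality
$f/\sigma_f = 5.83$ (half-octave smoothing; $\sigma_f$ is the
spectral-domain Gaussian SD and $\sigma_t = 1/(2\pi\sigma_f)$ — the only
reading under which the quality factor corresponds to half-octave spectral
smoothing). Power is the mean squared magnitude over 3/4-overlapping
windows of length $6\sigma_t$ whose samples are artifact-free, calibrated
as a one-sided spectral density and scaled by $f \ln 2$ into per-log2(Hz)
units, so white noise appears as density proportional to $f$.

Preprocessing is a 0.5 Hz high-pass (FIR, order $2 f_s$), a 49–51 Hz
Butterworth notch (order 4), both applied zero-phase (forward–backward,
realized in the frequency domain as the squared magnitude response), and
re-referencing to the average reference. Operator-dependent artifact
cleaning (visual inspection, ICA) is out of scope; in its place 1-s
segments whose peak-to-peak amplitude exceeds 150 µV on any channel are
excluded from spectral windowing. On artifact-controlled synthetic data
this stand-in is essentially inert, which is the point: the pipeline's
statistical behaviour is measured without an operator in the loop.

Each subject's spectra are aligned in log-frequency so that their
individual alpha peak (spectral maximum in 7–12 Hz, eyes-closed baseline;
boundary maxima flagged) lands on the group target of 9.3 Hz, then
normalized to unit total power ("relative power") and expressed as percent
change drug vs baseline. Alignment uses linear interpolation in
log2-frequency; bins shifted in from outside the grid are missing and are
excluded per-frequency from group statistics.

### Statistics

Frequency-resolved drug effects are tested with a cluster-based
randomization test: per-frequency paired $t$-tests, clusters formed from
contiguous frequencies with $p < 0.01$ and a common sign, and each observed
cluster's size referred to the permutation null distribution of the
*maximum* cluster size, which controls the family-wise error across the
grid. Because baseline and drug are within-subject, label randomization is
realized as sign flips of the paired differences; all $2^n$ patterns are
enumerated when that is cheaper than Monte-Carlo sampling. Cluster size
(count of grid frequencies) is the default statistic, with summed $|t|$
mass as an option. A caveat inherent to cluster-size statistics: they are
calibrated for spectrally smooth data like these half-octave-smoothed
spectra; on hypothetical white (unsmoothed) spectra the max-size null makes
the test very conservative.

Peak frequencies of effects are nonlinear group statistics, so their
standard errors come from jackknife pseudo-values
$p_i = n\hat\theta - (n-1)\hat\theta_{(-i)}$, with the peak localized on
the log2-frequency grid by parabolic interpolation between adjacent grid
points (effects need not sit on the grid). Two drugs' peak frequencies are
compared by a $t$-test on pseudo-values, paired by default. Spatial
topographies of effects are compared via the mean within-drug minus
between-drug cross-subject correlation, with a one-sided label-permutation
null.

### The EEG generator

Each subject's baseline power spectral density is
$s \cdot (f^{-\gamma} + a\,e^{-(\log_2 f - \log_2 p)^2 / 2\sigma_\alpha^2})$
with $\gamma = 1$, an alpha bump that is Gaussian in log2-frequency
($\sigma_\alpha = 0.2$ octaves — matching the pipeline's log-frequency
analysis) at a subject-specific peak $p \sim N(9.3, 0.87^2)$ Hz, and the
overall scale set for a realistic ~15 µV RMS. Drug effects multiply the
density by Gaussian-in-log2-frequency profiles with per-channel topography
weights. Recordings are realized by shaping the spectrum of white noise in
the frequency domain; a shared latent source with the channel-mean density
is mixed in (weight 0.3) to give cross-channel correlation. A fuller
latent-source model with per-source topographies was considered and
rejected: the topography test consumes subject × channel matrices directly,
so the extra machinery would add parameters without adding testable
behaviour. What the generator deliberately does *not* emulate: non-Gaussian
and nonstationary artifacts (muscle, blinks), line-noise harmonics, volume
conduction geometry, and 1/f knees — so passing recovery tests demonstrates
the pipeline's statistical correctness, not robustness to real-world
artifact structure.

## Problem sizes and reproducibility

All stochastic procedures accept explicit seeds, and the pipeline runner
derives a recorded per-stage sub-seed from the global seed by hashing the
stage name, so any stage reproduces identically in isolation. The test
suite and the acceptance script use desk-scale problem sizes chosen for
statistical adequacy: SRTM checks run on the full 26-frame schedule;
exposure–occupancy recovery uses 500 simulated cohorts (9 subjects for the
Emax arm, 4 animals per dose for the rat arm); EEG recovery uses 12
subjects at 2 channels × 64 s per condition across 100 repetitions, and
the cluster test's null calibration uses 500 synthetic spectra sets with
the pipeline's spectral smoothness. At these sizes the injected ±19%
effects are detected with near-certainty while the full battery completes
in minutes.

## Known limitations

- The Hill fitter does no global multi-curve fitting with shared
  parameters, and no Schild analysis.
- The SRTM implementation is the grid-search basis-function method;
  regularized basis-pursuit variants exist and can shrink noise-induced
  variance in $k_{2a}$, at the cost of a tuning parameter.
- EEG input is plain-text (CSV + JSON sidecar); there is no EDF reader in
  this implementation.
- The occupancy equation assumes the blocker cohort defines 100% blockade;
  if the blocker itself is partially selective the absolute occupancy scale
  inherits that bias (the rescale-to-asymptote option mitigates but cannot
  remove it).
- Alpha alignment shifts each subject's whole spectrum; a drug effect fixed
  in absolute frequency is therefore slightly smeared across subjects
  (≈0.14 octave SD), which is visible as a small low-frequency bias in
  recovered peak locations — within one grid step at the study's subject
  count.
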