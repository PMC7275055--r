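---
title: "Methods: smFRET trajectory simulation and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smFRET trajectory simulation and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`smfret` implements the trajectory-level analysis used to study the
conformational states of a dye-labelled E2~ubiquitin conjugate and the
RING-E3-catalysed transfer of its ubiquitin to substrate, observed one
molecule at a time by total internal reflection microscopy. Two experiment
types are covered:

* **equilibrium imaging** of a stable (isopeptide-linked) conjugate at
  100 ms per frame, which yields state populations, their Gaussian
  decomposition, rare interconversion statistics and donor-acceptor
  cross-correlation; and
* **real-time injection experiments** on the reactive (thioester-linked)
  conjugate at 1 s per frame, which yield per-molecule reaction /
  photobleach event calls, reacted fractions, dwell-time kinetics,
  per-initial-state rates and time-resolved population contours.

Because raw trace data for such experiments are rarely deposited, the
package pairs every analysis stage with a synthetic trajectory generator
whose ground truth labels make each stage testable end to end.

# FRET efficiency model

Apparent FRET efficiency is computed per frame from the raw donor
(`I_D`) and acceptor (`I_A`) intensities as

$$E = \frac{I_A}{I_D + \alpha I_A},$$

where `alpha = 0.88` corrects for the 12% bleed-through of donor emission
into the acceptor detection channel of a Cy3B / AlexaFluor 647 pair.
No gamma (detection-efficiency) or direct-excitation correction is
applied: the leakage term is the only calibration this analysis uses.
Frames with a non-positive corrected total are masked invalid rather than
propagated as infinities. The ratio is invariant under a common scaling
of both channels, which the tests assert as a property.

Distances map to efficiencies through the standard Förster relation
`E = 1 / (1 + (r/R0)^6)` with `R0 = 60` Å for this dye pair; the exact
inverse is provided and the two compose to identity to 1e-9.

**Averaging convention.** Population samples are one number per molecule:
the mean of `E` over the molecule's first ten valid frames. We compute
`E` per frame and then average, rather than averaging intensities first;
both conventions agree in the noise-free limit and differ negligibly at
the simulated noise level, but the per-frame convention is the
implemented default and `fret_samples()` documents it. Molecules with
fewer than ten valid frames contribute the mean of what they have;
molecules with fewer than three valid frames are dropped, since one- or
two-frame averages would inject high-variance samples into the
population. Histograms are normalised to unit area (asserted to 1e-9)
over a fixed support of [-0.1, 1.1] with 60 bins, wide enough to show
the sub-zero and above-one noise tails without clipping.

# Gaussian-mixture state decomposition

The population of per-molecule samples is decomposed into up to three
Gaussian components (low / intermediate / high FRET states) by
one-dimensional expectation-maximisation:

* initial means at evenly spaced sample quantiles, with 20 jittered
  restarts (seeded, caller's RNG untouched);
* component standard deviations floored at 0.01 so the likelihood cannot
  collapse onto a point mass;
* convergence at a log-likelihood improvement below 1e-6;
* the number of components chosen by BIC over k = 1..3 unless fixed.

Components are reported sorted by ascending mean and mapped to state
labels by that order; when BIC selects fewer than three components the
absent states are reported with zero weight rather than forcing k = 3.
A histogram-space least-squares fit (sum of bin-integrated Gaussians
fitted to the unit-area histogram) is also provided, since published
population fits are usually drawn over histograms; on synthetic data the
two routes agree and a test asserts it. The EM is written in-package;
an independent mixture implementation (`mclust`) serves as a
cross-check in the test suite only.

**Per-frame state assignment** uses the fitted means with a running
median (default width 5 frames), hysteresis and a minimum dwell: a label
change requires the smoothed efficiency to cross the midpoint between
the current and proposed component means, pushed 25% of the half-gap
into the new state's territory, and to stay there for at least 3 frames.
The initial label comes from the median of the first five smoothed
frames so a single noisy opening frame cannot seed a spurious
transition. These choices suppress noise flicker (false transition rate
about 0.1% of one-minute traces at the default noise) while localising
genuine switches to within about two frames.

# Event classification

In a real-time experiment each immobilised molecule ends in one of a
small set of signatures:

* **transfer**: the labelled ubiquitin leaves with the substrate, so
  donor and acceptor are lost *simultaneously* (within one frame at 1 s
  integration) with no subsequent recovery of either channel or of FRET;
* **acceptor photobleach**: the acceptor goes dark while the donor
  *rises* to its unquenched level in the same frame — the concomitant
  donor recovery is what distinguishes bleaching from reaction;
* **donor photobleach**: the donor goes dark; if the acceptor was still
  active it goes dark too (it was excited through FRET), which makes a
  FRET-pair donor bleach indistinguishable per molecule from a transfer.
  The published analysis separates these statistically through their
  dwell-time rates, and so does this package: donor bleaching is kept
  slow in the generator defaults, and the dwell fits report the rate
  mixture. Dual losses at or before the injection frame are classed as
  donor bleach, since no reagents are present yet;
* **donor-only molecules** (acceptor at background over the first five
  frames, from under-labelling or prior acceptor bleaching) that lose
  their donor are classed as donor-only transfers, matching how such
  molecules are counted in the reacted fractions.

Steps are found per channel as the single change point maximising the
two-segment mean-shift likelihood. A drop must land below background +
3 robust noise SDs (noise estimated from frame-to-frame differences) and
persist at least 3 frames; "no recovery" means no *sustained* (three or
more consecutive frames) return above threshold within the 10-frame
recovery window — a single Gaussian noise excursion above 3 SD is not
recovery. Conflicting signatures are flagged ambiguous and excluded from
rate fits. On labelled synthetic data at default noise the classifier
exceeds 95% accuracy with an ambiguous rate under 2%; the residual error
is dominated by the physically irreducible donor-bleach/transfer
degeneracy described above.

The dwell clock starts at the end of the injection frame; events at or
before it carry no dwell and are excluded from rate fits.

# Kinetics

Dwell-time distributions are binned at two frames per bin and fitted
with `A exp(-k t)` or a two-exponential sum by weighted nonlinear least
squares, each bin weighted by its inverse counting variance (error bars
of sqrt(count)); standard errors come from the fit covariance, and an
unbinned maximum-likelihood rate (1/mean) is reported as a cross-check.
Model choice between mono- and biexponential is by AIC when requested.
The degenerate all-equal-dwells case returns k = 1/mean with a warning
rather than failing. Per-initial-state reaction rates are summarised as
box-plot statistics (median, quartiles, extremes) of the per-molecule
rates 1/dwell, grouped by the state label the molecule held before
injection.

Cross-correlation of a single trajectory is

$$G(\tau) = \frac{\sum_t (I_D(t) - \bar I_D)(I_A(t+\tau) - \bar I_A)}
                 {N \,\overline{I_D I_A}},$$

with means over the whole trajectory. The printed form of the
denominator is typographically ambiguous between the mean of the
per-frame product and the product of the channel means; the mean of
products is the default and the other convention is available behind an
argument — the two differ only by a per-trace constant and neither
changes the sign structure or decay that the analysis interprets. A
brute-force double-loop oracle asserts equivalence to 1e-9.

# The synthetic generator and its calibration

The generator draws, per molecule: a donor-only flag, an initial state
from the condition's occupancy vector, an optional continuous-time
Markov state path (restricted to a `dynamic_fraction` of molecules), and
a single terminal event from competing exponentials — donor bleach,
acceptor bleach, and (after injection) transfer at the current state's
rate, integrated along the state path. Noise-free channel intensities
invert the efficiency formula — given target `E` and summed intensity
`T`, `I_D = T(1 - alpha E)/(1 - alpha E + E)` and
`I_A = E I_D/(1 - alpha E)` — so the analysis recovers ground truth
exactly in the noise-free limit; the physical leakage model lives only
in the movie renderer. Additive Gaussian noise per channel is the
default (Poisson counting noise is available behind a flag); the source
experiments publish no absolute intensity scale or noise level, so the
defaults of 1000 a.u. summed intensity and 50 a.u. per-channel noise are
a package choice giving per-frame efficiency noise of about 0.03-0.05,
comparable to the published trace appearance.

Condition presets encode the published population structure: state
means 0.36 / 0.57 / 0.71; a 41% closed-state preference at 12 °C;
loss of the high state at 22 °C; stabilisation of the low state by UEV;
capture of the high state by UEV plus the RNF4 RING dimer; and a
closed-shifted thioester conjugate for the injection experiments.

Rates were calibrated analytically, before any test was run, from the
competing-exponential identity
`P(transfer) = S_pre * k_s/(k_s + k_b) * (1 - exp(-(k_s + k_b) T))`
with `S_pre` the probability of surviving the pre-injection frames:

* *reaction preset*: 320 frames at 1 s, injection at frame 20, donor
  bleach 3e-4 /s, acceptor bleach 2.5e-3 /s, transfer 0.05 /s from the
  high state (dwell ~20 s), 1.5e-3 /s from the low state (the slow
  background route), zero from the intermediate state, occupancies
  (0.15, 0.25, 0.60) — giving an expected classified transfer fraction
  of ≈ 60%, the published reacted extent;
* *UEV-only preset*: the same geometry with a 5e-4 /s background rate in
  every state, giving ≈ 14-15%;
* *equilibrium presets*: 600 frames at 100 ms, bleach rates 0.004 and
  0.007 /s, and a dynamic subpopulation of 1.2% switching at 0.15 /s —
  so that about 1% of one-minute trajectories show a detectable switch
  before bleaching, matching the published interconversion incidence.

One deliberate simplification: each molecule experiences at most one
terminal event (after acceptor bleach the recovered donor persists to
the end of the trace). This keeps the ground truth single-valued and
the classification problem well posed; it forgoes second events
(donor bleach after acceptor bleach), which the published counting also
does not resolve.

**What the generator does not emulate**: dye blinking and triplet
photophysics, stage drift, EMCCD gain nonlinearity and excess noise,
background autofluorescence structure, and intensity heterogeneity
between molecules. Tests passing on this generator therefore validate
the estimators' correctness under the stated statistical model, not
robustness to every pathology of real recordings.

# Movie rendering and extraction

For testing the imaging front end, traces can be rendered into a
dual-channel stack: each molecule is a unit-normalised Gaussian spot
(sigma 1.1 px) in the left (donor) half-frame and at a half-width
horizontal offset in the right (acceptor) half, with 12% of the donor
flux added to the acceptor spot, constant background, and optional
per-pixel Gaussian noise. Spot detection is local-maxima-above-threshold
with centroid refinement and a brighter-spot tie-break below the minimum
separation; channel registration matches spots by nearest neighbour
after a coarse median offset and fits a translation (or affine map) by
least squares with residual-based outlier rejection; extraction sums a
4-px-radius aperture (capturing > 99.8% of the PSF, so the render ->
extract round-trip closes within 1%) minus the median of a local
annulus (2 px gap, 2 px wide). Coordinates are 0-based with the origin
at the top-left pixel, and the reference image for detection is the
average of the first five frames. All detection parameters are exposed
as arguments rather than fixed constants, since the original
acquisition pipeline's parameters are not published.

# Problem sizes and determinism

The shipped tests and the acceptance script use 3000 molecules for
population recovery, 1000 for interconversion statistics, 270 / 263 for
the two injection conditions (the published molecule counts) and 800-1000
for classifier accuracy — sizes at which every recovery lands well inside
its tolerance while a full run stays within a few minutes on one core.
All randomness flows from one master seed through fixed per-molecule
hashes, so identical configurations reproduce bit-identical datasets
regardless of molecule count or evaluation order.

# Known limitations

* The per-molecule transfer/donor-bleach degeneracy bounds classifier
  accuracy; only rate-level analysis separates the two.
* The mixture model assumes Gaussian state distributions; strongly
  skewed populations (e.g. from acceptor blinking) would bias weights.
* No hidden-Markov modelling of trajectories: state assignment is
  threshold-based and intended for the long-lived states this system
  exhibits, not for fast-exchanging systems.
* The UEV-only background reaction is modelled as state-independent;
  the data cannot distinguish this from a weakly state-dependent
  background.
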