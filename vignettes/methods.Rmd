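---
title: "Models and methods: GABA-A gating, chloride homeostasis and analgesic synergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabakcc2)
```

This package implements the quantitative backbone of a study of why
benzodiazepine-site analgesia collapses at high doses in neuropathic
animals and why enhancing KCC2-mediated chloride extrusion restores and
synergizes with it. Everything runs on synthetic data with recorded
ground truth, so each stage is testable end to end.

## Receptor gating

A GABA-A receptor is reduced to three states — unbound closed (C0),
bound closed (C1) and open (O):

$$C_0 \underset{k_2}{\overset{k_1[G]}{\rightleftarrows}} C_1
  \underset{k_4}{\overset{k_3}{\rightleftarrows}} O,
  \qquad [G](t) = G_{max}\,e^{-t/\tau}.$$

Desensitized states are deliberately omitted: the three-state scheme is
the smallest model that reproduces the measured event kinetics, and more
states would over-fit four observables per condition. The cleft
transient uses the standard estimates $G_{max} = 0.63$ mM and
$\tau = 1$ ms. A subtlety worth stating once: $k_1$ is a *bimolecular*
rate (per mM per ms). Rate tables often quote it in ms$^{-1}$, but it
always multiplies the GABA concentration in mM; the presets follow that
convention.

The built-in presets are $(k_1,k_2,k_3,k_4) = (40, 0.8, 1, 0.15)$ for
the control condition and $(11.2, 0.8, 0.43, 0.06)$ after nerve injury
— lower binding rate (lower apparent affinity, consistent with a shift
toward $\alpha2/\alpha3$-containing receptors) and slower opening and
closing. Two closed forms anchor the tests independently of the
integrator:

* steady state at constant $G$:
  $O_\infty = k_1 G k_3 / (k_2 k_4 + k_1 G (k_3+k_4))$, giving
  $EC_{50} = k_2 k_4 / (k_1 (k_3+k_4))$ — 2.61 µM (control) vs 8.75 µM
  (injured), the rightward shift of the steady-state curve;
* after the transmitter decays, (C1, O) obey a linear 2×2 system whose
  slow eigenvalue solves
  $\lambda^2 + (k_2+k_3+k_4)\lambda + k_2 k_4 = 0$; the open-fraction
  decay constant $-1/\lambda_{slow}$ is 15.7 ms (control) and 26.1 ms
  (injured). The fitted single-exponential decay of a simulated event
  agrees within 3% (the fit window, peak to 5% of peak, still contains
  a trace of the fast mode).

Integration uses `deSolve::lsoda` at relative tolerance $10^{-8}$ with
0.05 ms output sampling; rebinding during the transient is always
included since $k_1 G$ dominates early kinetics. Decay fitting uses a
single exponential with the offset fixed at zero because all states
relax to zero; the window rule (peak to the last sample above 5% of
peak) matches how single decay constants are conventionally reported.

`fit_gating_constraints()` recovers the seven free rates (three per
condition plus one shared unbinding rate) from seven targets: both
rise times, both decay times, a lower bound on the control peak open
fraction (imposed as a hinge penalty so it costs nothing once
satisfied), the relative peak reduction of the injured condition, and
the control steady-state EC50. Residuals are normalized per target and
equally weighted. One genuine tension is left visible rather than
resolved: a 37.2% higher receptor count at equal maximal conductance
arithmetically implies a $1-1/1.372 \approx 27.1\%$ lower open
fraction, yet the stated constraint is a 37.2% reduction. The fit
honors the literal 37.2% figure; with the preset constants themselves
the simulated reduction is 30.7%, and both numbers are reported instead
of being averaged away.

## Chloride homeostasis and the collapse of inhibition

The net anionic current through the inhibitory conductance is ohmic,

$$I = x\,g_{inh}(V_{eff} - E_{Cl}) + (1-x)\,g_{inh}(V_{eff} - E_{HCO_3}),$$

with $x = 0.8$ from the roughly 4:1 Cl:HCO3 permeability ratio. The GHK
flux formalism would be more exact but changes nothing qualitative
here; the ohmic form is the primary model. E_Cl sits at the equilibrium
where synaptic influx and KCC2 extrusion cancel:

$$E_{Cl} = \frac{g_{inh} V_{mean} + g_{KCC2} E_K}{g_{inh} + g_{KCC2}},$$

with $V_{mean} = -60$ mV and the KCC2 strength expressed as a
conductance $g_{KCC2} = F\,U_{KCC2}$. $V_{eff} = -55$ mV is the anion
reversal at which inhibition stops affecting firing (more depolarized
than rest because of shunting). Conductances are normalized to the
injured baseline ($g_{inh} = 1$, $g_{KCC2} = 0.81$), and relative
changes follow the convention that $\Delta g = 1.9$ multiplies a
conductance by 2.9.

At fixed $g_{KCC2}$ the current is the rational function
$I(g) = g(\alpha g + \beta)/(g + m)$ with $\alpha < 0$ whenever
chloride accumulation eventually wins: increasing the inhibitory
conductance first increases, then *collapses* the hyperpolarizing
current. The stationary point has the closed form
$g^* = -m + \sqrt{m(m + \beta/|\alpha|)}$, which the numeric optimizer
must match to $10^{-6}$ in the tests. Because $g^*$ grows with
$g_{KCC2}$, enhancing extrusion moves the collapse beyond the previous
optimum — the mechanistic reading of collapse prevention.

Calibration solves $(E_K, E_{HCO_3})$ exactly from two anchors — a
baseline weighted anion reversal of $-65$ mV and a current optimum at
$\Delta g_{inh} = 1.9$ — at fixed $x$ (the chloride fraction is not
identifiable from these anchors; any $x$ admits an exact solve, so it
stays a stated input). The third published anchor, a 26% current increase
at the optimum, is *over-determining*: with the optimum at
$g^* = 2.9$ and $m = 0.81$ the rational form caps the attainable
increase at about 23.8% regardless of the remaining constants. The
calibration reports this $\approx -2.2$-point residual as an
internal-consistency finding; forcing agreement would silently distort
the reversal potentials. The calibrated values, $E_K \approx -91$ mV
and an effective $E_{HCO_3} \approx -29$ mV, should be read as model
effective parameters, not measured potentials (the Nernst value for
16/26 mM bicarbonate is $-12.3$ mV; the gap absorbs what the
one-compartment ohmic form leaves out). Whether the $-65$ mV anchor
denotes the permeability-weighted reversal or E_Cl alone is ambiguous
in the source; the weighted reading is the default and the alternative
is one argument away.

The analgesia–current relation is the simplest saturating form,
$\mathrm{Effect}(\Delta I) = Max\cdot\Delta I/(Curhalf + \Delta I)$,
calibrated exactly from the two anchors (26%, 25%) and (67%, 42%) after
subtracting the 6% no-drug offset from all behavioral effects:
$Curhalf \approx 50.8$, $Max \approx 73.9$. In the low range the
relation is treated as linear through the first anchor, so a 19% effect
maps to a 19.8% current increase.

Dose–effector maps invert this chain per drug:
dose → offset-corrected effect → current change → conductance change,
the last step by bracketed monotone root finding at absolute tolerance
$10^{-9}$. Each map carries the dose domain on which all inversions
exist; outside it values are masked (`NA`), never extrapolated — with
the calibrated constants the benzodiazepine-site drug is invertible up
to about 6 mg/kg, where its corrected effect reaches the effect of the
attainable current maximum. The two combination surfaces then follow:
under the *common-effector* assumption the KCC2-drug dose is converted
to an equivalent conductance-drug dose and the sum pushed through the
single-effector chain; under the *distinct-effector* assumption each
drug moves its own conductance and the combined current feeds the
effect relation. The distinct surface dominates at every interior grid
point — the model's statement of qualitative synergy.

## Behavioral pharmacology

Thresholds are summarized as maximum possible analgesia,
$\%MPA = 100\,(WD_{50}(t) - WD_{50}^{pre\text{-}drug})/(WD_{50}^{pre\text{-}injury} - WD_{50}^{pre\text{-}drug})$,
reported unclipped by default (negative MPA is meaningful worsening)
with a clipped view for plotting. Because testing follows each
injection hourly over a 4-h window, fits operate on one value per
animal obtained by `mpa_by_animal()`: the per-animal 4-h maximum by
default, or the group-peak timepoint; the choice is exposed because the
source convention is ambiguous between the two.

Dose-response uses the four-parameter Hill equation, initialized from
the data (baseline = min, plateau = max, EC50 = median log dose,
slope 1) with the slope bounded to (0.1, 10]; fitting is per-animal by
default with optional mean aggregation (both give the same least-squares
estimates on balanced designs). A high-dose collapse multiplies the
drug-dependent part by the inverse sigmoid
$C_{50}^{H_{col}}/(d^{H_{col}} + C_{50}^{H_{col}})$; since the plateau
and the collapse are not jointly identifiable on a single declining
arm, `fit_hill_collapse()` requires the amplitude to be fixed from an
independent estimate and flags data without a high-dose decline.

Loewe additivity is implemented through the closed-form dose
equivalence $a_{eq}(b)$ (shared baseline, reference drug with the
larger plateau), the additive response $Y(a + a_{eq}(b))$, the isobole
$a + a_{eq}(b) = EC_{50}^a$ traced by root finding, and the theoretical
A50 at the isobole's intersection with the fixed-ratio ray (1:55 by
default). Interaction classification is a sign test outside an
uncertainty band, defaulting to the standard error of the observed
mean; formal hypothesis testing is out of scope. The cold-response
E-score is the sum of five ratings in {0, 1, 2}.

## Image quantification

Punctum ("cluster") detection is object-based: the image is convolved
with a zero-mean disc kernel whose diameter equals the PSF FWHM (a
positive disc, sum 1, inside a window twice its diameter with a
uniformly negative surround), so constant and low-frequency background
cancel exactly and no global raw-intensity threshold enters. The
filtered image is thresholded at median + 4 robust SD (MAD); the
z-score rule is an implementation choice since the source describes the
background statistic only as robust. Components are 8-connected;
objects touching the frame edge are kept but flagged. Replicate (not
circular) boundary padding avoids wrap-around artifacts on non-periodic
fields.

Channel-in-mask quantification multiplies a channel by a binary mask
(overall and per-object means, plus the percent overlap of a second
mask). Membrane profiles average a 3-pixel-thick crossing, locate the
two membrane maxima, and align profiles on the first peak before
averaging; the membrane index is mean(region) − mean(intracellular)
after background subtraction from a signal-free area, which cancels any
constant offset by construction. The expression-difference map smooths
both mean images with a 20 µm Gaussian before the pixelwise relative
difference, masking pixels where the reference is at the noise floor.

Soma detection subtracts a 50×50 box local average (odd-padded kernel)
from the image so that bright somata come out positive — the source
text states the subtraction in the opposite order, which would make
somata negative; this is a deliberate sign correction. Candidates
exceed the offset mean plus $k$ SD with $k = 0.75$ by default (midpoint
of the stated 0.5–1 working range), holes are filled, and components
pass only with area above 500 px and eccentricity at most 0.98.
Transcript dots are detected with the same matched filter at a smaller
PSF (replacing manual dot marking), assigned to somata, and cells are
typed inhibitory/excitatory by the presence of at least one marker dot,
with extracellular dots tallied separately; raw per-cell counts are
reported since no normalized "copy index" is defined. Two scalar
conveniences complete the module: total subunits = monomers + 2·dimers,
and bead-profile deconvolution
$\omega = \sqrt{\omega_{fit}^2 - D_{bead}^2}$.

## Synthetic data: what it emulates and what it does not

Generators cover every input class: behavioral threshold tables (exact
inverse-MPA construction, so zero-noise data reproduce the model curve
to machine precision; additive Gaussian noise on the MPA scale, 5% per
measurement by default, thresholds clipped to [0, pre-injury baseline],
optional snapping to the von Frey filament set, off by default because
it breaks exact invertibility), mIPSC traces (Poisson event times,
gating-model waveforms, lognormal amplitudes, Gaussian baseline noise),
and three image classes (PSF-blurred puncta, membrane rings, somata
with transcript dots) rendered with Poisson shot noise plus Gaussian
read noise and 12-bit clipping. The PSF is an isotropic Gaussian with
FWHM ≈ 0.25 µm (60×/1.4 NA-class optics). Punctum amplitude is defined
as the post-optics mean brightness over the planted footprint (the
generator pre-compensates PSF edge loss on a unit disc), which makes
"planted amplitude" directly recoverable by mask quantification.
Behavioral defaults mirror the in-vivo design: 8 animals per dose,
doses spanning 0.05–20 and 5–150 mg/kg for the two drugs, hourly
measurements over 4 h. Per-animal threshold variance is not stated in
the source, so the 5% noise default is a choice of plausible magnitude,
made once.

What passing tests on these fixtures do *not* show: real images carry
structured background, out-of-focus light and anisotropic PSFs that the
isotropic-Gaussian generator does not emulate; real withdrawal
thresholds are quantized by the filament ladder and the up-down
estimator (out of scope); real mIPSC trains involve dynamic chloride
accumulation that the equilibrium model deliberately excludes. Recovery
results quantify the correctness of the operators, not the difficulty
of real tissue.

## Problem sizes and reproducibility

Default problem sizes keep every analysis interactive on a laptop:
256×256 synthetic images (the quantification operators are
resolution-independent; acquisition-sized 2048×2048 frames change only
runtime), 100–120 ms gating simulations at 0.05–0.1 ms sampling,
13–25-point dose grids per surface axis, and 100–200 replicates for
recovery statistics. All randomness flows through explicit seed
arguments (`with_seed` restores the caller's RNG state), the pipeline
writes a manifest with the seed, each constant's provenance (published
default vs calibrated) and per-stage timings, and re-running an
identical configuration reproduces byte-identical outputs.
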