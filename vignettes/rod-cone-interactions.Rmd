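---
title: "Modelling asymmetric rod-cone interactions with LN cascades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling asymmetric rod-cone interactions with LN cascades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The mechanism

At mesopic light levels rod- and cone-driven signals reach an ON parasol
ganglion cell through parallel bipolar circuits that converge on a shared,
rectifying synapse. `rodcone` models that convergence as linear summation
of two kinetically distinct pathway signals followed by a single static
nonlinearity:

r(t) = N( (L_rod ∗ s_rod)(t) + (L_cone ∗ s_cone)(t) ) + noise.

The rod filter is slow and strongly biphasic; the cone filter fast and
weakly biphasic. With a rectifying `N`, the rod response's undershoot can
hold the summed generator signal below threshold for a few hundred
milliseconds, so a cone test flash delivered in that window is suppressed —
while the shallow cone undershoot suppresses a subsequent rod flash far
less. Everything downstream (paired-flash prediction, the interaction
index, the offset sweep) is parameter-free once the LN components are
known.

Assumptions worth keeping in view: the cascade is time-invariant over a
recording, a single shared `N` serves both pathways, stimuli are full-field
(no spatial receptive field), responses are an excitatory-input analogue
(no spike generation), and the noise is additive and Gaussian.

## Filters

`make_biphasic_filter()` builds impulse responses as a difference of two
gamma lobes of shape order 4 — smooth, causal, and controlled by exactly
the features the mechanism depends on. The positive lobe is anchored at
`peak_time`, the negative lobe at `undershoot_time`, and the negative-lobe
weight is solved by bisection so that the composite filter's undershoot
depth (|min|/max) equals `undershoot_ratio` exactly.

One consequence of using overlapping order-4 lobes deserves emphasis: the
*composite* extrema do not coincide with the lobe anchors. For the rod
preset (anchors 0.10 s / 0.20 s, ratio 0.5) the realized maximum falls near
0.086 s and the minimum near 0.28 s. We verified that no order-4 parameter
choice can pin both composite extrema to the anchor times at this lobe
spacing and depth — narrower (higher-order) negative lobes could, but they
introduce a spurious third lobe (a positive rebound after the undershoot)
that has no physiological counterpart. We therefore kept the order-4
family, anchored the lobes, and made the undershoot depth the exactly
enforced quantity, since depth and approximate timing of the undershoot are
what drive the interaction asymmetry. Tests freeze the realized extrema.

Presets: rod `peak_time` 0.10 s, `undershoot_time` 0.20 s, ratio 0.5; cone
0.05 s / 0.12 s / 0.1; support 0.5 s; `dt` 1 ms throughout. These place the
predicted rod→cone suppression maximum at ~0.22 s, within the 0.1–0.3 s
window where suppression is empirically maximal.

## Stimuli and the operating point

The characterization stimulus is 50%-contrast Gaussian noise band-limited
to 0–60 Hz, built by a frequency-domain brick wall on a white sequence and
rescaled to the target SD (the most literal reading of a stated bandwidth).
Raw intensities are converted to contrast drive `(x − mean)/mean` before
convolution; negative drive excursions are *not* clipped, because clipping
would distort the Gaussianity that reverse correlation relies on.

The default shared nonlinearity is threshold-linear with the threshold at
0.3 times the SD of the summed generator signal under this stimulus
(`default_nonlinearity()`). That places the operating point where
rectification is strong enough to produce clear interactions while flash
responses stay in range; the threshold scales with the filters, so the
choice is dimensionless.

Photoisomerization calibration multiplies photon flux by the collecting
area (rod 1.0 μm², cone 0.37 μm²) and the emission-weighted mean absorption
over the shared wavelength grid.

## LN estimation

`estimate_filter()` computes the Wiener solution in the frequency domain:
cross-spectrum over (power spectrum + ridge × mean power), with
out-of-passband components zeroed and the result truncated to lags
`[0, max_lag]`. The ridge (default 0.01) regularizes the division where the
band-limited stimulus has no power; naive cross-correlation would return
the filter smeared by the stimulus autocorrelation. Tests verify agreement
with a brute-force least-squares fit of lagged-stimulus coefficients on
short instances.

`estimate_nonlinearity()` bins the generator signal into quantile bins
(default 40, minimum occupancy 50 samples — quantile rather than uniform
bins keep the tail knots stable) and averages generator and response per
bin; adjacent monotonicity violations are pooled, count-weighted, as in an
isotonic fit. The amplitude ambiguity of the cascade (gain can sit in `L`
or `N`) is resolved by peak-normalizing the filter and absorbing all gain
into `N`.

Beyond the fitted knot range `N` is extrapolated linearly with the
end-segment slopes and floored at the smallest observed response. The rule
matters: flash prediction evaluates `N` well above the noise-sampled range,
and an unbounded-above extrapolation is what makes the flash-scaling
bisection well posed. Rod- and cone-derived nonlinearities are estimated
separately; predictions use the cone-derived one as the shared synapse (the
two are similar by construction; which to use is configurable).

## Interaction prediction

"Amplitude" for flash scaling means the peak response above baseline, not
the integral — the conventional reading, and the one that makes
`scale_filter_to_flash()` a monotone inversion (bisection to a relative
tolerance of 1e-6). The paired prediction offsets the scaled filters by
Δt, sums, and applies `N`.

`interaction_index()` integrates over `[test_onset, test_onset + 0.6 s]`;
0.6 s covers the flash responses at these kinetics, and the window is
configurable. Baselines: exact `N(0)` for model predictions; for simulated
"measured" traces, the mean over a pre-adapt window (default the first
0.5 s of the trace). The index is not clipped: facilitation (`II < 0`) and
overshoot-driven values above 1 are reported with a flag. The offset grid
default is 0–0.8 s in 25 ms steps, and argmax ties break toward the
smaller offset.

`biphasic_index()` uses the first 400 ms after flash onset of the
baseline-corrected response.

## The simulated observer

The matching task description specifies the staircase bookkeeping (six
reversals, increments shrinking by 1/3 per crossing, a hardware floor on
the increment, the inverse-step-weighted midpoint estimator, exclusion
rules) but not the observer; the decision model here is deliberately the
simplest one that exercises every analysis rule. The observer perceives the
adapted-location flash at `reference × cortical × (retinal if same-eye)`
with multiplicative Gaussian judgment noise, and steps the comparison flash
toward perceived equality.

Two design choices are worth flagging. First, the starting intensity (0.6×)
and the adjustment increments (initial step 0.15×, floored at
`(2/3)^8` of the initial step) are expressed relative to the observer's
initial percept of the reference. This makes the entire staircase
scale-equivariant in the perceived target, which has two exact
consequences: the noise-free recovered index equals `1 − s` identically
(matching the series-multiplicative gain model), and the cortical gain
cancels exactly in the one- vs two-eye ratio. Absolute (intensity-unit)
steps would leave a target-dependent bias in the match and break both
identities. Second, "step size between a pair of crossings" is interpreted
as the increment in force during the interval between those crossings,
i.e. the step set after the earlier crossing of the pair.

All six crossings enter the weighted estimator (the stop rule and the
estimator use the same crossings). Task v1's manual match is simulated as
the midpoint of the final bracket; v1 exclusions drop trials with fewer
than 2 crossings and invalidate condition cells with 3 or fewer surviving
trials.

Per-condition retinal suppressions in `simulate_session()` default to 0.6
(rod→cone, short offset), 0.95 (rod→cone, long offset — interactions
largely gone beyond ~1 s) and 0.9 (cone→rod, short): plausible mesopic
values chosen once to mirror the qualitative ordering of the physiological
asymmetry; the recovery tests use explicit gains and do not depend on
them.

## Synthetic data: what it does and does not emulate

The generator reproduces the statistical structure the analysis assumes:
band-limited Gaussian stimuli at 50% contrast on a ~20 R*/rod/s-equivalent
background, 10 ms flashes, kinetically distinct biphasic filters, shared
rectification, additive Gaussian response noise, and a staircase observer
with multiplicative gains. It does not emulate phototransduction dynamics,
adaptation of the filters to mean luminance, spiking, spatial structure,
inhibitory circuitry, or trial-to-trial kinetic variability of real cells.
Passing tests therefore demonstrate the self-consistency of the analysis
chain and the mechanistic sufficiency of the kinetics+rectification
account on data that satisfy its assumptions — not that real retinas
satisfy them. The response noise SD of recorded cells is not publicly
stated, so it is a free simulation parameter (defaults keep flash responses
at signal-to-noise comparable to averaged recordings).

## Problem sizes and numerical notes

Test and acceptance runs use 1 ms sampling with noise durations of
40–300 s (300 s for the parameter-recovery check, 80 s per draw for the
predicted-vs-simulated comparison across 12 random ground-truth systems,
averaged flash responses over 8 repeats) — sizes at which the estimators
are comfortably in their asymptotic regime while a full run stays at desk
scale. Convolutions are FFT-based, zero-padded to 2-3-5-smooth lengths;
every stochastic operation takes an explicit seed and restores the
caller's RNG state; derived sub-stream seeds stay below 2^31.

## Limitations

The filter family enforces undershoot depth exactly but composite extremum
times only approximately (see above). The Wiener estimator assumes
(approximately) Gaussian stimuli; it is biased for strongly non-Gaussian
inputs. The knot nonlinearity is piecewise linear, so its second
derivative is not meaningful. The observer model is a caricature: real
observers show sequential dependencies, lapses and criterion drift that
the exclusion rules exist to absorb. And the dichoptic decomposition
assumes strictly multiplicative, serial retinal and cortical gains — the
same assumption the perceptual index itself rests on.
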