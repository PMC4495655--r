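# rodcone

Linear–nonlinear models of rod–cone interactions at the retinal output.

At twilight light levels both rod and cone photoreceptors are active, and
their signals converge inside the retina before reaching the brain. In the
primate ON pathway the dedicated rod bipolar circuit and the cone bipolar
circuit share a final synapse onto the ganglion cell, and that synapse
rectifies. Because the rod pathway's impulse response is slow and strongly
biphasic (a depolarizing lobe followed by a pronounced undershoot) while the
cone pathway's is fast and nearly monophasic, a rod flash can park the
shared synapse below threshold just when a subsequent cone flash arrives —
suppressing it — whereas the weak cone undershoot barely affects a
subsequent rod flash. `rodcone` implements this mechanism end to end as a
testable pipeline: simulation, estimation, prediction, and a psychophysical
analogue. It is aimed at retinal and computational neuroscientists who want
to fit LN cascade models to stimulus–response data and predict paired-flash
interactions from them without free parameters.

## The model

The response of the retinal output to a full-field stimulus `s(t)` is
described by an LN cascade,

    r(t) = N( (L ∗ s)(t) ),

with a pathway-specific linear temporal filter `L` and a shared static
nonlinearity `N` (threshold-linear by default). Paired-flash interactions
are quantified by the interaction index

    II = 1 − R_pair / R_single,

where `R_single` is the integral of the response to the test flash alone
and `R_pair` the integral of the test response in the presence of the adapt
flash (paired response minus adapt-alone response). `II = 0` is linear
summation; `II = 1` is complete suppression. Filter shape is summarized by
the biphasic index `BI = A_H / (A_H + A_D)` (hyperpolarizing over total
excursion within 400 ms). Perceptual interactions from the dichoptic
matching task use the same form, `II = 1 − S_1eye / S_2eye`, on monocular
vs binocular sensitivity ratios.

The package's modules:

- **Synthetic retina** — gamma-lobe biphasic filters (`rod_filter()`,
  `cone_filter()`, `make_biphasic_filter()`), band-limited Gaussian noise
  and flash stimuli (`noise_stimulus()`, `flash_stimulus()`), cascade
  simulation (`simulate_response()`), photoisomerization calibration
  (`photoisomerization_rate()`).
- **LN estimation** — `ln_fit()` returns an `"ln_model"` with the filter
  estimated by regularized reverse correlation and the nonlinearity by
  quantile-binned generator-signal averaging; `print()`, `summary()`,
  `coef()`, `predict()`, `plot()`, `residuals()`, `simulate()` methods.
- **Interaction prediction** — `scale_filter_to_flash()`,
  `predict_paired_response()`, `interaction_index()`, `offset_sweep()`,
  `biphasic_index()`.
- **Psychophysics** — `observer_config()`, `simulate_observer_trial()`,
  `staircase_match()`, `apply_exclusions()`,
  `perceptual_interaction_index()`, `simulate_session()`.
- **Orchestration / IO** — `run_experiment()`, `read_trace()` /
  `write_trace()` (CSV + JSON sidecar), `write_ln_model()` /
  `read_ln_model()`, `experiment_config()`.

## Worked example

Predict the time course of rod→cone suppression from the preset pathway
filters and the default rectifying synapse:

```r
library(rodcone)

rodf  <- rod_filter()    # slow, undershoot ratio 0.5
conef <- cone_filter()   # fast, undershoot ratio 0.1
shared <- default_nonlinearity(rodf, conef)

sw <- offset_sweep(ln_model(rodf, shared), ln_model(conef, shared),
                   shared_nl = shared)
sw
#> Offset sweep (rod_to_cone): 33 offsets, II max 0.6850 at 0.225 s
```

Suppression is negligible for simultaneous flashes, maximal (`II = 0.69`)
when the cone test flash lands 0.225 s after the rod adapt flash — inside
the rod undershoot — and gone by 0.5 s. Reversing the roles
(`direction = "cone_to_rod"`) gives `II = 0.06` at the same 0.2 s offset:
the asymmetry follows directly from the rod filter being more biphasic than
the cone filter. An identity nonlinearity gives `II = 0` at every offset.

The simulated dichoptic observer recovers retinal suppression from
staircase matches:

```r
obs <- observer_config(retinal_suppression = 0.6, judgment_noise_sd = 0.05)
m_same <- sapply(1:12, function(k) staircase_match(
  simulate_observer_trial(obs, eye_mode = "same", seed = k))$matched_intensity)
m_sep <- sapply(1:12, function(k) staircase_match(
  simulate_observer_trial(obs, eye_mode = "separate", seed = 100 + k))$matched_intensity)
perceptual_interaction_index(m_same, m_sep)
#> <perceptual_interaction_result> II = 0.4045 (S_1eye = 0.5093, S_2eye = 0.8552)
```

The recovered perceptual index (0.40) matches the configured ground truth
`1 − 0.6 = 0.4`; the cortical gain cancels in the one- vs two-eye ratio.

`run_experiment(experiment_config(seed = 1))` runs the whole pipeline —
noise simulation, LN fitting, offset sweeps in both directions, indices and
a matching session — and returns a result bundle with a reproducible
manifest.

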