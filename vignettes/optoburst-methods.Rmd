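---
title: "Models and methods behind optoburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optoburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`optoburst` couples an analysis pipeline for two-compartment
optogenetics / calcium-imaging recordings with a generative model of the
same experiment. This vignette documents the models, the defaults and the
numerical choices, and states plainly what the synthetic data does and
does not emulate.

## The burst-ignition model

The unit of activity is a neuron's participation in a network burst, not a
single spike. Ignition follows the canonical discrete quorum-percolation
model: neuron $i$ activates when

$$ w \, c \, \#\{\text{active presynaptic inputs of } i\} \;\ge\; \theta, $$

where $w$ is the synaptic efficacy, $c \in [0,1]$ the CNQX multiplier and
$\theta$ the quorum threshold. Updates are synchronous; active neurons
stay active for the burst's duration; the iteration runs to its fixed
point. The synaptic graph is directed Erdős–Rényi with Poisson in-degrees
(`mean_in_degree`, default 100 on `n_neurons = 2000`); each compartment
draws one graph per simulation and reuses it across ignitions. One
synchronous update corresponds to one synaptic integration step of 1 ms,
matching the 1 kHz read-out granularity and producing transmission delays
of a few milliseconds, as observed.

The ignition delay of a burst is the number of steps until 95% of the
final recruited count is active. Because a seed of $k$ active inputs needs
more steps to percolate when $k$ is small, a compartment seeded through
few afferent axons ignites *later*: this single mechanism yields both the
longer reverse delays of axon-diode devices and their collapse to
unidirectionality when CNQX raises the effective threshold
$\theta / (w c)$.

Defaults ($\theta = 2$, $w = 1$, in-degree 100): the critical seed at
drug-free efficacy is below a handful of neurons, so 3 reverse axons can
still (slowly) ignite a burst; at 5 µM CNQX ($c = 0.5$, effective
threshold 4) the critical seed rises to roughly six neurons and 3 axons —
whose targets can receive at most 3 inputs — can never percolate, while
100 forward axons still can. These are analytic consequences of the
threshold model, not tuned constants.

## Light, pharmacology, populations

* **Photo-activation.** A 470 nm pulse of duration $d$ (intensity $I$)
  directly activates each ChR2-expressing neuron with probability
  $1 - e^{-\lambda d I}$ (`photoactivation_rate` $\lambda$, default
  0.1 ms⁻¹), so the directly recruited count is binomial in the transduced
  population. The photocurrent persists while the light is on, so the
  directly driven fraction stays active for
  $\max(\text{burst duration}, d)$.
* **Transduction.** 70% of *excitatory* neurons express ChR2; inhibitory
  neurons (default 15% of the population) never do, since the CaMKIIa
  promoter is inactive in them. `transduced_fraction` accepts a length-2
  vector for one-sided-transduction devices.
* **CNQX.** Concentration maps linearly to the efficacy multiplier
  $c = \max(0, 1 - [\mathrm{CNQX}]/10\,\mu M)$: 10 µM (the lowest
  saturating concentration) blocks transmission, 5 µM halves it. Linearity
  is the simplest defensible interpolation between the two documented
  anchor points; the mapping is exposed in the configuration.
* **Disinhibition.** Under CNQX the inhibitory neurons fall silent (their
  only excitatory drive is AMPAergic), so the responding excitatory
  neurons are released from inhibition. This is modelled as a gain
  (`disinhibition_gain`, default 2) on the calcium response amplitude,
  interpolated by $1 + (g-1)(1-c)$, applied after the indicator
  saturation — silenced inhibition raises the per-neuron calcium ceiling,
  not the optical drive. It is the minimal mechanism reproducing the
  observation that long-stimulus responses are *larger* with saturating
  CNQX than without.
* **Spontaneous activity.** Each compartment proposes ignitions as a
  Poisson process (`spontaneous_burst_rate`, default 8.4 min⁻¹) seeding
  `spontaneous_seed` = 50 neurons. A 3 s dead time after any burst
  suppresses *spontaneous* proposals only; light-evoked ignitions override
  it, as the experiments show. With the dead time the emitted rate is
  $r/(1 + 3\,\mathrm{s}\cdot r) \approx 5.9$ bursts/min, the published
  mean for DIV 12–13 cultures, with inter-burst intervals predominantly in
  the physiological 5–10 s band. The 8.4 min⁻¹ default follows
  analytically from that dead-time equation; it was not fitted to
  simulation output. Note that the calibration describes an *isolated*
  culture (`simulate_culture()`); in a coupled device each compartment
  additionally receives its neighbour's relayed bursts, roughly doubling
  the per-compartment rate.

## The calcium read-out

Activity (fraction of neurons active, 1 ms grid) is converted to
fluorescence in four steps, all at the 8 kHz line rate:

1. **Kernel.** Exact discrete convolution with the dual-exponential
   kernel $e^{-t/\tau_d} - e^{-t/\tau_r}$ (rise 10 ms, decay 500 ms),
   implemented as the difference of two one-pole recursive filters. The
   indicator's true kinetics are unpublished; these defaults make single
   bursts cleanly resolvable at 1 kHz while keeping 5–10 s inter-burst
   intervals well separated.
2. **Saturation.** The convolved drive, normalized so a canonical fully
   recruited burst equals 1, passes through the Michaelis-type response
   $S(r) = r(1+K)/(r+K)$ with `ca_saturation` $K = 0.15$. Bulk-loaded dye
   is nearly saturated during a full network burst, so holding the whole
   population active for 1 s barely raises the peak above a 100 ms burst
   (ratio $\le (1+K)$, about 1.15) — which is exactly why drug-free
   responses are duration-independent — while sub-saturation responses
   (partial recruitment under CNQX) still grow with drive. A purely
   linear integrator would instead grow ~5-fold over that range and
   cannot reproduce the flat drug-free curve. Large $K$ recovers the
   linear read-out.
3. **Scale and noise.** $F = F_0\,(1 + A\,g\,S(r))$ with `ca_amplitude`
   $A = 0.8$ ΔF/F per full burst, baseline $F_0 = 100$ a.u., plus i.i.d.
   Gaussian noise per scan line (`noise_sigma` = 2 a.u., i.e. ~0.7% of
   baseline after 8-line integration — a conservative confocal SNR).
4. **Acquisition.** `cycles_per_sample` = 8 consecutive lines are averaged
   per stored sample, so the effective rate is exactly
   `line_rate`/`cycles_per_sample` = 1 kHz. Any stored sample whose
   integration window overlaps a 470 nm pulse on the device is masked on
   *both* traces (the photodiode saturates globally); masked samples carry
   `NA` and are written as empty CSV fields.

## Analysis conventions

* **Baseline.** $F_0$ is a rolling 10th percentile over 10 s windows
  (piecewise evaluation at window centres, linear interpolation between
  them). With bursts occupying well under half the time, a low percentile
  tracks the quiescent level and ignores transients.
* **Burst detection.** Threshold default $5 \times \mathrm{MAD}$ of the
  ΔF/F trace; events merged below 500 ms separation (under the 5–10 s
  physiological inter-burst interval, above the transient width); masked
  gaps up to 1024 ms — the longest stimulus — bridged by linear
  interpolation, longer gaps split events.
* **Evoked success.** A stimulus succeeds when post-stimulus ΔF/F exceeds
  0.2 above the trial's 200 ms pre-stimulus baseline within 500 ms —
  comfortably covering evoked rise times (tens of ms) while excluding the
  next spontaneous event.
* **Amplitude curves.** The per-duration amplitude is the peak ΔF/F in a
  window extending 500 ms beyond the *end* of each pulse (nothing is
  recorded during the pulse), read directly off the ΔF/F trace rather than
  re-referenced to a per-trial pre-stimulus baseline: residual calcium
  from a spontaneous burst shortly before a pulse elevates such a baseline
  and would deflate the amplitude although the evoked transient itself is
  unchanged.
* **Delays.** Computed on the *mean* peristimulus traces (the figures'
  convention, averaging out non-specific activity), per-lag Pearson
  normalization on the unmasked overlap (robust to baseline offsets and
  indicator-loading differences; at least 10 valid pairs per lag),
  restricted to non-negative lags (causality), with parabolic refinement
  of the peak. Sub-sample refinement matters because genuine delays sit at
  1–3 samples of the 1 kHz read-out.
* **Classification.** A direction transmits when its success rate reaches
  `min_success` = 0.5 and a delay is defined. An exact-zero success rule
  is unattainable on finite noisy recordings: at ~6 bursts/min a
  spontaneous burst lands in a 500 ms post-stimulus window in ~5% of
  trials, so any blocked direction still scores a few spurious successes.
  0.5 sits far above that chance level and far below the ~0.9–1.0 of any
  connected direction. The symmetric class requires a relative delay
  difference below 10%, under the smallest asymmetry reported for diode
  devices (23%).

## What the generator does and does not emulate

Emulated: two mixed excitatory/inhibitory populations with realistic
transduction statistics; spontaneous bursting at calibrated rate and
inter-burst intervals; graded direct photo-activation versus all-or-none
percolated bursts; CNQX titration including disinhibition; symmetric and
diode axon bundles with count-dependent relay delays; saturating indicator
kinetics; line-scan acquisition arithmetic, additive noise and
stimulation-saturation data loss; full determinism under a seed (one
generator, sub-streams per compartment so coupling parameters never
perturb spontaneous event streams).

Not emulated: spatial structure within a compartment (the line scan
already integrates each population); single-spike electrophysiology;
synaptic depression, adaptation or plasticity across the stimulus train;
spectral absorption curves of ChR2 variants or dyes (crosstalk is reduced
to one probability parameter, default 0); shot noise and photobleaching;
any difference between reverse axons being fewer versus individually
weaker (the model carries counts only). Passing tests therefore validate
the pipeline's correctness and the stated population-level phenomenology,
not cellular-level realism.

## Degenerate inputs and tie-breaks

Zero-seed ignition returns zero recruitment with zero delay; an all-masked
trace is an error naming the problem; a culture with zero reference rate
is excluded from normalization with a warning; cross-correlation lags with
insufficient overlap (or zero variance) are undefined rather than
extrapolated; a delay whose parabolic neighbours are undefined is left at
the integer-lag argmax; paired t-tests on identical vectors return
$t = 0, p = 1$ and a constant non-zero difference is flagged as
degenerate; protocols with overlapping 470 nm pulses on one compartment,
events beyond the simulated duration, or unknown roles are rejected up
front. Time is in ms throughout and all windows are half-open
$[t_0, t_1)$.

## Problem sizes

Simulation-backed tests run at 300–2000 neurons per compartment and 30 s
to 10 min of simulated time; the spontaneous-rate check uses nine 10 min
cultures and the device-level checks use 8–30 stimulations per side, the
experiments' own design. The brute-force percolation oracle covers graphs
up to 50 neurons; delay-recovery checks inject 1–10 ms shifts at
line-level noise up to 20% of the transient amplitude. These sizes were
chosen so the full behaviour (percolation criticality, delay ordering,
rate calibration) is expressed while the whole suite stays comfortably
fast on a laptop.
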