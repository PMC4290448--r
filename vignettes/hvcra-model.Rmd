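---
title: "The hvcra model: strengthening-and-pruning of a song-motor circuit and the variability of RA firing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hvcra model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvcra)
```

## The scientific problem

Juvenile zebra finches learn their song by trial and error: early
renditions are highly variable, and variability falls as the song
crystallizes.  In the underlying motor circuit, premotor nucleus HVC
acts as a time-keeper - each HVC projection neuron fires one stereotyped
burst per song - while nucleus RA (the motor-cortex analogue) converts
that timing signal into muscle-related commands.  Variability is
injected into RA by LMAN, the cortical outflow of a basal-ganglia loop.
During learning, HVC->RA synapses are simultaneously *strengthened* and
*pruned*: fewer inputs per RA neuron, each stronger.

`hvcra` implements a minimal feed-forward spiking model of this circuit
to ask which circuit changes can account for the developmental drop in
rendition-to-rendition variability of RA firing, together with the
slice-electrophysiology estimators (single-fiber and maximal evoked
currents, input counts, receptor ratios, F-I analysis) that produced
the measurements the model is anchored to.

## The RA neuron model

The RA projection neuron is a leaky integrate-and-fire unit:

$$\tau_m \frac{dV}{dt} = (V_R - V) + R\,I_{HVC} + R\,I_{LMAN} - V_{INH}$$

with $\tau_m = 20$ ms, $V_R = -70$ mV, threshold $V_{th} = -50$ mV and
input resistance $R = 260\ \mathrm{M\Omega}$.  A threshold crossing
emits a spike and clamps $V$ at $V_R$ for the 1.5 ms refractory period,
during which the synaptic currents keep evolving.  All internal
arithmetic uses the mV / ms / pA / G$\Omega$ convention, so that
$R\,[\mathrm{G\Omega}] \times I\,[\mathrm{pA}] = V\,[\mathrm{mV}]$.

Each of the $N_{HVC} = 100$ HVC neurons fires five spikes 2 ms apart,
with neuron $i$ starting at $(i-1)\times 10$ ms, tiling the 1000 ms
song.  HVC input is a current-based exponential synapse
($\tau_s = 5$ ms) whose increments are the per-neuron peak EPSC weights
$W_i$.  LMAN input (a merged 80 Hz Poisson process standing in for two
~40 Hz neurons) splits into an AMPA component (fraction
$r = 0.1$, $\tau_s = 5$ ms) and an NMDA component (fraction $1-r$,
$\tau_{NMDA} = 100$ ms) whose efficacy is reduced by the voltage
dependence of the magnesium block,

$$G(V) = \left(1 + \frac{[\mathrm{Mg}]}{3.57\ \mathrm{mM}}
  e^{-V/16.13\ \mathrm{mV}}\right)^{-1},
  \qquad [\mathrm{Mg}] = 0.5\ \mathrm{mM}.$$

Two readings of how $G$ enters a delta-driven synaptic equation are
implemented (`ra_params(nmda_mode=)`).  The default, `"arrival"`, takes
the equation literally: each presynaptic spike's increment is scaled
once, by $G(V)$ at its arrival step (using the pre-update membrane
potential).  The `"continuous"` alternative accumulates ungated
increments and multiplies the stored NMDA current by $G(V(t))$ at every
step.  At this model's operating point the two differ by only a few
percent in firing rate and CC, so the choice is not load-bearing.

Tonic inhibition is proportional to the HVC drive,
$V_{INH} = R_{INH}\, m\, \rho$ with
$R_{INH} = 800\ \mathrm{M\Omega}$, where $m$ is the *distribution* mean
of the active weights (not the realized sample mean, so inhibition is
identical across realizations at a grid point) and $\rho$ the active
fraction.  It is recomputed from each grid point's $(m, \rho)$ on every
sweep axis, including the strengthen-only and prune-only controls,
because it is defined as a function of the HVC drive.

## The developmental connectivity axis

Active HVC->RA weights are log-normal.  The axis of development is
parameterized by the active fraction $\rho$; the mean and SD of the
active-weight distribution are linear in $\rho$, anchored at the two
measured profiles $\rho = 0.9 \to (50, 35)$ pA (plastic song) and
$\rho = 0.37 \to (70, 70)$ pA (adult), extrapolated linearly over
$\rho \in [0.2, 1]$ and clipped at $m > 0$, $s \ge 0$
(`profile_at()`).  Log-normal parameters come from exact moment
inversion, $\sigma^2 = \log(1 + s^2/m^2)$,
$\mu = \log m - \sigma^2/2$ (`params_from_moments()`); this inversion
is the bridge between measured moments and log-normal sampling and is
therefore tested by closed form and Monte Carlo.  Pruned indices are a
uniformly random subset per realization: the HVC index maps to song
time, so deterministic pruning would imprint artifactual temporal
structure.

## LMAN firing patterns

Three generators share the invariant that the mean rate never depends
on the shape parameter:

* `lman_poisson()`: homogeneous Poisson (standard model, 80 Hz).
* `lman_bursty()`: tonic Poisson at $40(1-b)$ Hz superposed with
  Poisson burst events at $8b$ Hz, each a stereotyped run of five
  spikes 2 ms apart; bursts near the song end truncate (expected loss
  0.16 spikes per 1 s train at $b = 1$).  The burstiness sweep uses two
  independent 40 Hz bursty neurons superposed, keeping the per-neuron
  rate fixed.
* `lman_modulated()`: inhomogeneous Poisson (thinning) with one sine
  period across the song, phase 0 (the phase is a free choice; it is
  common to all renditions, which is what matters for song-locking),
  $\lambda(t) = \text{rate}\,(1 + d \sin 2\pi t/T)$.

## The variability measure

Each rendition's RA spike train becomes an instantaneous firing rate
$R(t) = 1/(t_{k+1} - t_k)$ on a 1 ms grid (10x finer than the kernel,
and cheap), is smoothed with a unit-area 10 ms Gaussian
(edge-renormalized so constants are preserved exactly), and
mean-subtracted.  `cc_average()` reports the mean pairwise Pearson
correlation over all rendition pairs.  Two conventions are ours to fix:
the epochs before the first and after the last spike are zero-filled
(the NA-masking alternative is available through
`instantaneous_rate(fill = "na")` and is what the F-I analysis uses),
and the pairwise normalization is the standard Pearson denominator
$\sqrt{\langle \bar r_i^2\rangle\langle \bar r_j^2\rangle}$ - the only
normalization that keeps CC in $[-1, 1]$ with CC = 1 for identical
renditions.  A rendition whose smoothed trace has zero variance (a
silent rendition) has no defined correlation; its pairs count as 0 and
the rendition is flagged.

A "realization" in `run_point()` is one weight draw plus fresh LMAN
noise on every one of its renditions (both sources are redrawn across
realizations); the HVC raster never varies.  Desk-scale defaults are
50 realizations x 200 renditions; the publication-scale figure is 5000
realizations, which the same code reaches by changing one argument.

## The slice-electrophysiology estimators

`detect_sf()` implements minimal-stimulation quantification: traces are
smoothed with a 1 ms sliding window; a trial is a success when its peak
in the 2-30 ms post-stimulus window (the first millisecond is stimulus
artifact; measured latencies-to-peak are 7-13 ms) exceeds twice the
baseline-noise RMS (estimated from the 50 ms pre-stimulus baseline when
not supplied; recording noise is 2-5 pA RMS, hence the classic "<4 pA
is invisible" floor).  A single-fiber measurement is accepted only with
a 25-75% failure rate and more than three successes; a second fiber in
the same cell is accepted only if its success amplitudes differ from
the first by Student's t test at p < 0.05 (`accept_second_sf()`, type-I
calibrated in the tests).  `detect_max()` finds the lowest intensity
whose mean peak stops growing - all higher-intensity means within a
configurable 10% - verified over at least a threefold intensity range,
with a CV <= 0.2 gate.

`estimate_n_inputs()` offers the two classical input-count estimators:
per-cell MAX over the group-mean SF (averaged), and the inverse
group-mean fiber fraction (SF/MAX per input).  Both assume linear
summation and are lower bounds; they agree exactly when all inputs
equal the group mean, and within ~20% on realistic synthetic
populations.  `estimate_receptor_ratio()` inverts the holding-potential
amplitude-ratio formula
$\mathrm{ratio} = g_A(E+70)/\left((g_A+g_N)(E-40)\right)$ in magnitude
at $E = 0$, giving the AMPA fraction $r = \mathrm{ratio}\times 40/70$.

`fi_analysis()` extracts spikes by threshold crossing (default -20 mV,
1 ms dead time), averages instantaneous firing frequency across the
repeated sweeps of each 0.5 s current step, and reports the adaptation
ratio (first over last 5 ms of the step), the decay time constant of a
single-exponential fit ($a e^{-t/\tau} + c$, first 100 ms from the
first spike; NA when the curve does not decay by at least 5%), and the
F-I slope from a linear fit restricted to steps <= 1.4 nA.

## What the synthetic generators emulate - and what they do not

`gen_epsc_series()` produces intensity series with known fiber
composition: difference-of-exponentials EPSCs (1 ms rise, 5 ms decay -
the waveform is not parameterized by the measurements, these are
typical glutamatergic kinetics), Gaussian baseline noise in the 2-5 pA
RMS regime, Bernoulli failures only while the intensity sits within
20% of a fiber's recruitment threshold (release becomes reliable
above), and trial-level latency jitter shared by all fibers so that
peaks sum linearly by construction.  Not modeled: vesicle depletion,
per-fiber asynchrony, dendritic filtering, series-resistance artifacts.
A green recovery test therefore establishes that the estimators are
unbiased under clean recruitment and linear summation - not that they
are robust to every biological confound.

`gen_current_clamp()` renders voltage sweeps with painted action
potentials.  The `"lif"` kind reuses the network model's Euler core, so
its rate obeys the closed-form LIF frequency; the `"adapting"` kind
places spikes by integrating an instantaneous-rate profile that decays
exponentially (factor-2 initial elevation, known $\tau$) to the LIF
steady state.  The rate-profile construction is deliberate: a
spike-triggered adaptation *current* produces an effective IFF decay
faster than its own time constant (the closed loop between rate and
accumulated adaptation shortens it), so it cannot serve as a
ground-truth fixture for recovering a known $\tau$ to within 10%.

`gen_population()` draws per-cell input counts and log-normal weights
(population CV 0.8, matching the spread of fitted amplitude
distributions), observes up to three SFs per cell and a MAX with 5%
multiplicative noise.  The emulated truths are 19 / 26 / 11 inputs for
the three stages, hence a 2.4-fold plastic-to-adult decline.

## Numerical choices

* Forward Euler at $dt = 0.2$ ms; spike events are snapped to the grid
  by flooring; threshold crossings are detected after the Euler update.
  Halving $dt$ changes constant-drive spike counts by <1%, and the
  network rate moves by <1 Hz down to $dt = 0.02$ ms.
* The constant-drive oracle: with $R I = 40$ mV the inter-spike
  interval is $t_{ref} + \tau_m \ln 2 = 15.363$ ms (65.1 Hz); the
  simulator must match within 2%.
* Exponential-fit starts for the IFF decay come from the data (offset
  at the trace minimum, amplitude from the first sample) with a
  conservative validity window ($0 < \tau < 10\times$ the fit span).
* All stochastic entry points accept a `seed` and derive child seeds
  below $2^{31}$; every generator is bit-reproducible under a fixed
  seed.

## Known limitation: the operating point of the printed constants

The parameter set above is commonly summarized with a standard-model RA
firing rate of about 50 Hz during song.  Integrating exactly the stated
equations, this package obtains about 30 Hz (independently
cross-checked by a naive second implementation that reproduces the
compiled core spike for spike, and stable under $dt$ refinement and
under both NMDA gating readings).  A mean-field decomposition shows
why: HVC contributes ~29 mV of mean drive, LMAN-AMPA ~1 mV, LMAN-NMDA
~30 mV at the realistic subthreshold gating $G \approx 0.14$, against
$V_{INH} = 36$ mV - about 25 mV net, where ~33 mV is needed for 50 Hz.
Closing the gap would require an unprinted detail (for example
$R_{INH} \approx 650\ \mathrm{M\Omega}$, or gating sampled near
threshold).  We chose fidelity to the stated equations over retuning:
the acceptance suite keeps the 50 Hz anchor and reports the discrepancy
rather than hiding it.

Consequences at the ~30 Hz operating point, all visible in the
acceptance suite: the CC still increases monotonically along the
strengthening-and-pruning axis, burstier LMAN firing still decreases
CC, song-locked LMAN firing still increases it, and a pure-NMDA synapse
still shifts CC only marginally.  But the strengthen-only control
(inhibition co-scaled to $m = 70$, $\rho = 0.9$, i.e.
$V_{INH} = 50.4$ mV) drops the neuron to ~20 Hz, whose sparse firing
is *more* stereotyped than the combined profile's - so the
"combined beats either alone" comparison fails in this regime.  And
halving $W_{LMAN}$ removes roughly half the NMDA drive and nearly
silences the neuron (~6 Hz), which makes the share of the developmental
CC change attributed to LMAN weakening small but very noisy across
weight draws; the acceptance script therefore averages many more than
the minimum 50 realizations for that target.

## Limitations

Beyond the operating point: synapses are current-based (no conductance
saturation or driving-force effects), there are no RA interneurons or
lateral interactions, a single RA neuron is modeled (no population
averaging of motor output), LMAN inputs are uncorrelated across
renditions and neurons, and the model is static per developmental
point - strengthening-and-pruning is a parameter axis, not a learning
rule.
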