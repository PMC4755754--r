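---
title: "Methods: simulating and analyzing trans-tight-junction single-channel recordings"
author: "tjclamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing trans-tight-junction single-channel recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tjclamp)
```

## The problem

Epithelial tight junctions seal the paracellular space, and claudin-2 forms
cation-selective channels through them. Patch-clamping a pipette across the
bicellular tight junction resolves single paracellular channels: ~90 pS
(about 9 pA at ±100 mV) claudin-2-dependent openings that occur in bursts of
sub-millisecond flickers, a separate ~4.3 pA claudin-2-independent class,
and, away from the junction, sub-2 pA apical membrane channels. `tjclamp`
implements the quantitative analysis chain for such recordings —
idealization, NPo, amplitude and dwell-time kinetics, ramp reversal
potentials, electrochemical permeability algebra and equivalent-circuit
computations — together with a stochastic generator that emulates the
recordings, so that every stage can be verified against exact ground truth
without laboratory data.

## The gating model

A channel is a continuous-time Markov chain over labelled states, each open
or closed, with a rate generator $Q$ (off-diagonal rates in s$^{-1}$, rows
summing to zero) and a per-state pore conductance. The default claudin-2
scheme is linear,

$$c_{stable} \leftrightarrow o \leftrightarrow c_{transient},$$

so that openings alternate with transient closures inside bursts and bursts
end when the channel enters the stable closure. The observed kinetics only
bound the three time constants ($\tau_{open} < 1$ ms,
$\tau_{c,transient} < 2$ ms, $\tau_{c,stable} > 1$ s), and they do not
determine the connectivity (which closed state exchanges with which); the
linear scheme is the simplest one that produces bursts, and the constructor
accepts any generator for users who prefer another topology.

Default parameters, all overridable in `claudin2Model()`:

| parameter | default | rationale |
|---|---|---|
| $\tau_{open}$ | 0.6 ms | inside the sub-millisecond bound |
| $\tau_{c,transient}$ | 1.2 ms | inside the < 2 ms bound |
| $\tau_{c,stable}$ | 3 s | inside the > 1 s bound |
| openings per burst | 10 | sets the $o \to c_{transient}$ vs $o \to c_{stable}$ rate split |
| conductance $\gamma$ | 90 pS | unitary conductance (82 pS for the intestinal-epithelium variant) |
| $V_{rev}$ | 0 mV | symmetric solutions; a paracellular pathway reverses near 0 |

The stationary open probability that follows is
`openProbability(claudin2Model())` $\approx 0.002$: the channel is mostly in
the stable closure and activity is concentrated in bursts, which is exactly
the texture of the recordings being emulated.

Two further channel classes use two-state models:
`independentChannelModel()` (43 pS, 2 ms openings, 0.5 s$^{-1}$ opening
rate) for the claudin-2-independent events present in all monolayers, and
`membraneChannelModel()` (15 pS) for off-junction apical membrane channels,
whose opening rate is four-fold higher at positive potentials to reproduce
the observed voltage asymmetry in event frequency. Their kinetics are not
characterized in the source data; the defaults were chosen once as
plausible values that give clearly resolvable event statistics.

## The recording emulator

`renderCurrent()` converts per-channel state paths into a sampled trace:

$$I(t) = \sum_{\text{channels}} \gamma_i(t)\,\frac{V(t) - V_{rev,i}}{1000}
 + \frac{V(t)}{R_{seal}} + \varepsilon(t),$$

in pA with conductances in pS, voltages in mV and the seal resistance in
GΩ. Negative current corresponds to cations moving towards the recording
electrode, so an open 90 pS channel at −100 mV is a −9 pA deflection and a
30 GΩ seal leak contributes −3.3 pA. The sum is low-pass filtered and, when
rendered at an oversampled internal rate, block-averaged to the output rate.

The analog anti-alias stage is emulated as a 4-pole Bessel low-pass filter
(the standard patch-clamp choice: near-linear phase, no ringing on event
edges), discretized by the bilinear transform with frequency pre-warping so
the −3 dB point lands exactly on the cutoff. Defaults: 25 kHz sampling,
5 kHz cutoff; a 500 Hz re-filtering stage (`refilterTrace()`) is used for
off-junction analysis. Baseline noise is additive Gaussian with the
configured SD (0.6 pA) *after* filtering — the white noise injected before
the filter is scaled up by the filter's measured noise gain — chosen so
that 4 pA events are comfortably resolvable at 5 kHz while 2 pA events need
the 500 Hz stage, matching the observed behaviour.

Temperature is treated phenomenologically: a single scale factor multiplies
all gating rates and the expected active-channel count. No Arrhenius model
is fitted, because none is available to constrain one. Note that uniform
rate scaling leaves the stationary distribution (hence per-channel $P_o$)
unchanged, so the NPo reduction on cooling isolates the active-channel
count effect.

## Scenarios

`makeScenario()` packages the study conditions and returns the trace
together with exact per-class ground-truth dwell records:

- `cldn2_induced`: 3 claudin-2 channels + 1 independent channel. Three
  slots is a deliberate minimal choice — the real channel count per patch is
  unknown; only expression-proportional NPo is constrained.
- `cldn2_suppressed` / `caco2_kd`: the same 3 slots, each expressed with
  probability 1/8 (drawn per recording), so the expected NPo falls by
  87.5%. A fractional expected count cannot be realized with a fixed
  integer number of channels; per-slot expression draws realize it exactly
  in expectation while single recordings show 0–3 channels, reproducing the
  "infrequent events" phenotype.
- `parental`: no claudin-2-class channels at all.
- `la3_block`: lanthanum blocks every claudin-2 channel instantaneously at
  onset (claudin-2 NPo is exactly 0 afterwards).
- `mtset_i66c`: MTSET derivatization of the I66C pore mutant deactivates
  channels with an exponentially decaying active count (timescale 7 s), so
  events disappear within ~20 s of onset. Each channel is blocked
  completely or not at all, mirroring the all-or-none block observed.
- `cooled`: rates and expected active count scaled by 0.63 (the claudin-2
  class only; the ~4 pA class is cold-resistant).
- `off_junction`: one 15 pS membrane channel, −100 mV then +100 mV holds.

Scenario randomness derives entirely from the seed. Replicate seeds are
passed through one Lehmer (MINSTD) multiplicative step before seeding the
generator because the first draws after `set.seed(s)` and `set.seed(s+1)`
are strongly correlated in R's Mersenne twister — without this, a run of
consecutive replicate seeds can share the same binomial channel draw.

## Idealization

`detectEvents()` implements half-amplitude threshold idealization: after
baseline subtraction the rectified current is quantized to integer
multiples of the unitary amplitude (a sample belongs to level $k$ when it
lies within half an amplitude of $k\gamma V/1000$), which resolves stacked
openings; level runs shorter than the dead time (default 0.2 ms, limited by
the 5 kHz filter risetime) are merged into their neighbours. Event
amplitudes are means over the event interior, excluding two samples per
edge to avoid filter transients. No missed-event correction is applied —
durations below the dead time are simply excluded, and the fitted time
constants inherit the corresponding upward censoring bias (about +0.2 ms;
the acceptance bounds absorb it).

The baseline is the mode of the sample density, robust to roughly 30% open
time; when no dominant mode exists (e.g. a trace open throughout) the
estimator warns and falls back to the median. Whether the seal-leak current
should be subtracted before amplitude measurement is ambiguous in standard
practice; we always subtract the estimated baseline, which includes the
leak at a fixed holding potential.

Two-class analysis splits events at 6 pA — the midpoint between the ~9 and
~4.3 pA amplitude populations at ±100 mV. For claudin-2-class NPo the
detector runs at the 9 pA unitary amplitude, whose 4.5 pA half-amplitude
threshold excludes the small class (the thresholding strategy used on the
bench); for small-class statistics it runs at 4.3 pA followed by the
amplitude cut. NPo is computed exactly as

$$NP_o = \frac{\sum (\text{open time} \times \text{channels open})}
 {\text{total record time}}.$$

## Kinetics

All-points histograms use fixed 0.1 pA bins normalized to record duration
(samples/s). Gaussian mixtures are fitted to the binned density by
weighted EM from five deterministic starting configurations (weighted
quantiles, equal spacing, shifted variants), keeping the best likelihood —
deterministic given the data. Component SDs are floored at one bin width;
hitting the floor flags a degenerate fit.

Dwell-time fits use raw, unbinned durations by maximum likelihood; the
log-binned histogram (2 bins per decade, chosen to sample prolonged closed
durations) is display-only. Fitting raw durations is statistically
equivalent to ML on finely binned histograms but better posed, and the
one-component estimate is the closed-form sample mean. The two-component
exponential mixture is fitted by EM from a deterministic split at the
geometric mean. One vs two components is decided by a likelihood-ratio
test at $\alpha = 0.01$ (2 df); the default scenario yields one open and
two closed states, with the fast and slow closed components labelled
$c_{transient}$ and $c_{stable}$. Dwell fits default to per-recording use;
pooling durations across recordings is possible by concatenation but the
package takes no position on it.

## Ramps and reversal potentials

Ramp analysis follows the bench procedure: repetitive 1 s ramps from −100
to +100 mV, internally oversampled ten-fold and block-averaged down (the
100 kHz → 10 kHz averaging step), sweeps classified as event-containing or
event-free, the mean event-free sweep subtracted pointwise (removing seal
leak and any capacitive component), and a least-squares line fitted through
the event samples. Event samples are selected by the half-amplitude
criterion with a voltage-scaled threshold, floored near $V_{rev}$ at four
times a first-difference noise estimate (insensitive to the events
themselves); two samples at each event edge are excluded as filter
transients, which removes a systematic ~10% underestimate of the slope.
The reversal potential is the fitted zero crossing and the slope is
reported in pS.

## Electrochemistry

The GHK reversal potential for the Na⁺/Cl⁻ (plus at most one substituted
monovalent cation) system is

$$V_{rev} = \frac{RT}{F}\ln\frac{P_{Na} a_{Na,b} + P_X a_{X,b} + P_{Cl} a_{Cl,a}}
 {P_{Na} a_{Na,a} + P_X a_{X,a} + P_{Cl} a_{Cl,b}},
 \qquad V = V_{apical} - V_{basal}.$$

Activities use NaCl coefficients 0.755/0.812/0.882 at 135/67.5/13.5 mM,
log-linearly interpolated in concentration between the anchors (and applied
to substituted chloride salts for lack of better data); whether the
original analyses used activities or concentrations is not recorded, so
`useActivities = FALSE` switches to concentrations. Minor buffer ions are
ignored and liquid-junction potentials are set to zero (they are below
1 mV under these conditions). Dilution-potential inversion solves the
strictly monotone forward map by bisection to $10^{-12}$; biionic
substitution is closed-form because the GHK exponential is linear in the
unknown permeability. Absolute Na⁺ permeability uses the Kimizuka–Koketsu
transference form

$$P_{Na} = \frac{RT}{F^2}\, G\, \frac{p}{1+p}\, \frac{1}{a_{Na}},$$

with $G = 1/TER$ in S/cm², $p = P_{Na}/P_{Cl}$ and $a_{Na}$ in mol/cm³ —
verified against its limiting cases ($p \to \infty$ gives $RT G/F^2 a_{Na}$;
linear in $G$). Temperature defaults to 310.15 K.

Equivalent-circuit algebra is plain series/parallel combination over named
pathways with the measured defaults (2.5 MΩ electrode, ~30 GΩ seal leak,
11/25/50 GΩ channel pathways, 0.0045 MΩ monolayer shunt — negligible
against every other pathway).

## Problem sizes and what the tests show

The test suite and the acceptance script choose problem sizes as a
compromise between Monte-Carlo error and runtime, stated here as the
package's own defaults: dwell-kinetics fits use one 500 s single-channel
record (~1100 events, enough for a stable two-component closed fit);
ramp fits use 30–40 sweeps; the suppression comparison uses 32 recordings
of 20 s per condition; the cooling comparison uses 192 recordings per
condition, because the per-recording binomial active-channel draw
dominates its Monte-Carlo error.

The generator emulates the *statistical structure* of the recordings —
amplitudes, kinetics, channel-count regimes, seal leak, filtering, noise —
not their full physics. It does not model strand series/parallel
architecture, amplitude variability between patches, capacitive transients,
baseline drift, or MTSET/temperature chemistry beyond the phenomenological
parameters above. Passing tests therefore demonstrate that the analysis
chain is correct and self-consistent (it recovers known ground truth at
realistic SNR), not that it would be robust to every artifact of bench
data. Degenerate inputs are handled explicitly: all-open traces warn and
fall back to the median baseline; all-equal amplitude data collapse to a
flagged bin-width-floor Gaussian; singular generators (no transitions)
start uniformly; reductions from a zero reference NPo are refused.

## Known limitations

- No missed-event (dead-time) likelihood correction and no full Q-matrix
  global fit of the gating scheme; fitted $\tau$ values carry the
  censoring bias discussed above.
- No hidden-Markov or sub-conductance idealization; the half-amplitude
  detector assumes a known unitary amplitude.
- The event classifier uses total event amplitude, so a stacked pair of
  small-class events (not realizable with the default single independent
  channel) would be classed large.
- GHK algebra is restricted to monovalent Na⁺/Cl⁻ plus one test cation.
- The ABF (Axon Binary Format) ingestion adapter mentioned alongside the
  TSV trace format is not implemented; traces enter via `readTrace()`.
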