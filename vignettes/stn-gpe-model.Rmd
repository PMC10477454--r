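---
title: "The stngpe circuit model: dynamics, calibration and two-site analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The stngpe circuit model: dynamics, calibration and two-site analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stngpe)
```

## The model

`stngpe` simulates the reciprocally coupled subthalamic nucleus (STN) and
external globus pallidus (GPe) under cortical and striatal input, with
synaptic connections organised along a one-dimensional feature
(somatotopic) axis. The package exists to ask how the *structure* of those
connections — intact, partially displaced, or spatially skipping — shapes
cortically evoked responses, and to quantify the width of the "functional
channels" through which cortical inputs are processed.

### Neurons

STN and GPe neurons are adaptive quadratic integrate-and-fire (aQIF) units.
For a GPe neuron,

$$C \dot v = k (v - v_r)(v - v_t) - u_1 + I, \qquad
  \dot u_1 = a\,(b (v - v_r) - u_1),$$

with reset $v \to c$, $u_1 \to u_1 + d$ at $v \ge v_{peak}$. STN neurons
carry a second recovery variable $u_2$ that charges only below a rebound
threshold $\tilde v_r$ (Heaviside-gated) and enters both the membrane
equation (as $-w\,u_2$) and the spike threshold and reset through
$U = (w |u_2| + 1/w)^{-1}$. This produces rebound bursts after release from
hyperpolarisation — mainly through $u_1$, which accumulates a strongly
negative value during sustained hyperpolarisation, with $u_2$ shaping the
burst. Parameter defaults ([gpe_params()], [stn_params()]) are the
reference sets for prototypic GPe and rebound-bursting STN neurons;
per-neuron capacitances are Gaussian with a 10%-of-mean spread
(truncated at 0.2 of the mean, a set of measure ~1e-15 at this spread).
The original parameter table lists the reset potential `c` with time units; it is a
membrane potential and is treated as mV. It also lists a second
coupling `w_tilde = 0`; it is carried but never enters the dynamics.

Cortex (1000 units, 4 Hz) and striatal D2 medium spiny neurons (MSN, 1000
units, 0.67 Hz) are Poisson spike generators.

### Synapses

Synaptic conductances decay exponentially ($\tau \dot g = -g$) and jump by
a fixed increment $G$ when a presynaptic spike *arrives*, one transmission
delay $\lambda$ after it was fired. Conductances are pooled per
(source nucleus x receptor) per target — one state variable per channel,
not per synapse. AMPA and GABA-A currents are ohmic, $g (E - v)$. NMDA
conductances rise as well as decay: a slow ($\tau$ = 100 ms) and a fast
($\tau$ = 2 ms) state are both incremented by $G_{NMDA}$ on arrival, so
the effective conductance $g_{slow} - g_{fast}$ starts at zero, peaks at
$\ln(50) \cdot 200/98 \approx 8$ ms, and is gated by the magnesium block
$B(v) = (1 + 0.28 e^{-0.062 v})^{-1}$. The NMDA peak increments are fixed
ratios of the AMPA peaks: 0.6 (cortex to STN) and 0.36 (STN to GPe). The
increment convention (same $G$ into both states) is the package's choice;
the original formulation does not pin it down, and the standard
difference-of-exponentials form seemed the least surprising reading.

The noise term printed inside the current assembly ("$2\theta C \xi$") is
dimensionally ambiguous — taken literally it drives the GPe baseline to
about 44 Hz, far from the 30.4 Hz operating point the conductances were
fitted to. The package therefore treats it as a typeset artefact of a lost
radical and adds a per-step membrane increment
$\sqrt{2\theta\,\Delta t}\;\mathcal N(0,1)$ mV, independent of $C$, which
gives $\theta$ units of mV$^2$/ms and a GPe baseline near 28 Hz. The
literal reading stays available via `run_simulation(noise = "literal")`.

### Topographic networks

Each nucleus occupies the axis $[-L/2, L/2]$ ($L = 1$) on an equidistant
grid plus tiny uniform offsets ($10^{-4}L$ for generators, $10^{-3}L$ for
STN/GPe) that make all pairwise distances distinct, so nearest-neighbour
wiring is free of ties. Out-degrees are fixed per projection (CTX to STN 3,
MSN to GPe 10, GPe to STN 1, GPe to GPe 20, STN to GPe 3 or 30).

* **N-networks** connect each presynaptic neuron to its nearest
  postsynaptic neurons by coordinate difference.
* **D-networks** re-target a uniformly chosen 10% of edges to the neurons
  nearest the coordinate shifted by $d = 0.15L$. Displaced edges from one
  source take the nearest *distinct* shifted targets; shifted coordinates
  past the axis end clamp to the outermost neuron (there is no
  wrap-around — neurons near the boundary simply have asymmetric
  neighbourhoods, which is why all rate measurements use the centre third
  of the axis).
* **S-networks** skip every second postsynaptic neuron, starting from the
  nearest one, doubling the projection span. The skipping is applied to
  every projection.

Nearest-target selection per presynaptic neuron and global
sort-all-pairs-by-distance construction coincide when only out-degrees are
constrained, which is the case here.

### Stimulation

Cortical stimulation recruits each generator with the Lorentzian profile
$P(s|s_0) = (1 + ((s - s_0)/\sigma_s)^2)^{-1}$, $\sigma_s = 0.05L/\pi$;
recruited generators fire once at onset, superposed on their baseline
stream. A stimulus-evoked cortical spike drives the *closest* MSN through
a rate kernel (latency 10.5 ms): a Gaussian burst (peak 0.145 /ms at
2.1 ms), a silent period, and a linear recovery between 100 and 300 ms
after which the baseline rate resumes. As printed, the recovery ramp rises
to 1/ms — a thousand-fold dimensional mismatch with the baseline branch —
so the default ramp rises from 0 to the baseline rate over the same
interval (continuous with the final branch); the literal form is kept as
`msn_kernel_params(literal_ramp = TRUE)`. A new stimulus-evoked cortical
spike restarts the kernel (memoryless); baseline cortical spikes never
trigger it. Protocols are periodic (1.7 s) trains of single pulses or
priming/test pulse pairs at $\mp\Delta s/2$ separated by $\Delta t$.

### Integration and seeds

Euler–Maruyama at $\Delta t = 0.05$ ms; reset times are the spike times;
threshold crossings are detected after the full step (no within-step
interpolation). Delays are rounded to integer steps and delivered through
per-projection ring buffers. Poisson generators draw geometric waiting
times equivalent to per-step Bernoulli thinning (rate x dt <= 2e-4, so the
thinning bias is negligible). Two seed domains keep structure and dynamics
independent: the circuit seed fixes layouts and edge lists; the run seed
drives heterogeneity (capacitances, initial potentials uniform between
$v_r$ and $v_t$ — the initial-condition distribution is the package's
choice, left open in the original formulation; $u_1 = u_2 = 0$) and, via a separate
argument, noise and Poisson streams, so trials of one experiment share
heterogeneity but not noise. Population-rate halving checks at
$\Delta t = 0.025$ ms agree within 5%.

## Conductance calibration

Peak conductances are fitted in four stages, each against a published mean
firing rate, with a Nelder–Mead simplex in log-conductance space
(positivity by construction) and tolerance 0.1 on the rate mismatch:

1. isolated cortex-to-STN circuit: target 20.7 Hz (GPe-lesioned rats);
2. plus GPe as 30.4 Hz Poisson generators: target 11.8 Hz;
3. STN as 11.8 Hz Poisson generators driving the GPe with all GABA to GPe
   removed: target $1.55 \times 30.4 = 47.12$ Hz (GABA-antagonist
   disinhibition);
4. intact circuit, fitting the striato- and intra-pallidal conductances by
   minimising $\Delta R = |r_{STN} - 11.8|/9.1 + |r_{GPe} - 30.4|/11.4$.

Each candidate is evaluated as the centre-subset rate over the last
quarter of a 40 s run, averaged over independent initial conditions
(default 4; the reference protocol used 12 — `n_init` restores it).
Stage 3's "no GABAergic input to GPe" is realised by zeroing the MSN-to-GPe
and GPe-to-GPe conductances. Two published values exist for the
striato-pallidal conductance in the focused configuration (5.54 nS in the
original calibration account, 5.81 nS in its parameter table); both are shipped
([conductance_preset()]), with 5.54 — the value co-reported with the
achieved rates — as the default.

Forward checks ([verify_conductances()]) simulate each reduced circuit at
the published conductances. In this implementation they land within the
biological spread of the target rates (9.1 Hz STN, 11.4 Hz GPe — the
normalisers of $\Delta R$) but not on top of them: the isolated-circuit
STN rate comes out near 15 Hz rather than 20.7 Hz. The printed equations
and parameter tables, cross-checked here against an independent plain-R
integrator and against step-size refinement, imply a cortico-subthalamic
drive about half of what the published (conductance, rate) pairs require,
and no printed convention closes that gap without overshooting the
GPe-side checks, so the package reports what its equations produce rather
than tuning hidden factors. Re-running the calibration
([run_stage()]) instead recovers conductances whose achieved rates meet
every target within 1 Hz.

## Analysis layer

**PSTHs** ([compute_psth()]) are per-bin spike probabilities (1 ms bins)
relative to the closest stimulus onset, averaged over stimuli and then
over trials (per-trial PSTHs are averaged, not pooled spikes).
**Spatio-temporal maps** ([spatiotemporal_map()]) average PSTHs within
coordinate bins (0.01L for STN/GPe, 0.001L for generators). **Rate
histograms** ([rate_distribution()]) collect per-neuron rates over a
stationary window, pooled across trials.

The **two-site analysis** ([modulation_surface()]) compares the response
at the test site with and without a preceding priming stimulus:
$L_{base}$ integrates the squared difference of the window-averaged
responses (width $A = 0.045L$ around the test site) over the 190 ms
($T^-$) before the test onset, $L_{re}$ over the 200 ms ($T^+$) after it.
Integrals are left Riemann sums on the 1 ms grid (within $10^{-3}$ of a
trapezoid rule on smooth fixtures); only positive inter-stimulus intervals
are used. One printed form of the post-test integral references the
statistic itself inside its own integrand and flips the interval sign;
both are read as notational slips, and the response functions $F$ with
$\Delta t > 0$ are used in both integrals.

**Channel width** ([channel_width()]) is deliberately operationalised
(the source treats it qualitatively): at a saturated interval
(default: the largest $\Delta t$ on the surface, with $L_{base}$ — the
floor crossing is invariant under taking its logarithm; $L_{re}$ at
$\Delta t \approx 30\text{--}40$ ms is the more sensitive switchable
alternative), the width is the smallest $\Delta s$ whose
statistic falls below a noise floor estimated from zero-priming
surrogates (independent one-site run pairs), with a three-standard-
deviation margin. A profile that never crosses the floor within the
scanned range is flagged as unbounded rather than extrapolated.

## Problem sizes and what the tests show

The shipped test suite runs scaled-down versions of the reference
experiments: 30–50 stimuli and 1–3 trials for PSTH structure and lesion
direction checks (the reference protocol is 500 stimuli x 5 trials), 16
trials x 9 s for rate histograms (reference 96 trials), a 4 x 4
$(\Delta t, \Delta s)$ grid at 32 stimuli for the two-site sweep
(reference: 500 pairs x 24 trials), and 10 s settling where full
stationarity is not at issue (the slowest intrinsic timescale, the GPe
recovery variable, is ~0.2 s). One check cannot be scaled down in its stimulus count: the
displaced-network secondary modulation maximum is a ~1e-4 signal over a
noise floor that shrinks as 1/(stimuli x trials), so it is resolved at the
full 500-pair protocol with 2 trials; there the inter-stimulus period is
shortened from 1.7 s to 0.9 s, which is still far beyond the ~600 ms
evoked-response recovery and so leaves the modulation statistics
unchanged (verified against the 1.7 s period) while halving the run. At these sizes the qualitative signatures —
response feature order, lesion shift directions, D-network multimodality
and displaced-band responses, and the $L_{base}$ dependence on
$(\Delta t, \Delta s)$ — are all resolved above the estimation noise, but
the surfaces are far noisier than reference-scale ones; quantitative use
should restore the reference counts.

The synthetic conditions the generators emulate are those of the modelled
experiments (anesthetised-rat firing rates, periodic electrical-stimulation
trains). Real recordings differ in ways the model deliberately omits:
no 3-D anatomy, a single GPe and a single STN cell type, no arkypallidal
population, no STN-to-striatum feedback, no plasticity, and stationary
Poisson cortical statistics. Passing tests therefore validate the
implementation and its internal logic, not those biological
simplifications.

## Worked example

```{r example}
circ <- build_circuit(n_stn_gpe = 3, network = "N", seed = 1)
rec <- run_simulation(circ, duration = 40000, seed = 1)
mean_rate(rec, "stn", c(30000, 40000))   # ~11 Hz
mean_rate(rec, "gpe", c(30000, 40000))   # ~28 Hz

prot <- stimulation_protocol("one-site", n_stimuli = 50, warmup = 10000)
stim <- run_trials(circ, 3, seed = 2, protocol = prot)
psth <- compute_psth(stim, "stn")
F <- window_average_response(psth, s = 0, A = 0.045)
plot(psth$lag, F, type = "h", xlab = "lag (ms)",
     ylab = "spike probability / ms")
```
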