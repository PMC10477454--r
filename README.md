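# stngpe

Spiking-network simulation and analysis of the subthalamo-pallidal circuit
with topographically organised synaptic connectivity.

## What it is for

Cortical stimulation evokes a stereotyped response sequence in the basal
ganglia of rodents and primates: subthalamic (STN) neurons show an early
excitation (hyperdirect cortico-subthalamic pathway), a late excitation and
a long inhibition (indirect cortico-striato-pallidal pathway), while
pallidal (GPe) neurons show an early excitation, an inhibition and a late
excitation. `stngpe` implements a computational model of this circuit for
researchers who want to relate such evoked responses to the *structure* of
the underlying synaptic wiring: intact somatotopic (N), partially displaced
(D), and spatially skipping (S) network topologies, and a two-site
stimulation protocol that estimates the width of the functional channels in
which cortical inputs are processed.

The model:

- **Neurons.** STN and GPe are adaptive quadratic integrate-and-fire
  neurons: `C v' = k (v - v_r)(v - v_t) - u1 [- w u2] + I` with linear
  recovery variables and after-spike resets; the STN's second recovery
  variable is gated below a rebound threshold and makes it burst after
  hyperpolarisation. Cortex (CTX) and striatal D2 neurons (MSN) are Poisson
  generators (4 Hz / 0.67 Hz).
- **Synapses.** Conductance-based AMPA, NMDA (difference of exponentials,
  magnesium block `B(v) = 1/(1 + 0.28 e^{-0.062 v})`) and GABA-A, with
  per-pathway delays and instantaneous per-arrival increments; delivery
  through ring-buffered delay queues.
- **Networks.** 1000 CTX, 1000 MSN, 100 STN, 300 GPe on a feature axis
  `[-1/2, 1/2]`, wired by nearest-coordinate rules with fixed out-degrees
  (CTX->STN 3, MSN->GPe 10, GPe->STN 1, GPe->GPe 20, STN->GPe 3 or 30).
- **Calibration.** A four-stage Nelder-Mead pipeline fits the five peak
  conductances to published firing rates of reduced circuits (20.7 Hz
  isolated STN; 11.8 Hz with pallidal inhibition; 47.12 Hz disinhibited
  GPe; intact-circuit mismatch `dR = |r_STN - 11.8|/9.1 + |r_GPe - 30.4|/11.4`).
- **Analysis.** Peristimulus time histograms, per-neuron rate
  distributions, spatio-temporal response maps `p(t, s)`, and the two-site
  priming/test statistics `L_base`/`L_re` (integrated squared response
  differences before/after the test stimulus) from which a functional
  channel width is read.

The integration engine is compiled (Rcpp); a 40 s simulation of the full
circuit at dt = 0.05 ms takes on the order of ten seconds.

## Worked example

```r
library(stngpe)

circ <- build_circuit(n_stn_gpe = 3, network = "N", seed = 1)
rec  <- run_simulation(circ, duration = 40000, seed = 1)
mean_rate(rec, "stn", c(30000, 40000))
#> [1] 10.76364
mean_rate(rec, "gpe", c(30000, 40000))
#> [1] 27.644
```

These are the spontaneous mean rates (Hz) of the centre third of STN and
GPe neurons in the intact calibrated network over t in [30, 40) s —
the model's operating point, to be compared with the 11.8 +- 9.1 Hz (STN)
and 30.4 +- 11.4 Hz (GPe) measured in anesthetised rats.

```r
prot <- stimulation_protocol("one-site", n_stimuli = 50, warmup = 10000)
stim <- run_trials(circ, 3, seed = 2, protocol = prot)
psth <- compute_psth(stim, "stn")
F <- window_average_response(psth, s = 0, A = 0.045)
round(c(baseline = mean(F[psth$lag < -5]),
        early    = mean(F[psth$lag >= 2 & psth$lag < 8]),
        late_exc = mean(F[psth$lag >= 40 & psth$lag < 55]),
        late_inh = mean(F[psth$lag >= 80 & psth$lag < 250])), 4)
#> baseline    early late_exc late_inh
#>   0.0135   0.0617   0.0174   0.0111
```

Centre-STN spike probability per 1 ms bin: the early excitation (~4x
baseline within 10 ms of the stimulus), the weaker late excitation near
40-55 ms, and the long inhibition below baseline — the canonical evoked
pattern. Lesion experiments (`lesion_inputs()`), Poisson substitutions
(`substitute_poisson()`), D/S topologies and the two-site sweep
(`modulation_surface()`, `channel_width()`) follow the same pattern; see
the vignette in `vignettes/stn-gpe-model.Rmd`.

A thin command-line wrapper ships in `inst/cli/stngpe`
(`simulate` / `calibrate` / `verify` subcommands over YAML/JSON configs).

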