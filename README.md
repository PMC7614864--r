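# ca3pop

Heterogeneous populations of conductance-based CA3 pyramidal neuron
models, and the emergence of complex spike bursting under ion-channel
degeneracy.

Hippocampal CA3 pyramidal neurons fire complex spike bursts (CSB):
several action potentials within a few tens of milliseconds, riding a
depolarizing ramp, with decrementing spike amplitude. `ca3pop` asks the
population-level question: which combinations of ion-channel densities
produce a neuron with the full signature CA3 phenotype, and which
channels control its bursting? It is aimed at computational
neurophysiologists who want a self-contained, testable R implementation
of the multi-parametric multi-objective stochastic search (MPMOSS)
workflow: sample many models, keep the ones that look like real CA3
cells, then dissect them.

The pipeline:

1. **Model** — a reduced CA3-like morphology (or any SWC reconstruction)
   discretized by the d-lambda rule, with ten Hodgkin-Huxley mechanisms
   (NaF, KDR, KA, KM, CaL, CaN, CaT, SK, BK, HCN; calcium channels use
   Goldman-Hodgkin-Katz currents), annulus-resolved calcium handling with
   mobile buffer and pump, and colocalized AMPAR-NMDAR synapses with
   magnesium block. The solver (backward-Euler branched-cable solve,
   exponential-Euler gating, 25 us steps) is the package's own, in
   C++ via Rcpp.
2. **Search** — uniform sampling of 14 parameters
   (R_m, R_a, nine channel densities + HCN, pump, buffer) with rejection
   against 11 electrophysiological bounds: resting potential and its
   stability, input resistance `R_in` (V-I slope), sag ratio, impedance
   resonance `f_R`/`Q_R`/`|Z|_max` from a 0-15 Hz chirp
   (`|Z(f)| = |FFT(V)/FFT(I)|`), 250 pA firing rate, and backpropagating
   AP amplitudes at the soma and the 150/300 um apical sites.
3. **Phenotype** — intrinsically-bursting vs regular-spiking
   classification, correlation structure, PCA / t-SNE embeddings, group
   statistics.
4. **CSB** — five induction protocols (somatic 600/900/1200 pA pulse
   trains, dendritic 1000 pA, synaptic 5 Hz) scored per pulse: >= 3 APs in
   25 ms, first-to-second amplitude drop and median-filtered ramp each in
   [10, 30] mV; CSB rate over pulses 2-5.
5. **Virtual knockouts** — one channel conductance (or NMDAR
   permeability) zeroed at a time, percentage changes versus base.

## Worked example

```r
library(ca3pop)

model <- discretize(build_synthetic_morphology())
m <- measure_model(model, default_parameters(), classify = TRUE)
```

For the shipped base model (36 compartments, 5.2e-4 cm^2 membrane area)
this prints, against the validation bounds:

```
 measurement  lower  upper    value   ok
       v_rmp -70.00 -60.00 -67.7985 TRUE
     v_sd_uv   0.00   0.01   0.0000 TRUE
        r_in  60.00 150.00  65.7044 TRUE
         sag   0.94   1.00   0.9719 TRUE
         f_r   1.00   1.76   1.6667 TRUE
         q_r   1.00   1.10   1.0449 TRUE
       z_max  65.00 150.00  67.5024 TRUE
       f_250   4.00  10.00   9.0000 TRUE
       v_ap0  90.00 110.00 104.5399 TRUE
     v_ap150  70.00  90.00  89.4118 TRUE
     v_ap300  60.00  80.00  76.6413 TRUE
base model: 11/11 measurements within bounds; firing class RS
```

i.e. a regular-spiking cell resting at -67.8 mV with 66 MOhm input
resistance, a weak ~1.7 Hz impedance resonance, almost no sag, 9 spikes
to a 1 s 250 pA pulse, and backpropagating APs attenuating from 105 mV
at the soma to 77 mV at 300 um. Driving it with five 900 pA somatic
pulses elicits complex spike bursts with a ~21 mV spike-amplitude drop
and a CSB rate of 0.75:

```r
run <- run_csb_protocol(model, default_parameters(),
                        csb_protocol("somatic900"))
score_csb(run)$pulses
```

The staged analysis lives in `analysis/01_base_model.R` through
`analysis/05_vkm.R` (search, classification, burst induction, knockouts),
each writing tables under `results/`.

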