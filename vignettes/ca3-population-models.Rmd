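---
title: "Population modelling of CA3 pyramidal neurons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population modelling of CA3 pyramidal neurons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ca3pop` builds heterogeneous populations of conductance-based hippocampal
CA3 pyramidal-neuron models and analyses their signature
electrophysiology, with a focus on complex spike bursting (CSB) and on
ion-channel degeneracy: the ability of disparate channel combinations to
produce the same physiological phenotype. This vignette is the package's
own account of the models, the numerics and the design choices; the
`analysis/` scripts in the repository are thin drivers over the functions
described here.

## The model

Each model neuron is a branched passive cable with ten active membrane
mechanisms, discretized into iso-potential compartments by the d-lambda
rule: every section is split into the smallest odd number of segments
shorter than `d_lambda` (default 0.1) times the AC length constant at
`f_lambda` (default 100 Hz). Passive properties are uniform: specific
capacitance 0.75 uF/cm^2, membrane resistivity `R_m` (base 60 kOhm cm^2)
and axial resistivity `R_a` (base 200 Ohm cm).

The channel complement is a fast sodium channel (NaF), delayed-rectifier,
A-type and M-type potassium channels (KDR, KA, KM), L-, N- and T-type
calcium channels (CaL, CaN, CaT) with Goldman-Hodgkin-Katz (GHK)
constant-field currents, small- and big-conductance calcium-activated
potassium channels (SK, BK), and the hyperpolarization-activated HCN
conductance. Distribution rules: NaF, KDR, CaT, CaN, SK and BK are
uniform; CaL is perisomatic (path distance <= 50 um); KM is perisomatic
(<= 100 um); KA switches from proximal to distal gating kinetics at
100 um and rises linearly along the apical tree; HCN rises along the
apical dendrite as `g_h(x) = g_bar (1 + 3x/100)`. Ohmic reversal
potentials are `E_Na` = 50 mV and `E_K` = -91 mV; simulations run at
34 °C with a 25 us step.

Fourteen parameters define a model (two passive constants, ten maximal
conductance/permeability densities, and the total calcium pump density and
buffer concentration); `parameter_bounds()` holds the uniform search
ranges and `default_parameters()` the base values.

### Gating kinetics are data

Channel gating kinetics are not uniquely determined by the measurement
bounds the models must satisfy, and reasonable CA3/CA1 parameterizations
differ between publications. The package therefore treats kinetics as
configuration: `inst/extdata/kinetics/default.yaml` declares, per channel,
the current law, gate exponents, Boltzmann steady-state parameters and
bell-shaped (or, for HCN, sigmoidal) voltage-dependent time constants.
`load_kinetics()` accepts any file with the same schema. The shipped
defaults were written and tuned for this package so that the default
("base") model satisfies all eleven validation bounds below; they are
ordinary Hodgkin-Huxley parameterizations in the standard hippocampal
style, not transcriptions of any published channel file.

Two kinetics choices deserve mention. HCN deactivation is made strongly
asymmetric (sigmoidal tau, ~300 ms near rest but >2 s below -85 mV): this
yields a weak impedance resonance near 1.5 Hz at rest while keeping the
sag ratio of the -250 pA pulse above 0.94, two bounds that pull a
symmetric h-kinetics in opposite directions. CaT activation is placed
depolarized enough (half-activation -37 mV) that its resting window
current is negligible; a resting window current slowly loads the interior
calcium annuli through the buffer and produces a multi-second membrane
drift that is incompatible with the 0.01 uV quiescent-voltage
standard-deviation bound.

### Calcium handling

Each compartment carries four equal-thickness concentric annuli. Free
calcium, free buffer and bound buffer react by mass action (defaults:
k_on 5 /mM/ms, k_off 0.05 /ms, so the buffer Kd is 10 uM), diffuse
radially across annulus interfaces by Fick's law and longitudinally
between adjacent compartments (the buffer is mobile), and a membrane pump
extrudes calcium from the submembrane annulus with Michaelis kinetics
referenced to the 100 nM resting concentration, so the influx-free state
is exactly stationary. The search parameters `totbuf` and `totpp` scale
the total buffer concentration and pump density. Channel and NMDAR
calcium currents feed the submembrane annulus; SK and BK read the
submembrane concentration. With the pump disabled, total calcium is
conserved to better than 1e-6 relative per simulated second (a test
asserts this through the production solver).

The buffer Kd and pump speed were chosen jointly so that (a) the resting
state equilibrates well inside the 5 s stabilization window, (b)
spike-evoked submembrane transients decay over tens of milliseconds,
giving SK-mediated spike-frequency adaptation that keeps the 250 pA
firing rate in its 4-10 Hz window, and (c) burst-evoked calcium clears
between the pulses of the CSB protocols.

### Synapses

Colocalized AMPAR-NMDAR synapses are placed randomly (area-weighted,
seed-reproducible) over the stratum radiatum, defined as apical
compartments with path distance in [50, 300] um. Gating is the normalized
double exponential `s(t) = a [exp(-t/tau_d) - exp(-t/tau_r)]` with
`0 <= s <= 1` (NMDA 5/50 ms, AMPA 2/10 ms); presynaptic events superpose
linearly. Currents are GHK fluxes for sodium, potassium and (NMDA only)
calcium with relative permeabilities P_Na = P_K = 1 and P_Ca = 10.6, and
the NMDA current is scaled by the magnesium block factor
`MgB(v) = [1 + [Mg]_o exp(-0.062 v)/3.57]^{-1}` with 2 mM external
magnesium. The NMDAR:AMPAR ratio of 2 is implemented as a permeability
ratio, permeabilities being the only magnitude parameters in the current
laws. Each synapse is a point source whose permeability is referenced to
a nominal 1e-6 cm^2 contact area; the default AMPAR permeability
(2.5e-6 cm/s) gives unitary currents of a few tens of pA at rest.

One caveat the implementation makes explicit: with the stated ionic
composition the plain GHK mixture current of the NMDAR reverses at
+4.05 mV, not exactly 0 mV (the AMPAR reverses at -2.27 mV). The 0 mV
figure conventionally quoted for glutamatergic synapses is nominal; a
sum of constant-field fluxes with a 10.6-fold calcium permeability over a
2 mM calcium gradient necessarily pulls the reversal a few millivolts
positive. The test suite pins the computed values rather than the nominal
one.

## Numerics

The integrator (in C++ via Rcpp) advances the voltage system by a
backward-Euler solve of the branched cable equation using a
tree-structured (Hines-ordered) direct elimination each step — ohmic
conductances enter the linear system implicitly, GHK channel and synaptic
currents explicitly at the current voltage; gates advance by exponential
Euler with pre-tabulated steady states and step factors (0.5 mV grid,
linear interpolation); the calcium reaction-diffusion system sub-steps
after the membrane update with all geometric coupling coefficients
precomputed. The step is fixed at 25 us (halving it moves the somatic
spike peak by less than one step; a convergence test asserts this). A
5 s stimulus-free stabilization precedes every protocol; the settled
state is computed once per model and shared across its protocols, which
is exact because protocols never modify the model. Divergence (non-finite
or >500 mV voltages) aborts a run with a time stamp; negative
concentrations flag the calcium step as unstable rather than being
silently clamped.

## Measurements and validation

The validation battery follows standard intrinsic-excitability procedure:
resting potential and its standard deviation over the 5-6 s quiescent
window; input resistance as the V-I slope of -50..+50 pA, 300 ms steps
(steady state = mean of the last 10% of the pulse); sag ratio of the
-250 pA, 800 ms response (steady/peak deflection from baseline);
impedance amplitude |Z(f)| = |FFT(V)/FFT(I)| under a 100 pA peak-to-peak
chirp sweeping 0-15 Hz in 15 s, yielding the resonance frequency f_R
(band argmax), strength Q_R (|Z|(f_R)/|Z|(0.5 Hz), 0.5 Hz value
interpolated between FFT bins) and |Z|_max; the 250 pA x 1 s firing rate;
and backpropagating AP amplitudes (first-AP peak minus local baseline) at
the soma and at the apical sites nearest 150 and 300 um under a 1 nA x
50 ms somatic pulse. A model is valid iff all eleven measurements fall
inside their inclusive bounds (`measurement_bounds()`). Eleven further AP
measurements (latency, first ISI, AHP, half-width for regular-spiking
models from the first spike after 500 ms, threshold at the 20 V/s
upstroke crossing, and dV/dt extremes at three sites) characterize valid
models.

Spike detection — used throughout but rarely defined operationally in the
electrophysiology literature — is an upward crossing of -20 mV whose
local maximum reaches 0 mV, with a 1 ms refractory separation; the
criterion tolerates the within-burst amplitude decrements of complex
spike bursts (tens of mV). The 0-0.01 uV bound on the quiescent-voltage
standard deviation is retained verbatim as a numerical-stability check;
the shipped base model meets it with roughly a factor-of-three margin
after 5 s of stabilization.

## The search, phenotypes, bursts and knockouts

`run_search()` is pure rejection sampling: each row draws the 14
parameters uniformly within bounds (per-row seeds derive from the global
seed and the row index, so rows are independent, chunkable and exactly
reproducible), measures the model and validates it. Protocols run
cheapest-first and a row is rejected at its first out-of-bounds
measurement; valid models are always fully measured, so re-simulating a
valid row reproduces its measurement vector bit-for-bit. At the desk
scale used in the tests and scripts (200 models, ~30-compartment reduced
morphology) a search takes on the order of ten minutes on one CPU; the
yield is a few percent, as expected when eleven joint criteria prune a
14-dimensional uniform prior.

Valid models are classified from the 240 pA x 5.5 s somatic response:
intrinsically bursting (IB) if three or more consecutive spikes fall
within 25 ms and the first-to-second amplitude drop within that window
exceeds 5 mV (the paper-style rule gives no numeric threshold; 5 mV
separates the ~10 mV within-burst decrements from spike-height jitter),
otherwise regular spiking (RS). Population structure is summarized by
Pearson correlation matrices with their `choose(k, 2)` unique pairs, by
PCA (deterministic, largest-loading-positive sign convention) and by an
exact O(n^2) t-SNE written for this package (no compiled t-SNE
implementation is available in the supported R stack; exact gradients are
entirely adequate for populations of a few hundred models). Unpaired
two-group comparisons use the Wilcoxon rank-sum test: the source
literature names a signed-rank test for the IB-vs-RS contrast, but those
groups are unpaired and of unequal size, which a signed-rank design
cannot accommodate; the one-sample signed-rank test against zero is used
where it is well-posed, namely for knockout changes versus a no-change
null.

CSB induction uses five protocols: five somatic pulses of 600, 900 or
1200 pA (100 ms on, 80 ms off), five dendritic pulses of 1000 pA at the
~150 um apical site (50/50 ms), and synchronous 5 Hz stimulation of the
100 stratum-radiatum synapses (five events, 200 ms apart). A pulse shows
a valid burst iff (1) three or more spikes fall within some sliding 25 ms
window inside the pulse — the sliding window is the stricter,
burst-faithful reading of "three or more APs in 25 ms" — (2) the first-
minus-second AP amplitude (baseline-referenced) lies in [10, 30] mV, and
(3) the ramp amplitude lies in [10, 30] mV, where the ramp is the peak of
the 0.5 s-window median-filtered trace (computed on a 1 kHz decimated,
reflect-padded copy; a fixture test pins its fidelity to 0.5 mV) minus
the resting potential. The first pulse is excluded from the CSB rate,
which is the valid fraction of pulses 2-5. Upper bounds are enforced
exactly as stated even though they read physiologically as typical
ranges; notably, the default base model's synaptic protocol produces
bursts whose amplitude drop slightly exceeds the 30 mV cap, so the base
model is synaptically "too bursty" to validate while its 900 and 1200 pA
somatic protocols give a CSB rate of 0.75.

Virtual knockouts zero exactly one maximal conductance (eight channels;
NaF and KDR are exempt so knockouts can still spike) or the NMDAR
permeability (AMPAR left intact), re-run a CSB protocol under identical
seeds and synapse placement, and report percentage changes in the
amplitude drop, ramp and CSB rate; an exact-equality audit confirms every
non-target parameter is untouched. Per-model mean burst quantities are
taken over pulses 2-5 with per-pulse values retained. The paired
+/-NMDAR calcium comparison records submembrane calcium at the
compartment hosting the most synapses.

## The synthetic-data generators

`gen_trace()` builds voltage traces with machine-readable ground truth:
piecewise-linear (triangular) spike templates with configurable rise and
fall slopes — chosen over smooth templates because they make the
threshold crossing, the full width at half maximum
(`h/2 (1/m_rise + 1/m_fall)`) and the dV/dt extremes exactly analytic —
optional trapezoid ramp plateaus, burst patterns, after-hyperpolarization
dips and seeded noise. `gen_population_table()` draws multivariate-normal
surrogate tables realizing a requested correlation matrix (Cholesky
construction). `gen_passive_fixture()` wraps a single-compartment RC cell
together with its closed-form step response and impedance, serving as the
independent oracle for the solver and the measurement battery.

These generators emulate trace morphology and population correlation
structure, not biophysics: passing the measurement and classifier tests
on them demonstrates that the analysis operators compute what they claim
on known ground truth, but says nothing about whether real CA3 dynamics
are captured — that evidence comes from the solver oracles (closed-form
RC and cable responses, conservation laws) together with the base model's
validation against the physiological bounds.

## Scale, limitations and known gaps

The study conditions are kept verbatim where stated (25 us step, 5 s
stabilization, protocol amplitudes and timings, parameter and validation
bounds, 100 synapses at 5 Hz); the scaled-down choices are the reduced
~30-compartment synthetic morphology (a tapered-trunk, two-oblique,
two-basal-cylinder reduction with ~5e-4 cm^2 membrane area, in place of a
full reconstruction) and the 200-model search size used by the tests and
scripts. Channel gating kinetics are package defaults rather than
reproductions of the original models' (unpublished in numerical form), so
population-level yields, IB/RS proportions and knockout effect sizes are
not expected to match the source study quantitatively; the pipeline's
contracts — measurement definitions, validation logic, burst scoring,
scheduling arithmetic, determinism — are what the tests pin down.
Axonal compartments, stochastic gating, short-term plasticity and
endoplasmic-reticulum calcium stores are out of scope.
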