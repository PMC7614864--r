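# Colocalized AMPAR-NMDAR synapses: GHK multi-ion currents, magnesium
# block, normalized double-exponential gating, random stratum-radiatum
# placement and presynaptic train stimulation.

#' Magnesium block factor of the NMDA receptor
#'
#' `MgB(v) = [1 + [Mg]_o exp(-0.062 v) / 3.57]^{-1}` with `[Mg]_o` in mM
#' and `v` in mV; strictly increasing in `v`, in (0, 1).
#'
#' @param v membrane potential (mV), vectorized.
#' @param mg_out extracellular magnesium (mM).
#' @return unblocked fraction.
#' @export
mg_block <- function(v, mg_out = 2) {
  1 / (1 + mg_out * exp(-0.062 * v) / 3.57)
}

#' Normalized double-exponential synaptic gating variable
#'
#' `s(t) = a [exp(-t/tau_d) - exp(-t/tau_r)]` with the normalization `a`
#' chosen so the kernel peaks at exactly 1 (at
#' `t* = tau_r tau_d/(tau_d - tau_r) log(tau_d/tau_r)`).
#'
#' @param t time since the presynaptic event (ms), vectorized; negative
#'   times return 0.
#' @param tau_r,tau_d rise and decay time constants (ms), `tau_d > tau_r`.
#' @return gating value in `[0, 1]`.
#' @export
syn_gate <- function(t, tau_r = 5, tau_d = 50) {
  if (tau_d <= tau_r) stop("tau_d must exceed tau_r")
  a <- syn_gate_norm(tau_r, tau_d)
  ifelse(t < 0, 0, a * (exp(-t / tau_d) - exp(-t / tau_r)))
}

#' Peak time and normalization of the double-exponential kernel
#' @inheritParams syn_gate
#' @return `syn_gate_peak_time`: argmax (ms); `syn_gate_norm`: the factor
#'   `a` making the peak exactly 1.
#' @export
syn_gate_peak_time <- function(tau_r = 5, tau_d = 50) {
  if (tau_d <= tau_r) stop("tau_d must exceed tau_r")
  tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
}

#' @rdname syn_gate_peak_time
#' @export
syn_gate_norm <- function(tau_r = 5, tau_d = 50) {
  tp <- syn_gate_peak_time(tau_r, tau_d)
  1 / (exp(-tp / tau_d) - exp(-tp / tau_r))
}

# nominal synaptic contact area (cm^2) referencing permeability densities
.A_SYN <- 1e-6

#' Synapse population specification
#'
#' @param pbar_ampa maximal AMPAR permeability (cm/s).
#' @param nmda_ratio NMDAR:AMPAR permeability ratio (default 2).
#' @param ampa_tau_r,ampa_tau_d AMPAR kernel time constants (ms).
#' @param nmda_tau_r,nmda_tau_d NMDAR kernel time constants (ms).
#' @param ions an [ion_composition()].
#' @return a `synapse_spec` list.
#' @export
synapse_spec <- function(pbar_ampa = 2.5e-6, nmda_ratio = 2,
                         ampa_tau_r = 2, ampa_tau_d = 10,
                         nmda_tau_r = 5, nmda_tau_d = 50,
                         ions = ion_composition()) {
  stopifnot(ampa_tau_d > ampa_tau_r, ampa_tau_r > 0,
            nmda_tau_d > nmda_tau_r, nmda_tau_r > 0,
            pbar_ampa >= 0, nmda_ratio >= 0)
  structure(list(pbar_ampa = pbar_ampa,
                 pbar_nmda = nmda_ratio * pbar_ampa,
                 nmda_ratio = nmda_ratio,
                 ampa_tau_r = ampa_tau_r, ampa_tau_d = ampa_tau_d,
                 nmda_tau_r = nmda_tau_r, nmda_tau_d = nmda_tau_d,
                 ions = ions), class = "synapse_spec")
}

#' NMDA receptor current components (GHK, with magnesium block)
#'
#' Sodium, potassium and calcium components, each
#' `Pbar_NMDA * P_ion * s(t) * MgB(v) * GHK flux`; the calcium component is
#' the fraction that feeds the submembrane calcium annulus during
#' simulation.
#'
#' @param v membrane potential (mV).
#' @param t time since the presynaptic event (ms).
#' @param spec a [synapse_spec()].
#' @param ca_in submembrane calcium (mM).
#' @return named vector (`i_na`, `i_k`, `i_ca`) of current densities
#'   (uA/cm^2 referenced to the synaptic contact area; outward positive).
#' @export
nmda_current <- function(v, t, spec = synapse_spec(), ca_in = 100e-6) {
  io <- spec$ions
  s <- syn_gate(t, spec$nmda_tau_r, spec$nmda_tau_d) * mg_block(v, io$mg_out)
  P <- spec$pbar_nmda * s
  c(i_na = ghk_current(v, P * io$p_na, io$na_in, io$na_out, 1, io$temp_K),
    i_k = ghk_current(v, P * io$p_k, io$k_in, io$k_out, 1, io$temp_K),
    i_ca = ghk_current(v, P * io$p_ca, ca_in, io$ca_out, 2, io$temp_K))
}

#' AMPA receptor current components (GHK, no magnesium dependence)
#'
#' @inheritParams nmda_current
#' @return named vector (`i_na`, `i_k`).
#' @export
ampa_current <- function(v, t, spec = synapse_spec()) {
  io <- spec$ions
  s <- syn_gate(t, spec$ampa_tau_r, spec$ampa_tau_d)
  P <- spec$pbar_ampa * s
  c(i_na = ghk_current(v, P * io$p_na, io$na_in, io$na_out, 1, io$temp_K),
    i_k = ghk_current(v, P * io$p_k, io$k_in, io$k_out, 1, io$temp_K))
}

#' Place synapses randomly in a region, area-weighted
#'
#' Samples `n` synapse locations over the compartments carrying the region
#' label, with probability proportional to membrane area; reproducible for
#' a fixed seed.
#'
#' @param model a `compartmental_model`.
#' @param n number of synapses (default 100).
#' @param region region label; default `"apical_sr"` (stratum radiatum).
#' @param seed RNG seed.
#' @param spec a [synapse_spec()].
#' @return a `synapse_set`: data frame of synapse locations plus the spec.
#' @export
place_synapses <- function(model, n = 100, region = "apical_sr",
                           seed = 1, spec = synapse_spec()) {
  if (n < 1) stop("need at least one synapse")
  comps <- which(model$comp$region == region)
  if (!length(comps)) stop("region '", region, "' has no compartments")
  w <- model$comp$area_cm2[comps]
  loc <- withr_seed(seed, sample(comps, n, replace = TRUE, prob = w))
  structure(list(loc = loc, region = region, seed = seed, spec = spec,
                 train = NULL), class = "synapse_set")
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Attach a presynaptic event train to a synapse set
#'
#' Default: five synchronous events at 5 Hz (200 ms intervals) delivered to
#' every synapse, the synaptic complex-spike-burst induction frame.
#'
#' @param syns a `synapse_set`.
#' @param times event times (ms after settle); default `0, 200, ..., 800`.
#' @return the `synapse_set` with a train.
#' @export
synaptic_train <- function(syns, times = seq(0, 800, by = 200)) {
  syns$train <- sort(times)
  syns
}

# C++-facing synapse block: permeabilities aggregated per compartment
# (all synapses share the synchronous kernel, so currents sum linearly).
synapse_net_block <- function(syns, config) {
  if (is.null(syns$train))
    stop("synapse set has no presynaptic train; see synaptic_train()")
  spec <- syns$spec
  io <- spec$ions
  # each synapse is a point source: its permeability (cm/s, referenced to
  # the nominal contact area A_SYN) is pre-multiplied by that area so the
  # core computes absolute currents independent of host compartment size
  agg <- tapply(rep(1, length(syns$loc)), syns$loc, sum)
  comp <- as.integer(names(agg))
  count <- as.numeric(agg)
  list(enabled = TRUE, comp = comp - 1L,
       pbar_ampa = count * spec$pbar_ampa * .A_SYN,
       pbar_nmda = count * spec$pbar_nmda * .A_SYN,
       event_times = as.numeric(syns$train),
       ampa_tau_r = spec$ampa_tau_r, ampa_tau_d = spec$ampa_tau_d,
       nmda_tau_r = spec$nmda_tau_r, nmda_tau_d = spec$nmda_tau_d,
       ampa_norm = syn_gate_norm(spec$ampa_tau_r, spec$ampa_tau_d),
       nmda_norm = syn_gate_norm(spec$nmda_tau_r, spec$nmda_tau_d),
       mg_out = io$mg_out, na_in = io$na_in, na_out = io$na_out,
       k_in = io$k_in, k_out = io$k_out,
       p_na = io$p_na, p_k = io$p_k, p_ca = io$p_ca)
}
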