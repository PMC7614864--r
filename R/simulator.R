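# Simulation driver: assembles the compartmental system for the compiled
# core, defines stimulus protocols, and records traces at named sites.

#' Solver configuration
#'
#' @param dt integration step (ms); at most 0.025 (25 us, the study step).
#' @param record_every record every k-th step (1 = full rate).
#' @param celsius simulation temperature (degrees C).
#' @param v_init initial membrane potential (mV).
#' @param settle_s stabilization period before stimuli (s); 5 s default.
#' @return a `solver_config` list.
#' @export
solver_config <- function(dt = 0.025, record_every = 1L, celsius = 34,
                          v_init = -65, settle_s = 5) {
  if (dt > 0.025 + 1e-12) stop("dt must be <= 0.025 ms")
  structure(list(dt = dt, record_every = as.integer(record_every),
                 celsius = celsius, v_init = v_init, settle_s = settle_s),
            class = "solver_config")
}

# Build the C++-facing network list. Caches gate tables per (kinetics, dt)
# in the package namespace environment.
.net_cache <- new.env(parent = emptyenv())

assemble_net <- function(model, params, kinetics = load_kinetics(),
                         config = solver_config(),
                         cacfg = NULL, synapses = NULL) {
  if (is.null(cacfg))
    cacfg <- calcium_config(totbuf = params[["totbuf"]],
                            totpp = params[["totpp"]])
  n <- nrow(model$comp)
  rm <- params[["rm"]]; ra <- params[["ra"]]
  # rebuild axial conductances if R_a differs from the discretization value
  g_ax <- model$g_ax_uS * (model$ra / ra)
  key <- paste0(digest_string(kinetics), "_", config$dt)
  if (!exists(key, .net_cache)) {
    assign(key, build_gate_tables(kinetics, config$dt), .net_cache)
  }
  tabs <- get(key, .net_cache)
  dens <- assign_conductances(model, params, kinetics)
  chans <- list()
  for (nm in names(tabs$channels)) {
    ch <- tabs$channels[[nm]]
    act <- which(dens[, nm] > 0)
    chans[[nm]] <- list(law = ch$law, erev = ch$erev,
                        comps = act - 1L, dens = unname(dens[act, nm]),
                        gates = ch$gates0)
  }
  syn <- list(enabled = FALSE)
  if (!is.null(synapses)) syn <- synapse_net_block(synapses, config)
  list(n_comp = n, parent = model$parent - 1L, g_ax = g_ax,
       cm_nf = model$cm_nF, area = model$comp$area_cm2,
       g_pas = rep(1 / rm, n), e_pas = model$e_pas,
       radius_um = model$comp$diam_um / 2,
       length_um = model$comp$length_um,
       temp_K = 273.15 + config$celsius,
       vmin = tabs$vmin, dv = tabs$dv, nv = tabs$nv,
       channels = chans, gates = tabs$gates,
       calcium = calcium_net_block(model, cacfg),
       synapses = syn,
       stim_steps = matrix(0, 0, 4), ca_steps = matrix(0, 0, 4),
       stim_wave = list(enabled = FALSE),
       v_init = config$v_init)
}

# order-insensitive structural fingerprint used only for table caching
digest_string <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, digits.d = 10,
                                              list.len = 1000)),
             collapse = "")
  paste0("k", sum(utf8ToInt(s) * seq_len(nchar(s)) %% 97), "_", nchar(s))
}

#' Uniformly sampled recording trace
#'
#' @param samples numeric vector (mV or mM).
#' @param dt_ms sample interval (ms).
#' @param t0_ms time of first sample (ms).
#' @param site recording-site tag.
#' @param unit sample unit.
#' @return a `ca3_trace` object.
#' @export
new_trace <- function(samples, dt_ms, t0_ms = 0, site = "soma",
                      unit = "mV") {
  stopifnot(dt_ms > 0, all(is.finite(samples)))
  structure(list(v = samples, dt_ms = dt_ms, t0_ms = t0_ms,
                 site = site, unit = unit), class = "ca3_trace")
}

#' @export
print.ca3_trace <- function(x, ...) {
  cat(sprintf("ca3_trace: %d samples @ %.4g ms (%s, %s), t0 = %.4g ms\n",
              length(x$v), x$dt_ms, x$site, x$unit, x$t0_ms))
  invisible(x)
}

#' Sample times of a trace (ms)
#' @param trace a `ca3_trace`.
#' @return numeric vector of times.
#' @export
trace_times <- function(trace) {
  trace$t0_ms + (seq_along(trace$v) - 1) * trace$dt_ms
}

#' Generate a linear frequency chirp current stimulus
#'
#' Constant-amplitude sinusoid with instantaneous frequency rising linearly
#' from `f0` to `f1` over `duration`; defaults are the 100 pA peak-to-peak,
#' 0 to 15 Hz, 15 s impedance stimulus.
#'
#' @param amplitude_pp peak-to-peak amplitude (pA).
#' @param f0,f1 start/end frequency (Hz), `f1 > f0 >= 0`.
#' @param duration sweep duration (s).
#' @param dt sample interval (ms).
#' @return a `ca3_trace` with unit `"pA"`; instantaneous phase is
#'   `2*pi*(f0 t + (f1-f0) t^2 / (2 T))`.
#' @export
make_chirp <- function(amplitude_pp = 100, f0 = 0, f1 = 15, duration = 15,
                       dt = 0.025) {
  if (!(f1 > f0 && f0 >= 0)) stop("need f1 > f0 >= 0")
  if (duration <= 0) stop("duration must be positive")
  if (f1 > 0 && dt > 1000 / (20 * f1))
    stop("dt too coarse: fewer than 20 samples per cycle at f1")
  t <- seq(0, duration, by = dt / 1000)  # seconds
  phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * duration))
  new_trace((amplitude_pp / 2) * sin(phase), dt_ms = dt, site = "stimulus",
            unit = "pA")
}

#' Instantaneous frequency of a chirp waveform at its final sample
#'
#' Analytic phase derivative of the [make_chirp()] waveform:
#' `f(t) = f0 + (f1-f0) t/T`.
#'
#' @inheritParams make_chirp
#' @param t time (s) at which to evaluate; defaults to the sweep end.
#' @return frequency in Hz.
#' @export
chirp_instantaneous_freq <- function(f0 = 0, f1 = 15, duration = 15,
                                     t = duration) {
  f0 + (f1 - f0) * t / duration
}

#' Stimulus protocol
#'
#' @param settle_s stabilization period (s) preceding the stimuli.
#' @param steps data frame with `site`, `t_on`, `t_off` (ms after settle),
#'   `amp_nA` for step currents; `NULL` for none.
#' @param wave list(site, t0_ms, trace) for an arbitrary waveform (chirp).
#' @param synapses a synapse set from [place_synapses()] plus train times;
#'   `NULL` for none.
#' @param duration_ms recorded duration after settle (ms).
#' @param record sites to record voltage at.
#' @param record_ca sites to record submembrane calcium at.
#' @param record_every decimation for recording (overrides config).
#' @return a `protocol` list.
#' @export
protocol <- function(settle_s = 5, steps = NULL, wave = NULL,
                     synapses = NULL, duration_ms = 1000,
                     record = "soma", record_ca = NULL,
                     record_every = NULL) {
  structure(list(settle_s = settle_s, steps = steps, wave = wave,
                 synapses = synapses, duration_ms = duration_ms,
                 record = record, record_ca = record_ca,
                 record_every = record_every), class = "protocol")
}

#' Integrate a model under a protocol
#'
#' Backward-Euler branched-cable solve with exponential-Euler gating and
#' explicit GHK/synaptic currents, at fixed step `config$dt`. The settle
#' period runs stimulus-free; pass a `state` from [stabilize()] to reuse a
#' settled state across protocols (`settle_s = 0` then).
#'
#' @param model a `compartmental_model`.
#' @param params parameter vector.
#' @param proto a [protocol()].
#' @param config a [solver_config()].
#' @param kinetics a `kinetics_set`.
#' @param state optional settled state (from a previous run's `$state`).
#' @return list with `traces` (named `ca3_trace`s, time measured from
#'   stimulus onset = end of settle), `ca_traces`, `state` (final), and
#'   `diverged` flag.
#' @export
run_protocol <- function(model, params, proto, config = solver_config(),
                         kinetics = load_kinetics(), state = NULL) {
  net <- assemble_net(model, params, kinetics, config,
                      synapses = proto$synapses)
  dt <- config$dt
  rec_ev <- if (!is.null(proto$record_every)) as.integer(proto$record_every)
            else config$record_every
  v_sites <- vapply(proto$record, function(s) resolve_site(model, s), 0L)
  ca_sites <- if (!is.null(proto$record_ca))
    vapply(proto$record_ca, function(s) resolve_site(model, s), 0L)
    else integer(0)

  # settle (stimulus-free: synaptic events belong to the post-settle clock)
  t0 <- 0
  if (is.null(state) && proto$settle_s > 0) {
    nset <- round(proto$settle_s * 1000 / dt)
    net_settle <- net
    net_settle$synapses <- list(enabled = FALSE)
    out0 <- .sim_core(net_settle, dt, nset, 0, list(), nset, 0L,
                      integer(0))
    if (out0$diverged)
      stop("divergence during settle at t = ", out0$t_diverged, " ms")
    state <- out0$state
  }
  if (!is.null(state)) t0 <- 0  # stimulus clock restarts at settle end

  # stimuli (times relative to end of settle)
  stim <- matrix(0, 0, 4)
  if (!is.null(proto$steps)) {
    s <- proto$steps
    stim <- cbind(vapply(as.character(s$site),
                         function(x) resolve_site(model, x), 0L) - 1L,
                  s$t_on, s$t_off, s$amp_nA)
  }
  net$stim_steps <- stim
  if (!is.null(proto$wave)) {
    wtr <- proto$wave$trace
    if (abs(wtr$dt_ms - dt) > 1e-12)
      stop("waveform stimulus must be sampled at the solver dt")
    net$stim_wave <- list(enabled = TRUE,
                          comp = resolve_site(model, proto$wave$site) - 1L,
                          t0 = proto$wave$t0_ms,
                          i_nA = wtr$v / 1000)  # pA -> nA
  }

  nsteps <- round(proto$duration_ms / dt)
  out <- .sim_core(net, dt, nsteps, t0,
                   if (is.null(state)) list() else state,
                   rec_ev, v_sites - 1L, ca_sites - 1L)
  if (out$ca_negative)
    warning("negative calcium concentration encountered (dt too large?)")
  traces <- list()
  for (i in seq_along(proto$record))
    traces[[proto$record[i]]] <- new_trace(out$v[, i], dt * rec_ev, t0,
                                           proto$record[i], "mV")
  ca_traces <- list()
  for (i in seq_along(ca_sites))
    ca_traces[[as.character(proto$record_ca[i])]] <-
      new_trace(out$ca[, i], dt * rec_ev, t0,
                as.character(proto$record_ca[i]), "mM")
  list(traces = traces, ca_traces = ca_traces, state = out$state,
       diverged = out$diverged, t_diverged = out$t_diverged)
}

#' Stabilize a model to its resting state
#'
#' Stimulus-free integration for `duration_s`; returns the final state and
#' the residual somatic dV/dt over the last millisecond as a settledness
#' diagnostic (a spontaneously spiking model is flagged, not an error).
#'
#' @param model,params,config,kinetics as in [run_protocol()].
#' @param duration_s settle duration (s).
#' @return list(`state`, `v_rest` (somatic potential, mV), `residual_dvdt`
#'   (mV/ms), `settled` flag).
#' @export
stabilize <- function(model, params, duration_s = 5,
                      config = solver_config(), kinetics = load_kinetics()) {
  if (duration_s < 0) stop("duration must be non-negative")
  net <- assemble_net(model, params, kinetics, config)
  if (duration_s == 0) {
    n <- net$n_comp
    return(list(state = NULL, v_rest = config$v_init, residual_dvdt = NA,
                settled = NA))
  }
  dt <- config$dt
  nsteps <- round(duration_s * 1000 / dt)
  keep <- max(1L, round(1 / dt))  # last 1 ms at full rate
  out <- .sim_core(net, dt, nsteps, 0, list(), 1L,
                   resolve_site(model, "soma") - 1L, integer(0))
  if (out$diverged) stop("divergence during stabilization")
  v <- out$v[, 1]
  tailv <- v[max(1, length(v) - keep):length(v)]
  res <- max(abs(diff(tailv))) / dt
  list(state = out$state, v_rest = v[length(v)],
       residual_dvdt = res, settled = res < 1e-4)
}
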