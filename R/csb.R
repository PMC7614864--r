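# Complex spike bursts: the five induction protocols, per-pulse scoring
# against the burst criteria, and the CSB rate.

#' Complex-spike-burst induction protocol specification
#'
#' Five protocols: somatic current pulses of 600/900/1200 pA (five 100 ms
#' pulses, 80 ms gaps), a dendritic 1000 pA protocol (~150 um site, five
#' 50 ms pulses, 50 ms gaps), and synchronous 5 Hz stimulation of 100
#' colocalized AMPAR-NMDAR stratum-radiatum synapses (five events at
#' 200 ms intervals).
#'
#' @param kind one of `"somatic600"`, `"somatic900"`, `"somatic1200"`,
#'   `"dendritic1000"`, `"synaptic5Hz"`.
#' @param n_synapses synapse count for the synaptic protocol.
#' @param synapse_seed placement seed.
#' @param spec a [synapse_spec()] for the synaptic protocol.
#' @return a `csb_protocol` list with pulse geometry and injection site.
#' @export
csb_protocol <- function(kind = c("somatic900", "somatic600",
                                  "somatic1200", "dendritic1000",
                                  "synaptic5Hz"),
                         n_synapses = 100, synapse_seed = 1,
                         spec = synapse_spec()) {
  kind <- match.arg(kind)
  out <- switch(kind,
    somatic600 = list(site = "soma", amp_nA = 0.6, width = 100, gap = 80),
    somatic900 = list(site = "soma", amp_nA = 0.9, width = 100, gap = 80),
    somatic1200 = list(site = "soma", amp_nA = 1.2, width = 100, gap = 80),
    dendritic1000 = list(site = "apical150", amp_nA = 1.0, width = 50,
                         gap = 50),
    synaptic5Hz = {
      if (n_synapses < 1)
        stop("synaptic protocol configured with no synapses")
      list(site = NA, amp_nA = NA, width = 200, gap = 0,
           n_synapses = n_synapses,
           synapse_seed = synapse_seed, spec = spec)
    })
  out$kind <- kind
  out$n_pulses <- 5L
  structure(out, class = "csb_protocol")
}

#' Run a CSB induction protocol on a model
#'
#' @param model a `compartmental_model`.
#' @param params parameter vector.
#' @param proto a [csb_protocol()].
#' @param config a [solver_config()]; `config$settle_s` applies.
#' @param kinetics a `kinetics_set`.
#' @param state optional settled state (skips the settle).
#' @param record_ca record synapse-site calcium (synaptic protocol).
#' @param synapses optional pre-placed `synapse_set` (so knockout runs
#'   share placement).
#' @return list(`traces`, `ca_traces`, `pulse_windows` (matrix of pulse
#'   on/off ms), `v_rmp`, `proto`).
#' @export
run_csb_protocol <- function(model, params, proto,
                             config = solver_config(),
                             kinetics = load_kinetics(), state = NULL,
                             record_ca = FALSE, synapses = NULL) {
  period <- proto$width + proto$gap
  if (proto$kind == "synaptic5Hz") period <- 200
  onsets <- 10 + (0:(proto$n_pulses - 1)) * period
  dur <- onsets[proto$n_pulses] + period + 40
  if (is.null(state)) {
    st <- stabilize(model, params, config$settle_s, config, kinetics)
    state <- st$state
    v_rmp <- st$v_rest
  } else v_rmp <- state$v[resolve_site(model, "soma")]

  if (proto$kind == "synaptic5Hz") {
    if (!is.null(proto$n_synapses) && proto$n_synapses < 1)
      stop("synaptic protocol configured with no synapses")
    if (is.null(synapses))
      synapses <- place_synapses(model, n = proto$n_synapses,
                                 seed = proto$synapse_seed,
                                 spec = proto$spec)
    synapses <- synaptic_train(synapses, times = onsets)
    ca_site <- names(sort(table(model$comp$region[synapses$loc]),
                          decreasing = TRUE))[1]
    # record at the compartment hosting the most synapses
    host <- as.integer(names(sort(table(synapses$loc),
                                  decreasing = TRUE)))[1]
    pr <- protocol(settle_s = 0, duration_ms = dur, synapses = synapses,
                   record = c("soma", "apical150"),
                   record_ca = if (record_ca) host else NULL)
  } else {
    stim <- data.frame(site = proto$site, t_on = onsets,
                       t_off = onsets + proto$width, amp_nA = proto$amp_nA)
    pr <- protocol(settle_s = 0, duration_ms = dur, steps = stim,
                   record = c("soma", "apical150"))
  }
  out <- run_protocol(model, params, pr, config, kinetics, state = state)
  if (out$diverged)
    stop("divergence during CSB protocol at pulse ",
         max(1, sum(onsets < out$t_diverged)))
  win_width <- if (proto$kind == "synaptic5Hz") period else proto$width
  list(traces = out$traces, ca_traces = out$ca_traces,
       pulse_windows = cbind(on = onsets, off = onsets + win_width),
       v_rmp = v_rmp, proto = proto)
}

#' Depolarizing ramp amplitude of a pulse response
#'
#' Median-filters the voltage trace with a 0.5 s window (on a 1 kHz
#' decimated copy, reflect-padded at the edges) to remove spikes, then
#' takes the peak of the filtered trace minus the resting potential.
#'
#' @param trace voltage (`ca3_trace`).
#' @param v_rmp resting potential (mV).
#' @param window filter window (s).
#' @param t_range optional c(on, off) ms restricting the peak search.
#' @return ramp amplitude (mV).
#' @export
ramp_amplitude <- function(trace, v_rmp, window = 0.5, t_range = NULL) {
  dec <- max(1L, round(1 / trace$dt_ms))
  v <- trace$v[seq(1, length(trace$v), by = dec)]
  dtd <- trace$dt_ms * dec
  k <- round(window * 1000 / dtd)
  if (k %% 2 == 0) k <- k + 1
  if (k < 3) k <- 3
  half <- (k - 1) / 2
  vp <- c(rev(v[seq_len(min(half, length(v)))]), v,
          rev(v[seq(max(1, length(v) - half + 1), length(v))]))
  f <- runmed(vp, k)
  f <- f[(half + 1):(half + length(v))]
  if (!is.null(t_range)) {
    tt <- trace$t0_ms + (seq_along(v) - 1) * dtd
    f <- f[tt >= t_range[1] & tt <= t_range[2]]
  }
  max(f) - v_rmp
}

#' Score one pulse against the complex-spike-burst criteria
#'
#' Valid iff (1) three or more APs within some sliding 25 ms window inside
#' the pulse, (2) the first-to-second AP amplitude drop is within the
#' `dvap_bounds` (10-30 mV), and (3) the ramp amplitude is within
#' `ramp_bounds` (10-30 mV). With fewer than two spikes the amplitude drop
#' is undefined and the pulse invalid.
#'
#' @param trace full protocol voltage (`ca3_trace`).
#' @param v_rmp resting potential (mV).
#' @param t_on,t_off pulse window (ms).
#' @param dvap_bounds,ramp_bounds inclusive criterion bounds (mV).
#' @param ap_window burst window (ms).
#' @return list(`valid`, `flags` (ap/dvap/ramp), `n_ap`, `dv_ap`,
#'   `v_ramp`).
#' @export
score_pulse <- function(trace, v_rmp, t_on, t_off,
                        dvap_bounds = c(10, 30), ramp_bounds = c(10, 30),
                        ap_window = 25) {
  sp <- detect_spikes(trace)
  sp <- sp[sp$t_peak >= t_on & sp$t_peak <= t_off, ]
  n <- nrow(sp)
  ap_ok <- FALSE
  if (n >= 3)
    for (i in seq_len(n - 2))
      if (sp$t_peak[i + 2] - sp$t_peak[i] <= ap_window) { ap_ok <- TRUE
        break }
  dv_ap <- if (n >= 2) (sp$v_peak[1] - v_rmp) - (sp$v_peak[2] - v_rmp)
           else NA_real_
  v_ramp <- ramp_amplitude(trace, v_rmp, t_range = c(t_on, t_off))
  dv_ok <- !is.na(dv_ap) && dv_ap >= dvap_bounds[1] &&
    dv_ap <= dvap_bounds[2]
  rp_ok <- v_ramp >= ramp_bounds[1] && v_ramp <= ramp_bounds[2]
  list(valid = ap_ok && dv_ok && rp_ok,
       flags = c(ap = ap_ok, dvap = dv_ok, ramp = rp_ok),
       n_ap = n, dv_ap = dv_ap, v_ramp = v_ramp)
}

#' CSB rate from per-pulse validities
#'
#' The first pulse is excluded (it reliably bursts); the rate is the valid
#' fraction of pulses 2-5.
#'
#' @param validities logical vector of length 5.
#' @return rate in `[0, 1]`.
#' @export
csb_rate <- function(validities) {
  if (length(validities) != 5)
    stop("expected exactly five pulse validities")
  mean(validities[2:5])
}

#' Score a full CSB protocol run
#'
#' @param run output of [run_csb_protocol()].
#' @param site which recorded trace to score (default soma).
#' @param ... criterion bounds passed to [score_pulse()].
#' @return a `csb_result`: per-pulse table, mean `dv_ap` / `v_ramp` over
#'   pulses 2-5, and the CSB rate.
#' @export
score_csb <- function(run, site = "soma", ...) {
  tr <- run$traces[[site]]
  pulses <- lapply(seq_len(nrow(run$pulse_windows)), function(k)
    score_pulse(tr, run$v_rmp, run$pulse_windows[k, 1],
                run$pulse_windows[k, 2], ...))
  pt <- data.frame(pulse = seq_along(pulses),
                   n_ap = vapply(pulses, `[[`, 0, "n_ap"),
                   dv_ap = vapply(pulses, `[[`, 0, "dv_ap"),
                   v_ramp = vapply(pulses, `[[`, 0, "v_ramp"),
                   valid = vapply(pulses, `[[`, TRUE, "valid"))
  structure(list(pulses = pt,
                 dv_ap = mean(pt$dv_ap[2:5], na.rm = TRUE),
                 v_ramp = mean(pt$v_ramp[2:5]),
                 rate = csb_rate(pt$valid),
                 csb_valid = any(pt$valid[2:5]),
                 kind = run$proto$kind), class = "csb_result")
}
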