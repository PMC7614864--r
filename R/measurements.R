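# Electrophysiological measurements: the 11 validation measurements
# (resting potential and its SD, input resistance, sag ratio, impedance
# resonance, firing rate, backpropagating AP amplitudes) and the 11
# AP-waveform measurements.

#' Detect action potentials in a voltage trace
#'
#' A spike is an upward crossing of `thresh` whose subsequent local maximum
#' reaches `peak_min`, with crossings closer than `refractory` ms to the
#' previous accepted crossing ignored. Robust to the within-burst amplitude
#' decrements of complex spike bursts.
#'
#' @param trace a `ca3_trace` (mV).
#' @param thresh crossing threshold (mV).
#' @param peak_min minimum peak voltage (mV).
#' @param refractory minimum separation between crossings (ms).
#' @return data frame with `t_cross`, `t_peak` (ms), `v_peak` (mV); zero
#'   rows when no spikes.
#' @export
detect_spikes <- function(trace, thresh = -20, peak_min = 0,
                          refractory = 1) {
  v <- trace$v
  up <- which(v[-1] >= thresh & v[-length(v)] < thresh)
  tt <- trace_times(trace)
  out <- list(); last <- -Inf
  for (i in up) {
    if (tt[i] - last < refractory) next
    # local maximum: scan until v drops below thresh or series ends
    j <- i + 1
    while (j < length(v) && v[j] >= thresh) j <- j + 1
    seg <- i:(j - 1)
    k <- seg[which.max(v[seg])]
    if (v[k] < peak_min) next
    last <- tt[i]
    out[[length(out) + 1]] <- c(tt[i], tt[k], v[k])
  }
  if (!length(out))
    return(data.frame(t_cross = numeric(0), t_peak = numeric(0),
                      v_peak = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(t_cross = m[, 1], t_peak = m[, 2], v_peak = m[, 3])
}

#' Resting membrane potential and its standard deviation
#'
#' Mean and SD of the recorded voltage within a fixed absolute-time window
#' (default the 5-6 s span of a 6 s quiescent recording).
#'
#' @param trace a `ca3_trace` whose time base covers the window.
#' @param window window in seconds, default `c(5, 6)`.
#' @return list(`v_rmp` mV, `v_sd_uv` microvolts).
#' @export
measure_rmp_sd <- function(trace, window = c(5, 6)) {
  tt <- trace_times(trace) / 1000
  sel <- tt >= window[1] & tt <= window[2]
  if (!any(sel))
    stop("trace does not cover the ", window[1], "-", window[2],
         " s measurement window")
  list(v_rmp = mean(trace$v[sel]), v_sd_uv = sd(trace$v[sel]) * 1000)
}

#' Input resistance from a V-I steady-state table
#'
#' Least-squares slope of steady-state voltage deflection versus injected
#' current (the -50..+50 pA, 10 pA step family).
#'
#' @param i_pa injected currents (pA).
#' @param v_ss steady-state voltages (mV), same length.
#' @return input resistance in MOhm (mV/pA * 1000 = MOhm).
#' @export
measure_rin <- function(i_pa, v_ss) {
  if (length(i_pa) < 2 || length(unique(i_pa)) < 2)
    stop("need at least two distinct current levels")
  slope <- coef(lm(v_ss ~ i_pa))[[2]]  # mV per pA
  slope * 1000                          # mV/pA = GOhm -> MOhm
}

#' Sag ratio from a hyperpolarizing pulse response
#'
#' `Sag = V_SS / V_max` where both deflections are measured from the
#' pre-pulse baseline; `V_SS` is the mean over the last 10% of the pulse,
#' `V_max` the peak deflection.
#'
#' @param trace voltage response (`ca3_trace`) covering the pulse.
#' @param t_on,t_off pulse window (ms, trace time base).
#' @return sag ratio (1 = no sag).
#' @export
measure_sag <- function(trace, t_on = 0, t_off = 800) {
  tt <- trace_times(trace)
  base <- mean(trace$v[tt < t_on])
  if (!is.finite(base)) base <- trace$v[1]
  inpulse <- tt >= t_on & tt <= t_off
  defl <- trace$v[inpulse] - base
  peak <- min(defl)
  if (peak >= 0) stop("no hyperpolarizing deflection found")
  ss_win <- tt >= t_off - 0.1 * (t_off - t_on) & tt <= t_off
  ss <- mean(trace$v[ss_win]) - base
  ss / peak
}

#' Impedance amplitude profile from a chirp response
#'
#' `|Z(f)| = |FFT(V) / FFT(I)|` over the chirp band; resonance frequency
#' `f_R` is the band argmax, resonance strength `Q_R` the ratio of
#' `|Z|(f_R)` to `|Z|(0.5 Hz)`.
#'
#' @param v_trace voltage response (`ca3_trace`, mV), baseline-detrended by
#'   its pre-chirp value internally.
#' @param i_trace chirp current (`ca3_trace`, pA), same dt.
#' @param f_band analysis band (Hz), default `c(0.5, 15)`.
#' @return list(`f` Hz, `z` MOhm, `f_r`, `q_r`, `z_max`).
#' @export
impedance_profile <- function(v_trace, i_trace, f_band = c(0.5, 15)) {
  if (abs(v_trace$dt_ms - i_trace$dt_ms) > 1e-12)
    stop("voltage and current traces must share dt")
  nn <- min(length(v_trace$v), length(i_trace$v))
  v <- v_trace$v[seq_len(nn)]; i <- i_trace$v[seq_len(nn)]
  v <- v - v[1]
  fs <- 1000 / v_trace$dt_ms
  fr <- seq(0, fs * (nn - 1) / nn, length.out = nn)
  Z <- fft(v) / fft(i)                  # mV/pA = GOhm
  zabs <- Mod(Z) * 1000                 # MOhm
  band <- which(fr >= f_band[1] & fr <= f_band[2])
  if (!length(band) || any(!is.finite(zabs[band])))
    stop("chirp stimulus has no power in the analysis band")
  k <- band[which.max(zabs[band])]
  z05 <- approx(fr[seq_len(floor(nn / 2))], zabs[seq_len(floor(nn / 2))],
                xout = 0.5)$y
  list(f = fr[band], z = zabs[band], f_r = fr[k],
       q_r = zabs[k] / z05, z_max = zabs[k])
}

#' Action-potential measurements from a 250 pA step response
#'
#' Computes the firing rate (spike count in the injection window), latency
#' to the first spike, first interspike interval, spike
#' after-hyperpolarization (minimum voltage in the first 50 ms minus
#' resting potential), AP half-width (regular-spiking models only, from the
#' first spike after 500 ms, full width at half maximum referenced to the
#' resting potential), threshold (voltage at the first 20 V/s upstroke
#' crossing) and the dV/dt extremes.
#'
#' @param trace somatic voltage (`ca3_trace`) at full sampling rate; time 0
#'   = stimulus onset.
#' @param v_rmp resting potential (mV).
#' @param t_on,t_off injection window (ms).
#' @param firing_class `"RS"`, `"IB"` or `NA`; half-width is only defined
#'   for RS models.
#' @param dvdt_thresh threshold-detection slope (V/s = mV/ms).
#' @return list of measurements; undefined ones are `NA`.
#' @export
ap_measurements <- function(trace, v_rmp, t_on = 0, t_off = 1000,
                            firing_class = NA, dvdt_thresh = 20) {
  tt <- trace_times(trace)
  sp <- detect_spikes(trace)
  sp <- sp[sp$t_cross >= t_on & sp$t_cross <= t_off, ]
  f_250 <- as.numeric(nrow(sp))
  t_1ap <- if (nrow(sp) >= 1) sp$t_cross[1] - t_on else NA_real_
  t_1isi <- if (nrow(sp) >= 2) sp$t_peak[2] - sp$t_peak[1] else NA_real_
  early <- tt >= t_on & tt <= t_on + 50
  v_ahp <- min(trace$v[early]) - v_rmp
  dv <- diff(trace$v) / trace$dt_ms      # mV/ms = V/s

  v_th <- NA_real_
  if (nrow(sp) >= 1) {
    # first dV/dt >= threshold crossing in the upstroke of the first spike
    i1 <- max(which(tt <= sp$t_peak[1]))
    i0 <- max(which(tt <= sp$t_cross[1] - 5), 1)
    seg <- i0:(i1 - 1)
    hit <- seg[dv[seg] >= dvdt_thresh]
    if (length(hit)) v_th <- trace$v[hit[1]]
  }

  t_aphw <- NA_real_
  if (identical(firing_class, "RS")) {
    late <- sp[sp$t_cross >= t_on + 500, ]
    if (nrow(late) >= 1) {
      pk_i <- which.min(abs(tt - late$t_peak[1]))
      half <- v_rmp + (late$v_peak[1] - v_rmp) / 2
      iup <- pk_i; while (iup > 1 && trace$v[iup - 1] > half) iup <- iup - 1
      idn <- pk_i
      while (idn < length(tt) && trace$v[idn + 1] > half) idn <- idn + 1
      cross_t <- function(i, j) {  # linear interpolation at 'half'
        if (i == j) return(tt[i])
        tt[i] + (half - trace$v[i]) / (trace$v[j] - trace$v[i]) *
          (tt[j] - tt[i])
      }
      t_up <- cross_t(iup - 1, iup)
      t_dn <- cross_t(idn, idn + 1)
      t_aphw <- t_dn - t_up
    }
  }
  list(f_250 = f_250, t_1ap = t_1ap, t_1isi = t_1isi, v_ahp = v_ahp,
       t_aphw = t_aphw, v_th = v_th,
       dvdt_max = max(dv), dvdt_min = min(dv))
}

#' Backpropagating AP amplitudes at soma and dendritic sites
#'
#' Amplitude of the first action potential (peak minus local pre-stimulus
#' baseline) in each trace of a 1 nA x 50 ms somatic injection run.
#'
#' @param traces named list of `ca3_trace`s (e.g. soma, apical150,
#'   apical300), time 0 = stimulus onset.
#' @param t_on stimulus onset (ms).
#' @return named numeric vector of amplitudes (mV).
#' @export
bap_amplitudes <- function(traces, t_on = 0) {
  soma_sp <- detect_spikes(traces[[1]])
  if (!nrow(soma_sp)) stop("no somatic action potential in the bAP run")
  vapply(traces, function(tr) {
    tt <- trace_times(tr)
    base <- if (any(tt < t_on)) mean(tr$v[tt < t_on]) else tr$v[1]
    # first AP: peak within +-10 ms of the somatic first peak (the bAP may
    # not cross the somatic spike criterion distally)
    win <- tt >= soma_sp$t_cross[1] - 1 & tt <= soma_sp$t_peak[1] + 10
    max(tr$v[win]) - base
  }, 0)
}

#' Run the full validation + AP measurement battery on one model
#'
#' Executes the measurement protocols (quiescent recording; -50..+50 pA
#' V-I family; -250 pA sag pulse; 0-15 Hz chirp; 250 pA firing pulse; 1 nA
#' backpropagation pulse) reusing one settled state, and computes the 11
#' validation measurements plus the AP battery.
#'
#' @param model a `compartmental_model`.
#' @param params parameter vector.
#' @param config a [solver_config()]; `config$settle_s` is the
#'   stabilization period.
#' @param kinetics a `kinetics_set`.
#' @param classify also run the 240 pA x 5.5 s classification protocol and
#'   report the IB/RS label (slower; default FALSE).
#' @param bounds optional [measurement_bounds()] enabling staged rejection:
#'   protocols run cheapest-first and evaluation stops at the first
#'   out-of-bounds measurement, leaving later measurements `NA`. Used by
#'   the population search; a valid model is always fully measured.
#' @return named list: validation measurements (`v_rmp`, `v_sd_uv`, `r_in`,
#'   `sag`, `f_r`, `q_r`, `z_max`, `f_250`, `v_ap0`, `v_ap150`, `v_ap300`),
#'   AP measurements, and (optionally) `class`.
#' @export
measure_model <- function(model, params, config = solver_config(),
                          kinetics = load_kinetics(), classify = FALSE,
                          bounds = NULL) {
  dt <- config$dt
  st <- stabilize(model, params, config$settle_s, config, kinetics)
  settle_ms <- config$settle_s * 1000

  out <- list()
  reject <- function(keys) {
    if (is.null(bounds)) return(FALSE)
    for (k in keys) {
      b <- bounds[bounds$measurement == k, ]
      if (nrow(b) && (!is.finite(out[[k]]) || out[[k]] < b$lower ||
                      out[[k]] > b$upper))
        return(TRUE)
    }
    FALSE
  }

  nam <- c("v_rmp", "v_sd_uv", "r_in", "sag", "f_r", "q_r", "z_max",
           "f_250", "v_ap0", "v_ap150", "v_ap300", "t_1ap", "t_1isi",
           "v_ahp", "t_aphw", "v_th", "dvdt_max_soma", "dvdt_min_soma",
           "dvdt_max_150", "dvdt_min_150", "dvdt_max_300", "dvdt_min_300")
  out <- setNames(as.list(rep(NA_real_, length(nam))), nam)
  finish <- function() {
    if (classify) out$class <- cls
    out
  }
  cls <- NA_character_

  # quiescent recording: 1 s at rest; the trace time base is continued from
  # the settle so the absolute 5-6 s window applies
  rest <- run_protocol(model, params,
    protocol(settle_s = 0, duration_ms = 1000, record = "soma",
             record_every = 40L),
    config, kinetics, state = st$state)
  rest_tr <- rest$traces$soma; rest_tr$t0_ms <- settle_ms
  rmp <- measure_rmp_sd(rest_tr, window = c(settle_ms, settle_ms + 1000) /
                          1000)
  out$v_rmp <- rmp$v_rmp; out$v_sd_uv <- rmp$v_sd_uv
  if (reject(c("v_rmp", "v_sd_uv"))) return(finish())

  # sag: -250 pA, 800 ms
  sag_out <- run_protocol(model, params,
    protocol(settle_s = 0, duration_ms = 850,
             steps = data.frame(site = "soma", t_on = 10, t_off = 810,
                                amp_nA = -0.25),
             record = "soma", record_every = 40L),
    config, kinetics, state = st$state)
  out$sag <- tryCatch(measure_sag(sag_out$traces$soma, t_on = 10,
                                  t_off = 810),
                      error = function(e) NA_real_)
  if (reject("sag")) return(finish())

  # V-I family
  i_levels <- seq(-50, 50, by = 10)
  v_ss <- vapply(i_levels, function(ipa) {
    o <- run_protocol(model, params,
      protocol(settle_s = 0, duration_ms = 320,
               steps = data.frame(site = "soma", t_on = 0, t_off = 300,
                                  amp_nA = ipa / 1000),
               record = "soma", record_every = 40L),
      config, kinetics, state = st$state)
    tr <- o$traces$soma; tt <- trace_times(tr)
    mean(tr$v[tt >= 270 & tt <= 300])  # last 10% of the pulse
  }, 0)
  out$r_in <- measure_rin(i_levels, v_ss)
  if (reject("r_in")) return(finish())

  # chirp impedance
  chirp <- make_chirp(dt = dt)
  ch_out <- run_protocol(model, params,
    protocol(settle_s = 0, duration_ms = 15000,
             wave = list(site = "soma", t0_ms = 0, trace = chirp),
             record = "soma", record_every = 40L),
    config, kinetics, state = st$state)
  chirp_dec <- new_trace(chirp$v[seq(1, length(chirp$v), by = 40L)],
                         dt * 40, 0, "stimulus", "pA")
  imp <- impedance_profile(ch_out$traces$soma, chirp_dec)
  out$f_r <- imp$f_r; out$q_r <- imp$q_r; out$z_max <- imp$z_max
  if (reject(c("f_r", "q_r", "z_max"))) return(finish())

  # 250 pA firing + AP battery (full-rate recording at three sites)
  f_out <- run_protocol(model, params,
    protocol(settle_s = 0, duration_ms = 1050,
             steps = data.frame(site = "soma", t_on = 0, t_off = 1000,
                                amp_nA = 0.25),
             record = c("soma", "apical150", "apical300")),
    config, kinetics, state = st$state)
  if (classify) {
    ib_out <- run_protocol(model, params,
      protocol(settle_s = 0, duration_ms = 5600,
               steps = data.frame(site = "soma", t_on = 0, t_off = 5500,
                                  amp_nA = 0.24),
               record = "soma"),
      config, kinetics, state = st$state)
    cls <- classify_ib_rs(ib_out$traces$soma, rmp$v_rmp)$class
  }
  apm <- ap_measurements(f_out$traces$soma, rmp$v_rmp, 0, 1000,
                         firing_class = if (classify) cls else "RS")
  dvd <- lapply(f_out$traces, function(tr) {
    dv <- diff(tr$v) / tr$dt_ms
    c(max = max(dv), min = min(dv))
  })
  out[c("f_250", "t_1ap", "t_1isi", "v_ahp", "t_aphw", "v_th")] <-
    apm[c("f_250", "t_1ap", "t_1isi", "v_ahp", "t_aphw", "v_th")]
  out$dvdt_max_soma <- dvd$soma[["max"]]
  out$dvdt_min_soma <- dvd$soma[["min"]]
  out$dvdt_max_150 <- dvd$apical150[["max"]]
  out$dvdt_min_150 <- dvd$apical150[["min"]]
  out$dvdt_max_300 <- dvd$apical300[["max"]]
  out$dvdt_min_300 <- dvd$apical300[["min"]]
  if (reject("f_250")) return(finish())

  # bAP: 1 nA, 50 ms
  b_out <- run_protocol(model, params,
    protocol(settle_s = 0, duration_ms = 100,
             steps = data.frame(site = "soma", t_on = 10, t_off = 60,
                                amp_nA = 1),
             record = c("soma", "apical150", "apical300")),
    config, kinetics, state = st$state)
  bap <- tryCatch(bap_amplitudes(b_out$traces, t_on = 10),
                  error = function(e) rep(NA_real_, 3))
  out$v_ap0 <- unname(bap[1]); out$v_ap150 <- unname(bap[2])
  out$v_ap300 <- unname(bap[3])
  finish()
}
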