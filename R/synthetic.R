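# Synthetic fixtures with machine-readable ground truth: parameterized
# AP-train voltage traces, passive analytic fixtures, and surrogate
# population tables with known correlation structure.

#' Recipe for a synthetic voltage trace
#'
#' Spikes are piecewise-linear (triangular) templates with configurable
#' rise/fall slopes, so spike times, amplitudes, threshold crossings and
#' half-widths have closed-form ground truth; an optional trapezoid ramp
#' plateau and an after-hyperpolarization dip can be added, plus seeded
#' Gaussian noise.
#'
#' @param baseline resting level (mV).
#' @param spike_times spike onset times (ms); or use `burst` =
#'   list(n_bursts, spikes_per_burst, intra_isi, inter_gap, t0).
#' @param spike_height peak height above baseline (mV); scalar or
#'   per-spike (successive amplitudes model within-burst decrements).
#' @param rise_slope,fall_slope spike flank slopes (V/s = mV/ms).
#' @param ahp_depth,ahp_width after-hyperpolarization dip (mV, ms).
#' @param ramp list(amp, t_on, t_rise, t_off) trapezoid plateau (mV, ms);
#'   `NULL` for none.
#' @param noise_sd Gaussian noise SD (mV).
#' @param dt sample interval (ms).
#' @param duration trace duration (ms).
#' @param seed RNG seed for the noise.
#' @return a `trace_recipe`.
#' @export
trace_recipe <- function(baseline = -65, spike_times = numeric(0),
                         burst = NULL, spike_height = 95,
                         rise_slope = 100, fall_slope = 50,
                         ahp_depth = 0, ahp_width = 10,
                         ramp = NULL, noise_sd = 0, dt = 0.05,
                         duration = 1000, seed = 1) {
  if (!is.null(burst)) {
    b <- burst
    t0 <- if (!is.null(b$t0)) b$t0 else 20
    spike_times <- as.vector(outer(seq_len(b$spikes_per_burst) - 1,
                                   seq_len(b$n_bursts) - 1,
      function(i, j) t0 + i * b$intra_isi +
        j * ((b$spikes_per_burst - 1) * b$intra_isi + b$inter_gap)))
    spike_times <- sort(spike_times)
  }
  stopifnot(dt > 0, duration > 0, all(spike_times >= 0),
            all(spike_times < duration))
  structure(list(baseline = baseline, spike_times = spike_times,
                 spike_height = rep_len(spike_height,
                                        max(1, length(spike_times))),
                 rise_slope = rise_slope, fall_slope = fall_slope,
                 ahp_depth = ahp_depth, ahp_width = ahp_width,
                 ramp = ramp, noise_sd = noise_sd, dt = dt,
                 duration = duration, seed = seed),
            class = "trace_recipe")
}

#' Generate a synthetic voltage trace with ground truth
#'
#' @param recipe a [trace_recipe()].
#' @return list(`trace` (`ca3_trace`), `truth`: spike peak times,
#'   amplitudes, per-spike half-width `h/2 (1/rise + 1/fall)`, ramp
#'   amplitude).
#' @export
gen_trace <- function(recipe) {
  r <- recipe
  t <- seq(0, r$duration - r$dt / 2, by = r$dt)
  v <- rep(r$baseline, length(t))
  # ramp plateau (trapezoid riding on baseline)
  ramp_amp <- 0
  if (!is.null(r$ramp)) {
    rp <- r$ramp
    ramp_amp <- rp$amp
    up <- pmin(pmax((t - rp$t_on) / rp$t_rise, 0), 1)
    dn <- pmin(pmax((rp$t_off - t) / rp$t_rise, 0), 1)
    v <- v + rp$amp * pmin(up, dn)
  }
  base_of <- function(tm) {  # envelope (baseline + ramp) at a time
    if (is.null(r$ramp)) return(r$baseline)
    rp <- r$ramp
    r$baseline + rp$amp * min(max((tm - rp$t_on) / rp$t_rise, 0), 1,
                              max((rp$t_off - tm) / rp$t_rise, 0))
  }
  n_sp <- length(r$spike_times)
  truth_peak_t <- truth_amp <- numeric(n_sp)
  if (n_sp) {
    widths <- r$spike_height / r$rise_slope + r$spike_height / r$fall_slope
    ends <- r$spike_times + widths + r$ahp_width
    if (any(diff(r$spike_times) < widths[-n_sp]))
      stop("overlapping spike templates in recipe")
    for (k in seq_len(n_sp)) {
      t0 <- r$spike_times[k]; h <- r$spike_height[k]
      t_up <- h / r$rise_slope; t_dn <- h / r$fall_slope
      seg <- t >= t0 & t <= t0 + t_up + t_dn
      tr <- t[seg] - t0
      spike <- ifelse(tr <= t_up, r$rise_slope * tr,
                      h - r$fall_slope * (tr - t_up))
      v[seg] <- v[seg] + pmax(spike, 0)
      if (r$ahp_depth > 0) {
        sega <- t > t0 + t_up + t_dn & t <= ends[k]
        ta <- (t[sega] - (t0 + t_up + t_dn)) / r$ahp_width
        v[sega] <- v[sega] - r$ahp_depth * sin(pi * pmin(ta, 1))
      }
      truth_peak_t[k] <- t0 + t_up
      truth_amp[k] <- h + base_of(t0 + t_up) - r$baseline
    }
  }
  if (r$noise_sd > 0)
    v <- v + withr_seed(r$seed, rnorm(length(v), sd = r$noise_sd))
  list(trace = new_trace(v, r$dt, 0, "synthetic", "mV"),
       truth = list(spike_peak_times = truth_peak_t,
                    amplitudes = truth_amp,
                    half_width = if (n_sp)
                      r$spike_height / 2 * (1 / r$rise_slope +
                                            1 / r$fall_slope) else numeric(0),
                    ramp = ramp_amp,
                    baseline = r$baseline))
}

#' Surrogate population table with known correlation structure
#'
#' Multivariate normal rows realizing a requested correlation matrix
#' (Cholesky construction).
#'
#' @param n rows (models).
#' @param k columns (parameters/measurements); ignored when `corr` given.
#' @param corr target correlation matrix (positive semi-definite);
#'   `NULL` for identity.
#' @param seed RNG seed.
#' @return numeric matrix `n x k` with columns `P1..Pk`.
#' @export
gen_population_table <- function(n, k = NULL, corr = NULL, seed = 1) {
  if (is.null(corr)) {
    stopifnot(!is.null(k))
    corr <- diag(k)
  }
  k <- ncol(corr)
  ch <- tryCatch(chol(corr),
                 error = function(e)
                   stop("correlation matrix is not positive semi-definite"))
  z <- withr_seed(seed, matrix(rnorm(n * k), n, k))
  x <- z %*% ch
  colnames(x) <- paste0("P", seq_len(k))
  x
}

#' Passive RC fixture with closed-form responses
#'
#' A single-compartment passive membrane with input resistance `R` and
#' time constant `tau`, as both an actual `compartmental_model` (for
#' solver oracles) and closed-form response functions (for measurement
#' oracles).
#'
#' @param R input resistance (MOhm).
#' @param tau membrane time constant (ms).
#' @param e_pas resting potential (mV).
#' @return list(`model`, `rm`, `step_response(t_ms, i_nA)` (deflection mV),
#'   `impedance(f_hz)` (MOhm), `chirp_response(chirp)` (a `ca3_trace`)).
#' @export
gen_passive_fixture <- function(R = 100, tau = 20, e_pas = -65) {
  stopifnot(R > 0, tau > 0)
  # choose geometry: area such that Rm/area = R
  rm_kohm <- 60                       # kOhm cm^2
  area <- rm_kohm * 1e3 / (R * 1e6)   # cm^2
  cm <- tau / rm_kohm                 # uF/cm^2 (tau ms = kOhm cm^2 * uF/cm^2)
  # cylinder with diameter = length
  d_um <- sqrt(area / pi) * 1e4
  tree <- structure(list(
    sections = data.frame(id = 1L, parent = 0L, type = "soma"),
    geometry = list(cbind(x = c(-d_um / 2, d_um / 2), y = 0, z = 0,
                          diam = d_um))), class = "section_tree")
  model <- discretize(tree, rm = rm_kohm, ra = 200, cm = cm,
                      e_pas = e_pas)
  step_response <- function(t_ms, i_nA = 0.1)
    i_nA * R * (1 - exp(-pmax(t_ms, 0) / tau))  # nA * MOhm = mV
  impedance <- function(f_hz) R / sqrt(1 + (2 * pi * f_hz * tau / 1000)^2)
  chirp_response <- function(chirp) {
    # filter the chirp (pA) through the RC transfer function in frequency
    # domain; returns the voltage deflection trace (mV)
    n <- length(chirp$v)
    fr <- seq(0, n - 1) / n * (1000 / chirp$dt_ms)
    fr2 <- ifelse(fr > 1000 / chirp$dt_ms / 2, fr - 1000 / chirp$dt_ms, fr)
    H <- R / (1 + 2i * pi * fr2 * tau / 1000)         # MOhm
    v_uv <- Re(fft(fft(chirp$v) * H, inverse = TRUE)) / n  # pA*MOhm = uV
    new_trace(e_pas + v_uv / 1000, chirp$dt_ms, 0, "soma", "mV")
  }
  list(model = model, rm = rm_kohm, area_cm2 = area, cm = cm,
       R = R, tau = tau, e_pas = e_pas,
       step_response = step_response, impedance = impedance,
       chirp_response = chirp_response)
}
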