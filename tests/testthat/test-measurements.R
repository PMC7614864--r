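test_that("spike detection recovers constructed trains exactly", {
  # flat trace: no spikes
  flat <- new_trace(rep(-65, 1000), 0.05)
  expect_equal(nrow(detect_spikes(flat)), 0)
  # constructed 7-spike train
  g <- gen_trace(trace_recipe(spike_times = seq(50, 650, by = 100),
                              spike_height = 95, dt = 0.05))
  sp <- detect_spikes(g$trace)
  expect_equal(nrow(sp), 7)
  expect_equal(sp$t_peak, g$truth$spike_peak_times, tolerance = 0.06)
})

test_that("spike detection agrees with a brute-force local-maxima oracle
           on random synthetic trains", {
  oracle <- function(trace, thresh = -20, peak_min = 0) {
    # exhaustive: all local maxima above peak_min whose preceding
    # sub-threshold crossing exists
    v <- trace$v
    pk <- which(diff(sign(diff(v))) == -2) + 1
    pk <- pk[v[pk] >= peak_min]
    # merge peaks that belong to one crossing episode
    keep <- logical(length(pk))
    prev_below <- TRUE
    count <- 0
    for (k in seq_along(v)) {
      if (v[k] < thresh) prev_below <- TRUE
      if (k %in% pk && prev_below) { count <- count + 1
        prev_below <- FALSE }
    }
    count
  }
  for (seed in 1:20) {
    set.seed(seed)
    n_sp <- sample(0:12, 1)
    times <- sort(sample(seq(20, 950, by = 5), n_sp))
    while (n_sp > 1 && min(diff(times)) < 12) {
      times <- sort(sample(seq(20, 950, by = 5), n_sp))
    }
    g <- gen_trace(trace_recipe(spike_times = times,
                                spike_height = runif(max(n_sp, 1), 60, 110),
                                dt = 0.05))
    expect_equal(nrow(detect_spikes(g$trace)), oracle(g$trace),
                 label = paste("seed", seed))
  }
})

test_that("resting potential and SD measurements use the right window", {
  tr <- new_trace(rep(-65, 6000), dt_ms = 1)
  m <- measure_rmp_sd(tr)
  expect_equal(m$v_rmp, -65)
  expect_equal(m$v_sd_uv, 0)
  # sinusoid of amplitude a has SD a/sqrt(2)
  tt <- seq(0, 5999) / 1000  # s
  tr2 <- new_trace(-65 + 0.005 * sin(2 * pi * 7 * tt), dt_ms = 1)
  m2 <- measure_rmp_sd(tr2)
  expect_equal(m2$v_sd_uv, 5 / sqrt(2), tolerance = 0.01)
  # window slice agrees with the direct computation
  direct <- sd(tr2$v[tt >= 5 & tt <= 6]) * 1000
  expect_equal(m2$v_sd_uv, direct)
  expect_error(measure_rmp_sd(new_trace(rep(-65, 10), 1)), "window")
})

test_that("input resistance is the V-I slope in MOhm", {
  i <- seq(-50, 50, by = 10)
  expect_equal(measure_rin(i, -65 + 0.1 * i), 100)
  expect_equal(measure_rin(i, -40 + 0.1 * i), 100)  # offset invariant
  expect_error(measure_rin(rep(10, 3), c(1, 2, 3)), "distinct")
  # passive compartment: analytic R within 0.1% using closed-form responses
  fx <- gen_passive_fixture(R = 120, tau = 15)
  v_ss <- -65 + vapply(i, function(ipa) fx$step_response(1500, ipa / 1000),
                       0)
  expect_equal(measure_rin(i, v_ss), 120, tolerance = 1e-3)
})

test_that("sag ratio distinguishes rebound from pure RC responses", {
  tt <- seq(0, 900, by = 0.5)
  rc <- -65 - 10 * (1 - exp(-pmax(tt - 50, 0) / 15)) *
    (tt >= 50 & tt <= 850)
  tr <- new_trace(rc, 0.5)
  expect_equal(measure_sag(tr, 50, 850), 1, tolerance = 0.01)
  # constructed: peak deflection -10, steady -9.4
  sagv <- -65 - ifelse(tt >= 50 & tt <= 850,
                       pmin((tt - 50) / 10, 1) * 10 -
                         pmin(pmax(tt - 100, 0) / 200, 1) * 0.6, 0)
  expect_equal(measure_sag(new_trace(sagv, 0.5), 50, 850), 0.94,
               tolerance = 0.005)
  expect_error(measure_sag(new_trace(rep(-65, 100), 1), 10, 90),
               "deflection")
  # adding an HCN-like conductance to a fixture produces sag < passive
  mod <- discretize(tiny_stick())
  p0 <- quiet_params()
  p1 <- p0; p1[["g_h"]] <- 200  # strong h for a visible rebound
  sag_of <- function(p) {
    out <- run_protocol(mod, p,
      protocol(settle_s = 1, duration_ms = 900,
               steps = data.frame(site = "soma", t_on = 10, t_off = 810,
                                  amp_nA = -0.25),
               record = "soma", record_every = 40L),
      solver_config(v_init = -63.5))
    measure_sag(out$traces$soma, 10, 810)
  }
  expect_lt(sag_of(p1), sag_of(p0))
})

test_that("impedance profile matches the analytic RC curve within 3%", {
  fx <- gen_passive_fixture(R = 100, tau = 20)
  ch <- make_chirp(dt = 1)       # 1 kHz sampling is ample for 0-15 Hz
  resp <- fx$chirp_response(ch)
  imp <- impedance_profile(resp, ch)
  pred <- fx$impedance(imp$f)
  expect_lt(max(abs(imp$z - pred) / pred), 0.03)
  # non-resonant RC: maximum at the lowest evaluated frequency, Q ~ 1
  expect_equal(imp$f_r, min(imp$f))
  expect_equal(imp$q_r, 1, tolerance = 0.03)
  # linearity: doubling the voltage doubles |Z|
  resp2 <- resp; resp2$v <- 2 * (resp$v - resp$v[1]) + resp$v[1]
  imp2 <- impedance_profile(resp2, ch)
  expect_equal(imp2$z, 2 * imp$z, tolerance = 1e-9)
})

test_that("impedance resonance of a second-order kernel is located at its
           analytic peak", {
  # synthetic impedance |Z(f)| = |1/(1 + i f/f0 q - (f/fn)^2)| shaped
  # response built in the frequency domain
  ch <- make_chirp(dt = 1)
  n <- length(ch$v)
  fr <- seq(0, n - 1) / n * 1000
  fr2 <- ifelse(fr > 500, fr - 1000, fr)
  fn <- 5; q <- 0.8
  H <- 30 / (1 + 1i * (fr2 / fn) * q - (fr2 / fn)^2)   # MOhm
  v <- Re(fft(fft(ch$v) * H, inverse = TRUE)) / n / 1000
  resp <- new_trace(-65 + v, 1)
  imp <- impedance_profile(resp, ch)
  f_peak_true <- fn * sqrt(1 - q^2 / 2)
  expect_equal(imp$f_r, f_peak_true, tolerance = 0.15)
})

test_that("AP measurements recover constructed ground truth", {
  # six evenly spaced spikes in the injection second
  g <- gen_trace(trace_recipe(spike_times = seq(100, 850, by = 150),
                              spike_height = 95, rise_slope = 100,
                              fall_slope = 50, dt = 0.05,
                              duration = 1000))
  m <- ap_measurements(g$trace, v_rmp = -65, t_on = 0, t_off = 1000,
                       firing_class = "RS")
  expect_equal(m$f_250, 6)
  expect_equal(m$t_1ap, 100, tolerance = 0.1)
  expect_equal(m$t_1isi, 150, tolerance = 0.1)
  # linear 100 V/s upstroke: threshold sits at the spike foot
  expect_lt(abs(m$v_th - (-65)), 1)
  # triangular template: half-width h/2 (1/m1 + 1/m2)
  expect_equal(m$t_aphw, g$truth$half_width[1], tolerance = 0.1)
  expect_equal(m$dvdt_max, 100, tolerance = 2)
  expect_equal(m$dvdt_min, -50, tolerance = 2)
  # fewer than two spikes: undefined first ISI
  g1 <- gen_trace(trace_recipe(spike_times = 100, dt = 0.05))
  expect_true(is.na(ap_measurements(g1$trace, -65)$t_1isi))
})

test_that("backpropagating AP amplitudes are peak minus local baseline", {
  mk <- function(h) gen_trace(trace_recipe(spike_times = 60,
                                           spike_height = h,
                                           dt = 0.05, duration = 120))$trace
  trs <- list(soma = mk(100), apical150 = mk(80), apical300 = mk(65))
  amps <- bap_amplitudes(trs, t_on = 50)
  expect_equal(unname(amps), c(100, 80, 65), tolerance = 0.1)
  # identical traces give equal amplitudes
  same <- bap_amplitudes(list(a = mk(90), b = mk(90)), t_on = 50)
  expect_equal(same[["a"]], same[["b"]])
  expect_error(bap_amplitudes(list(soma = new_trace(rep(-65, 100), 1))),
               "somatic")
})

test_that("measurement suite is pure: identical traces give identical
           results", {
  g <- gen_trace(trace_recipe(spike_times = seq(100, 850, by = 150),
                              noise_sd = 0.3, seed = 5, dt = 0.05))
  m1 <- ap_measurements(g$trace, -65, firing_class = "RS")
  m2 <- ap_measurements(g$trace, -65, firing_class = "RS")
  expect_identical(m1, m2)
})
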