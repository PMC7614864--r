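test_that("passive step response matches the RC closed form within 1%", {
  fx <- gen_passive_fixture(R = 100, tau = 20)
  p <- quiet_params()
  out <- run_protocol(fx$model, p,
    protocol(settle_s = 0.2, duration_ms = 200,
             steps = data.frame(site = "soma", t_on = 0, t_off = 150,
                                amp_nA = 0.1),
             record = "soma"),
    solver_config(v_init = fx$e_pas))
  tr <- out$traces$soma
  tt <- trace_times(tr)
  sel <- tt > 0 & tt <= 150
  pred <- fx$e_pas + fx$step_response(tt[sel], 0.1)
  steady <- 0.1 * fx$R
  expect_lt(max(abs(tr$v[sel] - pred)) / steady, 0.01)
})

test_that("zero stimulus after settling is quiescent", {
  fx <- gen_passive_fixture()
  out <- run_protocol(fx$model, quiet_params(),
    protocol(settle_s = 0.3, duration_ms = 1000, record = "soma",
             record_every = 40L),
    solver_config(v_init = fx$e_pas))
  expect_lt(sd(out$traces$soma$v) * 1000, 1e-6)  # uV
})

test_that("passive cable DC attenuation matches the sealed-end cosh
           profile within 2%", {
  # single unbranched cylinder, fine discretization
  L_um <- 600; d_um <- 2; rm <- 60; ra <- 200
  tree <- build_synthetic_morphology(
    soma_length = 1, soma_diam = 1, trunk_length = L_um, trunk_diam = d_um,
    n_oblique = 0, n_basal = 0)
  mod <- discretize(tree, d_lambda = 0.02, rm = rm, ra = ra)
  p <- quiet_params(); p[["rm"]] <- rm; p[["ra"]] <- ra
  out <- run_protocol(mod, p,
    protocol(settle_s = 0.3, duration_ms = 1500,
             steps = data.frame(site = "soma", t_on = 0, t_off = 1500,
                                amp_nA = 0.05),
             record = c("soma", "apical150", "apical300")),
    solver_config(v_init = -63.5))
  lam <- sqrt((rm * 1e3 / (ra)) * (d_um * 1e-4 / 4)) * 1e4  # um
  ell <- L_um / lam
  atten <- function(x_um)
    cosh(ell - x_um / lam) / cosh(ell)
  v_end <- vapply(out$traces, function(tr) tail(tr$v, 1), 0)
  defl <- v_end - (-63.5)
  x150 <- path_distance(mod, resolve_site(mod, "apical150"))
  x300 <- path_distance(mod, resolve_site(mod, "apical300"))
  expect_equal(defl[["apical150"]] / defl[["soma"]], atten(x150),
               tolerance = 0.02)
  expect_equal(defl[["apical300"]] / defl[["soma"]], atten(x300),
               tolerance = 0.02)
})

test_that("chirp stimulus has the stated sweep and amplitude", {
  ch <- make_chirp(dt = 0.025)
  # instantaneous frequency at the end of the sweep
  expect_equal(chirp_instantaneous_freq(), 15)
  expect_equal(chirp_instantaneous_freq(t = 0), 0)
  # peak-to-peak amplitude 100 pA
  expect_equal(max(ch$v) - min(ch$v), 100, tolerance = 1e-3)
  # final zero-crossing interval corresponds to ~15 Hz
  zc <- which(diff(sign(ch$v)) != 0)
  f_end <- 1000 / (2 * diff(tail(trace_times(ch)[zc], 2)))
  expect_equal(f_end, 15, tolerance = 0.05)
  # degenerate chirp: pure sinusoid, FFT peak at its frequency
  ps <- make_chirp(f0 = 4.999999, f1 = 5.000001, duration = 2, dt = 0.5)
  sp <- Mod(fft(ps$v))
  fr <- seq(0, length(ps$v) - 1) / length(ps$v) * (1000 / ps$dt_ms)
  half <- seq_len(length(ps$v) %/% 2)
  expect_equal(fr[half][which.max(sp[half])], 5, tolerance = 0.3)
  expect_error(make_chirp(f0 = 10, f1 = 5), "f1 > f0")
  expect_error(make_chirp(dt = 10), "20 samples")
})

test_that("stabilize settles a passive model to its resting potential", {
  fx <- gen_passive_fixture(R = 100, tau = 20)
  st <- stabilize(fx$model, quiet_params(), duration_s = 0.2,
                  solver_config(v_init = fx$e_pas + 10))
  # 200 ms = 10 tau: settled to the leak reversal
  expect_equal(st$v_rest, fx$e_pas, tolerance = 1e-3)
  expect_true(st$settled)
  # zero-duration stabilization returns the initial condition
  st0 <- stabilize(fx$model, quiet_params(), duration_s = 0,
                   solver_config(v_init = -71))
  expect_equal(st0$v_rest, -71)
})

test_that("halving dt moves the somatic AP peak by less than one step", {
  mod <- discretize(tiny_stick())
  p <- default_parameters()
  peak_time <- function(dt) {
    out <- run_protocol(mod, p,
      protocol(settle_s = 0.5, duration_ms = 60,
               steps = data.frame(site = "soma", t_on = 5, t_off = 55,
                                  amp_nA = 0.5),
               record = "soma"),
      solver_config(dt = dt))
    detect_spikes(out$traces$soma)$t_peak[1]
  }
  t1 <- peak_time(0.025)
  t2 <- peak_time(0.0125)
  expect_false(is.na(t1))
  expect_lt(abs(t1 - t2), 0.075)
})

test_that("charge balance holds for the passive system within 0.5%", {
  fx <- gen_passive_fixture(R = 100, tau = 20)
  p <- quiet_params()
  i_nA <- 0.1; t_on <- 10; t_off <- 130
  out <- run_protocol(fx$model, p,
    protocol(settle_s = 0.3, duration_ms = 400,
             steps = data.frame(site = "soma", t_on = t_on, t_off = t_off,
                                amp_nA = i_nA),
             record = "soma"),
    solver_config(v_init = fx$e_pas))
  tr <- out$traces$soma; tt <- trace_times(tr)
  dt <- tr$dt_ms
  q_inj <- i_nA * (t_off - t_on)                # nA ms = pC
  # leak charge + capacitive charge over the full window
  g_uS <- 1 / fx$R                              # 1/MOhm = uS
  defl <- tr$v - fx$e_pas
  q_leak <- sum(defl[-1] * g_uS * dt)           # uS mV ms = nA ms = pC
  c_nF <- fx$tau / fx$R                         # ms/MOhm = nF
  q_cap <- c_nF * (tail(tr$v, 1) - tr$v[1])     # nF mV = pC
  expect_equal(q_leak + q_cap, q_inj, tolerance = 0.005)
})

test_that("divergent simulations are reported, not silently returned", {
  mod <- discretize(tiny_stick())
  p <- default_parameters()
  p[["g_kdr"]] <- 0; p[["g_na"]] <- 3000  # absurd sodium load
  out <- run_protocol(mod, p,
    protocol(settle_s = 0, duration_ms = 50,
             steps = data.frame(site = "soma", t_on = 0, t_off = 50,
                                amp_nA = 5),
             record = "soma"))
  expect_true(out$diverged || max(out$traces$soma$v) < 500)
})
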