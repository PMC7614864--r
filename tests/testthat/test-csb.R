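test_that("protocol specifications carry the printed pulse geometry", {
  s9 <- csb_protocol("somatic900")
  expect_equal(s9$amp_nA, 0.9)
  expect_equal(c(s9$width, s9$gap, s9$n_pulses), c(100, 80, 5))
  d <- csb_protocol("dendritic1000")
  expect_equal(d$amp_nA, 1.0)
  expect_equal(c(d$width, d$gap), c(50, 50))
  expect_equal(d$site, "apical150")
  expect_error(csb_protocol("somatic50"), "arg")
})

test_that("ramp amplitude uses a spike-removing median filter", {
  # constant trace at rest: zero ramp
  expect_equal(ramp_amplitude(new_trace(rep(-65, 4000), 0.5), -65), 0)
  # narrow spikes on a flat baseline are filtered out
  g <- gen_trace(trace_recipe(spike_times = seq(100, 1900, by = 200),
                              spike_height = 100, dt = 0.5,
                              duration = 2000))
  expect_lt(abs(ramp_amplitude(g$trace, -65)), 0.5)
  # a 20 mV plateau plus spikes reads ~20 mV
  g2 <- gen_trace(trace_recipe(
    spike_times = seq(400, 1400, by = 100), spike_height = 80,
    ramp = list(amp = 20, t_on = 200, t_rise = 100, t_off = 1800),
    dt = 0.5, duration = 2000))
  expect_equal(ramp_amplitude(g2$trace, -65), 20, tolerance = 0.5)
})

test_that("pulse scoring applies the three burst criteria with inclusive
           bounds", {
  mk_pulse <- function(amps, times = c(100, 110, 118), ramp_amp = 20) {
    gen_trace(trace_recipe(
      spike_times = times, spike_height = amps,
      ramp = list(amp = ramp_amp, t_on = 50, t_rise = 50, t_off = 800),
      dt = 0.5, duration = 1000))$trace
  }
  # all three clauses satisfied
  s <- score_pulse(mk_pulse(c(95, 80, 75)), -65, 0, 1000)
  expect_true(s$valid)
  expect_equal(s$n_ap, 3)
  expect_equal(s$dv_ap, 15, tolerance = 1)
  # amplitude drop below 10 mV invalidates
  s2 <- score_pulse(mk_pulse(c(95, 90, 85)), -65, 0, 1000)
  expect_false(s2$valid)
  expect_false(s2$flags[["dvap"]])
  # ramp above 30 mV invalidates
  s3 <- score_pulse(mk_pulse(c(95, 80, 75), ramp_amp = 35), -65, 0, 1000)
  expect_false(s3$valid)
  expect_false(s3$flags[["ramp"]])
  # spikes spread beyond 25 ms invalidate the count clause
  s4 <- score_pulse(mk_pulse(c(95, 80, 75), times = c(100, 140, 180)),
                    -65, 0, 1000)
  expect_false(s4$flags[["ap"]])
  # fewer than two spikes: undefined amplitude drop, invalid pulse
  s5 <- score_pulse(mk_pulse(95, times = 100), -65, 0, 1000)
  expect_true(is.na(s5$dv_ap))
  expect_false(s5$valid)
})

test_that("raising the plateau from 5 to 20 mV flips only the ramp
           clause", {
  mk <- function(ramp_amp) gen_trace(trace_recipe(
    spike_times = c(100, 110, 118), spike_height = c(95, 80, 75),
    ramp = list(amp = ramp_amp, t_on = 50, t_rise = 50, t_off = 800),
    dt = 0.5, duration = 1000))$trace
  lo <- score_pulse(mk(5), -65, 0, 1000)
  hi <- score_pulse(mk(20), -65, 0, 1000)
  expect_false(lo$flags[["ramp"]]); expect_true(hi$flags[["ramp"]])
  expect_equal(lo$flags[c("ap", "dvap")], hi$flags[c("ap", "dvap")])
})

test_that("CSB rate excludes the first pulse", {
  expect_equal(csb_rate(c(TRUE, TRUE, TRUE, TRUE, TRUE)), 1)
  expect_equal(csb_rate(c(TRUE, FALSE, FALSE, FALSE, FALSE)), 0)
  expect_equal(csb_rate(c(FALSE, TRUE, FALSE, TRUE, FALSE)), 0.5)
  expect_error(csb_rate(c(TRUE, TRUE)), "five")
})

test_that("scoring is a pure function of the trace and criteria", {
  g <- gen_trace(trace_recipe(
    spike_times = c(100, 110, 118), spike_height = c(95, 80, 75),
    ramp = list(amp = 20, t_on = 50, t_rise = 50, t_off = 800),
    dt = 0.5, duration = 1000))
  s1 <- score_pulse(g$trace, -65, 0, 1000)
  s2 <- score_pulse(g$trace, -65, 0, 1000)
  expect_identical(s1, s2)
})

test_that("somatic protocol runs produce five pulse segments and the
           dendritic site resolves near 150 um", {
  mod <- study_model()
  proto <- csb_protocol("somatic900")
  p <- default_parameters()
  run <- run_csb_protocol(mod, p, proto,
                          solver_config(settle_s = 0.5))
  expect_equal(nrow(run$pulse_windows), 5)
  expect_equal(unname(run$pulse_windows[, 2] - run$pulse_windows[, 1]),
               rep(100, 5))
  d_site <- resolve_site(mod, csb_protocol("dendritic1000")$site)
  expect_lt(abs(path_distance(mod, d_site) - 150),
            mod$comp$length_um[d_site])
  expect_error(csb_protocol("synaptic5Hz", n_synapses = 0), "synapses")
})
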