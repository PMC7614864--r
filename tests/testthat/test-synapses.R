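test_that("magnesium block matches the printed form and is monotone", {
  # hand evaluation at 0 mV: 1/(1 + 2/3.57)
  expect_equal(mg_block(0), 1 / (1 + 2 / 3.57), tolerance = 1e-9)
  expect_gt(mg_block(1000), 1 - 1e-6)   # asymptote
  v <- seq(-120, 60, by = 1)
  expect_true(all(diff(mg_block(v)) > 0))
  expect_true(all(mg_block(v) > 0 & mg_block(v) < 1))
})

test_that("double-exponential gating is normalized to peak exactly 1", {
  expect_equal(syn_gate(0), 0)
  tgrid <- seq(0, 500, by = 0.01)
  s <- syn_gate(tgrid, 5, 50)
  expect_equal(max(s), 1, tolerance = 1e-7)
  expect_true(all(s >= 0 & s <= 1))
  # closed-form argmax
  tp <- syn_gate_peak_time(5, 50)
  expect_equal(tp, 5 * 50 / 45 * log(10), tolerance = 1e-12)
  expect_equal(tgrid[which.max(s)], tp, tolerance = 0.01)
  expect_error(syn_gate(1, 10, 5), "exceed")
})

test_that("NMDA current components vanish with the gate and reverse near
           0 mV under the standard ionic composition", {
  spec <- synapse_spec()
  # s(t = 0) = 0 -> all components zero
  expect_equal(unname(nmda_current(-40, 0, spec)), c(0, 0, 0))
  # the mixture GHK reversal sits a few mV above the nominal 0 mV
  tot <- function(v) sum(nmda_current(v, syn_gate_peak_time(5, 50), spec))
  root <- uniroot(tot, c(-15, 15))$root
  expect_lt(abs(root), 5)
  # magnesium block: |I| at -70 is far below |I| at -20 at equal gating
  r <- abs(tot(-70)) / abs(tot(-20))
  expect_lt(r, 0.25)
  # the unblocked-fraction ratio itself is below 10%
  expect_lt(mg_block(-70) / mg_block(-20), 0.1)
  # calcium component is a minority share at physiological potentials
  comp <- nmda_current(-40, 10, spec)
  expect_lt(abs(comp[["i_ca"]]), abs(sum(comp)))
})

test_that("AMPA current is inward below reversal, linear in permeability,
           and reverses near 0 mV", {
  spec <- synapse_spec()
  tp <- syn_gate_peak_time(2, 10)
  expect_lt(sum(ampa_current(-70, tp, spec)), 0)
  s2 <- synapse_spec(pbar_ampa = 2 * spec$pbar_ampa)
  expect_equal(sum(ampa_current(-50, tp, s2)),
               2 * sum(ampa_current(-50, tp, spec)), tolerance = 1e-12)
  root <- uniroot(function(v) sum(ampa_current(v, tp, spec)),
                  c(-15, 15))$root
  expect_lt(abs(root), 3)
})

test_that("synapse placement is reproducible, region-restricted and
           area-weighted", {
  mod <- study_model()
  s1 <- place_synapses(mod, 100, seed = 42)
  s2 <- place_synapses(mod, 100, seed = 42)
  expect_identical(s1$loc, s2$loc)
  expect_true(all(mod$comp$region[s1$loc] == "apical_sr"))
  expect_error(place_synapses(mod, 10, region = "nonexistent"), "region")
  # chi-squared goodness of fit against area weights over many draws
  big <- place_synapses(mod, 10000, seed = 7)
  comps <- which(mod$comp$region == "apical_sr")
  w <- mod$comp$area_cm2[comps] / sum(mod$comp$area_cm2[comps])
  obs <- tabulate(match(big$loc, comps), nbins = length(comps))
  pval <- suppressWarnings(chisq.test(obs, p = w)$p.value)
  expect_gt(pval, 0.001)
})

test_that("multi-event trains superpose linearly in the compiled kernel", {
  # the shared-kernel state must equal the sum of per-event kernels
  mod <- discretize(tiny_stick())
  syn <- place_synapses(mod, 5, seed = 1)
  syn <- synaptic_train(syn, times = c(5, 30, 55))
  p <- quiet_params()
  out <- run_protocol(mod, p,
    protocol(settle_s = 0.2, duration_ms = 120, synapses = syn,
             record = "soma"),
    solver_config(v_init = -63.5))
  st <- out$state$syn  # (ampa rise, ampa decay, nmda rise, nmda decay)
  t_end <- 120
  expect_equal(st[3], sum(exp(-(t_end - c(5, 30, 55)) / 5)),
               tolerance = 1e-9)
  expect_equal(st[4], sum(exp(-(t_end - c(5, 30, 55)) / 50)),
               tolerance = 1e-9)
  # and the synaptic drive depolarizes the cell
  expect_gt(max(out$traces$soma$v), -63.4)
})
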