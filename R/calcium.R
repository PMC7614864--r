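# Calcium handling: mobile buffer, membrane pump, radial diffusion across
# four annuli per compartment and longitudinal diffusion along the tree.

#' Calcium-handling configuration
#'
#' Buffer kinetics, diffusion coefficients and pump constants with
#' documented defaults; the two search parameters `totbuf` (total buffer
#' concentration, mM) and `totpp` (total pump density, scaling factor on
#' the pump flux) plug in per model.
#'
#' The pump is net-zero at the 100 nM resting concentration (its Michaelis
#' term is referenced to rest), so the influx-free state is stationary.
#'
#' @param totbuf total calcium buffer concentration (mM).
#' @param totpp total calcium pump density (dimensionless scale).
#' @param k_on buffer forward rate (/mM/ms).
#' @param k_off buffer backward rate (/ms); `k_off/k_on` is the buffer Kd.
#' @param D_ca calcium diffusion coefficient (um^2/ms).
#' @param D_buf mobile-buffer diffusion coefficient (um^2/ms).
#' @param pump_vmax pump surface flux density per unit `totpp` (mM um/ms).
#' @param pump_km pump Michaelis constant (mM).
#' @param ca0 resting free calcium (mM; 100 nM).
#' @param ca_out extracellular calcium (mM).
#' @param longitudinal enable longitudinal diffusion between compartments.
#' @return a `calcium_config` list.
#' @export
calcium_config <- function(totbuf = 1.2, totpp = 0.2,
                           k_on = 5, k_off = 0.05,
                           D_ca = 0.22, D_buf = 0.05,
                           pump_vmax = 3e-2, pump_km = 2e-3,
                           ca0 = 1e-4, ca_out = 2,
                           longitudinal = TRUE) {
  stopifnot(totbuf >= 0, totpp >= 0, k_on > 0, k_off > 0,
            pump_km > 0, ca0 > 0)
  structure(list(totbuf = totbuf, totpp = totpp, k_on = k_on, k_off = k_off,
                 D_ca = D_ca, D_buf = D_buf, pump_vmax = pump_vmax,
                 pump_km = pump_km, ca0 = ca0, ca_out = ca_out,
                 longitudinal = longitudinal), class = "calcium_config")
}

# C++-facing calcium block for a model
calcium_net_block <- function(model, cacfg) {
  n <- nrow(model$comp)
  list(D_ca = cacfg$D_ca, D_buf = cacfg$D_buf,
       k_on = cacfg$k_on, k_off = cacfg$k_off,
       pump_km = cacfg$pump_km, ca0 = cacfg$ca0, ca_out = cacfg$ca_out,
       totbuf_comp = rep(cacfg$totbuf, n),
       pump_vmax_comp = rep(cacfg$totpp * cacfg$pump_vmax, n),
       longitudinal = isTRUE(cacfg$longitudinal))
}

#' Initialize the calcium state of a model
#'
#' Free calcium at the 100 nM resting value in all four annuli of every
#' compartment, with the mobile buffer equilibrated to its influx-free
#' steady state (`bound/total = ca0/(ca0 + Kd)`).
#'
#' @param model a `compartmental_model`.
#' @param cacfg a [calcium_config()].
#' @return A `calcium_state`: matrices (`compartments x 4` annuli, annulus 1
#'   the submembrane shell) `ca` (free calcium, mM), `buf` (free buffer),
#'   `cab` (bound buffer).
#' @export
init_calcium <- function(model, cacfg = calcium_config()) {
  n <- nrow(model$comp)
  kd <- cacfg$k_off / cacfg$k_on
  ca <- matrix(cacfg$ca0, n, 4)
  cab <- matrix(cacfg$totbuf * cacfg$ca0 / (cacfg$ca0 + kd), n, 4)
  buf <- matrix(cacfg$totbuf, n, 4) - cab
  structure(list(ca = ca, buf = buf, cab = cab, config = cacfg),
            class = "calcium_state")
}

# shell volumes (um^3) for a compartment, annulus 1 = submembrane
shell_volumes <- function(model) {
  r <- model$comp$diam_um / 2
  L <- model$comp$length_um
  dr <- r / 4
  sapply(0:3, function(s) {
    ro <- r - s * dr; ri <- r - (s + 1) * dr
    pi * (ro^2 - ri^2) * L
  })
}

#' Total calcium content of a calcium state (free + buffer-bound)
#'
#' Volume-weighted sum over all annuli and compartments; the conserved
#' quantity when the pump is disabled and no membrane flux occurs.
#'
#' @param model a `compartmental_model`.
#' @param state a `calcium_state` or a simulation `state` list with `ca`
#'   and `cab` entries.
#' @return total calcium in mM um^3 (attomol-scale arbitrary unit).
#' @export
total_calcium <- function(model, state) {
  vol <- shell_volumes(model)
  ca <- state$ca; cab <- state$cab
  if (!is.matrix(ca)) ca <- matrix(ca, ncol = 4, byrow = TRUE)
  if (!is.matrix(cab)) cab <- matrix(cab, ncol = 4, byrow = TRUE)
  sum((ca + cab) * vol)
}

#' Step the calcium system under a prescribed membrane calcium current
#'
#' Runs the reaction-diffusion calcium machinery (buffer mass action, pump,
#' radial and longitudinal diffusion, membrane influx into the submembrane
#' annulus) on a channel-free model for `duration` ms. Voltage dynamics are
#' passive and do not feed back on calcium, making this the isolated
#' calcium-module path of the integrator.
#'
#' @param model a `compartmental_model`.
#' @param state a `calcium_state` from [init_calcium()].
#' @param influx data frame / matrix with columns `comp`, `t_on`, `t_off`
#'   (ms), `amp` (inward calcium current density, uA/cm^2); `NULL` for
#'   none.
#' @param duration simulated time (ms).
#' @param dt step (ms), at most 0.025.
#' @param pump_off disable the pump (for conservation checks).
#' @return updated `calcium_state` with an attached `trace` attribute
#'   (submembrane calcium of compartment 1 over time).
#' @export
step_calcium <- function(model, state, influx = NULL, duration = 10,
                         dt = 0.025, pump_off = FALSE) {
  if (dt > 0.025 + 1e-12) stop("dt must be <= 0.025 ms")
  cacfg <- state$config
  if (pump_off) cacfg$totpp <- 0
  kin <- load_kinetics()
  params <- default_parameters()
  params[c("g_na", "g_kdr", "g_ka", "g_km", "g_h", "g_cal", "g_cat",
           "g_can", "g_sk", "g_bk")] <- 0
  net <- assemble_net(model, params, kin, solver_config(dt = dt),
                      cacfg = cacfg)
  if (!is.null(influx)) {
    influx <- as.matrix(influx)
    net$ca_steps <- cbind(influx[, 1] - 1, influx[, 2], influx[, 3],
                          influx[, 4])
  }
  st0 <- list(v = rep(net$v_init, net$n_comp),
              ca = as.numeric(t(state$ca)), buf = as.numeric(t(state$buf)),
              cab = as.numeric(t(state$cab)),
              gates = numeric(length(net$gates) * net$n_comp))
  nsteps <- round(duration / dt)
  out <- .sim_core(net, dt, nsteps, 0, st0, 1L, 0L, 0L)
  if (out$ca_negative)
    stop("calcium stepping produced a negative concentration; dt too large")
  fin <- out$state
  structure(list(ca = matrix(fin$ca, ncol = 4, byrow = TRUE),
                 buf = matrix(fin$buf, ncol = 4, byrow = TRUE),
                 cab = matrix(fin$cab, ncol = 4, byrow = TRUE),
                 config = state$config,
                 trace = list(t = out$t, ca = out$ca[, 1])),
            class = "calcium_state")
}
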