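# Channel mechanisms: declarative Hodgkin-Huxley kinetics, current laws
# (Ohmic / Goldman-Hodgkin-Katz) and somatodendritic distribution rules.

#' Load channel gating kinetics from a declarative YAML file
#'
#' Gating kinetics ship as data, not code: each channel declares its current
#' law (`ohmic` with a reversal potential, or `ghk` for calcium-permeable
#' channels), its gates (exponent plus steady-state and time-constant
#' parameters) and, for GHK channels, the permeability conversion factor
#' `p_factor` (cm/s per mS/cm^2) that maps the density parameter onto a GHK
#' permeability. The packaged default (`inst/extdata/kinetics/default.yaml`)
#' is a CA3/CA1-style Boltzmann parameterization written and tuned for this
#' package.
#'
#' Gate kinds: `v` (voltage-gated Boltzmann steady state
#' `1/(1+exp((vhalf-v)/k))` with bell-shaped time constant
#' `base + amp/(exp((v-vh)/ka)+exp(-(v-vh)/kb))`), `ca` (Hill activation by
#' submembrane calcium, constant tau), `vca` (voltage Boltzmann whose
#' half-activation shifts with log calcium; the BK mechanism).
#'
#' @param path YAML file; `NULL` loads the packaged default.
#' @return A `kinetics_set`: named list of channel specs.
#' @export
load_kinetics <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "kinetics", "default.yaml",
                        package = "ca3pop")
  spec <- yaml::read_yaml(path)
  ks <- spec$channels
  for (nm in names(ks)) {
    ch <- ks[[nm]]
    if (!ch$law %in% c("ohmic", "ghk"))
      stop("channel ", nm, ": unknown current law ", ch$law)
    for (g in ch$gates) {
      if (!g$kind %in% c("v", "ca", "vca"))
        stop("channel ", nm, ": unknown gate kind ", g$kind)
    }
  }
  structure(ks, class = "kinetics_set",
            celsius = if (!is.null(spec$celsius)) spec$celsius else 34)
}

#' Steady-state activation of a gate at given voltage / calcium
#'
#' @param gate a gate spec from a [load_kinetics()] channel.
#' @param v membrane potential (mV), vectorized.
#' @param ca submembrane calcium (mM), used by `ca`/`vca` gates.
#' @return steady-state value in `[0, 1]`.
#' @export
gate_inf <- function(gate, v, ca = 100e-6) {
  switch(gate$kind,
    v = 1 / (1 + exp((gate$inf$vhalf - v) / gate$inf$k)),
    ca = 1 / (1 + (gate$kd / ca)^gate$nhill),
    vca = {
      vh <- gate$vh0 - gate$sh * log10(ca / gate$caref)
      1 / (1 + exp(-(v - vh) / gate$k))
    })
}

#' Time constant of a gate at given voltage (ms)
#'
#' @inheritParams gate_inf
#' @return time constant in ms (> 0).
#' @export
gate_tau <- function(gate, v) {
  if (gate$kind != "v") return(rep(gate$tau, length.out = length(v)))
  tu <- gate$tau
  if (identical(tu$form, "sigmoid")) {
    # monotone voltage dependence (e.g. slow deactivation on
    # hyperpolarization): base + amp / (1 + exp((v - vhalf)/k))
    tu$base + tu$amp / (1 + exp((v - tu$vhalf) / tu$k))
  } else {
    tu$base + tu$amp / (exp((v - tu$vhalf) / tu$ka) +
                        exp(-(v - tu$vhalf) / tu$kb))
  }
}

#' HCN channel density as a function of apical path distance
#'
#' The h-conductance rises linearly along the apical dendrite:
#' `g_h(x) = g_bar (1 + 3x/100)`; soma and basal compartments carry the
#' somatic value `g_bar` (x treated as 0).
#'
#' @param x path distance from the soma (um), on the apical dendrite.
#' @param g_bar somatic maximal density (any density unit).
#' @return density in the unit of `g_bar`.
#' @export
hcn_density <- function(x, g_bar) {
  if (any(x < 0)) stop("path distance must be non-negative")
  g_bar * (1 + 3 * x / 100)
}

#' Table 1 channel names carried by a parameter vector
#' @return character vector of the ten channel mechanisms.
#' @export
channel_names <- function() {
  c("NaF", "KDR", "KA", "KM", "HCN", "CaL", "CaT", "CaN", "SK", "BK")
}

#' Assign channel densities to every compartment
#'
#' Applies the somatodendritic distribution rules: NaF, KDR, CaN, SK, BK and
#' CaT uniform everywhere; CaL perisomatic (path distance <= 50 um); KM
#' perisomatic (<= 100 um); KA with proximal kinetics at <= 100 um and
#' distal kinetics beyond, with density increasing linearly with apical
#' distance (`1 + x/100`); HCN increasing along the apical dendrite per
#' [hcn_density()]. GHK channel densities are converted to permeabilities
#' with the kinetics file's `p_factor`.
#'
#' @param model a `compartmental_model`.
#' @param params a parameter vector from [default_parameters()] /
#'   [sample_parameters()].
#' @param kinetics a `kinetics_set`.
#' @param ka_slope slope (per 100 um) of the linear apical A-type density
#'   gradient `1 + ka_slope * x / 100`.
#' @return matrix (compartments x mechanism instances) of densities
#'   (mS/cm^2 for ohmic channels, cm/s for GHK channels); KA appears as the
#'   two kinetic variants `KA_prox` / `KA_dist` with disjoint support.
#' @export
assign_conductances <- function(model, params, kinetics = load_kinetics(),
                                ka_slope = 12.5) {
  x <- model$comp$path_um
  apical <- startsWith(model$comp$region, "apical")
  n <- nrow(model$comp)
  need <- c("NaF", "KDR", "KA_prox", "KA_dist", "KM", "HCN",
            "CaL", "CaT", "CaN", "SK", "BK")
  miss <- setdiff(need, names(kinetics))
  if (length(miss))
    stop("kinetics file lacks channel definitions: ",
         paste(miss, collapse = ", "))
  dens <- matrix(0, n, length(need), dimnames = list(NULL, need))
  dens[, "NaF"] <- params[["g_na"]]
  dens[, "KDR"] <- params[["g_kdr"]]
  ka <- ifelse(apical, params[["g_ka"]] * (1 + ka_slope * x / 100),
               params[["g_ka"]])
  dens[, "KA_prox"] <- ifelse(x <= 100, ka, 0)
  dens[, "KA_dist"] <- ifelse(x > 100, ka, 0)
  dens[, "KM"] <- ifelse(x <= 100, params[["g_km"]], 0)
  gh_ms <- params[["g_h"]] / 1000  # uS/cm^2 -> mS/cm^2
  dens[, "HCN"] <- ifelse(apical, hcn_density(x, gh_ms), gh_ms)
  dens[, "CaL"] <- ifelse(x <= 50, params[["g_cal"]], 0)
  dens[, "CaT"] <- params[["g_cat"]]
  dens[, "CaN"] <- params[["g_can"]]
  dens[, "SK"] <- params[["g_sk"]]
  dens[, "BK"] <- params[["g_bk"]]
  for (nm in need) {
    if (kinetics[[nm]]$law == "ghk")
      dens[, nm] <- dens[, nm] * kinetics[[nm]]$p_factor
  }
  dens
}

#' Goldman-Hodgkin-Katz constant-field current density
#'
#' `I = P z^2 F^2 v/(RT) (c_in - c_out e^{-zFv/RT})/(1 - e^{-zFv/RT})`,
#' continuous at `v = 0` (analytic limit), outward current positive.
#'
#' @param v membrane potential (mV), vectorized.
#' @param P permeability (cm/s).
#' @param c_in,c_out intra-/extracellular concentrations (mM).
#' @param z ion valence.
#' @param T_K absolute temperature (K).
#' @return current density in uA/cm^2.
#' @export
ghk_current <- function(v, P, c_in, c_out, z = 2, T_K = 307.15) {
  if (any(c_in <= 0) || any(c_out <= 0))
    stop("concentrations must be positive")
  if (T_K <= 0) stop("temperature must be positive")
  xi <- z * (v * 1e-3) * .FARADAY / (.RGAS * T_K)
  term <- ifelse(abs(xi) < 1e-6,
                 (c_in - c_out) + 0.5 * xi * (c_in + c_out),
                 xi * (c_in - c_out * exp(-xi)) / (1 - exp(-xi)))
  P * z * .FARADAY * term  # (mM=1e-6 mol/cm^3) * 1e-6 -> A/cm^2 -> *1e6 uA
}

#' Membrane current of one channel at a given state
#'
#' Ohmic law: `g_bar * gates * (v - E_rev)`; GHK law:
#' `P_bar * gates * GHK flux` with submembrane/extracellular calcium.
#'
#' @param spec channel spec from a `kinetics_set`.
#' @param state named/ordered numeric vector of gate values in `[0,1]`.
#' @param v membrane potential (mV).
#' @param ca submembrane calcium (mM).
#' @param dens maximal density: mS/cm^2 (ohmic) or cm/s (GHK permeability).
#' @param ca_out extracellular calcium (mM).
#' @param T_K absolute temperature (K).
#' @return current density in uA/cm^2 (ohmic values are mS/cm^2 * mV =
#'   uA/cm^2).
#' @export
channel_current <- function(spec, state, v, ca = 100e-6, dens = 1,
                            ca_out = 2, T_K = 307.15) {
  if (any(state < 0 | state > 1)) stop("gate state outside [0, 1]")
  open <- prod(vapply(seq_along(spec$gates),
                      function(i) state[[i]]^spec$gates[[i]]$exponent, 0))
  if (spec$law == "ohmic") {
    dens * open * (v - spec$erev) * 1e3  # mS/cm^2 * mV -> uA/cm^2
  } else {
    ghk_current(v, dens * open, ca, ca_out, z = 2, T_K = T_K)
  }
}

# Precompute per-gate voltage tables (steady state and exponential-Euler
# step factor 1-exp(-dt/tau)) for the compiled core.
build_gate_tables <- function(kinetics, dt, vmin = -120, vmax = 60,
                              dv = 0.5) {
  vgrid <- seq(vmin, vmax, by = dv)
  chans <- list(); gates <- list()
  gi <- 0L
  for (nm in names(kinetics)) {
    ch <- kinetics[[nm]]
    gidx <- integer(0)
    for (g in ch$gates) {
      gi <- gi + 1L
      if (g$kind == "v") {
        tau <- pmax(gate_tau(g, vgrid), 1e-4)
        gates[[gi]] <- list(channel = gi, exponent = as.integer(g$exponent),
                            kind = 0L, inf = gate_inf(g, vgrid),
                            afac = 1 - exp(-dt / tau))
      } else if (g$kind == "ca") {
        gates[[gi]] <- list(channel = gi, exponent = as.integer(g$exponent),
                            kind = 1L, kd = g$kd, nhill = g$nhill,
                            afac = 1 - exp(-dt / g$tau))
      } else {
        gates[[gi]] <- list(channel = gi, exponent = as.integer(g$exponent),
                            kind = 2L, vh0 = g$vh0, sh = g$sh,
                            caref = g$caref, k = g$k,
                            afac = 1 - exp(-dt / g$tau))
      }
      gidx <- c(gidx, gi)
    }
    chans[[nm]] <- list(law = if (ch$law == "ohmic") 0L else 1L,
                        erev = if (!is.null(ch$erev)) ch$erev else 0,
                        gates0 = gidx - 1L)
  }
  list(channels = chans, gates = gates, vmin = vmin, dv = dv,
       nv = length(vgrid))
}
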