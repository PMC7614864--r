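# Multi-parametric multi-objective stochastic search: uniform sampling of
# the 14-parameter space, measurement evaluation, validation against the
# electrophysiological bounds, and population persistence.

#' Base values of the 14 model parameters
#'
#' Passive properties (R_m kOhm cm^2, R_a Ohm cm), the nine maximal channel
#' conductances (mS/cm^2; HCN in uS/cm^2) and the two calcium-handling
#' scales (total pump density, total buffer concentration).
#'
#' @return named numeric vector of length 14.
#' @export
default_parameters <- function() {
  c(rm = 60, ra = 200,
    g_na = 15, g_kdr = 11, g_h = 1, g_ka = 0.1,
    g_cal = 2.5, g_cat = 0.25, g_can = 2.5, g_km = 0.01,
    g_bk = 0.8, g_sk = 0.5,
    totpp = 0.2, totbuf = 1.2)
}

#' Search bounds of the 14 model parameters
#'
#' @return data frame with `parameter`, `lower`, `upper` (units as in
#'   [default_parameters()]).
#' @export
parameter_bounds <- function() {
  data.frame(
    parameter = names(default_parameters()),
    lower = c(60, 150, 7.5, 5.5, 0.5, 0.05, 1.25, 0.125, 1.25, 0.005,
              0.4, 0.25, 0.01, 0.1),
    upper = c(100, 400, 30, 22, 6, 0.2, 5, 0.5, 5, 0.02,
              1.6, 1, 0.5, 2.5))
}

#' Electrophysiological validation bounds (the 11 intrinsic measurements)
#'
#' @return data frame with `measurement`, `lower`, `upper`: resting
#'   potential (mV), its SD (uV), input resistance (MOhm), sag ratio,
#'   resonance frequency (Hz) and strength, peak impedance (MOhm), firing
#'   rate at 250 pA (Hz), and AP amplitudes at the soma, 150 um and 300 um
#'   (mV).
#' @export
measurement_bounds <- function() {
  data.frame(
    measurement = c("v_rmp", "v_sd_uv", "r_in", "sag", "f_r", "q_r",
                    "z_max", "f_250", "v_ap0", "v_ap150", "v_ap300"),
    lower = c(-70, 0, 60, 0.94, 1, 1, 65, 4, 90, 70, 60),
    upper = c(-60, 0.01, 150, 1, 1.76, 1.1, 150, 10, 110, 90, 80))
}

# deterministic per-row seed below 2^31
derive_seed <- function(seed, index) {
  (as.numeric(seed) %% 65536) * 32003 + index * 7 + 1
}

#' Draw one parameter vector uniformly within the search bounds
#'
#' Independent uniform draws per parameter, reproducible per
#' `(seed, index)` so search rows are independent tasks.
#'
#' @param bounds data frame from [parameter_bounds()].
#' @param seed global seed.
#' @param index row index (1-based).
#' @return named parameter vector.
#' @export
sample_parameters <- function(bounds = parameter_bounds(), seed = 1,
                              index = 1) {
  if (any(bounds$lower > bounds$upper))
    stop("malformed bounds: lower > upper")
  p <- withr_seed(derive_seed(seed, index),
                  runif(nrow(bounds), bounds$lower, bounds$upper))
  setNames(p, bounds$parameter)
}

#' Validate a measurement vector against the electrophysiological bounds
#'
#' Inclusive interval tests; a model is valid iff all 11 measurements fall
#' within their bounds.
#'
#' @param m named list/vector of measurements (from [measure_model()]).
#' @param bounds data frame from [measurement_bounds()].
#' @return list(`valid`, `flags` named logical vector).
#' @export
validate_measurements <- function(m, bounds = measurement_bounds()) {
  miss <- setdiff(bounds$measurement, names(m))
  if (length(miss))
    stop("missing measurements: ", paste(miss, collapse = ", "))
  vals <- unlist(m[bounds$measurement])
  flags <- is.finite(vals) & vals >= bounds$lower & vals <= bounds$upper
  names(flags) <- bounds$measurement
  list(valid = all(flags), flags = flags)
}

#' Run the stochastic population search
#'
#' Samples `n` parameter vectors uniformly within the Table-of-bounds
#' ranges, measures each model's full battery, validates it, and returns
#' the population table. Rows are independent (per-row seeds derive from
#' `(seed, index)`), so chunked or resumed runs reproduce the same rows.
#'
#' @param n number of models.
#' @param seed global seed.
#' @param model a `compartmental_model` shared by all rows.
#' @param config a [solver_config()].
#' @param kinetics a `kinetics_set`.
#' @param bounds parameter bounds; collapse `lower = upper` to pin values.
#' @param mbounds measurement bounds.
#' @param classify also classify IB/RS per model.
#' @param short_circuit reject models at the first out-of-bounds
#'   measurement, skipping the remaining (more expensive) protocols; valid
#'   models are always fully measured (default TRUE).
#' @param progress print one line per model.
#' @param indices optional subset of row indices to (re)compute.
#' @return a `population_table` data frame: model id, seed, the 14
#'   parameters, the measurements, per-criterion pass flags and the `valid`
#'   conjunction; failed (diverged) rows carry `failed = TRUE`.
#' @export
run_search <- function(n, seed = 1, model = NULL,
                       config = solver_config(), kinetics = load_kinetics(),
                       bounds = parameter_bounds(),
                       mbounds = measurement_bounds(),
                       classify = FALSE, short_circuit = TRUE,
                       progress = FALSE, indices = NULL) {
  if (is.null(model)) model <- discretize(build_synthetic_morphology())
  if (is.null(indices)) indices <- seq_len(n)
  rows <- vector("list", length(indices))
  for (k in seq_along(indices)) {
    i <- indices[k]
    p <- sample_parameters(bounds, seed, i)
    row <- tryCatch({
      m <- measure_model(model, p, config, kinetics, classify = classify,
                         bounds = if (short_circuit) mbounds else NULL)
      val <- validate_measurements(m, mbounds)
      cls <- if (classify) m$class else NA_character_
      m$class <- NULL
      data.frame(id = i, seed = derive_seed(seed, i), t(p),
                 as.data.frame(m, check.names = FALSE),
                 t(setNames(as.numeric(val$flags),
                            paste0("ok_", names(val$flags)))),
                 valid = val$valid, class = cls, failed = FALSE)
    }, error = function(e) {
      data.frame(id = i, seed = derive_seed(seed, i), t(p),
                 valid = FALSE, class = NA_character_, failed = TRUE)
    })
    rows[[k]] <- row
    if (progress)
      message(sprintf("model %d/%d%s", i, max(indices),
                      if (isTRUE(row$valid)) " [valid]" else ""))
  }
  # align columns across failed/ok rows before binding
  allc <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    for (cc in setdiff(allc, names(r))) r[[cc]] <- NA
    r[allc]
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("population_table", "data.frame")
  out
}

#' Degeneracy summary of a valid population
#'
#' Reports, for each of the 14 parameters, the span of values across the
#' valid models as a fraction of the search range (1 = the bound-to-bound
#' range is fully explored) plus min/max.
#'
#' @param pop a `population_table`.
#' @param bounds parameter bounds.
#' @return data frame per parameter.
#' @export
parameter_spans <- function(pop, bounds = parameter_bounds()) {
  vv <- pop[pop$valid %in% TRUE, , drop = FALSE]
  do.call(rbind, lapply(seq_len(nrow(bounds)), function(i) {
    pn <- bounds$parameter[i]
    x <- vv[[pn]]
    rng <- bounds$upper[i] - bounds$lower[i]
    data.frame(parameter = pn,
               n = length(x),
               min = if (length(x)) min(x) else NA_real_,
               max = if (length(x)) max(x) else NA_real_,
               span_frac = if (length(x) && rng > 0)
                 (max(x) - min(x)) / rng else NA_real_)
  }))
}
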