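# Virtual knockout models: zero one channel conductance or the NMDAR
# permeability, re-run CSB protocols with identical seeds, and report
# percentage changes.

#' Targets allowed for virtual knockout
#'
#' The spike-generating NaF and KDR channels are excluded so knockout
#' models can still fire.
#'
#' @param with_nmdar include the NMDAR (synaptic protocol only).
#' @return character vector of knockout targets.
#' @export
vkm_targets <- function(with_nmdar = FALSE) {
  ch <- c("KA", "KM", "CaL", "CaN", "CaT", "SK", "BK", "HCN")
  if (with_nmdar) c(ch, "NMDAR") else ch
}

.vkm_param <- c(KA = "g_ka", KM = "g_km", CaL = "g_cal", CaN = "g_can",
                CaT = "g_cat", SK = "g_sk", BK = "g_bk", HCN = "g_h")

#' Build a knockout configuration
#'
#' Returns the parameter vector (and synapse spec, for NMDAR) with exactly
#' one maximal conductance / permeability zeroed; all other fields are
#' untouched. AMPAR permeability stays intact under NMDAR knockout.
#'
#' @param params parameter vector.
#' @param target one of [vkm_targets()]`(TRUE)`.
#' @param spec a [synapse_spec()] (needed for NMDAR).
#' @return list(`params`, `spec`, `target`).
#' @export
make_knockout <- function(params, target, spec = synapse_spec()) {
  if (target %in% c("NaF", "KDR"))
    stop("NaF and KDR are excluded from knockout analyses")
  if (target == "NMDAR") {
    spec$pbar_nmda <- 0
    return(list(params = params, spec = spec, target = target))
  }
  if (!target %in% names(.vkm_param)) stop("unknown knockout target: ",
                                           target)
  params[[.vkm_param[[target]]]] <- 0
  list(params = params, spec = spec, target = target)
}

#' Enumerate knockout runs for a population
#'
#' Cartesian product of model ids and targets.
#'
#' @param model_ids vector of model identifiers.
#' @param targets knockout targets.
#' @return data frame with `model`, `target`; `nrow = |models| x
#'   |targets|`.
#' @export
schedule_vkm <- function(model_ids, targets = vkm_targets()) {
  if (!length(model_ids) || !length(targets))
    stop("need a non-empty population and target set")
  expand.grid(model = model_ids, target = targets,
              stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

#' Percentage change of a knockout measurement versus base
#'
#' `100 (vkm - base) / base`; undefined (NA) when the base is zero.
#'
#' @param base,vkm numeric values.
#' @return percentage change, vectorized.
#' @export
percent_change <- function(base, vkm) {
  ifelse(base == 0, NA_real_, 100 * (vkm - base) / base)
}

#' Run one virtual knockout and compare CSB measurements with base
#'
#' Re-runs the given CSB protocol with the target zeroed, under identical
#' seeds and synapse placement, and reports percentage changes in the
#' first-to-second AP amplitude drop, ramp amplitude and CSB rate.
#'
#' @param model a `compartmental_model`.
#' @param params base parameter vector.
#' @param target knockout target.
#' @param proto a [csb_protocol()].
#' @param config,kinetics as elsewhere.
#' @param base_result optional pre-computed base `csb_result`.
#' @return list(`base`, `knockout` (`csb_result`s), `change` named
#'   percentages).
#' @export
run_vkm <- function(model, params, target, proto = csb_protocol(),
                    config = solver_config(), kinetics = load_kinetics(),
                    base_result = NULL) {
  ko <- make_knockout(params, target,
                      spec = if (!is.null(proto$spec)) proto$spec
                             else synapse_spec())
  if (is.null(base_result)) {
    base_run <- run_csb_protocol(model, params, proto, config, kinetics)
    base_result <- score_csb(base_run)
  }
  proto_ko <- proto
  if (target == "NMDAR") proto_ko$spec <- ko$spec
  ko_run <- run_csb_protocol(model, ko$params, proto_ko, config, kinetics)
  ko_result <- score_csb(ko_run)
  list(base = base_result, knockout = ko_result, target = target,
       change = c(dv_ap = percent_change(base_result$dv_ap,
                                         ko_result$dv_ap),
                  v_ramp = percent_change(base_result$v_ramp,
                                          ko_result$v_ramp),
                  rate = percent_change(base_result$rate, ko_result$rate)))
}

#' Paired synapse-site calcium traces with and without NMDARs
#'
#' Runs the synaptic CSB protocol twice with identical synapse placement
#' (same seed): once intact and once with the NMDAR permeability zeroed,
#' recording submembrane calcium at the compartment hosting the most
#' synapses.
#'
#' @param model,params,config,kinetics as elsewhere.
#' @param proto a synaptic [csb_protocol()].
#' @return list(`base`, `knockout` calcium `ca3_trace`s, `peak_base`,
#'   `peak_ko` in mM).
#' @export
calcium_comparison <- function(model, params,
                               proto = csb_protocol("synaptic5Hz"),
                               config = solver_config(),
                               kinetics = load_kinetics()) {
  if (proto$kind != "synaptic5Hz")
    stop("calcium comparison requires the synaptic protocol")
  base <- run_csb_protocol(model, params, proto, config, kinetics,
                           record_ca = TRUE)
  ko <- make_knockout(params, "NMDAR", spec = proto$spec)
  proto_ko <- proto; proto_ko$spec <- ko$spec
  kor <- run_csb_protocol(model, ko$params, proto_ko, config, kinetics,
                          record_ca = TRUE)
  ca_b <- base$ca_traces[[1]]; ca_k <- kor$ca_traces[[1]]
  list(base = ca_b, knockout = ca_k,
       peak_base = max(ca_b$v), peak_ko = max(ca_k$v))
}
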