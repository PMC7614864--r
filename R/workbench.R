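# Workbench: configuration, staged pipeline orchestration and CSV
# persistence with seed/config provenance.

#' Pipeline run configuration
#'
#' Bundles the morphology source, solver settings, search size/seed and
#' output directory; all defaults reproduce the packaged study conditions
#' (the printed parameter and measurement bounds, 25 us steps, 5 s
#' settle).
#'
#' @param file optional YAML file whose top-level keys override defaults.
#' @param ... named overrides (applied after the file).
#' @return a `run_config` list.
#' @export
workbench_config <- function(file = NULL, ...) {
  cfg <- list(
    morphology = list(source = "synthetic", d_lambda = 0.1, f_lambda = 100),
    kinetics = NULL,          # NULL = packaged defaults
    n_models = 200, seed = 1,
    dt = 0.025, settle_s = 5,
    csb_protocols = c("somatic900", "synaptic5Hz"),
    vkm_targets = vkm_targets(),
    out_dir = "results")
  if (!is.null(file)) {
    ov <- yaml::read_yaml(file)
    cfg[names(ov)] <- ov
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

config_digest <- function(cfg) digest_string(unclass(cfg))

build_study_model <- function(cfg) {
  if (identical(cfg$morphology$source, "synthetic"))
    tree <- build_synthetic_morphology()
  else
    tree <- load_swc(cfg$morphology$source)
  discretize(tree, d_lambda = cfg$morphology$d_lambda,
             f = cfg$morphology$f_lambda)
}

#' Run the staged analysis pipeline
#'
#' Stages: `search` (stochastic population search), `classify` (IB/RS
#' labels for valid models), `csb` (burst induction + scoring), `vkm`
#' (virtual knockouts of models with valid bursts), `report` (summary
#' tables). Later stages require the artifacts of earlier ones (from this
#' call or a previous run persisted in `cfg$out_dir`).
#'
#' @param cfg a [workbench_config()].
#' @param stages ordered subset of
#'   `c("search", "classify", "csb", "vkm", "report")`.
#' @param quiet suppress progress output.
#' @return named list of stage artifacts (also written as CSV under
#'   `cfg$out_dir`).
#' @export
run_pipeline <- function(cfg = workbench_config(),
                         stages = c("search", "classify", "csb"),
                         quiet = TRUE) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  kin <- if (is.null(cfg$kinetics)) load_kinetics()
         else load_kinetics(cfg$kinetics)
  config <- solver_config(dt = cfg$dt, settle_s = cfg$settle_s)
  model <- build_study_model(cfg)
  art <- list()
  meta <- data.frame(key = c("config_digest", "seed", "n_models"),
                     value = c(config_digest(cfg), cfg$seed, cfg$n_models))
  write.csv(meta, file.path(cfg$out_dir, "provenance.csv"),
            row.names = FALSE)

  need <- function(stage, dep, key, reader) {
    if (!is.null(art[[key]])) return(art[[key]])
    f <- file.path(cfg$out_dir, paste0(key, ".csv"))
    if (!file.exists(f))
      stop("stage '", stage, "' requires the '", dep,
           "' artifact; run that stage first")
    reader(f)
  }

  for (st in stages) {
    if (st == "search") {
      pop <- run_search(cfg$n_models, cfg$seed, model, config, kin,
                        progress = !quiet)
      write.csv(pop, file.path(cfg$out_dir, "population.csv"),
                row.names = FALSE)
      art$population <- pop
    } else if (st == "classify") {
      pop <- need("classify", "search", "population", read.csv)
      valid <- pop[pop$valid %in% TRUE, ]
      labs <- lapply(valid$id, function(i) {
        p <- sample_parameters(parameter_bounds(), cfg$seed, i)
        st0 <- stabilize(model, p, cfg$settle_s, config, kin)
        out <- run_protocol(model, p,
          protocol(settle_s = 0, duration_ms = 5600,
                   steps = data.frame(site = "soma", t_on = 0,
                                      t_off = 5500, amp_nA = 0.24),
                   record = "soma"),
          config, kin, state = st0$state)
        pr <- classify_ib_rs(out$traces$soma, st0$v_rest)
        data.frame(id = i, class = pr$class,
                   n_spikes = length(pr$spike_times))
      })
      cl <- do.call(rbind, labs)
      if (is.null(cl)) cl <- data.frame(id = integer(0),
                                        class = character(0),
                                        n_spikes = integer(0))
      write.csv(cl, file.path(cfg$out_dir, "classes.csv"),
                row.names = FALSE)
      art$classes <- cl
    } else if (st == "csb") {
      pop <- need("csb", "search", "population", read.csv)
      valid <- pop[pop$valid %in% TRUE, ]
      rows <- list()
      for (pk in cfg$csb_protocols) {
        proto <- csb_protocol(pk)
        for (i in valid$id) {
          p <- sample_parameters(parameter_bounds(), cfg$seed, i)
          res <- tryCatch(
            score_csb(run_csb_protocol(model, p, proto, config, kin)),
            error = function(e) NULL)
          if (is.null(res)) next
          rows[[length(rows) + 1]] <-
            data.frame(id = i, protocol = pk, dv_ap = res$dv_ap,
                       v_ramp = res$v_ramp, rate = res$rate,
                       csb_valid = res$csb_valid)
        }
      }
      cs <- if (length(rows)) do.call(rbind, rows) else
        data.frame(id = integer(0), protocol = character(0),
                   dv_ap = numeric(0), v_ramp = numeric(0),
                   rate = numeric(0), csb_valid = logical(0))
      write.csv(cs, file.path(cfg$out_dir, "csb.csv"), row.names = FALSE)
      art$csb <- cs
    } else if (st == "vkm") {
      cs <- need("vkm", "csb", "csb", read.csv)
      rows <- list()
      for (pk in unique(cs$protocol)) {
        proto <- csb_protocol(pk)
        targets <- if (pk == "synaptic5Hz") vkm_targets(TRUE)
                   else vkm_targets()
        eligible <- cs[cs$protocol == pk & cs$csb_valid %in% TRUE, ]
        for (i in eligible$id) {
          p <- sample_parameters(parameter_bounds(), cfg$seed, i)
          base_run <- tryCatch(
            score_csb(run_csb_protocol(model, p, proto, config, kin)),
            error = function(e) NULL)
          if (is.null(base_run)) next
          for (tg in targets) {
            r <- tryCatch(
              run_vkm(model, p, tg, proto, config, kin,
                      base_result = base_run),
              error = function(e) NULL)
            if (is.null(r)) next
            rows[[length(rows) + 1]] <-
              data.frame(id = i, protocol = pk, target = tg,
                         d_dv_ap = r$change[["dv_ap"]],
                         d_v_ramp = r$change[["v_ramp"]],
                         d_rate = r$change[["rate"]])
          }
        }
      }
      vk <- if (length(rows)) do.call(rbind, rows) else
        data.frame(id = integer(0), protocol = character(0),
                   target = character(0), d_dv_ap = numeric(0),
                   d_v_ramp = numeric(0), d_rate = numeric(0))
      write.csv(vk, file.path(cfg$out_dir, "vkm.csv"), row.names = FALSE)
      art$vkm <- vk
    } else if (st == "report") {
      pop <- need("report", "search", "population", read.csv)
      spans <- parameter_spans(pop)
      write.csv(spans, file.path(cfg$out_dir, "parameter_spans.csv"),
                row.names = FALSE)
      art$report <- spans
    } else stop("unknown stage: ", st)
  }
  invisible(art)
}
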