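#!/usr/bin/env Rscript
# Virtual knockouts: re-run the 900 pA somatic and 5 Hz synaptic burst
# protocols on every CSB-valid model with one channel conductance (or the
# NMDAR permeability) zeroed, and summarize percentage changes. Also
# exports the paired +/-NMDAR synapse-site calcium traces for one model.
# Requires results/csb.csv from 04_csb.R.
suppressMessages(library(ca3pop))

cfg <- workbench_config(n_models = 200, seed = 1, out_dir = "results",
                        csb_protocols = c("somatic900", "synaptic5Hz"))
art <- run_pipeline(cfg, stages = "vkm")
vk <- art$vkm
if (!nrow(vk)) {
  cat("no CSB-valid models; run 04_csb.R first\n")
} else {
  cat(sprintf("%d knockout runs over %d models\n", nrow(vk),
              length(unique(vk$id))))
  for (proto in unique(vk$protocol)) {
    cat("\nprotocol", proto, "- median % change by knockout target:\n")
    sub <- vk[vk$protocol == proto, ]
    agg <- aggregate(cbind(d_dv_ap, d_v_ramp, d_rate) ~ target,
                     data = sub, FUN = function(x)
                       round(median(x, na.rm = TRUE), 1))
    print(agg, row.names = FALSE)
    # signed-rank test against a no-change scenario when enough models
    for (tg in unique(sub$target)) {
      x <- sub$d_rate[sub$target == tg]
      x <- x[is.finite(x)]
      if (length(x) >= 3 && length(unique(x)) > 1) {
        sr <- signed_rank_test(x)
        cat(sprintf("  %s rate change vs no-change: p = %.3f\n", tg,
                    sr$p))
      }
    }
  }
}

# paired calcium traces with and without NMDARs for the first CSB-valid
# model under the synaptic protocol
cs <- tryCatch(read.csv("results/csb.csv"), error = function(e) NULL)
pick <- cs$id[cs$protocol == "synaptic5Hz" & cs$csb_valid %in% TRUE][1]
if (length(pick) && !is.na(pick)) {
  model <- discretize(build_synthetic_morphology())
  p <- sample_parameters(parameter_bounds(), 1, pick)
  cmp <- calcium_comparison(model, p)
  cat(sprintf("\nmodel %d synapse-site calcium peak: %.2f uM intact, %.2f uM without NMDARs\n",
              pick, cmp$peak_base * 1e3, cmp$peak_ko * 1e3))
  write.csv(data.frame(t_ms = trace_times(cmp$base),
                       ca_base_mM = cmp$base$v,
                       ca_nmdar_ko_mM = cmp$knockout$v),
            "results/calcium_nmdar_comparison.csv", row.names = FALSE)
  cat("wrote results/calcium_nmdar_comparison.csv\n")
} else {
  cat("\nno synaptically CSB-valid model for the calcium comparison\n")
}
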