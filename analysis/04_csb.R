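#!/usr/bin/env Rscript
# Complex-spike-burst induction on the valid population: five protocols
# (somatic 600/900/1200 pA, dendritic 1000 pA, synaptic 5 Hz), scored
# against the burst criteria. Requires results/population.csv.
suppressMessages(library(ca3pop))

cfg <- workbench_config(n_models = 200, seed = 1, out_dir = "results",
                        csb_protocols = c("somatic600", "somatic900",
                                          "somatic1200", "dendritic1000",
                                          "synaptic5Hz"))
art <- run_pipeline(cfg, stages = "csb")
cs <- art$csb
if (!nrow(cs)) {
  cat("no valid models to stimulate; run 02_population_search.R first\n")
} else {
  agg <- aggregate(cbind(rate, dv_ap, v_ramp, csb_valid) ~ protocol,
                   data = cs, FUN = function(x) round(mean(x), 3))
  cat("per-protocol means over valid models",
      "(rate, amplitude drop mV, ramp mV, CSB-valid fraction):\n")
  print(agg, row.names = FALSE)
  cat(sprintf("CSB-valid models: %d of %d model x protocol runs\n",
              sum(cs$csb_valid), nrow(cs)))
}
cat("wrote results/csb.csv\n")
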