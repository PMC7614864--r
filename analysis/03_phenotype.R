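#!/usr/bin/env Rscript
# Firing-phenotype analytics on the valid population: intrinsically
# bursting vs regular spiking classification (240 pA x 5.5 s), parameter /
# measurement correlation structure, and dimensionality reduction.
# Requires results/population.csv from 02_population_search.R.
suppressMessages(library(ca3pop))

cfg <- workbench_config(n_models = 200, seed = 1, out_dir = "results")
art <- run_pipeline(cfg, stages = "classify")
cl <- art$classes
cat(sprintf("classified %d valid models: %d IB, %d RS\n", nrow(cl),
            sum(cl$class == "IB"), sum(cl$class == "RS")))

pop <- read.csv("results/population.csv")
valid <- pop[pop$valid %in% TRUE, ]
pnames <- parameter_bounds()$parameter
mnames <- measurement_bounds()$measurement

if (nrow(valid) >= 3) {
  # parameter correlations (14 columns -> 91 unique pairs)
  cp <- correlation_matrix(valid[pnames])
  cat(sprintf("parameter correlations: %d unique pairs, max |r| = %.2f\n",
              cp$n_pairs, max(abs(cp$pairs$r), na.rm = TRUE)))
  write.csv(cp$pairs, "results/parameter_correlations.csv",
            row.names = FALSE)
  # measurement correlations over the full measured battery
  meas_cols <- intersect(c(mnames, "t_1ap", "t_1isi", "v_ahp", "t_aphw",
                           "v_th", "dvdt_max_soma", "dvdt_min_soma",
                           "dvdt_max_150", "dvdt_min_150",
                           "dvdt_max_300", "dvdt_min_300"), names(valid))
  ok <- vapply(valid[meas_cols], function(x) all(is.finite(x)), TRUE)
  cm <- correlation_matrix(valid[meas_cols[ok]])
  write.csv(cm$pairs, "results/measurement_correlations.csv",
            row.names = FALSE)
  cat(sprintf("measurement correlations: %d unique pairs\n", cm$n_pairs))
}

if (nrow(valid) > 4) {
  emb <- embed(valid[pnames], "pca", dims = min(3, length(pnames) - 1))
  cat("PCA explained variance fractions:",
      round(emb$explained, 3), "\n")
  coords <- data.frame(id = valid$id, emb$coords)
  if (nrow(valid) > 8) {
    ts <- embed(valid[pnames], "tsne", dims = 2, seed = 1,
                perplexity = max(2, floor(nrow(valid) / 4)))
    coords$tsne1 <- ts$coords[, 1]; coords$tsne2 <- ts$coords[, 2]
  }
  coords <- merge(coords, cl, by = "id", all.x = TRUE)
  write.csv(coords, "results/embeddings.csv", row.names = FALSE)
  cat("wrote results/embeddings.csv\n")
}

# IB vs RS group comparison on the calcium / calcium-activated parameters
both <- merge(valid, cl, by = "id")
if (sum(both$class == "IB") >= 3 && sum(both$class == "RS") >= 3) {
  for (p in c("g_can", "g_sk", "g_cat", "g_cal", "g_bk")) {
    ct <- compare_groups(both[[p]][both$class == "IB"],
                         both[[p]][both$class == "RS"])
    cat(sprintf("%s IB vs RS: W = %.1f, p = %.3f\n", p, ct$statistic,
                ct$p))
  }
} else {
  cat("too few models in one class for group statistics at this scale\n")
}
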