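# Firing-phenotype analytics: intrinsically-bursting vs regular-spiking
# classification, ISI/amplitude temporal profiles, correlation structure,
# dimensionality reduction and group statistics.

#' Classify a firing response as intrinsically bursting or regular spiking
#'
#' A model is intrinsically bursting (IB) if its 240 pA x 5.5 s somatic
#' response contains three or more consecutive spikes within 25 ms whose
#' amplitude (peak minus resting potential) drops from the first to the
#' second spike by more than `amp_drop` mV; otherwise it is regular
#' spiking (RS). Fewer than three spikes yields RS with a low-count flag.
#'
#' @param trace somatic voltage (`ca3_trace`), time 0 = stimulus onset.
#' @param v_rmp resting potential (mV), the amplitude baseline.
#' @param amp_drop amplitude-reduction threshold (mV, default 5).
#' @param window burst window (ms, default 25).
#' @return a `firing_profile`: list(`class`, `spike_times`, `isis`,
#'   `amplitudes`, `low_count`).
#' @export
classify_ib_rs <- function(trace, v_rmp, amp_drop = 5, window = 25) {
  sp <- detect_spikes(trace)
  amps <- sp$v_peak - v_rmp
  n <- nrow(sp)
  cls <- "RS"; low <- FALSE
  if (n < 3) {
    low <- TRUE
  } else {
    for (i in seq_len(n - 2)) {
      if (sp$t_peak[i + 2] - sp$t_peak[i] <= window &&
          amps[i] - amps[i + 1] > amp_drop) {
        cls <- "IB"; break
      }
    }
  }
  structure(list(class = cls, spike_times = sp$t_peak,
                 isis = diff(sp$t_peak), amplitudes = amps,
                 low_count = low), class = "firing_profile")
}

#' ISI and amplitude temporal evolution profiles
#'
#' @param profile a `firing_profile`.
#' @return list(`isi` data frame: spike position vs interspike interval;
#'   `amplitude`: spike position vs amplitude).
#' @export
temporal_profiles <- function(profile) {
  if (length(profile$spike_times) < 2)
    stop("need at least two spikes for temporal profiles")
  list(isi = data.frame(position = seq_along(profile$isis),
                        isi_ms = profile$isis),
       amplitude = data.frame(position = seq_along(profile$amplitudes),
                              amp_mV = profile$amplitudes))
}

#' Pairwise Pearson correlation matrix with unique off-diagonal pairs
#'
#' @param table numeric matrix / data frame (rows = models, columns =
#'   parameters or measurements).
#' @return list(`matrix` (symmetric, unit diagonal), `pairs` data frame of
#'   the `choose(k, 2)` unique pairs with their coefficients, `n_pairs`,
#'   `n_defined`). Zero-variance columns give `NA` coefficients, excluded
#'   from `n_defined`.
#' @export
correlation_matrix <- function(table) {
  x <- as.matrix(table)
  if (ncol(x) < 2) stop("need at least two columns")
  if (nrow(x) < 3) stop("need at least three rows")
  cm <- suppressWarnings(cor(x))
  diag(cm) <- 1
  k <- ncol(x)
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- data.frame(a = colnames(x)[ut[, 1]], b = colnames(x)[ut[, 2]],
                      r = cm[ut])
  list(matrix = cm, pairs = pairs, n_pairs = nrow(pairs),
       n_defined = sum(!is.na(pairs$r)))
}

#' Dimensionality reduction of a population table
#'
#' Linear (PCA, deterministic with a fixed sign convention: the largest-
#' magnitude loading of each component is positive) or non-linear (exact
#' t-SNE, reproducible per seed) embedding of standardized columns.
#'
#' @param table numeric matrix / data frame.
#' @param method `"pca"` or `"tsne"`.
#' @param dims embedding dimensionality (default 3 for pca, 2 typical for
#'   tsne).
#' @param seed RNG seed (tsne).
#' @param perplexity t-SNE perplexity.
#' @param max_iter t-SNE iterations.
#' @return list(`coords` (rows x dims), and for PCA `explained` variance
#'   fractions and `loadings`).
#' @export
embed <- function(table, method = c("pca", "tsne"), dims = 3, seed = 1,
                  perplexity = 15, max_iter = 500) {
  method <- match.arg(method)
  x <- as.matrix(table)
  sdv <- apply(x, 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  x <- sweep(sweep(x, 2, colMeans(x)), 2, sdv, "/")
  if (nrow(x) <= dims) stop("need more rows than embedding dimensions")
  if (dims >= ncol(x)) stop("embedding dimension must be below column count")
  if (method == "pca") {
    pc <- prcomp(x, center = FALSE, scale. = FALSE)
    rot <- pc$rotation[, seq_len(dims), drop = FALSE]
    for (j in seq_len(ncol(rot))) {
      i <- which.max(abs(rot[, j]))
      if (rot[i, j] < 0) rot[, j] <- -rot[, j]
    }
    ev <- pc$sdev^2
    list(coords = x %*% rot, explained = ev[seq_len(dims)] / sum(ev),
         loadings = rot)
  } else {
    list(coords = tsne_exact(x, dims = dims, perplexity = perplexity,
                             max_iter = max_iter, seed = seed))
  }
}

#' Rank-based two-group comparison
#'
#' Two-sided Wilcoxon rank-sum test for unpaired groups (the IB vs RS
#' design); use [signed_rank_test()] for the one-sample no-change tests.
#'
#' @param a,b numeric vectors (each of length >= 3).
#' @return list(`statistic`, `p`).
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs at least three values")
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' One-sample Wilcoxon signed-rank test against zero
#'
#' Used for knockout effect distributions compared with a no-change
#' scenario.
#'
#' @param x numeric vector of (percentage) changes.
#' @return list(`statistic`, `p`).
#' @export
signed_rank_test <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3) stop("need at least three finite values")
  wt <- suppressWarnings(wilcox.test(x, mu = 0, exact = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
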