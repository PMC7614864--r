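test_that("burst and tonic firing patterns are classified correctly", {
  # triplet within 25 ms with decrementing amplitude -> IB
  g <- gen_trace(trace_recipe(spike_times = c(100, 110, 120),
                              spike_height = c(100, 88, 80), dt = 0.05,
                              duration = 400))
  pr <- classify_ib_rs(g$trace, -65)
  expect_equal(pr$class, "IB")
  # tonic 10 Hz constant amplitude -> RS
  g2 <- gen_trace(trace_recipe(spike_times = seq(50, 950, by = 100),
                               spike_height = 95, dt = 0.05))
  expect_equal(classify_ib_rs(g2$trace, -65)$class, "RS")
  # clustered but constant amplitude -> RS (amplitude clause fails)
  g3 <- gen_trace(trace_recipe(spike_times = c(100, 110, 120),
                               spike_height = 95, dt = 0.05,
                               duration = 400))
  expect_equal(classify_ib_rs(g3$trace, -65)$class, "RS")
  # fewer than three spikes -> RS with low-count flag
  g4 <- gen_trace(trace_recipe(spike_times = c(100, 300), dt = 0.05))
  pr4 <- classify_ib_rs(g4$trace, -65)
  expect_equal(pr4$class, "RS")
  expect_true(pr4$low_count)
})

test_that("classification is invariant to a trace baseline offset", {
  g <- gen_trace(trace_recipe(baseline = -65,
                              spike_times = c(100, 110, 120),
                              spike_height = c(100, 88, 80), dt = 0.05,
                              duration = 300))
  shifted <- g$trace; shifted$v <- shifted$v + 3
  expect_equal(classify_ib_rs(g$trace, -65)$class,
               classify_ib_rs(shifted, -62)$class)
})

test_that("temporal profiles align ISIs and amplitudes with spike index", {
  g <- gen_trace(trace_recipe(burst = list(n_bursts = 3,
                                           spikes_per_burst = 3,
                                           intra_isi = 10,
                                           inter_gap = 150, t0 = 50),
                              spike_height = rep(c(95, 85, 78), 3),
                              dt = 0.05, duration = 800))
  pr <- classify_ib_rs(g$trace, -65)
  expect_equal(pr$class, "IB")
  tp <- temporal_profiles(pr)
  expect_equal(nrow(tp$isi), length(pr$spike_times) - 1)
  # alternating short/long ISIs
  expect_true(all(tp$isi$isi_ms[c(1, 2, 4, 5, 7, 8)] < 15))
  expect_true(all(tp$isi$isi_ms[c(3, 6)] > 100))
  # constant-ISI fixture is flat
  g2 <- gen_trace(trace_recipe(spike_times = seq(50, 950, by = 100),
                               dt = 0.05))
  tp2 <- temporal_profiles(classify_ib_rs(g2$trace, -65))
  expect_lt(diff(range(tp2$isi$isi_ms)), 0.2)
})

test_that("correlation matrices report the unique pair counts", {
  for (k in c(21, 14, 5)) {
    x <- gen_population_table(50, k, seed = k)
    cm <- correlation_matrix(x)
    expect_equal(cm$n_pairs, choose(k, 2))
    expect_equal(dim(cm$matrix), c(k, k))
    expect_equal(unname(diag(cm$matrix)), rep(1, k))
    expect_equal(cm$matrix, t(cm$matrix))
  }
  # a perfectly collinear pair has coefficient 1
  x <- cbind(a = 1:10, b = 2 * (1:10) + 1, c = rnorm(10))
  expect_equal(correlation_matrix(x)$matrix["a", "b"], 1)
  # zero-variance columns are excluded from the defined count
  x2 <- cbind(x, d = rep(1, 10))
  cm2 <- correlation_matrix(x2)
  expect_equal(cm2$n_pairs - cm2$n_defined, 3)
  expect_error(correlation_matrix(x[, 1, drop = FALSE]), "two columns")
})

test_that("PCA embedding is deterministic with analytic variance
           structure", {
  x <- gen_population_table(60, 6, seed = 2)
  e1 <- embed(x, "pca", dims = 3)
  e2 <- embed(x[sample(60), ], "pca", dims = 3)
  # coordinates invariant to row order (as a set; compare sorted PC1)
  expect_equal(sort(e1$coords[, 1]), sort(e2$coords[, 1]),
               tolerance = 1e-9)
  expect_true(all(e1$explained >= 0) && sum(e1$explained) <= 1 + 1e-9)
  # rank-1 data: first component explains everything
  r1 <- outer(rnorm(40), c(1, 2, 3))
  colnames(r1) <- paste0("P", 1:3)
  er <- embed(r1 + 0, "pca", dims = 2)
  expect_gt(er$explained[1], 0.999)
  # reconstruction error equals the tail eigenvalue sum
  xs <- scale(x)
  pc <- prcomp(xs, center = FALSE)
  dims <- 3
  recon <- pc$x[, 1:dims] %*% t(pc$rotation[, 1:dims])
  err <- sum((xs - recon)^2) / (nrow(x) - 1)
  expect_equal(err, sum(pc$sdev[(dims + 1):length(pc$sdev)]^2),
               tolerance = 1e-8)
  expect_error(embed(x, "pca", dims = 10), "dimension")
})

test_that("t-SNE embedding is seed-reproducible and separates distant
           clusters", {
  set.seed(1)
  a <- matrix(rnorm(30 * 4), 30, 4)
  b <- matrix(rnorm(30 * 4, mean = 12), 30, 4)
  x <- rbind(a, b); colnames(x) <- paste0("P", 1:4)
  e1 <- embed(x, "tsne", dims = 2, seed = 3, max_iter = 300)
  e2 <- embed(x, "tsne", dims = 2, seed = 3, max_iter = 300)
  expect_identical(e1$coords, e2$coords)
  lab <- rep(1:2, each = 30)
  d_within <- mean(dist(e1$coords[lab == 1, ])) +
    mean(dist(e1$coords[lab == 2, ]))
  centroid <- function(g) colMeans(e1$coords[lab == g, ])
  d_between <- sqrt(sum((centroid(1) - centroid(2))^2))
  expect_gt(d_between, d_within / 2)
})

test_that("group comparison behaves like a two-sided rank test", {
  set.seed(4)
  a <- rnorm(30)
  expect_gt(compare_groups(a, a)$p, 0.9)
  b <- rnorm(30, mean = 10)   # ten SDs apart
  expect_lt(compare_groups(a, b)$p, 0.001)
  expect_equal(compare_groups(sample(a), b)$p, compare_groups(a, b)$p)
  expect_error(compare_groups(a, 1:2), "three")
  # one-sample signed-rank against zero
  expect_lt(signed_rank_test(rnorm(30, 5))$p, 0.001)
  expect_gt(signed_rank_test(c(-2, -1, -0.5, 0.5, 1, 2))$p, 0.9)
})
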