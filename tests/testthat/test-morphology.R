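test_that("SWC fixtures parse with correct sections and parentage", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(swc_fixture_text(), f)
  tree <- load_swc(f)
  expect_s3_class(tree, "section_tree")
  expect_equal(nrow(tree$sections), 3)
  expect_equal(tree$sections$type, c("soma", "apical", "basal"))
  expect_equal(tree$sections$parent, c(0L, 1L, 1L))
})

test_that("malformed and structurally invalid SWC files are rejected", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 4 0 10 0"), f)
  expect_error(load_swc(f), "line 2")
  writeLines(c("1 1 0 0 0 5 -1", "2 4 0 10 0 1 7"), f)
  expect_error(load_swc(f), "missing parent")
  writeLines(c("1 1 0 0 0 5 -1", "2 1 0 9 0 5 -1"), f)
  expect_error(load_swc(f), "multiple roots")
})

test_that("SWC round-trip preserves geometry", {
  f1 <- withr::local_tempfile(fileext = ".swc")
  f2 <- withr::local_tempfile(fileext = ".swc")
  writeLines(swc_fixture_text(), f1)
  tree <- load_swc(f1)
  write_swc(tree, f2)
  tree2 <- load_swc(f2)
  expect_equal(tree2$sections, tree$sections)
  for (s in seq_along(tree$geometry))
    expect_equal(unname(tree2$geometry[[s]]), unname(tree$geometry[[s]]),
                 tolerance = 1e-6)
})

test_that("synthetic morphology spans the recording sites and its area is
           the analytic cylinder sum", {
  tree <- build_synthetic_morphology()
  mod <- discretize(tree)
  expect_gte(max(mod$comp$path_um[startsWith(mod$comp$region, "apical")]),
             300)
  expect_true(all(c("soma", "apical", "basal") %in%
                  sub("_sr", "", mod$comp$region)))
  # analytic lateral area of all cylinders
  a_true <- 0
  defaults <- formals(build_synthetic_morphology)
  a_true <- pi * 20 * 20 +                       # soma
    sum(pi * c(6, 3.5, 2) * c(150, 150, 200)) +  # tapered trunk
    2 * pi * 3 * 150 +                           # obliques
    2 * pi * 16 * 420                            # basal
  expect_equal(tree_area(tree) * 1e8, a_true, tolerance = 1e-3)
  expect_equal(sum(mod$comp$area_cm2), tree_area(tree), tolerance = 1e-3)
  expect_error(build_synthetic_morphology(trunk_length = 200),
               "300 um")
  # unbranched ball-and-stick
  t0 <- build_synthetic_morphology(n_oblique = 0, n_basal = 0)
  expect_true(all(t0$sections$type %in% c("soma", "apical")))
})

test_that("d_lambda discretization yields the expected odd segment counts", {
  # cylinder exactly one AC length constant long -> 11 compartments at 0.1
  ra <- 200; cm <- 0.75
  lam <- lambda_f(2, 100, ra, cm)
  tree <- build_synthetic_morphology(trunk_length = lam, trunk_diam = 2,
                                     n_oblique = 0, n_basal = 0,
                                     require_bap_sites = FALSE)
  # trunk is split at 150/300; use a plain single-section stick instead
  tree$sections <- tree$sections[1:2, ]
  tree$geometry <- tree$geometry[1:2]
  tree$geometry[[2]][2, "y"] <- lam
  mod <- discretize(tree, d_lambda = 0.1, f = 100, ra = ra, cm = cm)
  expect_equal(sum(mod$comp$section == 2), 11)
  # d_lambda = 1 and a short section -> single compartment
  mod1 <- discretize(tree, d_lambda = 1, f = 100, ra = ra, cm = cm)
  expect_equal(sum(mod1$comp$section == 2), 1) # L = lambda -> one segment
  # halving d_lambda never decreases counts; bound holds per compartment
  for (dl in c(0.2, 0.1, 0.05)) {
    m <- discretize(tree, d_lambda = dl)
    lamf <- lambda_f(mod$comp$diam_um, 100, 200, 0.75)
    expect_true(all(m$comp$length_um <=
                    dl * lambda_f(m$comp$diam_um, 100, 200, 0.75) + 1e-9))
    n_sec <- table(m$comp$section)
    expect_true(all(n_sec %% 2 == 1))
  }
  n_counts <- vapply(c(0.4, 0.2, 0.1, 0.05),
                     function(dl) nrow(discretize(tree, d_lambda = dl)$comp),
                     0)
  expect_true(all(diff(n_counts) >= 0))
})

test_that("membrane area is conserved under rediscretization", {
  tree <- build_synthetic_morphology()
  a <- vapply(c(0.3, 0.1, 0.05),
              function(dl) sum(discretize(tree, d_lambda = dl)$comp$area_cm2),
              0)
  expect_lt(max(abs(a - a[1]) / a[1]), 0.005)
})

test_that("path distances are additive and zero at the soma", {
  mod <- study_model()
  soma <- which(mod$comp$region == "soma")
  expect_equal(path_distance(mod, soma), 0)
  # child at least as far as parent everywhere
  for (i in seq_len(nrow(mod$comp))[-soma]) {
    p <- mod$parent[i]
    if (mod$comp$region[p] == "soma") next
    expect_gte(path_distance(mod, i), path_distance(mod, p))
  }
  expect_error(path_distance(mod, 10000), "unknown compartment")
  # midpoint of a 200 um unbranched trunk attached to the soma
  tree <- tiny_stick()
  mod2 <- discretize(tree)
  ap <- which(startsWith(mod2$comp$region, "apical"))
  mid <- ap[which.min(abs(mod2$comp$path_um[ap] - 100))]
  expect_lt(abs(path_distance(mod2, mid) - 100),
            mod2$comp$length_um[mid] / 2 + 1e-9)
})
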