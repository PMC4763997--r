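test_that("submesothelial thickness: uniform band and wedge", {
  # uniform 400 um band below a 3 um mesothelium
  sec <- struct_section(900, 600, 0.5, boundary_um = 403)
  th <- measure_submesothelial_thickness(sec)
  expect_equal(as.numeric(th), 400, tolerance = 0.005)
  # linear wedge 200 -> 600 um: median transect = 400 (dense-transect oracle)
  nc <- 800
  wedge <- 3 + seq(200, 600, length.out = nc)
  secw <- struct_section(1300, nc, 0.5, boundary_um = wedge)
  dense <- measure_submesothelial_thickness(secw, n_transects = 401)
  th7 <- measure_submesothelial_thickness(secw, n_transects = 7)
  expect_equal(as.numeric(dense), 400, tolerance = 0.01)
  expect_equal(as.numeric(th7), as.numeric(dense), tolerance = 0.02)
  expect_length(attr(th7, "transects"), 7L)
})

test_that("thickness measurement needs a lower boundary and >= 5 transects", {
  sec <- struct_section(100, 100, 0.5, boundary_um = 1e6)  # no lower tissue
  expect_error(measure_submesothelial_thickness(sec), "fat/muscle/fascia")
  sec2 <- struct_section(100, 100, 0.5, boundary_um = 30)
  expect_error(measure_submesothelial_thickness(sec2, n_transects = 3),
               "five")
})

test_that("thickness is invariant to horizontal translation", {
  sec <- struct_section(900, 600, 0.5, boundary_um = 350)
  sh <- stain_section(sec$img[, c(301:600, 1:300)], "structural", 0.5)
  expect_identical(as.numeric(measure_submesothelial_thickness(sec)),
                   as.numeric(measure_submesothelial_thickness(sh)))
})

test_that("well-separated depth clusters are recovered exactly", {
  d <- c(30, 35, 40, 90, 95, 100, 185, 190, 200)
  for (m in c("gmm", "kmedians")) {
    fit <- cluster_vessel_layers(d, k = 3, method = m)
    expect_equal(fit$layer_medians, c(35, 95, 190), tolerance = 0.05)
    expect_identical(fit$assignments, rep(1:3, each = 3))
  }
})

test_that("clustering handles degenerate input", {
  w <- capture_warnings(fit <- cluster_vessel_layers(rep(50, 10), k = 3))
  expect_match(w, "distinct", all = FALSE)
  expect_identical(fit$k, 1L)
  expect_warning(f2 <- cluster_vessel_layers(c(10, 200), k = 3), "distinct")
  expect_identical(f2$k, 2L)
})

test_that("layer medians are ordered and permutation invariant", {
  set.seed(6)
  d <- c(rnorm(40, 40, 8), rnorm(40, 120, 12), rnorm(40, 260, 20))
  f1 <- cluster_vessel_layers(d)
  f2 <- cluster_vessel_layers(sample(d))
  expect_true(all(diff(f1$layer_medians) > 0))
  expect_equal(f1$layer_medians, f2$layer_medians, tolerance = 1e-6)
  # well-separated (gaps > 4x within-layer IQR): assignments = truth
  truth <- rep(1:3, each = 40)
  expect_identical(f1$assignments[order(d)], sort(truth))
  # determinism
  expect_identical(cluster_vessel_layers(d, seed = 2)$layer_medians,
                   cluster_vessel_layers(d, seed = 2)$layer_medians)
})

test_that("layer depth vs thickness correlation", {
  mkfit <- function(depths) cluster_vessel_layers(depths)
  set.seed(10)
  th <- runif(24, 150, 450)
  fits <- lapply(th, function(t)
    mkfit(c(rnorm(25, 0.1 * t, 2), rnorm(25, 0.3 * t, 3),
            rnorm(25, 0.6 * t, 4))))
  r <- layer_depth_vs_thickness(fits, th)
  expect_true(all(r$rho > 0.9))
  expect_true(all(r$p < 0.001))
  # independent depths: |rho| small
  fits0 <- lapply(seq_along(th), function(i)
    mkfit(c(rnorm(25, 40, 2), rnorm(25, 120, 3), rnorm(25, 250, 4))))
  r0 <- layer_depth_vs_thickness(fits0, th)
  expect_true(all(abs(r0$rho) < 0.45))
  expect_error(layer_depth_vs_thickness(fits[1:2], th[1:2]), "3 samples")
})
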