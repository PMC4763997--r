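test_that("ground-truth vessel counts are Poisson around density x area", {
  # truth-only generation at the infant parameters, full analysis area
  p <- section_params(seed = NULL)
  counts <- vapply(1:150, function(s) {
    p$seed <- s
    tr <- generate_section(p, channels = character(0))$truth
    c(sum(tr$vessels$class == "blood"), tr$analyzed_area)
  }, numeric(2))
  expected <- 223 * counts[2, 1]           # ~321 per section
  m <- mean(counts[1, ])
  expect_gt(m, expected * 0.96)
  expect_lt(m, expected * 1.04)
  # Poisson dispersion: variance within a reasonable factor of the mean
  expect_gt(var(counts[1, ]) / m, 0.6)
  expect_lt(var(counts[1, ]) / m, 1.6)
})

test_that("zero densities give an empty section", {
  p <- tiny_params(blood_density = 0, lymph_density = 0, mast_density = 0,
                   noise_sd = 0)
  sec <- generate_section(p, channels = c("cd31", "tryptase"))
  expect_identical(nrow(sec$truth$vessels), 0L)
  expect_equal(positivity(classify_pixels(sec$cd31)), 0)
  expect_identical(nrow(detect_vessels(sec$cd31)), 0L)
})

test_that("depth mixture reproduces the three layer medians", {
  # small dispersion, deep band so truncation does not bite
  p <- section_params(analyzed_area = 0.8, pixel_scale = 1,
                      blood_density = 400, lymph_density = 0,
                      layer_iqrs = c(4, 4, 4), submeso_thickness = 400,
                      seed = 42)
  tr <- generate_section(p, channels = character(0))$truth
  d <- tr$vessels$depth_um
  cuts <- c(-Inf, 66, 144, Inf)  # midpoints between well-separated layers
  med <- tapply(d, cut(d, cuts), median)
  expect_equal(as.numeric(med), c(36, 96, 192), tolerance = 0.05)
})

test_that("collapsed fraction matches the requested rate", {
  p <- section_params(analyzed_area = 1, pixel_scale = 1,
                      blood_density = 400, lymph_density = 0,
                      collapsed_fraction = 0.3, seed = 3)
  tr <- generate_section(p, channels = character(0))$truth
  n <- nrow(tr$vessels)
  k <- sum(tr$vessels$collapsed)
  ci <- qbinom(c(0.0005, 0.9995), n, 0.3)
  expect_gte(k, ci[1]); expect_lte(k, ci[2])
  expect_true(all(tr$vessels$r_in_um[tr$vessels$collapsed] == 0))
})

test_that("same seed gives bit-identical ground truth and images", {
  p <- tiny_params(seed = 99)
  a <- generate_section(p, channels = c("cd31", "podoplanin"))
  b <- generate_section(p, channels = c("cd31", "podoplanin"))
  expect_identical(a$truth$vessels, b$truth$vessels)
  expect_identical(a$truth$boundary_um, b$truth$boundary_um)
  expect_identical(a$cd31$img, b$cd31$img)
  expect_identical(a$podoplanin$img, b$podoplanin$img)
})

test_that("invalid parameters are rejected", {
  expect_error(section_params(blood_density = -1), "densities")
  expect_error(section_params(pixel_scale = 0), "pixel_scale")
  expect_error(section_params(layer_weights = c(0.5, 0.5, 0.5)), "simplex")
  expect_error(section_params(collapsed_fraction = 1.2), "collapsed")
  expect_error(section_params(analyzed_area = NaN), "finite")
})

test_that("render_annulus matches the analytic ring area", {
  m <- render_annulus(outer_radius = 5, inner_radius = 3.5,
                      pixel_scale = 0.1)
  expect_equal(sum(m) * 0.01, pi * (25 - 12.25), tolerance = 0.02)
  disc <- render_annulus(outer_radius = 4, inner_radius = 0,
                         pixel_scale = 0.1)
  expect_equal(sum(disc) * 0.01, pi * 16, tolerance = 0.02)
  expect_error(render_annulus(outer_radius = 3, inner_radius = 3,
                              pixel_scale = 0.1), "outer_radius")
  expect_warning(render_annulus(outer_radius = 0.2, inner_radius = 0,
                                pixel_scale = 0.5), "degenerate")
})

test_that("cohort generation respects group sizes and determinism", {
  tab <- peritoneal_group_params()
  # truth-only cohort at tiny area: sizes 14,10,15,15,18,21,14 -> 107
  coh <- generate_cohort(tab, seed = 5, channels = character(0),
                         analyzed_area = 0.01, pixel_scale = 2)
  expect_identical(nrow(coh$meta), 107L)
  expect_identical(as.integer(table(coh$meta$group)[tab$group]), tab$n)
  # ages fall inside their group bounds
  for (g in seq_len(nrow(tab))) {
    a <- coh$meta$age[coh$meta$group == tab$group[g]]
    expect_true(all(a >= tab$lo[g] & a < tab$hi[g] + 1e-9))
  }
  one <- generate_cohort(tab[1, ], n_per_group = 1, seed = 5,
                         channels = character(0),
                         analyzed_area = 0.01, pixel_scale = 2)
  expect_identical(nrow(one$meta), 1L)
  coh2 <- generate_cohort(tab, seed = 5, channels = character(0),
                          analyzed_area = 0.01, pixel_scale = 2)
  expect_identical(coh$meta, coh2$meta)
  expect_identical(lapply(coh$truths, `[[`, "vessels"),
                   lapply(coh2$truths, `[[`, "vessels"))
  expect_error(generate_cohort(tab[0, ]), "empty")
})

test_that("endothelial-fraction calibration is exact in expectation", {
  p <- section_params(collapsed_fraction = 0, lymph_density = 0,
                      wall_thickness = 4)
  p2 <- calibrate_endothelial_fraction(p, 5.8)
  w <- p2$wall_thickness
  ering <- pi * w * (2 * p2$vessel_radius_mean - w)
  expect_equal(p2$blood_density * ering / 1e4, 5.8, tolerance = 1e-8)
})
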