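test_that("a blank section yields no vessel records", {
  expect_identical(nrow(detect_vessels(blank_section(100, 100))), 0L)
})

test_that("one annulus reproduces the analytic ring metrics", {
  sec <- blank_section(160, 160, scale = 0.1)
  sec <- paint_rings(sec, x = 8, y = 8, r_out = 5, r_in = 3.5)
  rec <- detect_vessels(sec)
  expect_identical(nrow(rec), 1L)
  expect_equal(rec$endothelial_area, pi * (25 - 12.25), tolerance = 0.02)
  expect_equal(rec$lumen_area, pi * 12.25, tolerance = 0.02)
  expect_equal(rec$vessel_area, pi * 25, tolerance = 0.02)
  expect_equal(rec$outer_perimeter, 2 * pi * 5, tolerance = 0.02)
  expect_equal(rec$endoluminal_perimeter, 2 * pi * 3.5, tolerance = 0.02)
  expect_equal(rec$endothelial_thickness, 1.5, tolerance = 0.02)
  expect_false(rec$collapsed)
  expect_equal(rec$depth_um, 8, tolerance = 0.1)
})

test_that("separable synthetic sections are segmented exactly", {
  # 20 vessels, 2 collapsed, placed on a grid with clearance
  sec <- blank_section(300, 500, scale = 0.25)
  xy <- expand.grid(x = seq(12, 108, by = 24), y = seq(15, 63, by = 16))
  r_in <- rep(3, 20); r_in[c(4, 17)] <- 0
  sec <- paint_rings(sec, xy$x, xy$y, r_out = 5, r_in = r_in)
  rec <- detect_vessels(sec)
  expect_identical(nrow(rec), 20L)
  expect_identical(sum(rec$collapsed), 2L)
  # area additivity holds exactly on every record
  expect_equal(rec$vessel_area, rec$endothelial_area + rec$lumen_area)
  # depths match the construction within one pixel
  got <- sort(rec$depth_um)
  want <- sort(rep(seq(15, 63, by = 16), each = 5))
  expect_true(all(abs(got - want) <= 0.25 + 1e-9))
})

test_that("detection count is robust to doubled noise", {
  p <- tiny_params(seed = 31, noise_sd = 0.1, collapsed_fraction = 0)
  sec <- generate_section(p, channels = "cd31")
  rec <- detect_vessels(sec$cd31)
  n_true <- nrow(sec$truth$vessels)
  expect_lte(abs(nrow(rec) - n_true) / max(n_true, 1), 0.02)
})

test_that("touching rings are split by the watershed round", {
  sec <- blank_section(200, 200, scale = 0.25)
  sec <- paint_rings(sec, x = c(20, 30.2), y = c(25, 25),
                     r_out = 5, r_in = 3)
  rec <- detect_vessels(sec)
  expect_identical(nrow(rec), 2L)
  expect_identical(sum(rec$collapsed), 0L)
})

test_that("border-touching vessels are flagged and excluded from shape", {
  sec <- blank_section(200, 200, scale = 0.25)
  sec <- paint_rings(sec, x = c(2, 25), y = c(25, 25), r_out = 5, r_in = 3)
  rec <- detect_vessels(sec)
  expect_identical(nrow(rec), 2L)
  expect_identical(sum(rec$border), 1L)
  expect_true(is.na(rec$endothelial_thickness[rec$border]))
})

test_that("dual-stain differencing follows the intraindividual counting rule", {
  mk <- function(n, id = "s") {
    r <- data.frame(id = seq_len(n))
    attr(r, "sample_id") <- id
    r
  }
  a <- mk(25); b <- mk(5)
  res <- classify_by_dual_stain(a, b)
  expect_identical(res$blood, 20L)
  expect_identical(res$total, 25L)
  expect_identical(res$lymphatic, 5L)
  expect_warning(res2 <- classify_by_dual_stain(mk(3), mk(5)), "clamped")
  expect_identical(res2$blood, 0L)
  expect_true(res2$clamped)
  expect_error(classify_by_dual_stain(mk(3, "s1"), mk(3, "s2")),
               "different samples")
})

test_that("the podoplanin mesothelial band is masked, not counted", {
  p <- tiny_params(blood_density = 0, lymph_density = 120,
                   denuded_fraction = 0, seed = 17)
  sec <- generate_section(p, channels = "podoplanin")
  rec <- detect_vessels(sec$podoplanin)
  n_true <- sum(sec$truth$vessels$class == "lymphatic")
  expect_lte(abs(nrow(rec) - n_true), max(1, 0.1 * n_true))
})

test_that("mesothelial integrity recovers the denuded fraction", {
  full <- struct_section(100, 400, 0.5, boundary_um = 40)
  r <- mesothelial_integrity(full)
  expect_equal(r$coverage, 1.0)
  expect_false(r$denuded)
  p <- tiny_params(denuded_fraction = 0.6, seed = 12)
  sec <- generate_section(p, channels = c("structural", "podoplanin"))
  for (ch in c("structural", "podoplanin")) {
    r <- mesothelial_integrity(sec[[ch]])
    expect_equal(r$coverage, sec$truth$coverage, tolerance = 0.05)
    expect_true(r$denuded)
  }
})
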