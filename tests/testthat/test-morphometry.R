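test_that("microvessel density is count per area", {
  expect_equal(microvessel_density(10, 0.05), 200)
  expect_equal(microvessel_density(0, 1.44), 0)
  expect_error(microvessel_density(5, 0), "> 0")
})

test_that("endothelial thickness obeys the annulus identity", {
  sec <- blank_section(160, 160, scale = 0.1)
  sec <- paint_rings(sec, 8, 8, r_out = 5, r_in = 3.5)
  rec <- detect_vessels(sec)
  expect_equal(endothelial_thickness(rec[1, ]), 1.5, tolerance = 0.02)
  rec$collapsed <- TRUE
  expect_error(endothelial_thickness(rec[1, ]), "collapsed")
})

test_that("endothelial surface per volume cancels section thickness", {
  expect_equal(endothelial_surface_per_volume(c(40, 60), 1e4, 4), 0.01)
  expect_identical(endothelial_surface_per_volume(c(40, 60), 1e4, 8),
                   endothelial_surface_per_volume(c(40, 60), 1e4, 4))
  expect_message(z <- endothelial_surface_per_volume(numeric(0), 1e4),
                 "no vessels")
  expect_equal(z, 0)
})

test_that("relative endothelial area is a percentage of analyzed area", {
  expect_equal(relative_endothelial_area(11800, 1e6), 1.18)
  expect_equal(relative_endothelial_area(0, 1e6), 0)
})

test_that("point-cell counting respects the size window", {
  sec <- blank_section(400, 400, scale = 0.5)   # 0.04 mm2
  expect_equal(as.numeric(count_point_cells(sec)), 0)
  xy <- expand.grid(x = seq(20, 180, by = 40), y = seq(20, 180, by = 60))
  sec <- paint_rings(sec, xy$x[1:13], xy$y[1:13], r_out = 2.5, r_in = 0)
  d <- count_point_cells(sec)
  expect_identical(attr(d, "n"), 13L)
  expect_equal(as.numeric(d), 13 / sec$analyzed_area)
  # a large blob is not a point cell
  sec2 <- paint_rings(sec, 100, 100, r_out = 12, r_in = 0)
  expect_identical(attr(count_point_cells(sec2), "n"), 13L)
})

test_that("areas and perimeters are stable under grid refinement", {
  vals <- sapply(c(0.5, 0.25), function(sc) {
    sec <- blank_section(round(40 / sc), round(40 / sc), scale = sc)
    rec <- detect_vessels(paint_rings(sec, 20, 20, r_out = 5, r_in = 3))
    c(rec$vessel_area, rec$outer_perimeter, rec$endoluminal_perimeter)
  })
  expect_true(all(abs(vals[, 1] / vals[, 2] - 1) < 0.02))
})

test_that("sample summaries match an independent aggregation oracle", {
  p <- tiny_params(seed = 44)
  sec <- generate_section(p)
  q <- quantify_sample(sec, "sx")
  cd <- detect_vessels(sec$cd31, sample_id = "sx")
  po <- detect_vessels(sec$podoplanin, sample_id = "sx")
  area <- sec$cd31$analyzed_area
  m <- q$metrics
  # brute-force recomputation straight from the record tables
  expect_equal(m$total_density, nrow(cd) / area)
  expect_equal(m$lymph_density, nrow(po) / area)
  expect_equal(m$blood_density, max(nrow(cd) - nrow(po), 0) / area)
  ok <- !cd$collapsed & !cd$border
  expect_equal(m$vessel_area_blood, median(cd$vessel_area[ok]))
  expect_equal(m$endothelial_thickness_blood,
               median(cd$endothelial_thickness[ok]))
  expect_equal(m$relative_endothelial_area_blood,
               100 * sum(cd$endothelial_area) / (area * 1e6))
  expect_equal(m$surface_per_volume_blood,
               sum(cd$endoluminal_perimeter[ok]) / (area * 1e6))
})

test_that("missing channels yield missing metrics, not zeros", {
  p <- tiny_params(seed = 45)
  sec <- generate_section(p, channels = "cd31")
  m <- quantify_sample(list(cd31 = sec$cd31), "s1")$metrics
  expect_true(is.na(m$vessel_area_lymph))
  expect_true(is.na(m$lymph_density))
  expect_equal(m$blood_density, m$total_density)  # CD31-only convention
  empty <- summarize_sample(detect_vessels(blank_section(50, 50)),
                            detect_vessels(blank_section(50, 50),
                                           surface_margin = 0),
                            analyzed_area = 0.01)
  expect_equal(empty$total_density, 0)
  expect_true(is.na(empty$vessel_area_blood))
})
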