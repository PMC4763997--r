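# Per-vessel and per-sample quantitative morphometry.

#' Microvessel density
#'
#' Number of vessels (collapsed included) per unit analyzed tissue area.
#'
#' @param n_vessels Vessel count.
#' @param analyzed_area Analyzed area in mm2 (> 0).
#' @return Density in vessels/mm2.
#' @export
microvessel_density <- function(n_vessels, analyzed_area) {
  if (!is.finite(analyzed_area) || analyzed_area <= 0)
    stop("analyzed_area must be > 0")
  n_vessels / analyzed_area
}

#' Endothelial wall thickness of one vessel
#'
#' Endothelial area divided by the mean ring length (mean of the outer and
#' the endoluminal perimeter); for a perfect annulus this equals
#' r_out - r_in. Collapsed vessels have no defined wall thickness and are
#' rejected, matching their exclusion from shape metrics.
#'
#' @param record One row of a `vessel_records` data frame.
#' @return Thickness in um.
#' @export
endothelial_thickness <- function(record) {
  if (isTRUE(record$collapsed))
    stop("collapsed vessel: wall thickness undefined (excluded from shape metrics)")
  if (isTRUE(record$border))
    stop("border-truncated vessel: excluded from shape metrics")
  ring <- (record$outer_perimeter + record$endoluminal_perimeter) / 2
  record$endothelial_area / ring
}

#' Endothelial surface area per tissue volume
#'
#' Sum of endoluminal perimeters times section thickness, divided by
#' analyzed area times section thickness (um2/um3); the section thickness
#' cancels algebraically, so the result is numerically independent of it.
#'
#' @param perimeters Endoluminal perimeters (um) of the non-collapsed
#'   vessels of one class.
#' @param analyzed_area Analyzed area in um2.
#' @param section_thickness Section thickness in um (cancels; kept in the
#'   signature to mirror the definition).
#' @return um2 of endothelial surface per um3 of tissue.
#' @export
endothelial_surface_per_volume <- function(perimeters, analyzed_area,
                                           section_thickness = 4) {
  if (!is.finite(analyzed_area) || analyzed_area <= 0)
    stop("analyzed_area must be > 0")
  if (length(perimeters) == 0) {
    message("no vessels: endothelial surface per volume = 0")
    return(0)
  }
  (sum(perimeters) * section_thickness) /
    (analyzed_area * section_thickness)
}

#' Relative endothelial area
#'
#' Percentage of the analyzed tissue area covered by stain-positive
#' endothelium (all vessels of the class, collapsed included).
#'
#' @param endothelial_pixel_area Total endothelial area, um2.
#' @param analyzed_area Analyzed area, um2 (> 0).
#' @return Percentage in [0, 100].
#' @export
relative_endothelial_area <- function(endothelial_pixel_area, analyzed_area) {
  if (!is.finite(analyzed_area) || analyzed_area <= 0)
    stop("analyzed_area must be > 0")
  pct <- 100 * endothelial_pixel_area / analyzed_area
  stopifnot(pct <= 100 + 1e-9)
  pct
}

#' Count point-like cells (e.g. tryptase-positive mast cells)
#'
#' Connected stain-positive components within a cell-size window, per
#' analyzed area.
#'
#' @param section A [stain_section()] of a point-object stain.
#' @param thresholds [intensity_thresholds()].
#' @param min_cell_area,max_cell_area Size window in um2.
#' @return Density in cells/mm2, with attribute `n` (count).
#' @export
count_point_cells <- function(section, thresholds = intensity_thresholds(),
                              min_cell_area = 5, max_cell_area = 80) {
  lab <- classify_pixels(section, thresholds)
  L <- EBImage::imageData(EBImage::bwlabel(lab > 0L))
  n <- 0L
  if (max(L) > 0) {
    a <- tabulate(L, max(L)) * section$pixel_scale^2
    n <- sum(a >= min_cell_area & a <= max_cell_area)
  }
  structure(n / section$analyzed_area, n = n)
}

median_or_na <- function(x) if (length(x)) stats::median(x) else NA_real_

#' Aggregate one sample into a metrics row
#'
#' Combines the vessel records of the CD31 and podoplanin channels, the
#' mast-cell count and the structural measurements of one sample into a
#' single row of per-sample metrics. Densities count every vessel
#' (collapsed included); shape medians are computed over non-collapsed,
#' non-border records. Blood-class morphology summarizes the CD31 channel
#' and lymphatic-class morphology the podoplanin channel, mirroring the
#' dual-stain design in which individual CD31 objects are not registered
#' to podoplanin objects. A missing channel yields `NA` metrics for that
#' class, never zeros.
#'
#' @param cd31_records,podo_records `vessel_records` (or `NULL` if the
#'   channel is missing).
#' @param analyzed_area Analyzed area in mm2.
#' @param section_thickness Section thickness, um.
#' @param mast_density Cells/mm2 from [count_point_cells()], or `NA`.
#' @param submeso_thickness um, from
#'   [measure_submesothelial_thickness()], or `NA`.
#' @param layer_fit A [cluster_vessel_layers()] fit, or `NULL`.
#' @param coverage Mesothelial coverage fraction, or `NA`.
#' @param sample_id Sample identifier.
#' @return One-row data frame of class `sample_metrics`.
#' @export
summarize_sample <- function(cd31_records = NULL, podo_records = NULL,
                             analyzed_area, section_thickness = 4,
                             mast_density = NA_real_,
                             submeso_thickness = NA_real_,
                             layer_fit = NULL, coverage = NA_real_,
                             sample_id = NA_character_) {
  if (!is.finite(analyzed_area) || analyzed_area <= 0)
    stop("analyzed_area must be > 0")
  area_um2 <- analyzed_area * 1e6

  counts <- list(total = NA_integer_, lymphatic = NA_integer_,
                 blood = NA_integer_, clamped = FALSE)
  if (!is.null(cd31_records) && !is.null(podo_records)) {
    counts <- classify_by_dual_stain(cd31_records, podo_records)
  } else if (!is.null(cd31_records)) {
    counts$total <- counts$blood <- nrow(cd31_records)
  } else if (!is.null(podo_records)) {
    counts$lymphatic <- nrow(podo_records)
  }

  class_stats <- function(rec) {
    if (is.null(rec))
      return(list(va = NA_real_, per = NA_real_, ea = NA_real_,
                  th = NA_real_, rel = NA_real_, spv = NA_real_))
    ok <- !rec$collapsed & !rec$border
    list(va = median_or_na(rec$vessel_area[ok]),
         per = median_or_na(rec$endoluminal_perimeter[ok]),
         ea = median_or_na(rec$endothelial_area[ok]),
         th = median_or_na(rec$endothelial_thickness[ok]),
         rel = relative_endothelial_area(sum(rec$endothelial_area),
                                         area_um2),
         spv = endothelial_surface_per_volume(
           rec$endoluminal_perimeter[ok], area_um2, section_thickness))
  }
  bl <- suppressMessages(class_stats(cd31_records))
  ly <- suppressMessages(class_stats(podo_records))

  dens <- function(n) if (is.na(n)) NA_real_
                      else microvessel_density(n, analyzed_area)
  layer_depths <- rep(NA_real_, 3)
  if (!is.null(layer_fit))
    layer_depths[seq_along(layer_fit$layer_medians)] <-
      layer_fit$layer_medians

  out <- data.frame(
    sample_id = sample_id, analyzed_area = analyzed_area,
    total_density = dens(counts$total),
    blood_density = dens(counts$blood),
    lymph_density = dens(counts$lymphatic),
    density_clamped = isTRUE(counts$clamped),
    vessel_area_blood = bl$va, perimeter_blood = bl$per,
    endothelial_area_blood = bl$ea, endothelial_thickness_blood = bl$th,
    relative_endothelial_area_blood = bl$rel,
    surface_per_volume_blood = bl$spv,
    vessel_area_lymph = ly$va, perimeter_lymph = ly$per,
    endothelial_area_lymph = ly$ea, endothelial_thickness_lymph = ly$th,
    relative_endothelial_area_lymph = ly$rel,
    surface_per_volume_lymph = ly$spv,
    mast_cell_density = mast_density,
    submeso_thickness = submeso_thickness,
    layer_depth_1 = layer_depths[1], layer_depth_2 = layer_depths[2],
    layer_depth_3 = layer_depths[3],
    mesothelial_coverage = coverage, stringsAsFactors = FALSE)
  class(out) <- c("sample_metrics", "data.frame")
  out
}
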