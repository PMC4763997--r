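#' Parameters of a synthetic peritoneal section
#'
#' Bundles every generator-side counterpart of a measured quantity: vessel
#' densities, the three-layer depth mixture, vessel calibre and wall
#' thickness, submesothelial band thickness, mesothelial coverage, mast-cell
#' density and the stain intensity model. Defaults describe the parietal
#' peritoneum of an infant (<1 year): blood capillary density 223/mm2,
#' lymphatic density 58/mm2, vessel layers at 36/96/192 um below the
#' mesothelium, submesothelial thickness 230 um.
#'
#' @param analyzed_area Tissue area of the section in mm2 (default 1.44, the
#'   cohort median analysis area).
#' @param pixel_scale Pixel edge length in um/px (default 0.25, a 40x
#'   whole-slide scan).
#' @param section_thickness Physical section thickness in um (enters, and
#'   algebraically cancels from, the endothelial surface-per-volume measure).
#' @param blood_density,lymph_density True blood / lymphatic vessel density
#'   in vessels/mm2. Vessel counts are Poisson with mean density x area.
#' @param layer_depths Median depths (um below the mesothelial monolayer) of
#'   the three submesothelial vessel layers.
#' @param layer_iqrs Interquartile ranges of the three layers (um); the
#'   within-layer normal dispersion is IQR/1.349.
#' @param layer_weights Mixture weights over the three layers; must sum to 1.
#' @param vessel_radius_mean,vessel_radius_sd Outer vessel radius
#'   distribution (um); draws are clamped to at least `wall_thickness` + 1 um.
#' @param wall_thickness True endothelial wall thickness in um.
#' @param collapsed_fraction Fraction of vessels rendered without a lumen
#'   (filled discs), in [0,1].
#' @param submeso_thickness True submesothelial band thickness in um
#'   (mesothelium down to fat/muscle/fascia).
#' @param boundary_wedge Relative amplitude of the linear wedge imposed on
#'   the lower submesothelial boundary (0 = flat band); the wedge is
#'   median-preserving.
#' @param boundary_wave Relative amplitude of a whole-period sinusoidal
#'   roughness on the lower boundary.
#' @param denuded_fraction Fraction of the mesothelial surface lacking the
#'   monolayer, in [0,1].
#' @param meso_thickness Mesothelial monolayer band thickness in um.
#' @param mast_density True tryptase-positive mast cell density in cells/mm2.
#' @param mast_radius Mast cell radius in um.
#' @param intensity_pos,intensity_bg Stain intensity of positive objects and
#'   background on the [0,1] scale.
#' @param noise_sd Additive Gaussian intensity noise (sd, intensity units).
#' @param seed Integer seed; fixed seed gives bit-identical sections and
#'   ground truth.
#'
#' @return An object of class `section_params` (a validated list).
#' @seealso [generate_section()], [peritoneal_group_params()]
#' @export
#' @examples
#' p <- section_params(analyzed_area = 0.05, pixel_scale = 1, seed = 1)
#' p$blood_density
section_params <- function(analyzed_area = 1.44,
                           pixel_scale = 0.25,
                           section_thickness = 4,
                           blood_density = 223,
                           lymph_density = 58,
                           layer_depths = c(36, 96, 192),
                           layer_iqrs = c(20, 65, 133),
                           layer_weights = rep(1 / 3, 3),
                           vessel_radius_mean = 5,
                           vessel_radius_sd = 1,
                           wall_thickness = 1.29,
                           collapsed_fraction = 0.1,
                           submeso_thickness = 230,
                           boundary_wedge = 0.15,
                           boundary_wave = 0.03,
                           denuded_fraction = 0.21,
                           meso_thickness = 3,
                           mast_density = 12.9,
                           mast_radius = 2.5,
                           intensity_pos = 0.8,
                           intensity_bg = 0.1,
                           noise_sd = 0.05,
                           seed = NULL) {
  p <- list(
    analyzed_area = analyzed_area, pixel_scale = pixel_scale,
    section_thickness = section_thickness,
    blood_density = blood_density, lymph_density = lymph_density,
    layer_depths = layer_depths, layer_iqrs = layer_iqrs,
    layer_weights = layer_weights,
    vessel_radius_mean = vessel_radius_mean,
    vessel_radius_sd = vessel_radius_sd,
    wall_thickness = wall_thickness,
    collapsed_fraction = collapsed_fraction,
    submeso_thickness = submeso_thickness,
    boundary_wedge = boundary_wedge, boundary_wave = boundary_wave,
    denuded_fraction = denuded_fraction, meso_thickness = meso_thickness,
    mast_density = mast_density, mast_radius = mast_radius,
    intensity_pos = intensity_pos, intensity_bg = intensity_bg,
    noise_sd = noise_sd, seed = seed
  )
  class(p) <- "section_params"
  validate_section_params(p)
}

validate_section_params <- function(p) {
  num <- p[setdiff(names(p), "seed")]
  if (!all(vapply(num, function(v) is.numeric(v) && all(is.finite(v)), TRUE)))
    stop("section_params: all parameters must be finite numerics")
  if (p$pixel_scale <= 0) stop("pixel_scale must be > 0")
  if (p$analyzed_area <= 0) stop("analyzed_area must be > 0")
  if (p$section_thickness <= 0) stop("section_thickness must be > 0")
  dens <- c(p$blood_density, p$lymph_density, p$mast_density)
  if (any(dens < 0)) stop("densities must be >= 0")
  if (length(p$layer_depths) != 3L || length(p$layer_iqrs) != 3L ||
      length(p$layer_weights) != 3L)
    stop("layer_depths, layer_iqrs, layer_weights must have length 3")
  if (any(p$layer_iqrs < 0)) stop("layer_iqrs must be >= 0")
  if (abs(sum(p$layer_weights) - 1) > 1e-8 || any(p$layer_weights < 0))
    stop("layer_weights must be a simplex (non-negative, summing to 1)")
  for (f in c("collapsed_fraction", "denuded_fraction"))
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must be in [0,1]")
  if (p$wall_thickness <= 0) stop("wall_thickness must be > 0")
  if (p$vessel_radius_mean <= p$wall_thickness)
    stop("vessel_radius_mean must exceed wall_thickness")
  if (p$submeso_thickness <= 0) stop("submeso_thickness must be > 0")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(p$seed)) p$seed <- as.integer(p$seed)
  p
}

#' @export
print.section_params <- function(x, ...) {
  cat("Synthetic peritoneal section parameters\n")
  cat(sprintf("  analyzed area: %.3g mm2 at %.3g um/px\n",
              x$analyzed_area, x$pixel_scale))
  cat(sprintf("  vessel density (blood/lymph): %.4g / %.4g per mm2\n",
              x$blood_density, x$lymph_density))
  cat(sprintf("  layers: %s um (IQR %s)\n",
              paste(x$layer_depths, collapse = "/"),
              paste(x$layer_iqrs, collapse = "/")))
  cat(sprintf("  wall %.3g um, outer radius %.3g (sd %.3g) um, collapsed %.0f%%\n",
              x$wall_thickness, x$vessel_radius_mean, x$vessel_radius_sd,
              100 * x$collapsed_fraction))
  cat(sprintf("  submesothelium %.4g um, denuded %.0f%%, mast %.3g /mm2\n",
              x$submeso_thickness, 100 * x$denuded_fraction, x$mast_density))
  invisible(x)
}

# Age-group labels used throughout; pediatric bounds are half-open [lo, hi).
AGE_GROUPS <- data.frame(
  group = c("<1", "1-<2", "2-<7", "7-<12", "12-<18", "18-40", "41-60"),
  lo = c(0, 1, 2, 7, 12, 18, 40),
  hi = c(1, 2, 7, 12, 18, 40, 60),
  stringsAsFactors = FALSE
)

#' Cohort parameter tables by age group
#'
#' Default per-age-group generator parameters for parietal peritoneum
#' (`peritoneal_group_params()`) and omentum (`omental_group_params()`).
#' Vessel densities and endothelial wall thicknesses are the published group
#' medians; submesothelial thickness follows the published age course (thin
#' in infancy, maximal around 7-12 years, thinner again in adults). Group
#' sizes are the study's 14, 10, 15, 15, 18, 21 and 14 patients.
#'
#' @return A data frame with one row per age group: group label, age bounds,
#'   group size `n`, and the group-specific `section_params` fields
#'   (`blood_density`, `lymph_density`, `wall_thickness`,
#'   `submeso_thickness`).
#' @export
peritoneal_group_params <- function() {
  cbind(AGE_GROUPS,
        n = c(14L, 10L, 15L, 15L, 18L, 21L, 14L),
        blood_density = c(223, 89, 76, 35, 89, 106, 172),
        lymph_density = c(58, 37, 33, 39, 12, 44, 19),
        wall_thickness = c(1.29, 1.12, 1.45, 1.95, 1.48, 1.21, 1.17),
        submeso_thickness = c(230, 260, 330, 402, 300, 200, 173))
}

#' @rdname peritoneal_group_params
#' @export
omental_group_params <- function() {
  cbind(AGE_GROUPS,
        n = c(14L, 10L, 15L, 15L, 18L, 21L, 14L),
        blood_density = c(434, 151, 18, 24, 83, 44, 36),
        lymph_density = c(20, 6, 2, 3, 5, 7, 4),
        wall_thickness = c(1.04, 1.2, 1.36, 1.28, 1.29, 1.55, 1.55),
        submeso_thickness = c(230, 260, 330, 402, 300, 200, 173))
}
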