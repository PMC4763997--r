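# Shared fixtures: small, fast synthetic sections and hand-built canvases.

# Small default parameter set for unit tests (coarse grid, small area).
tiny_params <- function(...) {
  args <- utils::modifyList(
    list(analyzed_area = 0.04, pixel_scale = 0.5, blood_density = 150,
         lymph_density = 50, submeso_thickness = 200, seed = 1),
    list(...))
  do.call(section_params, args)
}

# Blank intensity canvas wrapped as a stain_section.
blank_section <- function(nr, nc, scale = 0.25, stain = "cd31", bg = 0.1) {
  stain_section(matrix(bg, nr, nc), stain, scale)
}

# Paint rings onto a section at given centres/radii (no noise).
paint_rings <- function(section, x, y, r_out, r_in = 0, value = 0.8) {
  img <- section$img
  r_in <- rep_len(r_in, length(x))
  r_out <- rep_len(r_out, length(x))
  for (k in seq_along(x))
    img[peritomorph:::ring_indices(nrow(img), ncol(img), x[k], y[k],
                                   r_out[k], r_in[k],
                                   section$pixel_scale)] <- value
  stain_section(img, section$stain, section$pixel_scale,
                section$section_thickness, section$analyzed_area)
}

# Structural tissue-code map with a given per-column boundary depth (um).
struct_section <- function(nr, nc, scale, boundary_um, meso_um = 3,
                           covered = rep(TRUE, nc)) {
  depth <- (seq_len(nr) - 0.5) * scale
  m <- matrix(1, nr, nc)
  m[outer(depth, rep_len(boundary_um, nc), ">")] <- 2
  meso_rows <- which(depth <= meso_um)
  if (length(meso_rows)) m[meso_rows, covered] <- 3
  stain_section(m, "structural", scale)
}

# Constant-curve LMS model built by hand (constant L, M, S over age).
lms_constant <- function(L, M, S, age_range = c(0, 60)) {
  structure(list(
    par = c(L, log(M), log(S)),
    idx = list(L = 1L, M = 2L, S = 3L),
    bases = list(L = list(ns = NULL, df = 1L),
                 M = list(ns = NULL, df = 1L),
                 S = list(ns = NULL, df = 1L)),
    df = c(L = 1, M = 1, S = 1), age_offset = 0.25,
    age_range = age_range, n = 0L, logLik = NA_real_, convergence = 0L,
    data = list(values = numeric(0), ages = numeric(0))),
    class = "lms_model")
}
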