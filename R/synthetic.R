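# Synthetic dual-stain peritoneal sections with per-object ground truth.
#
# Image convention: numeric matrix in [0,1]; row index = depth (row 1 is the
# peritoneal surface), column index = lateral position; 0-based physical
# coordinates, pixel (i,j) has centre ((j-0.5)*scale, (i-0.5)*scale) um.

# Evaluate expr under a local RNG state (seed NULL = use current stream).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Single-stain section container
#'
#' @param img Numeric matrix, intensities in [0,1] (or integer tissue codes
#'   for the structural channel); row 1 is the peritoneal surface.
#' @param stain Stain name (`"cd31"`, `"podoplanin"`, `"tryptase"`,
#'   `"structural"`, ...).
#' @param pixel_scale um per pixel (> 0).
#' @param section_thickness Physical section thickness, um.
#' @param analyzed_area Analyzed tissue area in mm2; defaults to the full
#'   canvas area.
#' @return An object of class `stain_section`.
#' @export
stain_section <- function(img, stain, pixel_scale, section_thickness = 4,
                          analyzed_area = NULL) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (pixel_scale <= 0) stop("pixel_scale must be > 0")
  canvas <- nrow(img) * ncol(img) * pixel_scale^2 / 1e6
  if (is.null(analyzed_area)) analyzed_area <- canvas
  if (analyzed_area > canvas * (1 + 1e-8))
    stop("analyzed_area exceeds the image area")
  structure(list(img = img, stain = stain, pixel_scale = pixel_scale,
                 section_thickness = section_thickness,
                 analyzed_area = analyzed_area),
            class = "stain_section")
}

#' @export
print.stain_section <- function(x, ...) {
  cat(sprintf("<stain_section> %s: %d x %d px, %.3g um/px, %.3g mm2\n",
              x$stain, nrow(x$img), ncol(x$img), x$pixel_scale,
              x$analyzed_area))
  invisible(x)
}

# Structural-channel tissue codes.
STRUCT_SUBMESO <- 1
STRUCT_LOWER <- 2
STRUCT_MESO <- 3

#' Rasterize an annular vessel cross-section
#'
#' Marks pixels whose centre lies within the ring `inner_radius < r <=
#' outer_radius` around `center`. As `pixel_scale` shrinks the mask area
#' converges to the analytic ring area pi*(r_out^2 - r_in^2). An inner
#' radius of 0 yields a filled disc (the collapsed-vessel phenotype).
#'
#' @param center Ring centre `c(x, y)` in um. Defaults to just fitting the
#'   ring on its own canvas.
#' @param outer_radius,inner_radius Outer/inner radius in um; must satisfy
#'   `outer_radius > inner_radius >= 0`.
#' @param pixel_scale um per pixel.
#' @param dim Optional canvas size `c(nrow, ncol)` in pixels.
#' @return Integer 0/1 matrix.
#' @export
#' @examples
#' m <- render_annulus(outer_radius = 5, inner_radius = 3.5, pixel_scale = 0.1)
#' sum(m) * 0.1^2          # ~ pi * (25 - 12.25) = 40.06 um2
render_annulus <- function(center = NULL, outer_radius, inner_radius = 0,
                           pixel_scale, dim = NULL) {
  if (!is.finite(outer_radius) || !is.finite(inner_radius) ||
      inner_radius < 0 || outer_radius <= inner_radius)
    stop("require outer_radius > inner_radius >= 0")
  if (pixel_scale <= 0) stop("pixel_scale must be > 0")
  if (outer_radius < pixel_scale)
    warning("outer radius below one pixel: degenerate mask")
  if (is.null(dim)) {
    n <- ceiling(2 * outer_radius / pixel_scale) + 4L
    dim <- c(n, n)
  }
  if (is.null(center))
    center <- c(dim[2], dim[1]) / 2 * pixel_scale
  x <- (seq_len(dim[2]) - 0.5) * pixel_scale - center[1]
  y <- (seq_len(dim[1]) - 0.5) * pixel_scale - center[2]
  d2 <- outer(y^2, x^2, "+")
  m <- matrix(0L, dim[1], dim[2])
  m[d2 <= outer_radius^2 & d2 > inner_radius^2] <- 1L
  if (inner_radius == 0) m[d2 == 0] <- 1L  # guard exact centre
  m
}

# Linear pixel indices of a ring; lets the caller stamp many rings into a
# large canvas by subassignment without copying the canvas.
ring_indices <- function(nr, nc, cx, cy, r_out, r_in, scale) {
  i0 <- max(1L, floor((cy - r_out) / scale))
  i1 <- min(nr, ceiling((cy + r_out) / scale) + 1L)
  j0 <- max(1L, floor((cx - r_out) / scale))
  j1 <- min(nc, ceiling((cx + r_out) / scale) + 1L)
  if (i0 > i1 || j0 > j1) return(integer(0))
  y <- (i0:i1 - 0.5) * scale - cy
  x <- (j0:j1 - 0.5) * scale - cx
  d2 <- outer(y^2, x^2, "+")
  sel <- which(d2 <= r_out^2 & d2 > r_in^2)
  rows <- (sel - 1L) %% length(y) + i0
  cols <- (sel - 1L) %/% length(y) + j0
  (cols - 1L) * nr + rows
}

# Draw one truncated-normal deviate by inverse CDF.
rtnorm1 <- function(mu, sd, lo, hi) {
  if (sd <= 0) return(min(max(mu, lo), hi))
  plo <- stats::pnorm(lo, mu, sd); phi <- stats::pnorm(hi, mu, sd)
  if (phi - plo < 1e-12) return(min(max(mu, lo), hi))
  stats::qnorm(stats::runif(1, plo, phi), mu, sd)
}

#' Generate one synthetic peritoneal section set
#'
#' Renders the requested stain channels of a single virtual biopsy plus the
#' exact ground truth. The CD31 channel carries every vessel (annuli;
#' collapsed vessels as filled discs), the podoplanin channel the lymphatic
#' vessels plus the mesothelial monolayer band, the tryptase channel the
#' mast cells, and the structural channel an HE-like tissue-code map
#' (1 = submesothelium, 2 = deeper fat/muscle/fascia, 3 = mesothelium).
#' Vessel depths follow the three-layer mixture truncated to the
#' submesothelial band; vessel positions are resampled (up to 100 attempts)
#' to keep objects separable.
#'
#' @param params A [section_params()] object.
#' @param channels Which channels to render (rendering fewer saves time and
#'   memory); ground truth is always returned.
#' @return A list with one [stain_section()] per requested channel and
#'   `$truth`, a `section_truth` list: `vessels` (one row per vessel:
#'   class, centre, depth, radii, collapsed flag), `mast` (cell positions),
#'   `coverage` (true mesothelial coverage fraction), `boundary_um`
#'   (true lower submesothelial boundary depth per column) and the realized
#'   `analyzed_area`.
#' @export
generate_section <- function(params,
                             channels = c("structural", "cd31",
                                          "podoplanin", "tryptase")) {
  p <- validate_section_params(params)
  if (length(channels))   # empty channels = ground truth only
    channels <- match.arg(channels, several.ok = TRUE)
  with_seed(p$seed, {
    scale <- p$pixel_scale
    band_max <- p$submeso_thickness *
      (1 + p$boundary_wedge + p$boundary_wave)
    h_um <- p$meso_thickness + band_max + 12
    nr <- max(8L, round(h_um / scale))
    nc <- max(8L, round(p$analyzed_area * 1e6 / (nr * scale^2)))
    h_um <- nr * scale
    w_um <- nc * scale
    area <- nr * nc * scale^2 / 1e6  # realized mm2

    # lower submesothelial boundary (depth from surface, per column)
    u <- ((seq_len(nc) - 0.5) / nc)
    thick_x <- p$submeso_thickness *
      (1 + p$boundary_wedge * (2 * u - 1) +
         p$boundary_wave * sin(4 * pi * u))
    boundary <- p$meso_thickness + thick_x

    # mesothelial coverage in ~50 um blocks
    nblk <- max(4L, round(w_um / 50))
    ndenud <- round(p$denuded_fraction * nblk)
    denuded <- if (ndenud > 0) sample.int(nblk, ndenud) else integer(0)
    blk_of_col <- pmin(nblk, ceiling(seq_len(nc) / (nc / nblk)))
    covered_col <- !(blk_of_col %in% denuded)
    coverage <- 1 - ndenud / nblk

    # ---- vessel ground truth ----
    n_blood <- stats::rpois(1, p$blood_density * area)
    n_lymph <- stats::rpois(1, p$lymph_density * area)
    n <- n_blood + n_lymph
    vclass <- rep(c("blood", "lymphatic"), c(n_blood, n_lymph))
    vessels <- NULL
    n_crowded <- 0L
    if (n > 0) {
      r_lo <- p$wall_thickness + 1
      r_hi <- max(r_lo + 0.5, p$vessel_radius_mean + 3 * p$vessel_radius_sd)
      r_out <- pmin(pmax(stats::rnorm(n, p$vessel_radius_mean,
                                      p$vessel_radius_sd), r_lo), r_hi)
      collapsed <- stats::runif(n) < p$collapsed_fraction
      r_in <- ifelse(collapsed, 0, r_out - p$wall_thickness)
      d_hi_band <- p$meso_thickness +
        p$submeso_thickness * (1 - p$boundary_wedge - p$boundary_wave)
      if (2 * max(r_out) + 4 > min(w_um, d_hi_band - p$meso_thickness)) {
        warning("section too small to hold a vessel; empty ground truth")
        n <- 0L
      } else {
        xs <- ds <- numeric(n)
        sds <- p$layer_iqrs / 1.349
        for (k in seq_len(n)) {
          d_lo <- p$meso_thickness + r_out[k] + 1
          d_hi <- d_hi_band - r_out[k] - 1
          ok <- FALSE
          for (att in 1:100) {
            comp <- sample.int(3L, 1L, prob = p$layer_weights)
            d <- rtnorm1(p$layer_depths[comp], sds[comp], d_lo, d_hi)
            x <- stats::runif(1, r_out[k] + 1, w_um - r_out[k] - 1)
            if (k == 1L) { ok <- TRUE } else {
              pv <- seq_len(k - 1L)
              sep <- (xs[pv] - x)^2 + (ds[pv] - d)^2 >=
                (r_out[pv] + r_out[k] + 2)^2
              ok <- all(sep)
            }
            if (ok) break
          }
          if (!ok) n_crowded <- n_crowded + 1L
          xs[k] <- x; ds[k] <- d
        }
        vessels <- data.frame(
          id = seq_len(n), class = vclass, x_um = xs, depth_um = ds,
          r_out_um = r_out, r_in_um = r_in, collapsed = collapsed,
          stringsAsFactors = FALSE)
      }
    }
    if (is.null(vessels))
      vessels <- data.frame(id = integer(0), class = character(0),
                            x_um = numeric(0), depth_um = numeric(0),
                            r_out_um = numeric(0), r_in_um = numeric(0),
                            collapsed = logical(0), stringsAsFactors = FALSE)

    # ---- mast cells ----
    n_mast <- stats::rpois(1, p$mast_density * area)
    mast <- data.frame(x_um = numeric(0), depth_um = numeric(0))
    if (n_mast > 0) {
      mr <- p$mast_radius
      mast <- data.frame(
        x_um = stats::runif(n_mast, mr + 0.5, w_um - mr - 0.5),
        depth_um = stats::runif(n_mast, p$meso_thickness + mr + 0.5,
                                h_um - mr - 0.5))
    }

    meso_rows <- which((seq_len(nr) - 0.5) * scale <= p$meso_thickness)

    noisy <- function(img) {
      if (p$noise_sd > 0) img <- img + stats::rnorm(length(img), 0, p$noise_sd)
      img[img < 0] <- 0; img[img > 1] <- 1
      img
    }
    mk <- function(img, stain)
      stain_section(img, stain, scale, p$section_thickness, area)

    out <- list()
    if ("structural" %in% channels) {
      depth_row <- (seq_len(nr) - 0.5) * scale
      m <- matrix(STRUCT_SUBMESO, nr, nc)
      m[outer(depth_row, boundary, ">")] <- STRUCT_LOWER
      if (length(meso_rows))
        m[meso_rows, covered_col] <- STRUCT_MESO
      out$structural <- mk(m, "structural")
    }
    if ("cd31" %in% channels) {
      img <- matrix(p$intensity_bg, nr, nc)
      for (k in seq_len(nrow(vessels)))
        img[ring_indices(nr, nc, vessels$x_um[k], vessels$depth_um[k],
                         vessels$r_out_um[k], vessels$r_in_um[k],
                         scale)] <- p$intensity_pos
      out$cd31 <- mk(noisy(img), "cd31")
    }
    if ("podoplanin" %in% channels) {
      img <- matrix(p$intensity_bg, nr, nc)
      if (length(meso_rows))
        img[meso_rows, covered_col] <- p$intensity_pos
      for (k in which(vessels$class == "lymphatic"))
        img[ring_indices(nr, nc, vessels$x_um[k], vessels$depth_um[k],
                         vessels$r_out_um[k], vessels$r_in_um[k],
                         scale)] <- p$intensity_pos
      out$podoplanin <- mk(noisy(img), "podoplanin")
    }
    if ("tryptase" %in% channels) {
      img <- matrix(p$intensity_bg, nr, nc)
      for (k in seq_len(nrow(mast)))
        img[ring_indices(nr, nc, mast$x_um[k], mast$depth_um[k],
                         p$mast_radius, 0, scale)] <- p$intensity_pos
      out$tryptase <- mk(noisy(img), "tryptase")
    }

    out$truth <- structure(list(
      vessels = vessels, mast = mast, coverage = coverage,
      boundary_um = boundary, submeso_thickness = p$submeso_thickness,
      analyzed_area = area, n_crowded = n_crowded, params = p),
      class = "section_truth")
    out
  })
}

#' Generate a virtual patient cohort
#'
#' One section set per virtual patient, with ages drawn uniformly within
#' each age-group's bounds and group-specific generator parameters taken
#' from a parameter table (default: the parietal peritoneum group medians).
#' Deterministic under a fixed seed.
#'
#' @param group_table Per-age-group parameter table as returned by
#'   [peritoneal_group_params()] (columns `group`, `lo`, `hi`, `n`, plus any
#'   `section_params` fields to override per group).
#' @param n_per_group Optional single size overriding the table's `n` for
#'   every group.
#' @param seed Cohort seed; per-patient seeds are derived from it.
#' @param channels Channels to render per patient.
#' @param handler Optional `function(sections, truth, meta_row)` applied to
#'   each patient as it is generated; when supplied only its results (and
#'   the truths) are kept, so large cohorts never hold all images in memory.
#' @param ... Further arguments to [section_params()] applied to every
#'   patient (e.g. `analyzed_area`, `pixel_scale`).
#' @return A list: `meta` (patient id, group, age, seed), `truths`,
#'   and `sections` (per patient; `NULL` when a handler is used) or
#'   `results` (handler outputs).
#' @export
generate_cohort <- function(group_table = peritoneal_group_params(),
                            n_per_group = NULL, seed = 1,
                            channels = c("structural", "cd31",
                                         "podoplanin", "tryptase"),
                            handler = NULL, ...) {
  if (is.null(group_table) || nrow(group_table) == 0)
    stop("empty group table")
  sizes <- if (is.null(n_per_group)) group_table$n
           else rep(n_per_group, nrow(group_table))
  if (any(sizes < 1)) stop("group sizes must be >= 1")
  total <- sum(sizes)
  seeds <- with_seed(seed, sample.int(2^30, total + nrow(group_table)))
  ages <- numeric(0)
  gi <- 0L
  meta <- NULL
  for (g in seq_len(nrow(group_table))) {
    a <- with_seed(seeds[total + g],
                   stats::runif(sizes[g], group_table$lo[g],
                                group_table$hi[g]))
    meta <- rbind(meta, data.frame(
      patient = sprintf("P%03d", gi + seq_len(sizes[g])),
      group = group_table$group[g], age = a,
      seed = seeds[gi + seq_len(sizes[g])], stringsAsFactors = FALSE))
    gi <- gi + sizes[g]
  }
  extra <- list(...)
  par_fields <- intersect(names(group_table),
                          setdiff(names(formals(section_params)), "seed"))
  truths <- vector("list", total)
  keep <- is.null(handler)
  sections <- if (keep) vector("list", total) else NULL
  results <- if (!keep) vector("list", total) else NULL
  i <- 0L
  for (g in seq_len(nrow(group_table))) {
    args_g <- c(as.list(group_table[g, par_fields, drop = FALSE]), extra)
    for (k in seq_len(sizes[g])) {
      i <- i + 1L
      args_g$seed <- meta$seed[i]
      sp <- do.call(section_params, args_g)
      sec <- generate_section(sp, channels = channels)
      truths[[i]] <- sec$truth
      if (keep) {
        sections[[i]] <- sec
      } else {
        results[i] <- list(handler(sec, sec$truth, meta[i, ]))
      }
    }
  }
  names(truths) <- meta$patient
  out <- list(meta = meta, truths = truths)
  if (keep) { names(sections) <- meta$patient; out$sections <- sections }
  else { names(results) <- meta$patient; out$results <- results }
  out
}

#' Calibrate vessel calibre to a target endothelial area fraction
#'
#' Solves the outer-radius mean so that the expected endothelial
#' (stain-positive) pixel area per analyzed area equals `target_pct`
#' percent, holding density and wall thickness fixed. For open rings the
#' expected ring area is linear in the radius,
#' `pi * w * (2*mu_r - w)`, so the solution is exact in expectation;
#' collapsed vessels (filled discs, area `pi*(mu_r^2 + sd_r^2)`) are
#' accounted for numerically.
#'
#' @param params A [section_params()] object.
#' @param target_pct Target endothelial area percentage of the analyzed
#'   area, attributed to the blood-vessel (CD31) channel.
#' @return `params` with `vessel_radius_mean` replaced.
#' @export
calibrate_endothelial_fraction <- function(params, target_pct) {
  p <- validate_section_params(params)
  dens <- p$blood_density + p$lymph_density
  if (dens <= 0) stop("densities are zero; nothing to calibrate")
  target_um2_per_mm2 <- target_pct / 100 * 1e6
  w <- p$wall_thickness; cf <- p$collapsed_fraction; s <- p$vessel_radius_sd
  f <- function(mu) {
    ring <- pi * w * (2 * mu - w)
    disc <- pi * (mu^2 + s^2)
    dens * ((1 - cf) * ring + cf * disc) - target_um2_per_mm2
  }
  sol <- stats::uniroot(f, lower = w + 1.01, upper = 500)$root
  p$vessel_radius_mean <- sol
  p
}
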