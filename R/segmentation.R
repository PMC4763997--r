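# Vessel object detection on stained sections.
#
# A vessel is a connected stain-positive component (the endothelial wall);
# its lumen is recovered by hole filling. Components below the minimum
# object area are treated as noise. Collapsed vessels (no distinct lumen)
# are kept for density counting but flagged, and excluded from shape
# metrics. Perimeters use a Crofton-type digitization correction: naive
# 4-neighbour boundary-edge counting overestimates smooth contours by a
# factor 4/pi, so edge counts are scaled by pi/4.

# Per-label exposed-edge count (image border counts as exposure).
label_edge_counts <- function(L, nlab) {
  nr <- nrow(L); nc <- ncol(L)
  cnt <- numeric(nlab)
  acc <- function(v) {
    v <- v[v > 0L]
    if (length(v)) cnt <<- cnt + tabulate(v, nbins = nlab)
  }
  a <- L[-nr, , drop = FALSE]; b <- L[-1, , drop = FALSE]
  d <- a != b
  acc(a[d]); acc(b[d])
  a <- L[, -nc, drop = FALSE]; b <- L[, -1, drop = FALSE]
  d <- a != b
  acc(a[d]); acc(b[d])
  acc(L[1, ]); acc(L[nr, ]); acc(L[, 1]); acc(L[, nc])
  cnt
}

# Watershed split of one filled component with >1 lumen; returns the
# component's pixels relabeled 1..k (matrix over the bounding box).
split_component <- function(sub_mask) {
  dm <- EBImage::distmap(sub_mask)
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  EBImage::imageData(ws)
}

empty_vessel_records <- function() {
  structure(data.frame(
    id = integer(0), x_um = numeric(0), depth_um = numeric(0),
    stain = character(0), vessel_class = character(0),
    endothelial_area = numeric(0), lumen_area = numeric(0),
    vessel_area = numeric(0), outer_perimeter = numeric(0),
    endoluminal_perimeter = numeric(0), endothelial_thickness = numeric(0),
    collapsed = logical(0), border = logical(0), stringsAsFactors = FALSE),
    class = c("vessel_records", "data.frame"))
}

#' Detect vessel cross-sections in a stained section
#'
#' Segments stain-positive connected components, recovers each component's
#' lumen by hole filling, and returns one record per vessel with areas
#' (endothelial, lumen, total), digitization-corrected perimeters, depth
#' below the mesothelial surface and the collapsed / border flags. Vessel
#' area equals endothelial area plus lumen area by construction. On the
#' podoplanin channel a surface margin is masked first so the mesothelial
#' band is not counted as a vessel. Touching rings (detected as one
#' component with several lumina) are split by one round of watershed on
#' the distance transform.
#'
#' @param section A [stain_section()] with the mesothelial surface along
#'   the top row.
#' @param thresholds [intensity_thresholds()] for positive pixels.
#' @param min_object_area Minimum component area in um2 (default 12;
#'   suppresses noise specks well below capillary size).
#' @param lumen_threshold_px Lumen area (in pixels) below which a vessel is
#'   flagged collapsed (default 4).
#' @param surface_margin Depth in um to mask from the surface before
#'   detection; default 15 for podoplanin, 0 otherwise.
#' @param split_touching Split merged rings by watershed (default TRUE).
#' @param sample_id Optional sample identifier stored on the result.
#' @return A `vessel_records` data frame, one row per vessel, sorted by
#'   depth; units um and um2. `endothelial_thickness` is endothelial area
#'   divided by the mean of outer and endoluminal perimeter (equal to
#'   r_out - r_in for a perfect annulus) and is `NA` for collapsed or
#'   border-touching vessels.
#' @export
detect_vessels <- function(section, thresholds = intensity_thresholds(),
                           min_object_area = 12, lumen_threshold_px = 4,
                           surface_margin = NULL, split_touching = TRUE,
                           sample_id = NULL) {
  if (!inherits(section, "stain_section"))
    stop("section must be a stain_section (surface reference = top row)")
  scale <- section$pixel_scale
  if (is.null(surface_margin))
    surface_margin <- if (identical(section$stain, "podoplanin")) 15 else 0
  lab <- classify_pixels(section, thresholds)
  mask <- lab > 0L
  if (surface_margin > 0) {
    m_rows <- seq_len(min(nrow(mask), ceiling(surface_margin / scale)))
    mask[m_rows, ] <- FALSE
  }
  L <- EBImage::imageData(EBImage::bwlabel(mask))
  nlab <- max(L)
  if (nlab == 0) return(empty_vessel_records())

  # drop sub-threshold specks
  area_px <- tabulate(L, nlab)
  keep <- area_px * scale^2 >= min_object_area
  lut <- c(0L, ifelse(keep, cumsum(keep), 0L))
  L <- matrix(lut[L + 1L], nrow(L), ncol(L))
  nlab <- max(L)
  if (nlab == 0) return(empty_vessel_records())
  filled <- EBImage::imageData(EBImage::fillHull(L))

  # split components holding more than one distinct lumen
  if (split_touching) {
    lum_mask <- filled > 0L & L == 0L
    if (any(lum_mask)) {
      Lu <- EBImage::imageData(EBImage::bwlabel(lum_mask))
      nlu <- max(Lu)
      if (nlu > 0) {
        lu_px <- tabulate(Lu, nlu)
        lu_idx <- which(Lu > 0L)
        owner <- integer(nlu)
        owner[Lu[lu_idx]] <- filled[lu_idx]
        real <- lu_px >= lumen_threshold_px
        multi <- as.integer(names(which(table(owner[real]) > 1)))
        for (ob in multi) {
          sel <- which(filled == ob)
          rr <- range((sel - 1L) %% nrow(filled) + 1L)
          cc <- range((sel - 1L) %/% nrow(filled) + 1L)
          sm <- filled[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE] == ob
          parts <- split_component(sm)
          kparts <- max(parts)
          if (kparts > 1) {
            sub_f <- filled[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
            sub_l <- L[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
            newid <- c(ob, nlab + seq_len(kparts - 1L))
            nlab <- nlab + kparts - 1L
            repl <- sm & parts > 0
            sub_f[repl] <- newid[parts[repl]]
            wall <- repl & sub_l == ob
            sub_l[wall] <- sub_f[wall]
            filled[rr[1]:rr[2], cc[1]:cc[2]] <- sub_f
            L[rr[1]:rr[2], cc[1]:cc[2]] <- sub_l
          }
        }
      }
    }
  }

  idx <- which(filled > 0L)
  flab <- filled[idx]
  vessel_px <- tabulate(flab, nlab)
  wlab <- L[L > 0L]
  endo_px <- tabulate(wlab, nlab)
  lumen_px <- vessel_px - endo_px

  nr <- nrow(filled)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  srow <- rowsum(as.numeric(rows), flab)
  scol <- rowsum(as.numeric(cols), flab)
  ids <- as.integer(rownames(srow))
  crow <- ccol <- numeric(nlab)
  crow[ids] <- srow[, 1] / vessel_px[ids]
  ccol[ids] <- scol[, 1] / vessel_px[ids]

  border_ids <- unique(c(filled[1, ], filled[nr, ], filled[, 1],
                         filled[, ncol(filled)]))
  border <- seq_len(nlab) %in% border_ids[border_ids > 0L]

  outer_per <- label_edge_counts(filled, nlab) * (pi / 4) * scale
  Lu2 <- filled
  Lu2[L > 0L] <- 0L
  lum_per <- label_edge_counts(Lu2, nlab) * (pi / 4) * scale

  collapsed <- lumen_px < lumen_threshold_px
  lum_per[collapsed] <- 0
  endo_area <- endo_px * scale^2
  thick <- endo_area / ((outer_per + lum_per) / 2)
  thick[collapsed | border] <- NA_real_

  rec <- data.frame(
    id = seq_len(nlab),
    x_um = (ccol - 0.5) * scale,
    depth_um = (crow - 0.5) * scale,
    stain = section$stain,
    vessel_class = if (identical(section$stain, "podoplanin"))
      "lymphatic" else "unassigned",
    endothelial_area = endo_area,
    lumen_area = lumen_px * scale^2,
    vessel_area = vessel_px * scale^2,
    outer_perimeter = outer_per,
    endoluminal_perimeter = lum_per,
    endothelial_thickness = thick,
    collapsed = collapsed, border = border, stringsAsFactors = FALSE)
  rec <- rec[order(rec$depth_um), ]
  rec$id <- seq_len(nrow(rec))
  rownames(rec) <- NULL
  class(rec) <- c("vessel_records", "data.frame")
  attr(rec, "sample_id") <- sample_id
  attr(rec, "analyzed_area") <- section$analyzed_area
  rec
}

#' Per-sample vessel counts from the dual-stain design
#'
#' CD31 stains blood and lymphatic endothelium, podoplanin only lymphatic
#' endothelium (and mesothelium, which is masked during detection), so the
#' blood vessel count is the intraindividual difference of the two counts,
#' clamped at zero.
#'
#' @param cd31_records,podo_records `vessel_records` from the CD31 and
#'   podoplanin sections of one sample.
#' @return List with `total`, `lymphatic`, `blood` counts and a `clamped`
#'   flag (TRUE when podoplanin exceeded CD31 and blood was clamped to 0,
#'   with a warning).
#' @export
classify_by_dual_stain <- function(cd31_records, podo_records) {
  s1 <- attr(cd31_records, "sample_id")
  s2 <- attr(podo_records, "sample_id")
  if (!is.null(s1) && !is.null(s2) && !identical(s1, s2))
    stop("records come from different samples: ", s1, " vs ", s2)
  total <- nrow(cd31_records)
  lymphatic <- nrow(podo_records)
  blood <- total - lymphatic
  clamped <- blood < 0
  if (clamped) {
    warning(sprintf(
      "podoplanin count (%d) exceeds CD31 count (%d); blood count clamped to 0",
      lymphatic, total))
    blood <- 0L
  }
  list(total = total, lymphatic = lymphatic, blood = blood,
       clamped = clamped)
}

#' Mesothelial surface integrity
#'
#' Fraction of the surface length covered by mesothelial signal, measured
#' in a thin band under the top edge: on the structural channel by the
#' mesothelium tissue code, on the podoplanin channel by stain-positive
#' pixels (podoplanin marks mesothelial cells).
#'
#' @param section Structural or podoplanin [stain_section()].
#' @param cutoff Coverage below which the sample is flagged denuded
#'   (default 0.5).
#' @param band_um Surface band depth inspected, um.
#' @param thresholds [intensity_thresholds()] (podoplanin channel only).
#' @return List with `coverage` in [0,1] and logical `denuded`.
#' @export
mesothelial_integrity <- function(section, cutoff = 0.5, band_um = 6,
                                  thresholds = intensity_thresholds()) {
  if (!inherits(section, "stain_section")) stop("need a stain_section")
  img <- section$img
  nband <- min(nrow(img), max(1L, ceiling(band_um / section$pixel_scale)))
  if (nrow(img) == 0 || ncol(img) == 0)
    stop("no surface present in image")
  band <- img[seq_len(nband), , drop = FALSE]
  pos <- if (identical(section$stain, "structural")) band == STRUCT_MESO
         else band > thresholds$negative_max
  coverage <- mean(colSums(pos) > 0)
  list(coverage = coverage, denuded = coverage < cutoff)
}
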