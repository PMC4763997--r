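# Pixel-level stain classification (positive pixel counting) and the
# positivity statistic: positive pixels / all analyzed pixels.

#' Intensity thresholds for positive-pixel classification
#'
#' Bin boundaries on the [0,1] intensity scale separating negative, weak,
#' medium and strong pixels. Defaults are calibrated to the generator's
#' intensity model (background 0.1, positive objects 0.8) and are meant to
#' be adapted per stain.
#'
#' @param negative_max Upper bound of the negative bin.
#' @param weak_max,medium_max Upper bounds of the weak and medium bins;
#'   everything above `medium_max` is strong. Boundaries must be strictly
#'   increasing.
#' @return An object of class `intensity_thresholds`.
#' @export
intensity_thresholds <- function(negative_max = 0.3, weak_max = 0.5,
                                 medium_max = 0.7) {
  b <- c(negative_max, weak_max, medium_max)
  if (any(!is.finite(b)) || any(diff(b) <= 0))
    stop("threshold boundaries must be finite and strictly increasing")
  structure(list(negative_max = negative_max, weak_max = weak_max,
                 medium_max = medium_max), class = "intensity_thresholds")
}

PIXEL_LABELS <- c("negative", "weak", "medium", "strong")

#' Classify pixels into negative/weak/medium/strong
#'
#' Intensity binning of a stained section: each pixel is assigned to one of
#' the four classes by the threshold boundaries.
#'
#' @param section A [stain_section()] (or a plain numeric matrix).
#' @param thresholds An [intensity_thresholds()] object.
#' @return Integer matrix of the same shape, values 0..3 =
#'   negative/weak/medium/strong, with `levels` attribute.
#' @export
classify_pixels <- function(section, thresholds = intensity_thresholds()) {
  img <- if (inherits(section, "stain_section")) section$img else section
  if (!is.matrix(img) || length(img) == 0) stop("empty image")
  if (anyNA(img) || any(!is.finite(img))) {
    bad <- which(!is.finite(img), arr.ind = TRUE)
    stop(sprintf("non-finite pixels, first at row %d col %d (%d total)",
                 bad[1, 1], bad[1, 2], nrow(bad)))
  }
  lab <- matrix(0L, nrow(img), ncol(img))
  lab[img > thresholds$negative_max] <- 1L
  lab[img > thresholds$weak_max] <- 2L
  lab[img > thresholds$medium_max] <- 3L
  attr(lab, "levels") <- PIXEL_LABELS
  lab
}

#' Positivity: fraction of positive pixels
#'
#' Total number of weak + medium + strong pixels divided by the total
#' number of analyzed pixels.
#'
#' @param label_map Label matrix from [classify_pixels()].
#' @return Fraction in [0, 1].
#' @export
positivity <- function(label_map) {
  if (length(label_map) == 0) stop("empty label map")
  sum(label_map > 0L) / length(label_map)
}
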