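# Submesothelial thickness by transect measurement and the three-layer
# vessel architecture.

#' Submesothelial thickness by perpendicular transects
#'
#' Measures, at `n_transects` evenly spaced lateral positions (5% margins
#' from the lateral edges), the perpendicular distance from the bottom of
#' the mesothelial monolayer down to the first deeper tissue class (fat /
#' muscle / fascia) on the structural channel, and returns the median
#' transect. Where the surface is denuded the transect starts at the top
#' edge.
#'
#' @param section Structural [stain_section()] (tissue-code map).
#' @param n_transects Number of transects (>= 5).
#' @return Median transect thickness in um, with attribute `transects`
#'   (the individual measurements).
#' @export
measure_submesothelial_thickness <- function(section, n_transects = 7) {
  if (!inherits(section, "stain_section") ||
      !identical(section$stain, "structural"))
    stop("need the structural (tissue-code) channel")
  if (n_transects < 5) stop("at least five transects are required")
  img <- section$img
  scale <- section$pixel_scale
  nc <- ncol(img)
  cols <- round(seq(0.05 * nc, 0.95 * nc, length.out = n_transects))
  cols <- pmin(pmax(cols, 1L), nc)
  if (!any(img == STRUCT_LOWER))
    stop("no deeper tissue class (fat/muscle/fascia, code ",
         STRUCT_LOWER, ") present below the submesothelium")
  tr <- vapply(cols, function(j) {
    col <- img[, j]
    meso <- which(col == STRUCT_MESO)
    top <- if (length(meso)) max(meso) else 0L
    low <- which(col == STRUCT_LOWER)
    if (!length(low)) return(NA_real_)
    (min(low) - 1L - top) * scale
  }, numeric(1))
  structure(stats::median(tr, na.rm = TRUE), transects = tr)
}

# Seeded k-medians in 1-D with depth-tercile initialization.
kmedians_1d <- function(x, k, maxit = 200) {
  med <- as.numeric(stats::quantile(x, probs = (seq_len(k) - 0.5) / k,
                                    names = FALSE))
  assign <- rep(1L, length(x))
  for (it in seq_len(maxit)) {
    d <- abs(outer(x, med, "-"))
    assign <- max.col(-d, ties.method = "first")
    new <- vapply(seq_len(k), function(j)
      if (any(assign == j)) stats::median(x[assign == j]) else med[j],
      numeric(1))
    new <- sort(new)
    if (max(abs(new - med)) < 1e-10) break
    med <- new
  }
  list(centers = med, assign = assign)
}

#' Cluster vessel depths into ordered layers
#'
#' 1-D clustering of vessel depths below the mesothelium into `k` ordered
#' layers. The default method fits a k-component normal mixture by EM
#' (unequal variances) and reports each component's median depth; the
#' alternative `"kmedians"` partitions depths by seeded k-medians with
#' depth-quantile initialization and reports the within-cluster medians.
#' The mixture method is the default because the submesothelial layers
#' overlap substantially (the deep layer is several times wider than the
#' superficial one) and hard partitioning of overlapping, unequal-width
#' layers systematically inflates the upper layer positions, whereas the
#' mixture ML estimate of the layer centres is consistent.
#'
#' @param depths Vessel depths in um.
#' @param k Number of layers (default 3).
#' @param method `"gmm"` (default) or `"kmedians"`.
#' @param seed Seed for reproducibility (both methods are deterministic
#'   given the data; the seed also covers any EM restart).
#' @return An object of class `layer_fit`: `layer_medians` (strictly
#'   increasing), `layer_iqrs`, `assignments` (MAP layer per vessel),
#'   `k`, `method` and a mean silhouette `validity` score.
#' @export
cluster_vessel_layers <- function(depths, k = 3, method = c("gmm", "kmedians"),
                                  seed = 1) {
  method <- match.arg(method)
  k <- as.integer(k)
  depths <- depths[is.finite(depths)]
  n <- length(depths)
  if (n == 0) stop("no depths supplied")
  if (length(unique(depths)) < k) {
    k_new <- max(1L, length(unique(depths)))
    warning(sprintf("fewer than %d distinct depths; fitting %d layer(s)",
                    k, k_new))
    k <- k_new
  }
  fit <- with_seed(seed, {
    if (method == "gmm" && k > 1) {
      # Mclust resolves mclustBIC in the caller's frame; bind it locally
      mclustBIC <- mclust::mclustBIC
      mc <- tryCatch(
        mclust::Mclust(depths, G = k, modelNames = "V", verbose = FALSE),
        error = function(e) NULL)
      if (is.null(mc)) {
        km <- kmedians_1d(depths, k)
        list(centers = km$centers, assign = km$assign,
             iqr_from_assign = TRUE)
      } else {
        mu <- as.numeric(mc$parameters$mean)
        sg <- sqrt(as.numeric(mc$parameters$variance$sigmasq))
        if (length(sg) == 1) sg <- rep(sg, k)
        ord <- order(mu)
        cls <- match(mc$classification, ord)
        list(centers = mu[ord], sigma = sg[ord], assign = cls,
             iqr_from_assign = FALSE)
      }
    } else if (k == 1) {
      if (stats::sd(depths) == 0 || n < 2)
        warning("degenerate depths: single layer")
      list(centers = stats::median(depths), assign = rep(1L, n),
           iqr_from_assign = TRUE)
    } else {
      km <- kmedians_1d(depths, k)
      list(centers = km$centers, assign = km$assign,
           iqr_from_assign = TRUE)
    }
  })
  iqrs <- if (isTRUE(fit$iqr_from_assign)) {
    vapply(seq_len(k), function(j) {
      xj <- depths[fit$assign == j]
      if (length(xj) > 1) stats::IQR(xj) else 0
    }, numeric(1))
  } else 1.349 * fit$sigma
  # mean silhouette on the 1-D partition
  validity <- NA_real_
  if (k > 1) {
    d <- abs(outer(depths, fit$centers, "-"))
    own <- d[cbind(seq_len(n), fit$assign)]
    d[cbind(seq_len(n), fit$assign)] <- Inf
    nearest <- apply(d, 1, min)
    validity <- mean((nearest - own) / pmax(nearest, own))
  }
  structure(list(layer_medians = fit$centers, layer_iqrs = iqrs,
                 assignments = fit$assign, k = k, method = method,
                 validity = validity, n = n),
            class = "layer_fit")
}

#' @export
print.layer_fit <- function(x, ...) {
  cat(sprintf("<layer_fit> %d vessels in %d layer(s) [%s]\n", x$n, x$k,
              x$method))
  cat("  median depths (um):", paste(round(x$layer_medians, 1),
                                     collapse = ", "), "\n")
  cat("  IQRs (um):        ", paste(round(x$layer_iqrs, 1),
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Correlate layer depths with submesothelial thickness across a cohort
#'
#' Rank (Spearman) correlation, per layer, between the layer's median
#' depth and the total submesothelial thickness across samples.
#'
#' @param layer_fits List of [cluster_vessel_layers()] fits, one per
#'   sample.
#' @param thicknesses Submesothelial thicknesses (um), same length.
#' @return Data frame with `layer`, `rho`, `p` (NA when undefined).
#' @export
layer_depth_vs_thickness <- function(layer_fits, thicknesses) {
  if (length(layer_fits) != length(thicknesses))
    stop("one thickness per layer fit required")
  if (length(layer_fits) < 3) stop("need at least 3 samples")
  k <- max(vapply(layer_fits, function(f) f$k, integer(1)))
  out <- lapply(seq_len(k), function(j) {
    d <- vapply(layer_fits, function(f)
      if (f$k >= j) f$layer_medians[j] else NA_real_, numeric(1))
    ok <- is.finite(d) & is.finite(thicknesses)
    r <- correlate(d[ok], thicknesses[ok], force = "spearman")
    data.frame(layer = j, rho = r$estimate, p = r$p.value)
  })
  do.call(rbind, out)
}
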