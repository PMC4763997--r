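# Readers/writers and the pipeline stages binding the modules together:
# simulate (sections to disk), quantify (sections to metrics tables),
# reference (metrics tables to LMS centile models).

#' Write / read a stain section
#'
#' Images are written as single-channel TIFF (32-bit float) or PNG
#' (16-bit), with a JSON sidecar (`<path>.json`) holding the stain name,
#' pixel scale, section thickness and analyzed area. Structural tissue
#' codes are stored scaled into [0,1] and recovered on read via the
#' sidecar.
#'
#' @param section A [stain_section()].
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_section <- function(section, path) {
  stopifnot(inherits(section, "stain_section"))
  fac <- if (identical(section$stain, "structural")) 10 else 1
  img <- section$img / fac
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 32L)
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else stop("unsupported image format: .", ext)
  meta <- list(stain = section$stain, pixel_scale = section$pixel_scale,
               section_thickness = section$section_thickness,
               analyzed_area = section$analyzed_area, scale_factor = fac)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_section
#' @export
read_section <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing metadata sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else if (ext == "png") png::readPNG(path)
         else stop("unsupported image format: .", ext)
  if (is.array(img) && length(dim(img)) == 3) img <- img[, , 1]
  img <- img * meta$scale_factor
  if (identical(meta$stain, "structural")) img <- round(img)
  stain_section(img, meta$stain, meta$pixel_scale,
                meta$section_thickness, meta$analyzed_area)
}

# Serialize an LMS model (knots + coefficients + transform) to JSON.

#' @rdname fit_lms
#' @param model An `lms_model`.
#' @param path JSON file path.
#' @export
write_lms <- function(model, path) {
  knots <- lapply(model$bases, function(b) {
    if (is.null(b$ns)) list(df = 1)
    else list(df = b$df, knots = as.numeric(attr(b$ns, "knots")),
              boundary = as.numeric(attr(b$ns, "Boundary.knots")))
  })
  jsonlite::write_json(list(
    par = model$par, idx = model$idx, knots = knots, df = as.list(model$df),
    age_offset = model$age_offset, age_range = model$age_range,
    n = model$n, logLik = model$logLik), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fit_lms
#' @export
read_lms <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild <- function(k) {
    if (is.null(k$knots) || length(k$knots) == 0) {
      if (is.null(k$boundary)) return(list(ns = NULL, df = 1L))
      ns <- splines::ns(k$boundary, Boundary.knots = k$boundary, df = 1)
    } else {
      ns <- splines::ns(k$boundary, knots = k$knots,
                        Boundary.knots = k$boundary)
    }
    list(ns = ns, df = as.integer(k$df))
  }
  structure(list(
    par = j$par, idx = lapply(j$idx, as.integer),
    bases = lapply(j$knots, rebuild),
    df = unlist(j$df), age_offset = j$age_offset,
    age_range = j$age_range, n = j$n, logLik = j$logLik,
    convergence = 0L,
    data = list(values = numeric(0), ages = numeric(0))),
    class = "lms_model")
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(out_dir = "peritomorph_out", seed = 1,
                   tissue = "peritoneal", n_per_group = NULL,
                   pixel_scale = 0.25, analyzed_area = 1.44,
                   format = "tif",
                   channels = c("structural", "cd31", "podoplanin",
                                "tryptase"),
                   metrics = c("submeso_thickness", "blood_density",
                               "lymph_density"))
  cfg <- utils::modifyList(defaults, as.list(config))
  cfg
}

config_hash <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), "out_dir")]  # identify the science, not paths
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg[order(names(cfg))], f, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(f))
}

#' Pipeline stage: simulate a cohort to disk
#'
#' Writes per-patient channel images with JSON sidecars, per-patient
#' ground-truth JSON, the cohort table as CSV and a manifest carrying the
#' seed, configuration hash and per-file checksums.
#'
#' @param config A list (or YAML file path) with any of: `out_dir`,
#'   `seed`, `tissue` ("peritoneal"/"omental"), `n_per_group`,
#'   `pixel_scale`, `analyzed_area`, `format` ("tif"/"png"), `channels`.
#' @return The manifest, invisibly.
#' @export
run_simulate <- function(config = list()) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(cfg$out_dir, 2) != 0)
    stop("output directory not writable: ", cfg$out_dir)
  tab <- switch(cfg$tissue, peritoneal = peritoneal_group_params(),
                omental = omental_group_params(),
                stop("unknown tissue: ", cfg$tissue))
  files <- character(0)
  handler <- function(sec, truth, meta) {
    for (ch in setdiff(names(sec), "truth")) {
      f <- file.path(cfg$out_dir,
                     sprintf("%s_%s.%s", meta$patient, ch, cfg$format))
      write_section(sec[[ch]], f)
      files <<- c(files, f, paste0(f, ".json"))
    }
    tf <- file.path(cfg$out_dir, sprintf("%s_truth.json", meta$patient))
    jsonlite::write_json(list(
      vessels = truth$vessels, mast = truth$mast,
      coverage = truth$coverage,
      submeso_thickness = truth$submeso_thickness,
      analyzed_area = truth$analyzed_area, seed = meta$seed), tf,
      auto_unbox = TRUE, digits = NA)
    files <<- c(files, tf)
    NULL
  }
  coh <- generate_cohort(tab, n_per_group = cfg$n_per_group,
                         seed = cfg$seed, channels = cfg$channels,
                         handler = handler,
                         pixel_scale = cfg$pixel_scale,
                         analyzed_area = cfg$analyzed_area)
  cf <- file.path(cfg$out_dir, "cohort.csv")
  utils::write.csv(coh$meta, cf, row.names = FALSE)
  files <- c(files, cf)
  manifest <- list(stage = "simulate", seed = cfg$seed,
                   config = cfg[order(names(cfg))],
                   config_hash = config_hash(cfg),
                   n_patients = nrow(coh$meta),
                   generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   checksums = as.list(tools::md5sum(sort(files))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Quantify one sample's channel sections
#'
#' Runs the full measurement chain (pixel classification, vessel
#' detection, dual-stain differencing, mast-cell counting, structural
#' measurements, layer clustering) over the channels present and returns
#' the per-sample metrics row plus the vessel records.
#'
#' @param sections Named list with any of `cd31`, `podoplanin`,
#'   `tryptase`, `structural` [stain_section()]s.
#' @param sample_id Sample identifier.
#' @param thresholds [intensity_thresholds()].
#' @return List: `metrics` (one-row [summarize_sample()] frame),
#'   `records` (combined vessel records), `layer_fit`.
#' @export
quantify_sample <- function(sections, sample_id = NA_character_,
                            thresholds = intensity_thresholds()) {
  area <- NULL
  for (s in sections) if (inherits(s, "stain_section")) area <- s$analyzed_area
  if (is.null(area)) stop("no stain_section supplied")
  cd <- po <- NULL
  if (!is.null(sections$cd31))
    cd <- detect_vessels(sections$cd31, thresholds, sample_id = sample_id)
  if (!is.null(sections$podoplanin))
    po <- detect_vessels(sections$podoplanin, thresholds,
                         sample_id = sample_id)
  mast <- NA_real_
  if (!is.null(sections$tryptase))
    mast <- as.numeric(count_point_cells(sections$tryptase, thresholds))
  thick <- NA_real_
  if (!is.null(sections$structural))
    thick <- as.numeric(measure_submesothelial_thickness(
      sections$structural))
  cov <- NA_real_
  surf <- sections$structural
  if (is.null(surf)) surf <- sections$podoplanin
  if (!is.null(surf)) cov <- mesothelial_integrity(surf)$coverage
  lf <- NULL
  if (!is.null(cd) && nrow(cd) >= 3)
    lf <- cluster_vessel_layers(cd$depth_um)
  st <- if (!is.null(sections$cd31)) sections$cd31$section_thickness else 4
  metrics <- summarize_sample(cd, po, analyzed_area = area,
                              section_thickness = st, mast_density = mast,
                              submeso_thickness = thick, layer_fit = lf,
                              coverage = cov, sample_id = sample_id)
  tag <- function(r) {
    if (is.null(r) || nrow(r) == 0) return(NULL)
    cbind(sample_id = sample_id, r)
  }
  recs <- rbind(tag(cd), tag(po))
  list(metrics = metrics, records = recs, layer_fit = lf)
}

#' Pipeline stage: quantify simulated sections on disk
#'
#' Reads every patient listed in `<in_dir>/cohort.csv`, quantifies the
#' channels found, and writes `sample_metrics.csv` (one row per sample)
#' and `vessel_records.csv` (one row per vessel). A sample whose images
#' are missing or unreadable is skipped with a logged reason; row counts
#' always reconcile (input = output + logged exclusions).
#'
#' @param config List or YAML path: `out_dir` (the simulate output,
#'   also used for results), `format`.
#' @return List with `metrics`, `records`, `skipped`; invisible.
#' @export
run_quantify <- function(config = list()) {
  cfg <- read_pipeline_config(config)
  cf <- file.path(cfg$out_dir, "cohort.csv")
  if (!file.exists(cf)) stop("no cohort table at ", cf)
  meta <- utils::read.csv(cf, stringsAsFactors = FALSE)
  all_metrics <- list(); all_records <- list(); skipped <- character(0)
  for (i in seq_len(nrow(meta))) {
    pid <- meta$patient[i]
    res <- tryCatch({
      secs <- list()
      for (ch in c("structural", "cd31", "podoplanin", "tryptase")) {
        f <- file.path(cfg$out_dir,
                       sprintf("%s_%s.%s", pid, ch, cfg$format))
        if (file.exists(f)) secs[[ch]] <- read_section(f)
      }
      if (!length(secs)) stop("no channel images found")
      quantify_sample(secs, sample_id = pid)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("skipping %s: %s", pid, conditionMessage(res)))
      skipped <- c(skipped, pid)
    } else {
      all_metrics[[pid]] <- res$metrics
      if (!is.null(res$records)) all_records[[pid]] <- res$records
    }
  }
  if (!length(all_metrics)) stop("all samples failed")
  metrics <- do.call(rbind, all_metrics)
  records <- if (length(all_records)) do.call(rbind, all_records) else NULL
  utils::write.csv(metrics, file.path(cfg$out_dir, "sample_metrics.csv"),
                   row.names = FALSE)
  if (!is.null(records))
    utils::write.csv(records,
                     file.path(cfg$out_dir, "vessel_records.csv"),
                     row.names = FALSE)
  message(sprintf("quantified %d/%d samples (%d skipped)",
                  nrow(metrics), nrow(meta), length(skipped)))
  invisible(list(metrics = metrics, records = records, skipped = skipped))
}

#' Pipeline stage: fit LMS reference curves from the metrics table
#'
#' Fits an LMS centile model over age for each configured metric
#' (defaults: submesothelial thickness, blood density, lymphatic density)
#' and writes each model as JSON plus a centile table CSV.
#'
#' @param config List or YAML path: `out_dir`, `metrics`.
#' @return Named list of `lms_model`s, invisible.
#' @export
run_reference <- function(config = list()) {
  cfg <- read_pipeline_config(config)
  mf <- file.path(cfg$out_dir, "sample_metrics.csv")
  cf <- file.path(cfg$out_dir, "cohort.csv")
  if (!file.exists(mf)) stop("no sample metrics at ", mf)
  metrics <- utils::read.csv(mf, stringsAsFactors = FALSE)
  meta <- utils::read.csv(cf, stringsAsFactors = FALSE)
  d <- merge(metrics, meta, by.x = "sample_id", by.y = "patient")
  models <- list()
  for (m in cfg$metrics) {
    if (!m %in% names(d)) stop("metric not present: ", m)
    ok <- is.finite(d[[m]]) & d[[m]] > 0
    if (sum(ok) < 30)
      stop(sprintf("metric '%s': %d positive rows, need >= 30", m, sum(ok)))
    fit <- fit_lms(d[[m]][ok], d$age[ok])
    models[[m]] <- fit
    write_lms(fit, file.path(cfg$out_dir, sprintf("lms_%s.json", m)))
    utils::write.csv(centile_table(fit),
                     file.path(cfg$out_dir, sprintf("centiles_%s.csv", m)),
                     row.names = FALSE)
  }
  invisible(models)
}
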