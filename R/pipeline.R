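# End-to-end pipeline: configuration, per-subject analysis, study-level
# orchestration.

.default_config <- function() {
  list(
    preprocess = list(
      equalize = TRUE,
      nbins = 256L            # paper-gap: equalization variant unstated
    ),
    vesselness = list(
      small = list(kernel_px = 3L),
      large = list(kernel_px = 30L),
      beta = 0.5,             # paper-gap: Frangi default
      c_mode = "adaptive"     # paper-gap: structureness scale unstated
    ),
    threshold = list(factor = 1.1),
    morphometry = list(
      prune_px = 10L,         # paper-gap: spur pruning unstated
      bins_um = c(0, 10, 20, 30, 40, 50, Inf),
      min_object_px = 0L,     # optional small-object cleanup, off
      fill_holes_px = 100L    # interior pinhole filling before thinning
    ),
    plaque = list(
      spot_scale_um = 15,     # paper-gap: plaque size unstated
      min_sep_um = 30,
      rel_threshold = 0.4
    ),
    stats = list(welch = FALSE),
    seed = 1L
  )
}

.check_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stop("unknown config key(s): ",
         paste0(path, extra, collapse = ", "))
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
      .check_keys(cfg[[k]], ref[[k]], paste0(path, k, "."))
  }
}

.merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !is.null(names(base[[k]])))
      base[[k]] <- .merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Build and validate a pipeline configuration
#'
#' Starts from the package defaults (global threshold factor 1.1, kernel
#' scales 3 and 30 px, 2 x 2 mm / 512 x 512 geometry) and overlays the
#' supplied values.  Unknown keys and out-of-range parameters are
#' rejected before any computation runs.
#'
#' @param ... named overrides, nested lists mirroring the default
#'   structure (e.g. `vesselness = list(small = list(kernel_px = 5))`).
#' @param file optional YAML file of overrides.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- .default_config()
  if (!is.null(file)) {
    user <- yaml::read_yaml(file)
    .check_keys(user, cfg)
    cfg <- .merge_config(cfg, user)
  }
  dots <- list(...)
  if (length(dots)) {
    .check_keys(dots, cfg)
    cfg <- .merge_config(cfg, dots)
  }
  if (cfg$vesselness$small$kernel_px < 1 ||
      cfg$vesselness$large$kernel_px < 1)
    stop("kernel_px must be >= 1")
  if (cfg$threshold$factor <= 0) stop("threshold factor must be > 0")
  if (cfg$morphometry$prune_px < 0) stop("prune_px must be >= 0")
  if (is.unsorted(cfg$morphometry$bins_um))
    stop("bins_um must be increasing")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full vascular pipeline on one subject
#'
#' Equalization, background estimation, the three binarization maps and
#' their combination, skeletonization, the segment graph, the VLD
#' profile, and (when a CFM image is given) automated plaque detection.
#' Deterministic: rerunning with the same inputs and config reproduces
#' every output.
#'
#' @param image PAM `intensity_image`.
#' @param config a [pipeline_config()].
#' @param cfm optional CFM `intensity_image` for plaque detection.
#' @param out_dir optional directory; when given, writes the four map
#'   TIFFs, the skeleton TIFF, segment and VLD CSVs, plaque CSV and a
#'   JSON manifest.
#' @return list with `maps`, `skeleton`, `graph`, `vld`, `plaque`
#'   (or `NULL`) and `config`.
#' @export
run_subject <- function(image, config = pipeline_config(), cfm = NULL,
                        out_dir = NULL) {
  stopifnot(inherits(image, "intensity_image"))
  maps <- vessel_maps(
    image,
    equalize_first = isTRUE(config$preprocess$equalize),
    threshold = threshold_params(config$threshold$factor),
    small = vesselness_params(kernel_px = config$vesselness$small$kernel_px,
                              beta = config$vesselness$beta,
                              c_mode = config$vesselness$c_mode),
    large = vesselness_params(kernel_px = config$vesselness$large$kernel_px,
                              beta = config$vesselness$beta,
                              c_mode = config$vesselness$c_mode))
  final <- maps$mapult
  if (config$morphometry$fill_holes_px > 0)
    final <- fill_holes(final, config$morphometry$fill_holes_px)
  if (config$morphometry$min_object_px > 0)
    final <- remove_small_objects(final, config$morphometry$min_object_px)
  skel <- skeletonize_mask(final)
  graph <- build_graph(skel, final, image$pixel_pitch_um,
                       prune_px = config$morphometry$prune_px)
  vld <- vld_profile(graph, config$morphometry$bins_um)
  plaque <- if (!is.null(cfm)) {
    detect_plaques(cfm,
                   min_sep_um = config$plaque$min_sep_um,
                   spot_scale_um = config$plaque$spot_scale_um,
                   rel_threshold = config$plaque$rel_threshold)
  } else NULL
  res <- list(maps = maps, skeleton = skel, graph = graph, vld = vld,
              plaque = plaque, config = config)
  if (!is.null(out_dir)) .write_subject(res, image, out_dir)
  res
}

.write_subject <- function(res, image, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wmask <- function(m, f) write_tiff_gray(.as_mask(m) * 255, file.path(
    out_dir, f), bits = 8L)
  wmask(res$maps$map1, "map1.tif")
  wmask(res$maps$map2, "map2.tif")
  wmask(res$maps$map3, "map3.tif")
  wmask(res$maps$mapult, "mapult.tif")
  wmask(res$skeleton, "skeleton.tif")
  utils::write.csv(res$graph$segments,
                   file.path(out_dir, "segments.csv"), row.names = FALSE)
  utils::write.csv(res$vld$profile, file.path(out_dir, "vld.csv"),
                   row.names = FALSE)
  if (!is.null(res$plaque))
    save_annotations(res$plaque, file.path(out_dir, "plaques.csv"))
  manifest <- list(
    pixel_pitch_um = image$pixel_pitch_um,
    image_area_mm2 = res$graph$image_area_mm2,
    config = unclass(res$config),
    artifacts = list.files(out_dir),
    background_level = res$maps$background$level,
    n_segments = nrow(res$graph$segments),
    total_vld = res$vld$total_vld)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run a simulated or loaded study end to end
#'
#' Takes per-subject records (as produced by [simulate_cohort()], or
#' assembled from loaded TIFFs), runs [run_subject()] on each, and
#' returns the cohort comparison table.  All subjects must share one
#' pixel pitch.
#'
#' @param subjects list of records with `label`, `image` and optionally
#'   `cfm`; at least 2 subjects per group.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for per-subject bundles and the
#'   study report CSV.
#' @return list with `per_subject` (run results), `report`
#'   (data.frame from [compare_cohort()]) and `labels`.
#' @export
run_study <- function(subjects, config = pipeline_config(),
                      out_dir = NULL) {
  if (length(subjects) == 0L) stop("no subjects given")
  labels <- vapply(subjects, function(s) s$label, character(1))
  if (any(table(labels) < 2))
    stop("every group needs at least 2 subjects")
  pitches <- vapply(subjects, function(s) s$image$pixel_pitch_um,
                    numeric(1))
  if (length(unique(pitches)) > 1L)
    stop("mixed pixel pitches across subjects: ",
         paste(unique(pitches), collapse = ", "))
  runs <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    sdir <- if (is.null(out_dir)) NULL else
      file.path(out_dir, subjects[[i]]$subject %||% sprintf("s%02d", i))
    runs[[i]] <- run_subject(subjects[[i]]$image, config,
                             cfm = subjects[[i]]$cfm, out_dir = sdir)
  }
  plq <- vapply(runs, function(r)
    if (is.null(r$plaque)) NA_real_ else r$plaque$density_per_mm2,
    numeric(1))
  report <- compare_cohort(lapply(runs, `[[`, "vld"), labels,
                           plaque_density = if (all(is.na(plq))) NULL
                           else plq,
                           welch = isTRUE(config$stats$welch))
  if (!is.null(out_dir))
    utils::write.csv(report, file.path(out_dir, "study_report.csv"),
                     row.names = FALSE)
  list(per_subject = runs, report = report, labels = labels)
}
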