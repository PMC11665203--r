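# Amyloid plaque quantification from CFM images.
#
# The authoritative route is manual annotation (counts per field); the
# automated detector is an explicitly labeled surrogate: scale-matched
# difference-of-Gaussians blob detection with relative thresholding and
# non-maximum suppression.

.new_plaque_result <- function(xy, area_mm2, method) {
  structure(list(coordinates = xy, count = nrow(xy),
                 density_per_mm2 = nrow(xy) / area_mm2,
                 area_mm2 = area_mm2, method = method),
            class = "plaque_result")
}

#' @export
print.plaque_result <- function(x, ...) {
  cat(sprintf("<plaque_result> %s: %d plaques, %.2f / mm2\n",
              x$method, x$count, x$density_per_mm2))
  invisible(x)
}

#' Load manual plaque annotations
#'
#' Reads a CSV of point annotations with header `x_um,y_um` (micrometre
#' coordinates) or `x_px,y_px` (0-based pixel indices, converted using
#' `pixel_pitch_um`).
#'
#' @param path CSV file.
#' @param field_size_um field of view; points outside it are rejected
#'   with an error naming the row.
#' @param pixel_pitch_um needed only for pixel-unit annotations.
#' @return a `plaque_result` with method `"manual"`.
#' @export
load_annotations <- function(path, field_size_um = 2000,
                             pixel_pitch_um = 2000 / 512) {
  df <- utils::read.csv(path)
  if (all(c("x_um", "y_um") %in% names(df))) {
    xy <- cbind(x_um = df$x_um, y_um = df$y_um)
  } else if (all(c("x_px", "y_px") %in% names(df))) {
    xy <- cbind(x_um = df$x_px * pixel_pitch_um,
                y_um = df$y_px * pixel_pitch_um)
  } else stop("annotation CSV must have columns x_um,y_um or x_px,y_px")
  if (nrow(xy)) {
    bad <- which(xy[, 1] < 0 | xy[, 1] > field_size_um |
                 xy[, 2] < 0 | xy[, 2] > field_size_um)
    if (length(bad))
      stop("annotation outside the field at row(s): ",
           paste(bad, collapse = ", "))
  }
  .new_plaque_result(xy, (field_size_um / 1000)^2, "manual")
}

#' Export plaque coordinates in the annotation CSV dialect
#' @param result a `plaque_result`.
#' @param path output CSV (header `x_um,y_um`).
#' @export
save_annotations <- function(result, path) {
  utils::write.csv(as.data.frame(result$coordinates), path,
                   row.names = FALSE)
  invisible(path)
}

#' Automated plaque (bright spot) detection
#'
#' Difference-of-Gaussians band-pass matched to the expected spot scale,
#' local-maximum selection, a threshold relative to the strongest
#' response (hence invariance to positive intensity rescaling), and
#' greedy non-maximum suppression enforcing a minimum separation.
#'
#' @param image a CFM `intensity_image`.
#' @param min_sep_um minimum distance between two detections.
#' @param spot_scale_um expected spot FWHM (default 15 um, typical
#'   cortical plaque appearance at this pitch).
#' @param rel_threshold keep maxima whose band-pass response exceeds this
#'   fraction of the strongest response.
#' @param min_peak_frac absolute floor: unless the strongest band-pass
#'   response reaches this fraction of the image's dynamic range, the
#'   field is declared spot-free (otherwise pure noise would always
#'   yield "detections" under a purely relative threshold).
#' @return a `plaque_result` with method `"auto"`.
#' @export
detect_plaques <- function(image, min_sep_um = 30, spot_scale_um = 15,
                           rel_threshold = 0.4, min_peak_frac = 0.1) {
  stopifnot(inherits(image, "intensity_image"))
  pitch <- image$pixel_pitch_um
  m <- image$pixels
  s1 <- spot_scale_um / (2 * sqrt(2 * log(2))) / pitch
  s2 <- 1.6 * s1
  dog <- gaussian_smooth(m, s1) - gaussian_smooth(m, s2)
  nr <- nrow(dog); nc <- ncol(dog)
  empty <- .new_plaque_result(
    matrix(numeric(0), 0, 2,
           dimnames = list(NULL, c("x_um", "y_um"))),
    image_area_mm2(image), "auto")
  rng <- diff(range(m))
  if (rng == 0 || max(dog) < min_peak_frac * rng) return(empty)
  # strict local maxima over the 8-neighbourhood
  sh <- function(di, dj) {
    ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
    dog[ri, ci]
  }
  ismax <- dog > 0
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & (dog >= sh(di, dj))
  }
  thr <- rel_threshold * max(dog)
  cand <- which(ismax & dog > thr)
  if (length(cand) == 0L) return(empty)
  ri <- ((cand - 1L) %% nr) + 1L
  ci <- ((cand - 1L) %/% nr) + 1L
  resp <- dog[cand]
  ord <- order(resp, decreasing = TRUE)
  ri <- ri[ord]; ci <- ci[ord]
  sep_px <- min_sep_um / pitch
  keep <- logical(length(ri))
  for (k in seq_along(ri)) {
    if (!any(keep)) { keep[k] <- TRUE; next }
    dmin <- min(sqrt((ri[keep] - ri[k])^2 + (ci[keep] - ci[k])^2))
    if (dmin >= sep_px) keep[k] <- TRUE
  }
  xy <- cbind(x_um = (ci[keep] - 1L) * pitch,
              y_um = (ri[keep] - 1L) * pitch)
  .new_plaque_result(xy, image_area_mm2(image), "auto")
}

#' Plaque density
#' @param result a `plaque_result`.
#' @param area_mm2 area; defaults to the area recorded on the result.
#' @return count per mm^2.
#' @export
plaque_density <- function(result, area_mm2 = result$area_mm2) {
  stopifnot(area_mm2 > 0)
  result$count / area_mm2
}

#' Match detections to ground-truth spots
#'
#' Greedy nearest-neighbour matching (best response first) at a fixed
#' radius; reports recall and precision against the truth coordinates.
#'
#' @param result a `plaque_result`.
#' @param truth_xy n x 2 matrix of true (x_um, y_um).
#' @param radius_um match radius (use the spot FWHM).
#' @return list with `recall`, `precision`, `n_matched`.
#' @export
match_plaques <- function(result, truth_xy, radius_um = 15) {
  det <- result$coordinates
  if (nrow(truth_xy) == 0L)
    return(list(recall = NA_real_,
                precision = if (nrow(det)) 0 else NA_real_,
                n_matched = 0L))
  if (nrow(det) == 0L)
    return(list(recall = 0, precision = NA_real_, n_matched = 0L))
  taken <- logical(nrow(truth_xy))
  matched <- 0L
  for (k in seq_len(nrow(det))) {
    dd <- sqrt((truth_xy[, 1] - det[k, 1])^2 +
               (truth_xy[, 2] - det[k, 2])^2)
    dd[taken] <- Inf
    j <- which.min(dd)
    if (dd[j] <= radius_um) {
      taken[j] <- TRUE
      matched <- matched + 1L
    }
  }
  list(recall = matched / nrow(truth_xy),
       precision = matched / nrow(det),
       n_matched = matched)
}
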