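# IntensityImage container and pre-processing: image I/O, volume
# projection, histogram equalization, background estimation.

#' Create an intensity image
#'
#' The basic container every operation in the pipeline consumes: a 2-D
#' non-negative scalar field with an isotropic pixel pitch in micrometres.
#'
#' @param pixels numeric matrix of non-negative, finite values.
#' @param pixel_pitch_um pixel pitch in micrometres per pixel (> 0).
#'   The default `2000/512` is the instrument geometry of a 2 x 2 mm field
#'   sampled at 512 x 512 points (about 3.906 um/px).
#' @param modality `"PAM"` (photoacoustic angiogram) or `"CFM"`
#'   (confocal fluorescence).
#' @param provenance free-text note carried along with the image.
#' @return an object of class `intensity_image`.
#' @export
intensity_image <- function(pixels, pixel_pitch_um = 2000 / 512,
                            modality = c("PAM", "CFM"), provenance = "") {
  modality <- match.arg(modality)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop("pixels must be finite")
  if (any(pixels < 0))
    stop("pixels must be non-negative")
  if (!is.numeric(pixel_pitch_um) || length(pixel_pitch_um) != 1 ||
      pixel_pitch_um <= 0)
    stop("pixel_pitch_um must be a single positive number")
  structure(list(pixels = pixels, pixel_pitch_um = pixel_pitch_um,
                 modality = modality, provenance = provenance),
            class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %s, %d x %d px, %.3f um/px, range [%g, %g]\n",
              x$modality, nrow(x$pixels), ncol(x$pixels), x$pixel_pitch_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.intensity_image <- function(x) dim(x$pixels)

#' Image area in square millimetres
#' @param image an `intensity_image`.
#' @export
image_area_mm2 <- function(image) {
  prod(dim(image$pixels)) * (image$pixel_pitch_um / 1000)^2
}

#' Load a grayscale TIFF as an intensity image
#'
#' @param path single-channel uncompressed TIFF (8/16-bit or 32-bit float).
#' @param pixel_pitch_um pixel pitch in micrometres per pixel.
#' @inheritParams intensity_image
#' @return an `intensity_image`; a multi-page file is rejected (use
#'   [load_volume()] for stacks).
#' @export
load_image <- function(path, pixel_pitch_um = 2000 / 512,
                       modality = c("PAM", "CFM")) {
  m <- read_tiff_gray(path)
  if (length(dim(m)) == 3L)
    stop("multi-page TIFF; use load_volume() for stacks: ", path)
  intensity_image(m, pixel_pitch_um, modality, provenance = path)
}

#' Save an intensity image as TIFF
#'
#' Integer-valued images round-trip bit-exactly; fractional images are
#' stored as 32-bit float.
#'
#' @param image an `intensity_image` or numeric matrix.
#' @param path output path.
#' @param bits 8, 16 or 32; the default picks 16-bit for integer-valued
#'   data in range and float otherwise.
#' @export
save_image <- function(image, path, bits = NULL) {
  m <- if (inherits(image, "intensity_image")) image$pixels else image
  if (is.null(bits)) {
    intlike <- all(m == round(m)) && all(m >= 0) && all(m <= 65535)
    bits <- if (intlike) 16L else 32L
  }
  write_tiff_gray(m, path, bits = as.integer(bits))
}

#' Load a multi-page TIFF as a volume
#'
#' @param path multi-page grayscale TIFF; depth along pages.
#' @return 3-D array `[row, col, depth]`.
#' @export
load_volume <- function(path) {
  a <- read_tiff_gray(path)
  if (length(dim(a)) != 3L) stop("expected a multi-page TIFF: ", path)
  a
}

# analytic-signal magnitude along the first dimension of a matrix whose
# columns are depth profiles
.envelope_cols <- function(m) {
  n <- nrow(m)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  sp <- stats::mvfft(m) * h
  Mod(stats::mvfft(sp, inverse = TRUE) / n)
}

#' Maximum-amplitude projection of a raw volume
#'
#' Envelope-detects each depth profile (magnitude of the analytic signal,
#' the standard demodulation of a photoacoustic A-line) and takes the
#' per-pixel maximum along depth, yielding the maximum-amplitude
#' projection (MAP) image that the vascular analysis consumes.
#'
#' @param volume 3-D array `[row, col, depth]`, or a matrix (returned
#'   unchanged with a warning).
#' @param pixel_pitch_um pitch of the lateral axes.
#' @return an `intensity_image`.
#' @export
project_volume <- function(volume, pixel_pitch_um = 2000 / 512) {
  if (is.matrix(volume)) {
    warning("2-D input passed through unchanged")
    return(intensity_image(volume, pixel_pitch_um, "PAM",
                           provenance = "passthrough"))
  }
  stopifnot(length(dim(volume)) == 3L)
  d <- dim(volume)
  flat <- matrix(aperm(volume, c(3, 1, 2)), nrow = d[3])
  env <- .envelope_cols(flat)
  proj <- matrix(apply(env, 2, max), nrow = d[1], ncol = d[2])
  intensity_image(proj, pixel_pitch_um, "PAM", provenance = "projected")
}

#' Envelope of a volume without projecting
#' @keywords internal
envelope_volume <- function(volume) {
  d <- dim(volume)
  flat <- matrix(aperm(volume, c(3, 1, 2)), nrow = d[3])
  aperm(array(.envelope_cols(flat), dim = d[c(3, 1, 2)]), c(2, 3, 1))
}

#' Global histogram equalization
#'
#' Spreads the intensity histogram over `[0, 1]` using the mid-cumulative
#' mapping: every pixel in bin k is sent to (C[k-1] + C[k]) / 2, where C
#' is the cumulative pixel proportion over `nbins` equal-width bins.  The
#' mid-bin convention halves the worst-case deviation of the output
#' distribution from uniform compared with the usual C[k] mapping, while
#' remaining a monotone function of the input ranks.
#'
#' @param image an `intensity_image` or matrix.
#' @param nbins number of histogram bins (default 256).
#' @return equalized image of the same class, values in `[0, 1]`.
#' @export
equalize <- function(image, nbins = 256L) {
  m <- if (inherits(image, "intensity_image")) image$pixels else image
  rng <- range(m)
  if (rng[1] == rng[2]) {
    warning("constant image: equalization undefined, returning zeros")
    out <- matrix(0, nrow(m), ncol(m))
  } else {
    breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
    idx <- findInterval(m, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    counts <- tabulate(idx, nbins)
    C <- cumsum(counts) / length(m)
    mid <- (c(0, C[-nbins]) + C) / 2
    out <- matrix(mid[idx], nrow(m), ncol(m))
  }
  if (inherits(image, "intensity_image")) {
    image$pixels <- out
    image
  } else out
}

#' Estimate the background level of an image
#'
#' With an explicit region of interest the estimate is the arithmetic mean
#' over that region.  Without one, the default automatic fallback is an
#' iteratively sigma-clipped mean (the standard sky/background estimator
#' in imaging): pixels beyond 2.5 robust standard deviations of the
#' current center are discarded until stable, so the bright vessel tail
#' drops out while a symmetric noise background is estimated without
#' bias.  Two simpler estimators are kept for comparison: the
#' interquartile mean and the darkest-quartile mean (the latter
#' underestimates a Gaussian background by about 1.27 sigma).
#'
#' @param image an `intensity_image` or matrix.
#' @param roi optional logical matrix (same shape) marking the background
#'   region.
#' @param method automatic estimator when no roi is given:
#'   `"sigma_clip"` (default), `"midmean"` or `"darkest_quartile"`.
#' @return a list with `level`, `method` and `n` (pixels used), of class
#'   `background_estimate`.
#' @export
estimate_background <- function(image, roi = NULL,
                                method = c("sigma_clip", "midmean",
                                           "darkest_quartile")) {
  m <- if (inherits(image, "intensity_image")) image$pixels else image
  if (!is.null(roi)) {
    if (!is.logical(roi) || !identical(dim(roi), dim(m)))
      stop("roi must be a logical matrix with the same shape as the image")
    if (!any(roi)) stop("empty roi")
    level <- mean(m[roi])
    method <- "roi"
    n <- sum(roi)
  } else {
    method <- match.arg(method)
    if (method == "sigma_clip") {
      x <- as.vector(m)
      for (it in 1:6) {
        ctr <- stats::median(x)
        s <- stats::mad(x)
        if (s == 0) {
          # a dominant constant plateau IS the background
          x <- x[x == ctr]
          break
        }
        keep <- abs(x - ctr) <= 2.5 * s
        if (all(keep)) break
        x <- x[keep]
      }
      level <- mean(x)
      n <- length(x)
    } else if (method == "midmean") {
      q <- stats::quantile(m, c(0.25, 0.75), names = FALSE)
      sel <- m >= q[1] & m <= q[2]
      level <- mean(m[sel])
      n <- sum(sel)
    } else {
      sel <- m <= stats::quantile(m, 0.25, names = FALSE)
      level <- mean(m[sel])
      n <- sum(sel)
    }
  }
  structure(list(level = level, method = method, n = n),
            class = "background_estimate")
}
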