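# Three-way vessel binarization and the combination rule
# MAPult = (MAP1 AND MAP3) OR MAP2.
#
# MAP1: global threshold at factor x background level -- tracks the true
#       vessel distribution but admits noise and hemorrhage.
# MAP2: small-kernel vesselness -- rejects noise and hemorrhage, keeps
#       capillaries connected, but fragments wide vessels in the middle.
# MAP3: large-kernel vesselness -- keeps wide vessels whole but dilates
#       small ones.

.as_mask <- function(x) if (is.list(x) && !is.null(x$mask)) x$mask else x

.new_mask <- function(mask, source, params_digest = "") {
  structure(list(mask = mask, source = source,
                 params_digest = params_digest),
            class = "binary_vessel_mask")
}

#' @export
print.binary_vessel_mask <- function(x, ...) {
  cat(sprintf("<binary_vessel_mask> %s, %d x %d, %.1f%% vessel\n",
              x$source, nrow(x$mask), ncol(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Threshold parameters for the global map
#'
#' @param factor multiple of the background level used as the global
#'   threshold (default 1.1).
#' @param comparison tie-break at exactly factor x background; only
#'   `"strict_greater"` is provided (deterministic and conservative).
#' @export
threshold_params <- function(factor = 1.1, comparison = "strict_greater") {
  if (factor <= 0) stop("factor must be > 0")
  comparison <- match.arg(comparison, "strict_greater")
  structure(list(factor = factor, comparison = comparison),
            class = "threshold_params")
}

#' MAP1: global thresholding
#'
#' A pixel is vessel iff its value is strictly greater than
#' `factor * background$level`.  The background level must have been
#' estimated on the same (typically equalized) image.
#'
#' @param image an `intensity_image` or matrix.
#' @param background a [estimate_background()] result or a bare level.
#' @param params a [threshold_params()] object.
#' @return a `binary_vessel_mask` with source `"MAP1"`.
#' @export
map1_global <- function(image, background, params = threshold_params()) {
  m <- if (inherits(image, "intensity_image")) image$pixels else image
  level <- if (inherits(background, "background_estimate"))
    background$level else as.numeric(background)
  if (level == 0 && any(m > 0))
    warning("background level is 0: threshold degenerate, every positive ",
            "pixel passes")
  mask <- m > params$factor * level
  .new_mask(mask, "MAP1",
            sprintf("factor=%g;level=%g", params$factor, level))
}

#' Otsu's threshold
#'
#' @param x numeric vector.
#' @param nbins histogram bins.
#' @return the threshold maximizing between-class variance.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins)
  p <- counts / sum(counts)
  mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins)
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  breaks[which.max(bcv) + 1L]
}

#' MAP2 / MAP3: binarize a vesselness image
#'
#' With `method = "otsu"` (the default) the level is chosen by Otsu's
#' criterion on the nonzero vesselness values, so the abundant exact
#' zeros outside any structure do not drag the threshold down.
#'
#' @param vimg a `vesselness_image` from [frangi()].
#' @param method `"otsu"` or `"fixed"`.
#' @param level threshold when `method = "fixed"`.
#' @param source label recorded on the mask (`"MAP2"` or `"MAP3"`).
#' @return a `binary_vessel_mask`.
#' @export
map_from_vesselness <- function(vimg, method = c("otsu", "fixed"),
                                level = NULL, source = "MAP2") {
  method <- match.arg(method)
  v <- vimg$values
  nz <- v[v > 0]
  if (length(nz) == 0) {
    return(.new_mask(matrix(FALSE, nrow(v), ncol(v)), source, "empty"))
  }
  thr <- if (method == "otsu") otsu_threshold(nz) else {
    if (is.null(level)) stop("level required for method = 'fixed'")
    level
  }
  .new_mask(v > thr, source,
            sprintf("kernel=%d;method=%s;level=%g",
                    vimg$params$kernel_px, method, thr))
}

#' Combine the three binarization maps
#'
#' The final vessel mask is the Boolean combination
#' `MAPult = (MAP1 AND MAP3) OR MAP2`: the global map is trusted only
#' where the large-kernel map confirms vessel-like structure, and the
#' small-kernel map is added unconditionally to preserve capillary
#' connectivity.
#'
#' @param m1,m2,m3 `binary_vessel_mask` objects (or logical matrices) for
#'   MAP1, MAP2 and MAP3, all the same shape.
#' @return a `binary_vessel_mask` with source `"MAPult"`.
#' @export
combine_maps <- function(m1, m2, m3) {
  a <- .as_mask(m1); b <- .as_mask(m2); c3 <- .as_mask(m3)
  if (!identical(dim(a), dim(b)) || !identical(dim(a), dim(c3)))
    stop("map shapes differ: ",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), " vs ",
         paste(dim(c3), collapse = "x"))
  .new_mask((a & c3) | b, "MAPult", "rule=(MAP1&MAP3)|MAP2")
}

#' Remove connected components smaller than a pixel count
#'
#' Optional cleanup (off by default in the pipeline): drops 8-connected
#' components with fewer than `min_px` pixels.
#'
#' @param mask a `binary_vessel_mask` or logical matrix.
#' @param min_px minimum component size to keep.
#' @export
remove_small_objects <- function(mask, min_px = 5L) {
  m <- .as_mask(mask)
  lab <- cpp_label(m, 8L)
  keep <- which(tabulate(lab[lab > 0]) >= min_px)
  out <- matrix(lab %in% keep & m, nrow(m), ncol(m))
  if (inherits(mask, "binary_vessel_mask")) {
    mask$mask <- out
    mask
  } else out
}

#' Fill small enclosed holes in a mask
#'
#' Background components that touch no image border and are smaller than
#' `max_px` are turned foreground.  Unlike opening/closing this moves no
#' object boundary; it only removes interior pinholes, which would
#' otherwise force topology-preserving thinning to build spurious loops
#' inside wide vessels.  Genuine inter-vessel gaps (e.g. the inside of a
#' capillary loop, typically hundreds of pixels) stay untouched.
#'
#' @param mask a `binary_vessel_mask` or logical matrix.
#' @param max_px largest hole area (pixels) to fill.
#' @export
fill_holes <- function(mask, max_px = 100L) {
  m <- .as_mask(mask)
  lab <- cpp_label(!m, 4L)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0])
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                       lab[, ncol(lab)]))
    fill <- setdiff(which(sizes < max_px), border)
    if (length(fill)) m[matrix(lab %in% fill, nrow(m))] <- TRUE
  }
  if (inherits(mask, "binary_vessel_mask")) {
    mask$mask <- m
    mask
  } else m
}

#' Count 8-connected components of a mask
#' @param mask logical matrix or `binary_vessel_mask`.
#' @export
count_components <- function(mask) {
  m <- .as_mask(mask)
  max(cpp_label(m, 8L))
}

#' Compute MAP1, MAP2, MAP3 and MAPult for one image
#'
#' Convenience wrapper running the full binarization stage: histogram
#' equalization (optional), background estimation on the working image,
#' the global map, the two single-scale vesselness maps, and their
#' combination.
#'
#' @param image an `intensity_image`.
#' @param equalize_first run [equalize()] before anything else
#'   (default `TRUE`, the published workflow order).
#' @param threshold a [threshold_params()] object.
#' @param small,large [vesselness_params()] for MAP2 / MAP3.
#' @param roi optional background region passed to
#'   [estimate_background()].
#' @return list with `map1`, `map2`, `map3`, `mapult`, the equalized
#'   `working` image and the `background` estimate.
#' @export
vessel_maps <- function(image, equalize_first = TRUE,
                        threshold = threshold_params(),
                        small = vesselness_params(kernel_px = 3L),
                        large = vesselness_params(kernel_px = 30L),
                        roi = NULL) {
  work <- if (equalize_first) equalize(image) else image
  bg <- estimate_background(work, roi)
  m1 <- map1_global(work, bg, threshold)
  v2 <- frangi(work, small)
  v3 <- frangi(work, large)
  m2 <- map_from_vesselness(v2, source = "MAP2")
  m3 <- map_from_vesselness(v3, source = "MAP3")
  list(map1 = m1, map2 = m2, map3 = m3,
       mapult = combine_maps(m1, m2, m3),
       working = work, background = bg)
}
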