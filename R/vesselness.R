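# Single-scale Hessian (Frangi) vesselness filtering.
#
# Each binarization map uses ONE kernel scale: 3 px (~4 um) tuned to the
# smallest vessels and 30 px (~40 um) tuned to the largest.  The scale in
# pixels maps to the Gaussian standard deviation as sigma = kernel_px / 2.

#' Sampled, normalized 1-D Gaussian kernel
#' @keywords internal
gaussian_kernel <- function(sigma, half_width = max(1L, ceiling(3.5 * sigma))) {
  x <- seq(-half_width, half_width)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing with symmetric boundary reflection
#'
#' @param m numeric matrix.
#' @param sigma standard deviation in pixels; `sigma = 0` returns the
#'   input unchanged.
#' @export
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel(sigma)
  cpp_sepconv(m, k, k)
}

#' Vesselness filter parameters
#'
#' @param kernel_px kernel scale in pixels (3 for the small-vessel map,
#'   30 for the large-vessel map).
#' @param beta ridge-anisotropy sensitivity (Frangi's beta, default 0.5).
#' @param c_mode `"adaptive"` sets the structureness scale c to half the
#'   maximum Hessian Frobenius norm over the image; `"fixed"` uses
#'   `c_value`.
#' @param c_value structureness scale when `c_mode = "fixed"`.
#' @param bright_on_dark if `TRUE` (the default, correct for PAM
#'   angiograms) only ridges brighter than their surroundings respond.
#' @export
vesselness_params <- function(kernel_px = 3L, beta = 0.5,
                              c_mode = c("adaptive", "fixed"),
                              c_value = NULL, bright_on_dark = TRUE) {
  c_mode <- match.arg(c_mode)
  if (kernel_px < 1) stop("kernel_px must be >= 1")
  if (beta <= 0) stop("beta must be > 0")
  if (c_mode == "fixed" && (is.null(c_value) || c_value <= 0))
    stop("c_value must be a positive number when c_mode = 'fixed'")
  structure(list(kernel_px = as.integer(kernel_px), beta = beta,
                 c_mode = c_mode, c_value = c_value,
                 bright_on_dark = isTRUE(bright_on_dark)),
            class = "vesselness_params")
}

#' Eigenvalues of the scale-normalized Gaussian Hessian
#'
#' The image is smoothed with a sampled Gaussian of the given sigma, the
#' Hessian is assembled from central finite differences of the smoothed
#' field, scale-normalized by sigma^2, and eigendecomposed in closed form.
#' Eigenvalues are ordered by magnitude, |lambda1| <= |lambda2|.
#'
#' @param image an `intensity_image` or matrix.
#' @param sigma Gaussian scale in pixels (> 0).
#' @return list with matrices `l1`, `l2` and the Hessian components
#'   `hxx`, `hxy`, `hyy`.
#' @export
hessian_eigenvalues <- function(image, sigma) {
  stopifnot(sigma > 0)
  m <- if (inherits(image, "intensity_image")) image$pixels else image
  # anchor at zero so large additive offsets cannot leak rounding noise
  # into the second differences (offset invariance to ~1e-12)
  m <- m - min(m)
  s <- gaussian_smooth(m, sigma)
  nr <- nrow(s); nc <- ncol(s)
  # clamped-edge shifts; the 2*sigma border is flagged unreliable downstream
  up    <- s[c(1, seq_len(nr - 1)), ]
  down  <- s[c(seq_len(nr - 1) + 1, nr), ]
  left  <- s[, c(1, seq_len(nc - 1))]
  right <- s[, c(seq_len(nc - 1) + 1, nc)]
  ul <- s[c(1, seq_len(nr - 1)), c(1, seq_len(nc - 1))]
  ur <- s[c(1, seq_len(nr - 1)), c(seq_len(nc - 1) + 1, nc)]
  dl <- s[c(seq_len(nr - 1) + 1, nr), c(1, seq_len(nc - 1))]
  dr <- s[c(seq_len(nr - 1) + 1, nr), c(seq_len(nc - 1) + 1, nc)]
  g <- sigma^2   # gamma-normalization so responses compare across scales
  hyy <- g * (up + down - 2 * s)       # second derivative along rows
  hxx <- g * (left + right - 2 * s)    # second derivative along columns
  hxy <- g * (dr + ul - dl - ur) / 4
  tr2 <- (hxx + hyy) / 2
  disc <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
  a <- tr2 + disc
  b <- tr2 - disc
  swap <- abs(a) > abs(b)
  l1 <- ifelse(swap, b, a)
  l2 <- ifelse(swap, a, b)
  list(l1 = l1, l2 = l2, hxx = hxx, hxy = hxy, hyy = hyy)
}

#' Single-scale Frangi vesselness
#'
#' Standard 2-D vesselness at one scale: zero where lambda2 > 0 (for
#' bright vessels on a dark background), otherwise
#' `exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))` with
#' `Rb = lambda1 / lambda2` (blobness) and `S = sqrt(l1^2 + l2^2)`
#' (structureness, the Hessian Frobenius norm).
#'
#' @param image an `intensity_image` or matrix.
#' @param params a [vesselness_params()] object.
#' @return list of class `vesselness_image` with `values` in `[0, 1]`,
#'   the `params`, and `border_px`, the width of the boundary band
#'   (2 sigma) where responses are unreliable.
#' @export
frangi <- function(image, params = vesselness_params()) {
  sigma <- params$kernel_px / 2
  eig <- hessian_eigenvalues(image, sigma)
  l1 <- eig$l1; l2 <- eig$l2
  S <- sqrt(l1^2 + l2^2)
  border <- ceiling(2 * sigma)
  cc <- if (params$c_mode == "adaptive") {
    # the boundary band carries padding artifacts; keep it out of the
    # normalization so one bad border pixel cannot rescale the image
    nr <- nrow(S); nc <- ncol(S)
    Si <- if (nr > 2 * border + 2 && nc > 2 * border + 2)
      S[(border + 1):(nr - border), (border + 1):(nc - border)] else S
    cmax <- max(Si)
    if (cmax == 0) 1 else cmax / 2
  } else params$c_value
  rb2 <- ifelse(l2 == 0, 0, (l1 / l2)^2)
  v <- exp(-rb2 / (2 * params$beta^2)) * (1 - exp(-S^2 / (2 * cc^2)))
  if (params$bright_on_dark) {
    v[l2 > 0] <- 0
  } else {
    v[l2 < 0] <- 0
  }
  v[l2 == 0] <- 0
  structure(list(values = v, params = params, border_px = border),
            class = "vesselness_image")
}

#' @export
print.vesselness_image <- function(x, ...) {
  cat(sprintf("<vesselness_image> %d x %d, kernel %d px, max %.3f\n",
              nrow(x$values), ncol(x$values), x$params$kernel_px,
              max(x$values)))
  invisible(x)
}
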