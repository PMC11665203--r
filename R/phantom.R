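# Synthetic PAM/CFM phantoms with exact ground truth.
#
# The vessel phantom emulates what the analysis assumes about cortical
# angiograms: branching trees spanning capillaries (~5 um) to pial
# vessels (> 100 um), Gaussian optical blur (ESF FWHM ~ 8 um), additive
# background noise, and occasional diffuse hemorrhage blobs that are
# bright but not tube-like.  Geometry and noise draw from independent
# sub-streams of one master seed, so the vessel layout is reproducible
# independent of the noise realization.

`%||%` <- function(a, b) if (is.null(a)) b else a

.derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483629L)
}

#' Vessel phantom specification
#'
#' Defaults state the imaging geometry of the emulated instrument
#' (2 x 2 mm field, 512 x 512 px, PSF FWHM 8 um) and a vascular scene
#' spanning the full diameter range the analysis is built for.
#'
#' @param field_size_um field of view, micrometres (square).
#' @param grid_px image side in pixels.
#' @param n_trees number of vascular trees seeded at the field edges.
#' @param root_diameter_um trunk diameter of each tree.
#' @param branch_decay child diameter = parent x decay, in (0, 1].
#' @param capillary_fraction target fraction of total centerline length
#'   with diameter < 10 um; extra capillary twigs are grown until reached.
#' @param psf_fwhm_um Gaussian optical blur, FWHM in micrometres.
#' @param noise_sigma additive Gaussian noise s.d. (intensity units).
#' @param noise_corr_um correlation length (FWHM) of the background
#'   noise.  Envelope-projected acoustic noise is bandlimited by the
#'   detection chain, so the default matches the optical PSF; set 0 for
#'   white noise.  The marginal s.d. is `noise_sigma` either way.
#' @param background_level constant background (intensity units).
#' @param vessel_amplitude vessel interior intensity above zero.
#' @param n_hemorrhages number of diffuse hemorrhage disks.
#' @param hemorrhage_radius_um hemorrhage disk radius (much larger than a
#'   vessel diameter).
#' @param hemorrhage_contrast hemorrhage intensity as a fraction of
#'   `vessel_amplitude` (diffuse, low contrast).
#' @param min_diameter_um branching stops below this diameter.
#' @param seed master seed; geometry and noise use derived sub-streams.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(field_size_um = 2000, grid_px = 512L,
                         n_trees = 6L, root_diameter_um = 110,
                         branch_decay = 0.6, capillary_fraction = 0.3,
                         psf_fwhm_um = 8, noise_sigma = 0.03,
                         noise_corr_um = 8,
                         background_level = 0.1, vessel_amplitude = 1,
                         n_hemorrhages = 0L, hemorrhage_radius_um = 150,
                         hemorrhage_contrast = 0.3,
                         min_diameter_um = 5, seed = 1L) {
  stopifnot(field_size_um > 0, grid_px >= 8, psf_fwhm_um >= 0,
            n_trees >= 0, n_hemorrhages >= 0, noise_sigma >= 0,
            background_level >= 0, branch_decay > 0, branch_decay <= 1,
            capillary_fraction >= 0, capillary_fraction < 1,
            min_diameter_um > 0)
  structure(as.list(environment()), class = "phantom_spec")
}

.pitch <- function(spec) spec$field_size_um / spec$grid_px

# ---- geometry ------------------------------------------------------------

# grow one branch: smooth polyline from `pos` in direction `ang`,
# truncated at the field boundary; returns NULL if it exits immediately
.grow_branch <- function(pos, ang, diameter, spec, wiggle = 0.22) {
  L <- min(max(stats::runif(1, 5, 12) * diameter, 120), 650)
  step <- 40
  n_steps <- max(2L, ceiling(L / step))
  pts <- matrix(NA_real_, n_steps + 1L, 2L)
  pts[1L, ] <- pos
  lim <- spec$field_size_um
  for (k in seq_len(n_steps)) {
    ang <- ang + stats::rnorm(1, 0, wiggle)
    nxt <- pts[k, ] + step * c(cos(ang), sin(ang))
    if (any(nxt < 0) || any(nxt > lim)) {
      pts <- pts[seq_len(k), , drop = FALSE]
      break
    }
    pts[k + 1L, ] <- nxt
  }
  pts <- pts[!is.na(pts[, 1]), , drop = FALSE]
  if (nrow(pts) < 2L) return(NULL)
  # smooth spline through the waypoints, resampled at ~2 um steps
  t0 <- seq_len(nrow(pts))
  nf <- max(8L, 20L * nrow(pts))
  tf <- seq(1, nrow(pts), length.out = nf)
  sx <- stats::spline(t0, pts[, 1], xout = tf)$y
  sy <- stats::spline(t0, pts[, 2], xout = tf)$y
  sx <- pmin(pmax(sx, 0), lim)
  sy <- pmin(pmax(sy, 0), lim)
  # vessels taper along their run; a continuous diameter distribution is
  # what real angiograms show (no discrete size classes)
  taper <- stats::runif(1, 0.78, 0.95)
  dias <- seq(diameter, diameter * taper, length.out = nf)
  list(points = cbind(x = sx, y = sy), diameter_um = mean(dias),
       diameters_um = dias, end_diameter_um = dias[nf],
       end = c(sx[nf], sy[nf]), end_angle = atan2(sy[nf] - sy[nf - 1],
                                                  sx[nf] - sx[nf - 1]))
}

.polyline_length <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
}

#' Random branching vessel geometry for a phantom spec
#'
#' Grows `n_trees` binary branching trees from the field edges (child
#' diameter = parent x `branch_decay`, stopping below `min_diameter_um`),
#' then adds capillary twigs until `capillary_fraction` of the total
#' centerline length has diameter < 10 um.  Uses only the geometry
#' sub-stream of the master seed.
#'
#' @param spec a [phantom_spec()].
#' @return list of branches, each `list(points, diameter_um)` with
#'   `points` an n x 2 matrix of (x, y) in micrometres.
#' @export
vessel_branches <- function(spec) {
  set.seed(.derive_seed(spec$seed, 1L))
  lim <- spec$field_size_um
  branches <- list()
  grow_tree <- function(pos, ang, d, depth) {
    br <- .grow_branch(pos, ang, d, spec)
    if (is.null(br)) return(invisible(NULL))
    branches[[length(branches) + 1L]] <<-
      br[c("points", "diameter_um", "diameters_um")]
    child <- br$end_diameter_um * spec$branch_decay *
      stats::runif(2, 0.9, 1.1)
    if (depth < 8L) {
      for (s in 1:2) {
        if (child[s] >= spec$min_diameter_um) {
          dev <- stats::runif(1, 0.35, 0.9) * (if (s == 1) 1 else -1)
          cang <- br$end_angle + dev
          # sprout at the parent's surface, not its axis, so the child's
          # recorded centerline is not buried inside the parent tube
          cpos <- br$end + (br$end_diameter_um / 2) * c(cos(cang), sin(cang))
          grow_tree(cpos, cang, child[s], depth + 1L)
        }
      }
    }
    invisible(NULL)
  }
  if (spec$n_trees > 0) {
    for (t in seq_len(spec$n_trees)) {
      side <- sample.int(4L, 1L)
      u <- stats::runif(1, 0.1, 0.9) * lim
      pos <- switch(side, c(0, u), c(lim, u), c(u, 0), c(u, lim))
      ang <- switch(side, 0, pi, pi / 2, -pi / 2) +
        stats::runif(1, -0.5, 0.5)
      grow_tree(pos, ang, spec$root_diameter_um *
                  stats::runif(1, 0.85, 1.15), 1L)
    }
    # top up capillary length to the requested fraction
    cap_frac <- function() {
      len <- vapply(branches, function(b) .polyline_length(b$points),
                    numeric(1))
      d <- vapply(branches, function(b) b$diameter_um, numeric(1))
      if (sum(len) == 0) 0 else sum(len[d < 10]) / sum(len)
    }
    # capillaries branch off arterioles/venules, not the big pial trunks
    hosts <- function() {
      d <- vapply(branches, function(b) b$diameter_um, numeric(1))
      h <- which(d >= 10 & d <= 40)
      if (length(h) == 0L) which(d >= 10) else h
    }
    it <- 0L
    while (cap_frac() < spec$capillary_fraction && it < 300L) {
      it <- it + 1L
      h <- hosts()
      if (length(h) == 0L) break
      b <- branches[[h[sample.int(length(h), 1L)]]]
      at <- sample.int(nrow(b$points), 1L)
      tang <- stats::runif(1, -pi, pi)
      tpos <- b$points[at, ] + (b$diameter_um / 2) * c(cos(tang), sin(tang))
      if (any(tpos < 0) || any(tpos > lim)) next
      tw <- .grow_branch(tpos, tang, stats::runif(1, 5, 9), spec,
                         wiggle = 0.35)
      if (!is.null(tw))
        branches[[length(branches) + 1L]] <-
          tw[c("points", "diameter_um", "diameters_um")]
    }
  }
  branches
}

# ---- rendering -----------------------------------------------------------

.stamp_disks <- function(canvas, rows, cols, r_px, value, op = "max") {
  nr <- nrow(canvas); nc <- ncol(canvas)
  R <- ceiling(r_px)
  og <- expand.grid(di = -R:R, dj = -R:R)
  og <- og[og$di^2 + og$dj^2 <= r_px^2, , drop = FALSE]
  m <- nrow(og)
  rr <- rep(rows, each = m) + og$di
  cc <- rep(cols, each = m) + og$dj
  ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  lin <- (cc[ok] - 1L) * nr + rr[ok]
  lin <- unique(lin)
  if (is.logical(canvas)) canvas[lin] <- TRUE
  else if (op == "max") canvas[lin] <- pmax(canvas[lin], value)
  else canvas[lin] <- value
  canvas
}

.um_to_px <- function(u, pitch) as.integer(round(u / pitch)) + 1L

#' Render a vessel phantom from explicit branch geometry
#'
#' Shared by the random generator and by tests that construct exact
#' geometry.  Interior intensity is constant per vessel; the scene is
#' convolved with a Gaussian PSF of FWHM `psf_fwhm_um` and Gaussian noise
#' is added on top of `background_level`.  The truth records the
#' unblurred mask and exact per-bin centerline lengths.
#'
#' @param branches list of `list(points, diameter_um)` (micrometres).
#' @param spec a [phantom_spec()] (rendering parameters + seed).
#' @param bins_um diameter bin edges for the truth lengths.
#' @return list with `image` (an `intensity_image`) and `truth` (class
#'   `phantom_truth`: `mask`, `centerlines`, `per_bin_length_um`,
#'   `total_length_um`, `plaque_xy`, `hemorrhage_mask`).
#' @export
render_phantom <- function(branches, spec, bins_um = default_bins_um()) {
  pitch <- .pitch(spec)
  small <- vapply(branches, function(b) b$diameter_um, numeric(1))
  if (length(small) && min(small) < pitch)
    stop(sprintf(
      "pixel pitch %.3f um exceeds smallest requested vessel diameter %.3f um: unrenderable",
      pitch, min(small)))
  n <- spec$grid_px
  mask <- matrix(FALSE, n, n)
  amp <- matrix(0, n, n)
  set.seed(.derive_seed(spec$seed, 3L))  # per-vessel amplitude stream
  for (b in branches) {
    p <- b$points
    dd <- b$diameters_um %||% rep(b$diameter_um, nrow(p))
    # resample to ~pitch/2 steps so disk stamping leaves no gaps
    L <- .polyline_length(p)
    if (L > 0) {
      s <- c(0, cumsum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)))
      ns <- max(2L, ceiling(L / (pitch / 2)))
      sq <- seq(0, L, length.out = ns)
      px <- stats::approx(s, p[, 1], xout = sq, ties = "ordered")$y
      py <- stats::approx(s, p[, 2], xout = sq, ties = "ordered")$y
      pd <- stats::approx(s, dd, xout = sq, ties = "ordered")$y
    } else {
      px <- p[1, 1]; py <- p[1, 2]; pd <- dd[1]
    }
    rows <- .um_to_px(py, pitch); cols <- .um_to_px(px, pitch)
    a <- spec$vessel_amplitude * stats::runif(1, 0.85, 1)
    # group samples by quarter-pixel radius so tapered tubes render with
    # a smoothly shrinking cross-section
    r_px <- (pd / 2) / pitch
    rq <- round(r_px * 4) / 4
    for (r in unique(rq)) {
      sel <- rq == r
      mask <- .stamp_disks(mask, rows[sel], cols[sel], r, TRUE)
      amp <- .stamp_disks(amp, rows[sel], cols[sel], r, a)
    }
  }
  hem <- matrix(FALSE, n, n)
  if (spec$n_hemorrhages > 0) {
    set.seed(.derive_seed(spec$seed, 4L))
    r_px <- spec$hemorrhage_radius_um / pitch
    margin <- spec$hemorrhage_radius_um
    for (k in seq_len(spec$n_hemorrhages)) {
      cx <- stats::runif(1, margin, spec$field_size_um - margin)
      cy <- stats::runif(1, margin, spec$field_size_um - margin)
      hem <- .stamp_disks(hem, .um_to_px(cy, pitch), .um_to_px(cx, pitch),
                          r_px, TRUE)
    }
    hval <- spec$hemorrhage_contrast * spec$vessel_amplitude
    amp[hem & !mask] <- pmax(amp[hem & !mask], hval)
  }
  scene <- amp
  if (spec$psf_fwhm_um > 0) {
    sigma_px <- spec$psf_fwhm_um / (2 * sqrt(2 * log(2))) / pitch
    scene <- gaussian_smooth(scene, sigma_px)
  }
  set.seed(.derive_seed(spec$seed, 2L))  # noise stream
  noise <- matrix(stats::rnorm(n * n), n, n)
  if (spec$noise_corr_um > 0) {
    s_n <- spec$noise_corr_um / (2 * sqrt(2 * log(2))) / pitch
    noise <- gaussian_smooth(noise, s_n)
    noise <- noise / stats::sd(noise)
  }
  img <- pmax(spec$background_level + scene + spec$noise_sigma * noise, 0)
  lens <- vapply(branches, function(b) .polyline_length(b$points),
                 numeric(1))
  dias <- vapply(branches, function(b) b$diameter_um, numeric(1))
  nb <- length(bins_um) - 1L
  per_bin <- stats::setNames(numeric(nb), .bin_labels(bins_um))
  if (length(dias)) {
    k <- findInterval(dias, bins_um, rightmost.closed = FALSE,
                      all.inside = TRUE)
    for (bb in seq_len(nb)) per_bin[bb] <- sum(lens[k == bb])
  }
  truth <- structure(list(mask = mask, centerlines = branches,
                          per_bin_length_um = per_bin,
                          total_length_um = sum(lens),
                          bins_um = bins_um,
                          plaque_xy = matrix(numeric(0), 0, 2),
                          hemorrhage_mask = hem),
                     class = "phantom_truth")
  list(image = intensity_image(img, pitch, "PAM",
                               provenance = "vessel phantom"),
       truth = truth)
}

#' Generate a synthetic PAM vessel phantom
#'
#' Random branching geometry ([vessel_branches()]) rendered with
#' [render_phantom()].  Deterministic for a fixed `spec$seed`; geometry
#' and noise come from independent sub-streams, so the layout is
#' identical across noise realizations.
#'
#' @inheritParams render_phantom
#' @param branches optional explicit geometry overriding the random trees.
#' @return list with `image` and `truth` (see [render_phantom()]).
#' @export
generate_vessel_phantom <- function(spec = phantom_spec(), branches = NULL,
                                    bins_um = default_bins_um()) {
  render_phantom(branches %||% vessel_branches(spec), spec, bins_um)
}

#' Straight-tube branch geometry
#'
#' One straight vessel of given length, diameter and orientation,
#' centered in the field: exact geometry for morphometry tests.
#'
#' @param length_um,diameter_um tube dimensions.
#' @param angle_deg orientation (0 = horizontal).
#' @param field_size_um field of view.
#' @export
straight_vessel <- function(length_um, diameter_um, angle_deg = 0,
                            field_size_um = 2000) {
  c0 <- field_size_um / 2
  a <- angle_deg * pi / 180
  t <- seq(-length_um / 2, length_um / 2, length.out = 200L)
  list(list(points = cbind(x = c0 + t * cos(a), y = c0 + t * sin(a)),
            diameter_um = diameter_um))
}

# ---- plaque phantom ------------------------------------------------------

#' Generate a synthetic CFM plaque phantom
#'
#' `n_plaques` Gaussian bright spots with pairwise separation at least
#' `3 * spot_fwhm_um`, placed uniformly at random over a diffuse dye
#' background -- either flat or contaminated by low-contrast vessels
#' (`"vessel_bleed"`), emulating intravascular dye that has not yet
#' cleared.
#'
#' @param n_plaques number of spots (>= 0).
#' @param spot_fwhm_um spot FWHM in micrometres (> 0).
#' @param background_model `"flat"` or `"vessel_bleed"`.
#' @param seed master seed.
#' @param field_size_um,grid_px imaging geometry.
#' @return list with `image` (CFM `intensity_image`) and `truth`
#'   (`phantom_truth` whose `plaque_xy` holds the exact spot centers in
#'   micrometres).
#' @export
generate_plaque_phantom <- function(n_plaques, spot_fwhm_um = 15,
                                    background_model = c("flat",
                                                         "vessel_bleed"),
                                    seed = 1L, field_size_um = 2000,
                                    grid_px = 512L) {
  background_model <- match.arg(background_model)
  stopifnot(n_plaques >= 0, spot_fwhm_um > 0)
  pitch <- field_size_um / grid_px
  sep <- 3 * spot_fwhm_um
  margin <- 2 * spot_fwhm_um
  usable <- (field_size_um - 2 * margin)^2
  if (n_plaques > 0 && n_plaques * pi * (sep / 2)^2 > 0.55 * usable)
    stop(sprintf(
      "cannot place %d spots with pairwise separation %.0f um in a %.0f um field",
      n_plaques, sep, field_size_um))
  set.seed(.derive_seed(seed, 11L))
  xy <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  while (nrow(xy) < n_plaques) {
    attempts <- attempts + 1L
    if (attempts > 400L * max(n_plaques, 1L))
      stop("failed to place all spots at the requested separation")
    cand <- stats::runif(2, margin, field_size_um - margin)
    if (nrow(xy) == 0 ||
        min(sqrt((xy[, 1] - cand[1])^2 + (xy[, 2] - cand[2])^2)) >= sep)
      xy <- rbind(xy, cand)
  }
  n <- grid_px
  bg <- matrix(0.2, n, n)
  if (background_model == "vessel_bleed") {
    vs <- phantom_spec(field_size_um = field_size_um, grid_px = grid_px,
                       n_trees = 4L, root_diameter_um = 60,
                       capillary_fraction = 0.2, vessel_amplitude = 0.35,
                       noise_sigma = 0, background_level = 0,
                       seed = .derive_seed(seed, 12L))
    bg <- bg + generate_vessel_phantom(vs)$image$pixels
    # slowly-varying diffuse dye field
    set.seed(.derive_seed(seed, 13L))
    dif <- gaussian_smooth(matrix(stats::rnorm(n * n), n, n), 25)
    bg <- bg + 0.15 * (dif - min(dif)) / max(1e-12, diff(range(dif)))
  }
  img <- bg
  if (n_plaques > 0) {
    set.seed(.derive_seed(seed, 14L))
    amps <- stats::runif(n_plaques, 0.7, 1)
    s_px <- spot_fwhm_um / (2 * sqrt(2 * log(2))) / pitch
    R <- ceiling(4 * s_px)
    og <- expand.grid(di = -R:R, dj = -R:R)
    g <- exp(-(og$di^2 + og$dj^2) / (2 * s_px^2))
    for (k in seq_len(n_plaques)) {
      r0 <- .um_to_px(xy[k, 2], pitch); c0 <- .um_to_px(xy[k, 1], pitch)
      rr <- r0 + og$di; cc <- c0 + og$dj
      ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
      lin <- (cc[ok] - 1L) * n + rr[ok]
      img[lin] <- img[lin] + amps[k] * g[ok]
    }
  }
  set.seed(.derive_seed(seed, 15L))
  img <- pmax(img + matrix(stats::rnorm(n * n, 0, 0.02), n, n), 0)
  colnames(xy) <- c("x_um", "y_um")
  truth <- structure(list(mask = NULL, centerlines = list(),
                          per_bin_length_um = stats::setNames(
                            numeric(length(default_bins_um()) - 1L),
                            .bin_labels(default_bins_um())),
                          total_length_um = 0, bins_um = default_bins_um(),
                          plaque_xy = xy, hemorrhage_mask = NULL),
                     class = "phantom_truth")
  list(image = intensity_image(img, pitch, "CFM",
                               provenance = "plaque phantom"),
       truth = truth)
}

# ---- cohorts -------------------------------------------------------------

#' Cohort design for simulation studies
#'
#' Emulates a two-group imaging study (e.g. Alzheimer's-model vs
#' wild-type mice): per-group multipliers scale the expected true vessel
#' length in each diameter bin, and a plaque density sets the expected
#' spot count per mm^2.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param groups list of `list(label, vld_multiplier_per_bin,
#'   plaque_density_per_mm2)`; multipliers are recycled across the
#'   diameter bins and must be > 0.
#' @param seed master seed.
#' @export
cohort_spec <- function(n_per_group = 5L,
                        groups = list(
                          list(label = "WT",
                               vld_multiplier_per_bin = 1,
                               plaque_density_per_mm2 = 1),
                          list(label = "AD",
                               vld_multiplier_per_bin =
                                 c(0.85, 0.8, 1, 1, 1, 1),
                               plaque_density_per_mm2 = 8)),
                        seed = 1L) {
  stopifnot(n_per_group >= 2, length(groups) >= 1)
  for (g in groups) {
    stopifnot(!is.null(g$label), all(g$vld_multiplier_per_bin > 0),
              g$plaque_density_per_mm2 >= 0)
  }
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 seed = seed), class = "cohort_spec")
}

# thin (m < 1) or replicate-with-jitter (m > 1) branches per diameter bin
.apply_multipliers <- function(branches, mult, bins_um, field_size_um) {
  if (length(branches) == 0L) return(branches)
  mult <- rep_len(mult, length(bins_um) - 1L)
  d <- vapply(branches, function(b) b$diameter_um, numeric(1))
  k <- findInterval(d, bins_um, rightmost.closed = FALSE, all.inside = TRUE)
  out <- list()
  for (i in seq_along(branches)) {
    m <- mult[k[i]]
    keep_p <- min(m, 1)
    if (stats::runif(1) <= keep_p) out[[length(out) + 1L]] <- branches[[i]]
    extra <- m - 1
    while (extra > 0) {
      if (stats::runif(1) <= min(extra, 1)) {
        b <- branches[[i]]
        shift <- stats::runif(2, -150, 150)
        p <- b$points
        p[, 1] <- pmin(pmax(p[, 1] + shift[1], 0), field_size_um)
        p[, 2] <- pmin(pmax(p[, 2] + shift[2], 0), field_size_um)
        b$points <- p
        out[[length(out) + 1L]] <- b
      }
      extra <- extra - 1
    }
  }
  out
}

#' Simulate an imaging cohort
#'
#' One phantom per subject; each group's branch set is thinned (or
#' augmented) per diameter bin by its `vld_multiplier_per_bin`, so the
#' expected true per-bin VLD scales by the multiplier.  Plaque
#' coordinates are drawn with per-subject counts ~
#' Poisson(density x area).  With `render = FALSE` only the geometry and
#' ground truth are produced (no image), which makes large Monte-Carlo
#' designs cheap.
#'
#' @param cohort a [cohort_spec()].
#' @param base a [phantom_spec()] giving the common scene parameters.
#' @param render render PAM images (`TRUE`) or return truth only.
#' @return list of subject records: `label`, `subject`, `image` (or
#'   `NULL`), `truth`.
#' @export
simulate_cohort <- function(cohort, base = phantom_spec(), render = TRUE) {
  out <- list()
  area <- (base$field_size_um / 1000)^2
  sidx <- 0L
  for (gi in seq_along(cohort$groups)) {
    g <- cohort$groups[[gi]]
    for (s in seq_len(cohort$n_per_group)) {
      sidx <- sidx + 1L
      sseed <- .derive_seed(cohort$seed, 100L * gi + s)
      spec <- base
      spec$seed <- sseed
      br <- vessel_branches(spec)
      set.seed(.derive_seed(sseed, 21L))
      br <- .apply_multipliers(br, g$vld_multiplier_per_bin,
                               default_bins_um(), base$field_size_um)
      if (render) {
        ph <- render_phantom(br, spec)
      } else {
        lens <- vapply(br, function(b) .polyline_length(b$points),
                       numeric(1))
        dias <- vapply(br, function(b) b$diameter_um, numeric(1))
        bins <- default_bins_um()
        per_bin <- stats::setNames(numeric(length(bins) - 1L),
                                   .bin_labels(bins))
        if (length(dias)) {
          kk <- findInterval(dias, bins, rightmost.closed = FALSE,
                             all.inside = TRUE)
          for (bb in seq_along(per_bin))
            per_bin[bb] <- sum(lens[kk == bb])
        }
        ph <- list(image = NULL,
                   truth = structure(
                     list(mask = NULL, centerlines = br,
                          per_bin_length_um = per_bin,
                          total_length_um = sum(lens), bins_um = bins,
                          plaque_xy = matrix(numeric(0), 0, 2),
                          hemorrhage_mask = NULL),
                     class = "phantom_truth"))
      }
      set.seed(.derive_seed(sseed, 22L))
      n_plq <- stats::rpois(1, g$plaque_density_per_mm2 * area)
      if (n_plq > 0) {
        xy <- cbind(x_um = stats::runif(n_plq, 0, base$field_size_um),
                    y_um = stats::runif(n_plq, 0, base$field_size_um))
        ph$truth$plaque_xy <- xy
      }
      out[[sidx]] <- list(label = g$label, subject = sprintf(
        "%s_%02d", g$label, s), image = ph$image, truth = ph$truth)
    }
  }
  out
}

#' Per-bin true VLD of a phantom truth
#'
#' Ground-truth vessel length density: exact centerline length per bin
#' divided by the field area.
#'
#' @param truth a `phantom_truth`.
#' @param area_mm2 field area in mm^2.
#' @export
truth_vld <- function(truth, area_mm2) {
  truth$per_bin_length_um / 1000 / area_mm2
}
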