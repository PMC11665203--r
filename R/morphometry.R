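# Skeleton-based morphometry: centerline extraction, the vessel segment
# graph, per-segment diameters, and size-binned vessel length density.

#' Default diameter bin edges (micrometres)
#'
#' `[0,10), [10,20), [20,30), [30,40), [40,50), [50,Inf)`; a diameter
#' falling exactly on an edge goes to the upper bin.
#' @export
default_bins_um <- function() c(0, 10, 20, 30, 40, 50, Inf)

.bin_labels <- function(bins) {
  n <- length(bins) - 1L
  lab <- character(n)
  for (k in seq_len(n)) {
    lab[k] <- if (is.infinite(bins[k + 1])) sprintf(">%g", bins[k])
    else sprintf("%g-%g", bins[k], bins[k + 1])
  }
  lab
}

#' Skeletonize a binary vessel mask
#'
#' Topology-preserving Zhang-Suen thinning; the skeleton is a 1-px-wide
#' subset of the mask.
#'
#' @param mask a `binary_vessel_mask` or logical matrix.
#' @return logical matrix.
#' @export
skeletonize_mask <- function(mask) {
  m <- .as_mask(mask)
  if (!any(m)) return(m)
  cpp_thin(m)
}

# adjacency of skeleton pixels; drops diagonal links that shortcut an
# existing orthogonal connection (avoids spurious triangles)
.skeleton_adjacency <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  idx <- which(skel)
  n <- length(idx)
  pid <- integer(nr * nc)
  pid[idx] <- seq_len(n)
  ri <- ((idx - 1L) %% nr) + 1L
  ci <- ((idx - 1L) %/% nr) + 1L
  off <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
               c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  edges_from <- integer(0); edges_to <- integer(0); diag_e <- logical(0)
  for (k in seq_len(8L)) {
    ri2 <- ri + off[k, 1]; ci2 <- ci + off[k, 2]
    ok <- ri2 >= 1L & ri2 <= nr & ci2 >= 1L & ci2 <= nc
    tgt <- integer(n)
    tgt[ok] <- pid[(ci2[ok] - 1L) * nr + ri2[ok]]
    hit <- ok & tgt > 0L
    if (k >= 5L) {
      # diagonal: skip when either shared orthogonal neighbour is skeleton
      o1 <- hit
      o1[hit] <- skel[(ci[hit] - 1L) * nr + ri2[hit]] |
                 skel[(ci2[hit] - 1L) * nr + ri[hit]]
      hit <- hit & !o1
    }
    edges_from <- c(edges_from, which(hit))
    edges_to <- c(edges_to, tgt[hit])
    diag_e <- c(diag_e, rep(k >= 5L, sum(hit)))
  }
  adj <- vector("list", n)
  sp <- split(edges_to, edges_from)
  adj[as.integer(names(sp))] <- sp
  list(adj = adj, ri = ri, ci = ci, n = n)
}

# polyline length in pixels: chords sampled every `chord` path pixels,
# endpoints always included; damps the +/-0.5 px staircase jitter of the
# discrete skeleton without shortcutting real curvature
.path_length_px <- function(ri, ci, chord = 12L) {
  np <- length(ri)
  if (np < 2L) return(0)
  keep <- unique(c(seq(1L, np, by = chord), np))
  sum(sqrt(diff(ri[keep])^2 + diff(ci[keep])^2))
}

#' Build the vessel segment graph from a skeleton
#'
#' Splits the skeleton at branchpoints (pixels with three or more
#' skeleton neighbours; adjacent branch pixels are merged into one
#' junction node), prunes terminal spurs shorter than `prune_px` pixels
#' (thinning artifacts), merges pass-through junctions left behind by
#' pruning, and measures each remaining segment:
#' length as a chord-resampled polyline length in micrometres, diameter
#' as the path mean of `(2 * EDT - 1) * pitch` where EDT is the exact
#' Euclidean distance transform of the mask at the skeleton pixel.
#'
#' @param skeleton logical matrix from [skeletonize_mask()].
#' @param mask the `binary_vessel_mask` (or logical matrix) the skeleton
#'   came from; used for the distance-transform diameters.
#' @param pixel_pitch_um pixel pitch in micrometres.
#' @param prune_px terminal spurs shorter than this many pixels are
#'   discarded (default 10).
#' @return an object of class `vessel_graph`: list with `segments` (a
#'   data.frame: id, length_um, mean_diameter_um, n_px), `paths` (list of
#'   2-column row/col matrices), `n_nodes` and `image_area_mm2`.
#' @export
build_graph <- function(skeleton, mask, pixel_pitch_um, prune_px = 10L) {
  m <- .as_mask(mask)
  stopifnot(identical(dim(skeleton), dim(m)))
  empty <- function() structure(
    list(segments = data.frame(id = integer(0), length_um = numeric(0),
                               mean_diameter_um = numeric(0),
                               n_px = integer(0)),
         paths = list(), n_nodes = 0L,
         image_area_mm2 = prod(dim(m)) * (pixel_pitch_um / 1000)^2,
         pixel_pitch_um = pixel_pitch_um),
    class = "vessel_graph")
  if (!any(skeleton)) return(empty())

  sk <- .skeleton_adjacency(skeleton)
  deg <- vapply(sk$adj, length, integer(1))
  is_node <- deg != 2L
  edt <- cpp_edt(m)
  # EDT reaches the nearest background pixel *center*; the boundary lies
  # half a pixel closer, so radius ~ EDT - 0.5 and diameter ~ 2 EDT - 1;
  # the skeleton sits up to half a pixel off-axis, giving back ~ +0.5
  dia_px <- pmax(2 * edt[cbind(sk$ri, sk$ci)] - 0.5, 0.8)

  # trace raw segments between node pixels
  segs <- list()
  used_dir <- new.env(hash = TRUE)   # "from:to" directed-edge marker
  mark <- function(a, b) assign(paste0(a, ":", b), TRUE, envir = used_dir)
  seen <- function(a, b) exists(paste0(a, ":", b), envir = used_dir)
  trace_from <- function(start, nxt) {
    path <- c(start, nxt)
    mark(start, nxt); mark(nxt, start)
    prev <- start; cur <- nxt
    while (!is_node[cur] && cur != start) {  # cur == start: closed loop
      nbrs <- sk$adj[[cur]]
      nxt2 <- nbrs[nbrs != prev]
      if (length(nxt2) == 0L) break          # dead end (shouldn't happen)
      nxt2 <- nxt2[1L]
      mark(cur, nxt2); mark(nxt2, cur)
      path <- c(path, nxt2)
      prev <- cur; cur <- nxt2
    }
    path
  }
  for (p in which(is_node)) {
    for (q in sk$adj[[p]]) {
      if (!seen(p, q)) segs[[length(segs) + 1L]] <- trace_from(p, q)
    }
  }
  # pure cycles with no node pixel
  visited_cycle <- logical(sk$n)
  for (p in which(!is_node)) {
    if (visited_cycle[p]) next
    nb <- sk$adj[[p]]
    if (length(nb) == 0L) next
    if (!seen(p, nb[1L])) {
      path <- trace_from(p, nb[1L])
      visited_cycle[path] <- TRUE
      segs[[length(segs) + 1L]] <- path
    }
  }

  # junction clusters: adjacent node pixels with deg >= 3 count as one node
  junc <- is_node & deg >= 3L
  cl <- integer(sk$n)
  nxt_cl <- 0L
  for (p in which(junc)) {
    if (cl[p] > 0L) next
    nxt_cl <- nxt_cl + 1L
    stack <- p
    while (length(stack)) {
      cur <- stack[[1L]]; stack <- stack[-1L]
      if (cl[cur] > 0L) next
      cl[cur] <- nxt_cl
      nb <- sk$adj[[cur]]
      stack <- c(stack, nb[junc[nb] & cl[nb] == 0L])
    }
  }
  end_cluster <- function(p) if (junc[p]) cl[p] else -p  # terminals unique

  seg_info <- function(path) {
    ri <- sk$ri[path]; ci <- sk$ci[path]
    np <- length(path)
    # the distance transform is inflated where a segment plugs into a
    # junction blob; average the diameter over the segment interior only
    d_all <- dia_px[path]
    trim <- min((np - 1L) %/% 4L, ceiling(stats::median(d_all)))
    core <- if (np > 2L * trim) (trim + 1L):(np - trim) else seq_len(np)
    list(len_px = .path_length_px(ri, ci),
         dia = mean(d_all[core]),
         a = end_cluster(path[1L]),
         b = end_cluster(path[length(path)]),
         path = path)
  }
  info <- lapply(segs, seg_info)

  # prune terminal spurs and isolated fragments shorter than prune_px:
  # both are thinning/speckle artifacts at this scale (a real unbranched
  # vessel is far longer than 10 px ~ 40 um)
  is_spur <- vapply(info, function(s) {
    free_a <- s$a < 0 && length(sk$adj[[abs(s$a)]]) <= 1L
    free_b <- s$b < 0 && length(sk$adj[[abs(s$b)]]) <= 1L
    (free_a || free_b) && s$len_px < prune_px
  }, logical(1))
  info <- info[!is_spur]

  # merge chains through junctions reduced to degree 2 by pruning;
  # one sweep merges every disjoint mergeable pair, repeated until stable
  NULL_seg <- list(drop = TRUE)
  repeat {
    if (length(info) < 2L) break
    ea <- vapply(info, function(s) s$a, numeric(1))
    eb <- vapply(info, function(s) s$b, numeric(1))
    ends <- c(ea, eb)
    seg_of <- rep(seq_along(info), 2L)
    pos <- split(seq_along(ends), ends)
    tab <- vapply(pos, length, integer(1))
    cand <- names(tab)[tab == 2 & as.numeric(names(tab)) > 0]
    if (length(cand) == 0L) break
    touched <- logical(length(info))
    merged_any <- FALSE
    for (nd_chr in cand) {
      at <- seg_of[pos[[nd_chr]]]
      if (length(unique(at)) != 2L) next   # self-loop at the node
      if (any(touched[at])) next
      nd <- as.numeric(nd_chr)
      s1 <- info[[at[1]]]; s2 <- info[[at[2]]]
      p1 <- if (s1$b == nd) s1$path else rev(s1$path)
      p2 <- if (s2$a == nd) s2$path else rev(s2$path)
      ns <- seg_info(c(p1, p2))
      ns$a <- if (s1$b == nd) s1$a else s1$b
      ns$b <- if (s2$a == nd) s2$b else s2$a
      info[[at[1]]] <- ns
      info[[at[2]]] <- NULL_seg
      touched[at] <- TRUE
      merged_any <- TRUE
    }
    info <- Filter(function(s) is.null(s$drop), info)
    if (!merged_any) break
  }

  info <- Filter(function(s) s$len_px > 0, info)
  if (length(info) == 0L) return(empty())

  # thinning retracts terminal tips inside rounded vessel ends; recover
  # the lost length by extending each free end along its tangent to the
  # mask boundary and subtracting the local radius
  tip_ext <- function(path, at_end) {
    pp <- if (at_end) rev(path) else path
    k <- min(6L, length(pp))
    if (k < 2L) return(0)
    tip <- pp[1L]; back <- pp[k]
    v <- c(sk$ri[tip] - sk$ri[back], sk$ci[tip] - sk$ci[back])
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(0)
    v <- v / nv
    r <- dia_px[tip] / 2
    lim <- r + 3
    step <- 0.5
    inside <- 0
    t <- step
    while (t <= lim) {
      ii <- as.integer(round(sk$ri[tip] + v[1] * t))
      jj <- as.integer(round(sk$ci[tip] + v[2] * t))
      if (ii < 1L || ii > nrow(m) || jj < 1L || jj > ncol(m) ||
          !m[ii, jj]) break
      inside <- t
      t <- t + step
    }
    max(0, min(inside - r, r))
  }
  for (i in seq_along(info)) {
    ext <- 0
    if (info[[i]]$a < 0) ext <- ext + tip_ext(info[[i]]$path, FALSE)
    if (info[[i]]$b < 0) ext <- ext + tip_ext(info[[i]]$path, TRUE)
    info[[i]]$len_px <- info[[i]]$len_px + ext
  }
  segments <- data.frame(
    id = seq_along(info),
    length_um = vapply(info, function(s) s$len_px, numeric(1)) *
      pixel_pitch_um,
    mean_diameter_um = vapply(info, function(s) s$dia, numeric(1)) *
      pixel_pitch_um,
    n_px = vapply(info, function(s) length(s$path), integer(1)))
  paths <- lapply(info, function(s) cbind(row = sk$ri[s$path],
                                          col = sk$ci[s$path]))
  all_ends <- c(vapply(info, function(s) s$a, numeric(1)),
                vapply(info, function(s) s$b, numeric(1)))
  structure(list(segments = segments, paths = paths,
                 n_nodes = length(unique(all_ends[all_ends > 0])),
                 image_area_mm2 = prod(dim(m)) * (pixel_pitch_um / 1000)^2,
                 pixel_pitch_um = pixel_pitch_um),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d segments, %d junctions, %.2f mm total on %.2f mm2\n",
              nrow(x$segments), x$n_nodes, sum(x$segments$length_um) / 1000,
              x$image_area_mm2))
  invisible(x)
}

#' Vessel length density per diameter bin
#'
#' Each segment's full centerline length is assigned to the diameter bin
#' containing its mean diameter (a diameter exactly on an edge goes to the
#' upper bin).  VLD is centerline length (mm) per image area (mm^2).
#'
#' @param graph a [build_graph()] result.
#' @param bins_um ordered bin edges, default [default_bins_um()].
#' @return object of class `vld_profile`: data.frame `profile` (bin,
#'   lo_um, hi_um, length_mm, vld), plus `total_vld` and `area_mm2`.
#' @export
vld_profile <- function(graph, bins_um = default_bins_um()) {
  stopifnot(graph$image_area_mm2 > 0, !is.unsorted(bins_um))
  nb <- length(bins_um) - 1L
  seg <- graph$segments
  len_mm <- numeric(nb)
  if (nrow(seg) > 0) {
    k <- findInterval(seg$mean_diameter_um, bins_um,
                      rightmost.closed = FALSE, all.inside = TRUE)
    for (b in seq_len(nb))
      len_mm[b] <- sum(seg$length_um[k == b]) / 1000
  }
  profile <- data.frame(bin = .bin_labels(bins_um),
                        lo_um = bins_um[-length(bins_um)],
                        hi_um = bins_um[-1],
                        length_mm = len_mm,
                        vld = len_mm / graph$image_area_mm2)
  structure(list(profile = profile,
                 total_vld = sum(profile$vld),
                 area_mm2 = graph$image_area_mm2,
                 bins_um = bins_um),
            class = "vld_profile")
}

#' @export
print.vld_profile <- function(x, ...) {
  cat(sprintf("<vld_profile> total %.3f mm/mm2 on %.2f mm2\n",
              x$total_vld, x$area_mm2))
  print(x$profile, row.names = FALSE)
  invisible(x)
}

#' Synthetic blurred edge image
#'
#' A vertical high-contrast step edge blurred by a Gaussian of the given
#' standard deviation, evaluated analytically at pixel centers.  Used to
#' exercise [measure_esf()].
#'
#' @param sigma_um Gaussian blur in micrometres (0 = ideal step).
#' @param pixel_pitch_um pixel pitch.
#' @param n image side in pixels.
#' @param lo,hi intensities left/right of the edge.
#' @export
synthetic_edge_image <- function(sigma_um, pixel_pitch_um = 2000 / 512,
                                 n = 64L, lo = 0.1, hi = 1.0) {
  x <- (seq_len(n) - 1) * pixel_pitch_um
  x0 <- stats::median(x)
  prof <- if (sigma_um <= 0) ifelse(x >= x0, hi, lo)
  else lo + (hi - lo) * stats::pnorm((x - x0) / sigma_um)
  intensity_image(matrix(rep(prof, each = n), nrow = n),
                  pixel_pitch_um, "PAM", provenance = "synthetic edge")
}

#' Measure the edge spread function width
#'
#' Averages intensity profiles perpendicular to a straight edge, takes
#' adjacent differences to obtain the line spread function at mid-pixel
#' positions, fits a Gaussian, removes the variance `h^2/12` contributed
#' by the differencing kernel (h = pixel pitch), and reports
#' `FWHM = 2 sqrt(2 ln 2) * sigma` in micrometres.  An ideal (unblurred)
#' step bottoms out at the one-pixel discretization floor.
#'
#' @param image an `intensity_image` containing one straight high-contrast
#'   edge.
#' @param edge list with `axis`: `"x"` if intensity varies along columns
#'   (vertical edge), `"y"` for a horizontal edge.
#' @return FWHM in micrometres.
#' @export
measure_esf <- function(image, edge = list(axis = "x")) {
  m <- image$pixels
  h <- image$pixel_pitch_um
  if (identical(edge$axis, "y")) m <- t(m)
  esf <- colMeans(m)
  rngm <- diff(range(esf))
  if (rngm == 0) stop("no edge found: flat profile")
  d <- diff(esf)
  if (sum(d) < 0) { esf <- rev(esf); d <- diff(esf) }
  if (min(d) < -0.05 * rngm)
    stop("non-monotone ESF: profile is not a single clean edge")
  x <- (seq_along(d) - 0.5) * h
  y <- pmax(d, 0)
  if (sum(y > 0.01 * max(y)) <= 2L) return(h)  # discretization floor
  w <- y / sum(y)
  mu <- sum(w * x)
  s2 <- sum(w * (x - mu)^2)
  fit <- tryCatch(
    stats::nls(y ~ A * exp(-(x - mu0)^2 / (2 * s0^2)),
               start = list(A = max(y), mu0 = mu, s0 = sqrt(s2)),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    s2 <- cf[["s0"]]^2
  }
  s2c <- s2 - h^2 / 12
  if (s2c <= (h / (2 * sqrt(2 * log(2))))^2 * 0.9^2)
    return(h)  # at or below the sampling floor
  2 * sqrt(2 * log(2)) * sqrt(s2c)
}
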