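# The (alpha, beta, gamma) particle-distribution landscape.
#
# Each particle's relative orientation is a point in a Cartesian coordinate
# system with the z-y-x angles as axes; binning all particles gives the
# conformational landscape. alpha and gamma are periodic (wrap at +/-180),
# beta is bounded in [-90, 90] by construction of the decomposition.

#' Compute per-particle relative orientations
#'
#' For every paired record, builds both body rotation matrices from their
#' refinement (z-y-z) Euler angles, forms the relative rotation
#' `t(R_mod) %*% R_cond` (or the transpose when `reference = "cond"`), and
#' decomposes it into z-y-x angles. Fully vectorised.
#'
#' @param pairs a `particle_pairs` table from [pair_refinements()].
#' @param canonicalize if `TRUE`, replace each orientation by its canonical
#'   C2 representative (see [canonicalize_orientation()]).
#' @param reference which body provides the fixed reference frame,
#'   `"mod"` (default) or `"cond"`.
#' @param axis_mod,axis_cond C2 axes used when `canonicalize = TRUE`.
#' @return data.frame with columns `particle_id`, `expansion_index`,
#'   `alpha`, `beta`, `gamma` (degrees).
#' @export
compute_orientations <- function(pairs, canonicalize = FALSE,
                                 reference = c("mod", "cond"),
                                 axis_mod = c(0, 0, 1), axis_cond = c(0, 0, 1)) {
  reference <- match.arg(reference)
  if (nrow(pairs) == 0) stop("empty particle table")
  em <- .zyz_elems(pairs$rot_mod, pairs$tilt_mod, pairs$psi_mod)
  ec <- .zyz_elems(pairs$rot_cond, pairs$tilt_cond, pairs$psi_cond)
  rel <- if (reference == "mod") .elems_mult(.elems_t(em), ec)
         else .elems_mult(.elems_t(ec), em)
  ang <- .elems_to_zyx(rel)
  if (canonicalize) {
    can <- t(apply(as.matrix(ang), 1, canonicalize_orientation,
                   axis_mod = axis_mod, axis_cond = axis_cond))
    ang <- data.frame(alpha = can[, 1], beta = can[, 2], gamma = can[, 3])
  }
  data.frame(particle_id = pairs$particle_id,
             expansion_index = pairs$expansion_index,
             ang, stringsAsFactors = FALSE)
}

# Bin index helpers. alpha/gamma live on (-180, 180], beta on [-90, 90].
.bin_wrap <- function(x, bw) {
  i <- ceiling((wrap180(x) + 180) / bw)
  n <- as.integer(round(360 / bw))
  i[i < 1L] <- n
  pmin(pmax(i, 1L), n)
}
.bin_clamp <- function(x, bw) {
  n <- as.integer(round(180 / bw))
  pmin(pmax(ceiling((x + 90) / bw), 1L), n)
}

# Separable 1-D Gaussian smoothing along one array dimension; circular wrap
# for periodic axes, zero padding for the clamped beta axis.
.smooth_dim <- function(arr, sigma, dim, circular) {
  if (sigma <= 0) return(arr)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  d <- dim(arr)
  perm <- c(dim, setdiff(seq_along(d), dim))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[dim])
  n <- d[dim]
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    if (circular) {
      src <- ((src - 1L) %% n) + 1L
      out <- out + k[j] * m[src, , drop = FALSE]
    } else {
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], , drop = FALSE]
    }
  }
  a2 <- array(out, dim = d[perm])
  aperm(a2, order(perm))
}

#' Build the conformational landscape grid
#'
#' 3D histogram of orientations over (alpha, beta, gamma) with periodic
#' wrapping of alpha and gamma and a clamped beta axis, followed by
#' separable Gaussian smoothing; the smoothed density is normalised to sum
#' to 1 so landscapes of different particle counts are directly comparable.
#'
#' @param orients orientation table from [compute_orientations()] (or any
#'   data.frame with `alpha`, `beta`, `gamma` in degrees).
#' @param bin_width bin width in degrees; must divide 180 (default 2).
#' @param smooth_sigma Gaussian smoothing width in bins (default 1; 0
#'   disables smoothing).
#' @return an object of class `landscape_grid`: list with bin `edges` and
#'   `mids` per axis, integer `counts` array, real `density` array (sums to
#'   1), `bin_width`, `smooth_sigma`, `n_particles`.
#' @export
build_landscape <- function(orients, bin_width = 2, smooth_sigma = 1) {
  if (nrow(orients) == 0) stop("cannot build a landscape from zero orientations")
  if (bin_width <= 0) stop("bin_width must be positive")
  if (abs(180 / bin_width - round(180 / bin_width)) > 1e-9)
    stop("bin_width must divide 180 degrees")
  na <- as.integer(round(360 / bin_width))
  nb <- as.integer(round(180 / bin_width))
  ia <- .bin_wrap(orients$alpha, bin_width)
  ib <- .bin_clamp(orients$beta, bin_width)
  ig <- .bin_wrap(orients$gamma, bin_width)
  lin <- (ig - 1L) * na * nb + (ib - 1L) * na + ia
  counts <- array(tabulate(lin, nbins = na * nb * na), dim = c(na, nb, na))
  dens <- counts
  dens <- .smooth_dim(dens, smooth_sigma, 1L, circular = TRUE)
  dens <- .smooth_dim(dens, smooth_sigma, 2L, circular = FALSE)
  dens <- .smooth_dim(dens, smooth_sigma, 3L, circular = TRUE)
  dens <- dens / sum(dens)
  edges_ag <- seq(-180, 180, by = bin_width)
  edges_b <- seq(-90, 90, by = bin_width)
  grid <- list(edges = list(alpha = edges_ag, beta = edges_b, gamma = edges_ag),
               mids = list(alpha = edges_ag[-1] - bin_width / 2,
                           beta = edges_b[-1] - bin_width / 2,
                           gamma = edges_ag[-1] - bin_width / 2),
               counts = counts, density = dens,
               bin_width = bin_width, smooth_sigma = smooth_sigma,
               n_particles = nrow(orients))
  class(grid) <- "landscape_grid"
  grid
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("landscape_grid: %d particles, %.3g deg bins (%d x %d x %d), smooth %.3g bins\n",
              x$n_particles, x$bin_width, dim(x$counts)[1], dim(x$counts)[2],
              dim(x$counts)[3], x$smooth_sigma))
  invisible(x)
}

#' Local landscape density at a coordinate
#'
#' Trilinear interpolation of the smoothed, normalised density at an
#' arbitrary (alpha, beta, gamma) coordinate, with periodic wrapping of
#' alpha and gamma and clamping of beta.
#'
#' @param grid a `landscape_grid`.
#' @param coord numeric `(alpha, beta, gamma)` in degrees.
#' @return a non-negative scalar density.
#' @export
local_density <- function(grid, coord) {
  bw <- grid$bin_width
  frac_wrap <- function(x) {
    na <- length(grid$mids$alpha)
    p <- (wrap180(x) + 180) / bw - 0.5     # 0-based position among centers
    i0 <- floor(p)
    list(lo = (i0 %% na) + 1L, hi = ((i0 + 1) %% na) + 1L, t = p - i0)
  }
  frac_clamp <- function(x) {
    nb <- length(grid$mids$beta)
    p <- (x + 90) / bw - 0.5
    i0 <- floor(p)
    lo <- pmin(pmax(i0 + 1, 1L), nb); hi <- pmin(pmax(i0 + 2, 1L), nb)
    list(lo = lo, hi = hi, t = pmin(pmax(p - i0, 0), 1))
  }
  fa <- frac_wrap(coord[[1]]); fb <- frac_clamp(coord[[2]]); fg <- frac_wrap(coord[[3]])
  v <- 0
  for (da in 0:1) for (db in 0:1) for (dg in 0:1) {
    ia <- if (da == 0) fa$lo else fa$hi
    ib <- if (db == 0) fb$lo else fb$hi
    ig <- if (dg == 0) fg$lo else fg$hi
    w <- (if (da == 0) 1 - fa$t else fa$t) *
         (if (db == 0) 1 - fb$t else fb$t) *
         (if (dg == 0) 1 - fg$t else fg$t)
    v <- v + w * grid$density[ia, ib, ig]
  }
  v
}

# Neighbour-maximum array over the 26-connected neighbourhood, with wrap on
# the periodic axes and -Inf padding on the beta axis.
.neighbour_max <- function(dens) {
  d <- dim(dens)
  shift <- function(arr, off, dim, circular) {
    if (off == 0) return(arr)
    n <- dim(arr)[dim]
    src <- seq_len(n) + off
    if (circular) {
      src <- ((src - 1L) %% n) + 1L
      idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      idx[[dim]] <- src
      return(arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
    }
    out <- array(-Inf, dim(arr))
    ok <- src >= 1L & src <= n
    idx_to <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_from <- idx_to
    idx_to[[dim]] <- which(ok)
    idx_from[[dim]] <- src[ok]
    out[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <-
      arr[idx_from[[1]], idx_from[[2]], idx_from[[3]], drop = FALSE]
    out
  }
  nmax <- array(-Inf, d)
  for (da in -1:1) for (db in -1:1) for (dg in -1:1) {
    if (da == 0 && db == 0 && dg == 0) next
    s <- shift(dens, da, 1L, TRUE)
    s <- shift(s, db, 2L, FALSE)
    s <- shift(s, dg, 3L, TRUE)
    nmax <- pmax(nmax, s)
  }
  nmax
}

# Wrapped Euclidean distance in degrees between (alpha,beta,gamma) points.
.wrapped_dist <- function(a, b) {
  sqrt(angle_diff(a[1], b[1])^2 + (a[2] - b[2])^2 + angle_diff(a[3], b[3])^2)
}

#' Detect landscape hotspots
#'
#' Hotspots are strict local density maxima (26-connected, with periodic
#' wrap on alpha and gamma) whose density is at or above the given
#' percentile of the nonzero-density bins, greedily pruned so that no two
#' returned centers lie closer than `min_separation` (wrapped Euclidean
#' degrees), sorted by decreasing density.
#'
#' @param grid a `landscape_grid`.
#' @param percentile density percentile threshold in (0, 100), default 97.5.
#' @param min_separation minimum center-to-center distance in degrees,
#'   default 10.
#' @return data.frame with columns `alpha`, `beta`, `gamma` (bin centers),
#'   `density`, and `n_within` (particle count within `min_separation` of
#'   the center); zero rows if no strict local maximum clears the threshold.
#' @export
find_hotspots <- function(grid, percentile = 97.5, min_separation = 10) {
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must be in (0, 100)")
  dens <- grid$density
  nz <- dens[dens > 0]
  if (length(nz) == 0) return(.empty_hotspots())
  thr <- stats::quantile(nz, percentile / 100, names = FALSE)
  is_max <- dens > .neighbour_max(dens) & dens >= thr
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(.empty_hotspots())
  cand <- data.frame(alpha = grid$mids$alpha[idx[, 1]],
                     beta = grid$mids$beta[idx[, 2]],
                     gamma = grid$mids$gamma[idx[, 3]],
                     density = dens[idx])
  cand <- cand[order(-cand$density), , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    p <- c(cand$alpha[i], cand$beta[i], cand$gamma[i])
    ok <- all(vapply(keep, function(j)
      .wrapped_dist(p, c(cand$alpha[j], cand$beta[j], cand$gamma[j])) >= min_separation,
      logical(1)))
    if (ok) keep <- c(keep, i)
  }
  hs <- cand[keep, , drop = FALSE]
  rownames(hs) <- NULL
  hs$n_within <- vapply(seq_len(nrow(hs)), function(i)
    .count_within(grid, c(hs$alpha[i], hs$beta[i], hs$gamma[i]), min_separation),
    numeric(1))
  hs
}

.empty_hotspots <- function() {
  data.frame(alpha = numeric(0), beta = numeric(0), gamma = numeric(0),
             density = numeric(0), n_within = numeric(0))
}

# Raw particle count in all bins whose centers lie within `radius` of a point.
.count_within <- function(grid, center, radius) {
  ga <- grid$mids$alpha; gb <- grid$mids$beta; gg <- grid$mids$gamma
  da <- angle_diff(ga, center[1])^2
  db <- (gb - center[2])^2
  dg <- angle_diff(gg, center[3])^2
  m <- outer(outer(da, db, "+"), dg, "+") <= radius^2
  sum(grid$counts[m])
}

#' Marginal density of a landscape along one or two axes
#'
#' Sums the normalised 3D density over the other axes.
#'
#' @param grid a `landscape_grid`.
#' @param axes character vector of one or two of `"alpha"`, `"beta"`,
#'   `"gamma"`.
#' @return for one axis, a data.frame `(mid, density)`; for two, a matrix
#'   with dimnames set to the bin centers (first axis in rows).
#' @export
marginal_density <- function(grid, axes = "alpha") {
  axmap <- c(alpha = 1L, beta = 2L, gamma = 3L)
  dims <- axmap[match.arg(axes, names(axmap), several.ok = TRUE)]
  m <- apply(grid$density, dims, sum)
  if (length(dims) == 1) {
    data.frame(mid = grid$mids[[names(axmap)[dims]]], density = as.numeric(m))
  } else {
    dimnames(m) <- list(grid$mids[[names(axmap)[dims[1]]]],
                        grid$mids[[names(axmap)[dims[2]]]])
    m
  }
}

#' Mean and variance of a (possibly periodic) marginal
#'
#' Variance of the binned marginal density along one axis; for the periodic
#' alpha/gamma axes the first trigonometric moment defines the circular
#' mean and deviations are wrapped about it.
#'
#' @param grid a `landscape_grid`.
#' @param axis one of `"alpha"`, `"beta"`, `"gamma"`.
#' @return list with `mean` and `variance` (degrees, degrees squared).
#' @export
marginal_moments <- function(grid, axis = "alpha") {
  m <- marginal_density(grid, axis)
  w <- m$density / sum(m$density)
  if (axis %in% c("alpha", "gamma")) {
    th <- deg2rad(m$mid)
    mu <- rad2deg(atan2(sum(w * sin(th)), sum(w * cos(th))))
    dev <- angle_diff(m$mid, mu)
  } else {
    mu <- sum(w * m$mid)
    dev <- m$mid - mu
  }
  list(mean = mu, variance = sum(w * dev^2))
}

#' Render landscape projections
#'
#' Writes 2D marginal heat maps (alpha-gamma and alpha-beta) of the density
#' and a pseudo-3D scatter of occupied bins, optionally overlaying the
#' corresponding marginal of a second landscape as red contours (levels at
#' 50/75/90% of its marginal maximum).
#'
#' @param grid a `landscape_grid`.
#' @param file_prefix path prefix; files `<prefix>_alpha_gamma.png`,
#'   `<prefix>_alpha_beta.png`, `<prefix>_scatter.png` are written.
#' @param overlay optional second `landscape_grid` drawn as contours.
#' @return character vector of the files written, invisibly.
#' @export
render_landscape <- function(grid, file_prefix, overlay = NULL) {
  files <- character(0)
  draw2d <- function(ax1, ax2, fname) {
    m <- marginal_density(grid, c(ax1, ax2))
    grDevices::png(fname, width = 900, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::image(grid$mids[[ax1]], grid$mids[[ax2]], m,
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = sprintf("%s (deg)", ax1), ylab = sprintf("%s (deg)", ax2),
                    main = sprintf("landscape marginal %s-%s (n = %d)", ax1, ax2,
                                   grid$n_particles))
    if (!is.null(overlay)) {
      mo <- marginal_density(overlay, c(ax1, ax2))
      graphics::contour(overlay$mids[[ax1]], overlay$mids[[ax2]], mo,
                        levels = max(mo) * c(0.5, 0.75, 0.9),
                        col = "red", add = TRUE, drawlabels = FALSE)
    }
    fname
  }
  files <- c(files, draw2d("alpha", "gamma", paste0(file_prefix, "_alpha_gamma.png")))
  files <- c(files, draw2d("alpha", "beta", paste0(file_prefix, "_alpha_beta.png")))
  occ <- which(grid$counts > 0, arr.ind = TRUE)
  f3 <- paste0(file_prefix, "_scatter.png")
  grDevices::png(f3, width = 900, height = 700)
  d <- grid$density[occ]
  cols <- grDevices::hcl.colors(64, "viridis")[
    pmax(1L, ceiling(64 * d / max(d)))]
  graphics::plot(grid$mids$alpha[occ[, 1]], grid$mids$gamma[occ[, 3]],
                 pch = 16, cex = 0.4 + 1.6 * (grid$mids$beta[occ[, 2]] + 90) / 180,
                 col = cols, xlab = "alpha (deg)", ylab = "gamma (deg)",
                 main = "occupied bins (size ~ beta, colour ~ density)")
  grDevices::dev.off()
  files <- c(files, f3)
  invisible(files)
}
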