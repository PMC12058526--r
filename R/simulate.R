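# Synthetic paired-refinement scenes with known ground truth.
#
# A scene emulates two focused refinements of one particle stack: body-1
# (modifying) viewing orientations are uniform over SO(3); each particle's
# relative orientation is drawn from a mixture of per-axis wrapped
# Gaussians in (alpha, beta, gamma); body-2 (condensing) orientations are
# the composition of body 1 with that relative rotation; small independent
# noise rotations per body emulate the angular-assignment error of two
# separate refinements. Optional C2 expansion emits each particle twice
# with per-monomer class labels, as focused classification of a homodimer
# would.

#' Define one mixture component of a scene
#'
#' @param center numeric `(alpha, beta, gamma)` degrees.
#' @param sigma isotropic per-axis wrapped-Gaussian width, degrees.
#' @param weight mixture weight (weights over the scene must sum to 1).
#' @param cond_labels character(2): condensing labels of monomers 1 and 2.
#' @param mod_labels character(2): modifying labels of monomers 1 and 2.
#' @return a list describing the component.
#' @export
scene_component <- function(center, sigma = 5, weight = 1,
                            cond_labels = c("no-ACP", "no-ACP"),
                            mod_labels = c("psi-unresolved", "psi-unresolved")) {
  if (sigma < 0 || weight < 0) stop("sigma and weight must be >= 0")
  list(center = as.numeric(center), sigma = sigma, weight = weight,
       cond_labels = cond_labels, mod_labels = mod_labels)
}

#' Default three-component scene
#'
#' Mirrors the geography of a real dual-wing landscape: a hotspot with ACP
#' on the KS site near (13, 0, 14), a hotspot with ACP on the MAT site near
#' (-3, -8, -8), and a broad unengaged background centred at the origin.
#'
#' @return list of [scene_component()]s.
#' @export
default_scene_components <- function() {
  list(
    scene_component(c(13, 0, 14), sigma = 5, weight = 0.4,
                    cond_labels = c("ACP-KS", "dynamic-MAT"),
                    mod_labels = c("psi-resolved", "psi-unresolved")),
    scene_component(c(-3, -8, -8), sigma = 5, weight = 0.35,
                    cond_labels = c("ACP-MAT", "dynamic-MAT"),
                    mod_labels = c("psi-unresolved", "psi-unresolved")),
    scene_component(c(0, 0, 0), sigma = 30, weight = 0.25,
                    cond_labels = c("no-ACP", "no-ACP"),
                    mod_labels = c("psi-resolved", "psi-resolved")))
}

# Half-normal noise rotation batch: uniform random axis, |N(0, sigma)| angle.
.noise_elems <- function(n, sigma) {
  z <- matrix(stats::rnorm(3 * n), ncol = 3)
  axes <- z / sqrt(rowSums(z^2))
  .axis_angle_elems(axes, abs(stats::rnorm(n, sd = sigma)))
}

#' Simulate a paired-refinement scene
#'
#' Draws `n` particles from the mixture, composes per-body matrices, applies
#' per-body angular noise, optionally C2-expands, and (optionally) writes
#' the two STAR files plus a ground-truth JSON. Output is reproducible
#' given `seed`.
#'
#' @param components list of [scene_component()]s; weights must sum to 1.
#' @param n number of particles (before C2 expansion).
#' @param noise_sigma per-body angular assignment error scale, degrees.
#' @param seed RNG seed.
#' @param c2_expand emit each particle twice, composed with the C2 operator
#'   of both bodies (axis z) and carrying the second monomer's labels.
#' @param alpha_range optional `c(lo, hi)`: resample each particle's
#'   relative orientation until its ground-truth alpha lies inside the
#'   range (emulates a constricted specimen).
#' @param out_prefix if non-NULL, write `<prefix>_mod.star`,
#'   `<prefix>_cond.star` and `<prefix>_truth.json`.
#' @return list with `mod` and `cond` half-tables, `truth` (per-particle
#'   data.frame with component index and true angles), and `files`.
#' @export
simulate_scene <- function(components = default_scene_components(),
                           n = 10000, noise_sigma = 1, seed = 1,
                           c2_expand = FALSE, alpha_range = NULL,
                           out_prefix = NULL) {
  w <- vapply(components, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) stop("component weights must sum to 1")
  if (n < 0) stop("n must be >= 0")
  set.seed(seed)
  files <- character(0)
  if (n == 0) {
    mod <- cond <- .empty_half()
    truth <- data.frame(particle_id = character(0), component = integer(0),
                        alpha = numeric(0), beta = numeric(0), gamma = numeric(0))
  } else {
    comp <- sample.int(length(components), n, replace = TRUE, prob = w)
    centers <- t(vapply(components, `[[`, numeric(3), "center"))
    sig <- vapply(components, `[[`, numeric(1), "sigma")[comp]
    draw_rel <- function(idx) {
      m <- length(idx)
      data.frame(alpha = wrap180(centers[comp[idx], 1] + stats::rnorm(m) * sig[idx]),
                 beta = pmax(-90, pmin(90, centers[comp[idx], 2] + stats::rnorm(m) * sig[idx])),
                 gamma = wrap180(centers[comp[idx], 3] + stats::rnorm(m) * sig[idx]))
    }
    rel <- draw_rel(seq_len(n))
    if (!is.null(alpha_range)) {
      for (it in 1:200) {
        bad <- which(rel$alpha < alpha_range[1] | rel$alpha > alpha_range[2])
        if (length(bad) == 0) break
        rel[bad, ] <- draw_rel(bad)
      }
      if (length(bad <- which(rel$alpha < alpha_range[1] |
                              rel$alpha > alpha_range[2])))
        stop("alpha_range too narrow for the component mixture")
    }
    em <- .random_rotation_elems(n)
    erel <- .zyx_elems(rel$alpha, rel$beta, rel$gamma)
    ec <- .elems_mult(em, erel)
    if (noise_sigma > 0) {
      em <- .elems_mult(.noise_elems(n, noise_sigma), em)
      ec <- .elems_mult(.noise_elems(n, noise_sigma), ec)
    }
    ids <- sprintf("%06d@sim_particles.mrcs", seq_len(n))
    mics <- sprintf("sim_mic_%04d.mrc", (seq_len(n) - 1L) %/% 500L + 1L)
    truth <- data.frame(particle_id = ids, component = comp,
                        alpha = rel$alpha, beta = rel$beta, gamma = rel$gamma,
                        stringsAsFactors = FALSE)
    clab <- t(vapply(components, `[[`, character(2), "cond_labels"))
    mlab <- t(vapply(components, `[[`, character(2), "mod_labels"))
    if (c2_expand) {
      c2 <- .zyx_elems(rep(180, n), rep(0, n), rep(0, n))
      em2 <- .elems_mult(em, c2)
      ec2 <- .elems_mult(ec, c2)
      mod <- .make_half(ids, mics, rbind_zyz(.elems_to_zyz(em), .elems_to_zyz(em2)),
                        expansion = c(rep(0L, n), rep(1L, n)),
                        class = c(mlab[comp, 1], mlab[comp, 2]))
      cond <- .make_half(ids, mics, rbind_zyz(.elems_to_zyz(ec), .elems_to_zyz(ec2)),
                         expansion = c(rep(0L, n), rep(1L, n)),
                         class = c(clab[comp, 1], clab[comp, 2]))
    } else {
      mod <- .make_half(ids, mics, .elems_to_zyz(em),
                        expansion = rep(0L, n), class = mlab[comp, 1])
      cond <- .make_half(ids, mics, .elems_to_zyz(ec),
                         expansion = rep(0L, n), class = clab[comp, 1])
    }
  }
  truth_meta <- list(
    components = lapply(components, function(cm)
      cm[c("center", "sigma", "weight", "cond_labels", "mod_labels")]),
    n = n, noise_sigma = noise_sigma, seed = seed, c2_expand = c2_expand,
    alpha_range = alpha_range)
  if (!is.null(out_prefix)) {
    fm <- paste0(out_prefix, "_mod.star")
    fc <- paste0(out_prefix, "_cond.star")
    ft <- paste0(out_prefix, "_truth.json")
    .write_half_star(mod, fm)
    .write_half_star(cond, fc)
    jsonlite::write_json(list(meta = truth_meta, particles = truth), ft,
                         auto_unbox = TRUE, digits = NA)
    files <- c(mod = fm, cond = fc, truth = ft)
  }
  list(mod = mod, cond = cond, truth = truth, meta = truth_meta, files = files)
}

rbind_zyz <- function(a, b) rbind(a, b)

.empty_half <- function() {
  h <- data.frame(particle_id = character(0), micrograph = character(0),
                  rot = numeric(0), tilt = numeric(0), psi = numeric(0),
                  expansion_index = integer(0), class = character(0),
                  optics_group = integer(0))
  attr(h, "raw") <- .half_raw(h)
  attr(h, "optics") <- .sim_optics()
  class(h) <- c("rotascape_half", "data.frame")
  h
}

.make_half <- function(ids, mics, zyz, expansion, class) {
  k <- length(expansion) / length(ids)
  h <- data.frame(particle_id = rep(ids, k), micrograph = rep(mics, k),
                  rot = zyz$rot, tilt = zyz$tilt, psi = zyz$psi,
                  expansion_index = expansion, class = class,
                  optics_group = rep(1L, length(expansion)),
                  stringsAsFactors = FALSE)
  ord <- order(match(h$particle_id, ids), h$expansion_index)
  h <- h[ord, , drop = FALSE]
  rownames(h) <- NULL
  attr(h, "raw") <- .half_raw(h)
  attr(h, "optics") <- .sim_optics()
  class(h) <- c("rotascape_half", "data.frame")
  h
}

.half_raw <- function(h) {
  data.frame(rlnImageName = h$particle_id,
             rlnMicrographName = h$micrograph,
             rlnAngleRot = .fmt_angle(h$rot),
             rlnAngleTilt = .fmt_angle(h$tilt),
             rlnAnglePsi = .fmt_angle(h$psi),
             rlnExpansionIndex = as.character(h$expansion_index),
             rlnClassLabel = h$class,
             rlnOpticsGroup = as.character(h$optics_group),
             stringsAsFactors = FALSE)
}

.sim_optics <- function() {
  data.frame(rlnOpticsGroup = "1", rlnOpticsGroupName = "opticsGroup1",
             rlnImagePixelSize = "1.045", rlnVoltage = "300.000000",
             stringsAsFactors = FALSE)
}

.write_half_star <- function(h, path) {
  write_star_blocks(list(optics = attr(h, "optics"),
                         particles = attr(h, "raw")), path)
}

#' End-to-end recovery check of a simulated scene
#'
#' Runs the full pipeline on a scene — pairing, orientation computation,
#' landscape, hotspot detection, per-truth-center selections — and compares
#' against the ground truth: hotspot center errors, mixture weights
#' re-estimated as the fraction of particles nearest each truth center, and
#' selection counts versus an independent brute-force distance scan.
#'
#' @param scene result of [simulate_scene()].
#' @param bin_width,smooth_sigma landscape parameters.
#' @param percentile,min_separation hotspot parameters.
#' @param radius selection radius (degrees) for the per-center counts.
#' @return list with `orients`, `grid`, `hotspots`, `center_errors`,
#'   `weights_true`, `weights_recovered`, `selection` (per-center counts
#'   and brute-force agreement).
#' @export
recovery_check <- function(scene, bin_width = 2, smooth_sigma = 1,
                           percentile = 97.5, min_separation = 10,
                           radius = 14) {
  pairs <- pair_refinements(scene$mod, scene$cond)
  core <- pairs[pairs$expansion_index == 0L, , drop = FALSE]
  orients <- compute_orientations(core)
  grid <- build_landscape(orients, bin_width, smooth_sigma)
  hs <- find_hotspots(grid, percentile, min_separation)
  centers <- t(vapply(scene$meta$components, function(c) as.numeric(c$center),
                      numeric(3)))
  center_errors <- apply(centers, 1, function(ct) {
    if (nrow(hs) == 0) return(NA_real_)
    min(vapply(seq_len(nrow(hs)), function(i)
      .wrapped_dist(ct, c(hs$alpha[i], hs$beta[i], hs$gamma[i])), numeric(1)))
  })
  # nearest-truth-center assignment for weight recovery
  dmat <- vapply(seq_len(nrow(centers)), function(k)
    angle_diff(orients$alpha, centers[k, 1])^2 +
      (orients$beta - centers[k, 2])^2 +
      angle_diff(orients$gamma, centers[k, 3])^2,
    numeric(nrow(orients)))
  nearest <- max.col(-dmat)
  weights_rec <- tabulate(nearest, nbins = nrow(centers)) / nrow(orients)
  sel <- lapply(seq_len(nrow(centers)), function(k) {
    idx <- select_within_radius(orients, centers[k, ], radius)
    brute <- which(vapply(seq_len(nrow(orients)), function(i)
      .wrapped_dist(c(orients$alpha[i], orients$beta[i], orients$gamma[i]),
                    centers[k, ]) <= radius, logical(1)))
    list(center = centers[k, ], n = length(idx),
         brute_force_agrees = identical(sort(idx), sort(brute)))
  })
  list(orients = orients, grid = grid, hotspots = hs,
       center_errors = center_errors,
       weights_true = vapply(scene$meta$components, `[[`, numeric(1), "weight"),
       weights_recovered = weights_rec,
       selection = sel)
}
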