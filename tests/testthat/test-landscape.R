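test_that("identical body angles give the zero orientation", {
  sc <- simulate_scene(list(scene_component(c(0, 0, 0), sigma = 0, weight = 1)),
                       n = 5, noise_sigma = 0, seed = 1)
  pr <- pair_refinements(sc$mod, sc$cond)
  expect_equal(pr$rot_mod, pr$rot_cond, tolerance = 1e-9)
  o <- compute_orientations(pr)
  expect_equal(abs(wrap180(o$alpha)) %% 360, rep(0, 5), tolerance = 1e-9)
  expect_equal(o$beta, rep(0, 5), tolerance = 1e-9)
})

test_that("zero-noise construction returns the truth orientation exactly", {
  sc <- simulate_scene(list(scene_component(c(13, 0, 14), sigma = 0, weight = 1)),
                       n = 20, noise_sigma = 0, seed = 2)
  o <- compute_orientations(pair_refinements(sc$mod, sc$cond))
  expect_equal(o$alpha, rep(13, 20), tolerance = 1e-9)
  expect_equal(o$beta, rep(0, 20), tolerance = 1e-9)
  expect_equal(o$gamma, rep(14, 20), tolerance = 1e-9)
})

test_that("computed orientations track the truth within the noise budget", {
  sc <- simulate_scene(list(scene_component(c(13, 0, 14), sigma = 0, weight = 1)),
                       n = 1000, noise_sigma = 2, seed = 4)
  o <- compute_orientations(pair_refinements(sc$mod, sc$cond))
  rms_alpha <- sqrt(mean((wrap180(o$alpha - 13))^2))
  # two independent half-normal body-noise rotations of scale 2 degrees
  expect_lt(rms_alpha, 2 * sqrt(2))
})

test_that("histogramming conserves particles and localises a single point", {
  o1 <- data.frame(alpha = 10, beta = 5, gamma = -20)
  g <- build_landscape(o1, bin_width = 2, smooth_sigma = 0)
  expect_equal(sum(g$counts), 1)
  expect_equal(sum(g$counts > 0), 1)
  idx <- which(g$counts > 0, arr.ind = TRUE)
  expect_lte(abs(g$mids$alpha[idx[1]] - 10), 1)
  expect_lte(abs(g$mids$beta[idx[2]] - 5), 1)
  expect_lte(abs(g$mids$gamma[idx[3]] - (-20)), 1)
  # boundary values land in valid bins and are conserved
  ob <- data.frame(alpha = c(180, -179.999, 0), beta = c(90, -90, 0),
                   gamma = c(180, -180, 0))
  gb <- build_landscape(ob, bin_width = 2, smooth_sigma = 1)
  expect_equal(sum(gb$counts), 3)
  expect_equal(sum(gb$density), 1, tolerance = 1e-9)
  expect_true(all(gb$density >= 0))
  set.seed(5)
  on <- data.frame(alpha = runif(500, -180, 180), beta = runif(500, -90, 90),
                   gamma = runif(500, -180, 180))
  expect_equal(sum(build_landscape(on)$counts), 500)
  expect_error(build_landscape(on[0, ]), "zero")
  expect_error(build_landscape(on, bin_width = 7), "divide")
})

test_that("the argmax of a single smoothed mode sits within one bin of truth", {
  set.seed(6)
  n <- 20000
  o <- data.frame(alpha = wrap180(13 + rnorm(n, sd = 5)),
                  beta = pmax(-90, pmin(90, 0 + rnorm(n, sd = 5))),
                  gamma = wrap180(14 + rnorm(n, sd = 5)))
  g <- build_landscape(o, bin_width = 2, smooth_sigma = 1)
  idx <- which(g$density == max(g$density), arr.ind = TRUE)[1, ]
  expect_lte(abs(g$mids$alpha[idx[1]] - 13), 2)
  expect_lte(abs(g$mids$beta[idx[2]] - 0), 2)
  expect_lte(abs(g$mids$gamma[idx[3]] - 14), 2)
})

test_that("local density interpolates between neighbouring bin values", {
  o1 <- data.frame(alpha = 10, beta = 5, gamma = -20)
  g0 <- build_landscape(o1, bin_width = 2, smooth_sigma = 0)
  idx <- which(g0$counts > 0, arr.ind = TRUE)
  ctr <- c(g0$mids$alpha[idx[1]], g0$mids$beta[idx[2]], g0$mids$gamma[idx[3]])
  expect_equal(local_density(g0, ctr), g0$density[idx])
  expect_equal(local_density(g0, c(wrap180(ctr[1] + 180), -ctr[2], wrap180(ctr[3] + 180))), 0)
  # midway between two centers along alpha: between the two bin values
  set.seed(7)
  o <- data.frame(alpha = rnorm(2000, 0, 10), beta = rnorm(2000, 0, 10),
                  gamma = rnorm(2000, 0, 10))
  g <- build_landscape(o, bin_width = 2, smooth_sigma = 1)
  ia <- which.min(abs(g$mids$alpha - 1)); ib <- which.min(abs(g$mids$beta - 1))
  ig <- which.min(abs(g$mids$gamma - 1))
  v1 <- g$density[ia, ib, ig]; v2 <- g$density[ia + 1, ib, ig]
  mid <- local_density(g, c(g$mids$alpha[ia] + 1, g$mids$beta[ib], g$mids$gamma[ig]))
  expect_gte(mid, min(v1, v2) - 1e-15)
  expect_lte(mid, max(v1, v2) + 1e-15)
})

test_that("hotspot detection returns none for flat density, one for a point mass", {
  o1 <- data.frame(alpha = 10, beta = 5, gamma = -20)
  g <- build_landscape(o1, bin_width = 2, smooth_sigma = 0)
  flat <- g
  flat$density <- array(1 / length(g$density), dim(g$density))
  expect_equal(nrow(find_hotspots(flat)), 0)
  hs <- find_hotspots(g, percentile = 50)
  expect_equal(nrow(hs), 1)
  expect_equal(c(hs$alpha, hs$beta, hs$gamma), c(9, 5, -21) + 0)
  expect_equal(hs$n_within, 1)
  expect_error(find_hotspots(g, percentile = 0), "percentile")
})

test_that("two modes 60 degrees apart in alpha are found as two hotspots", {
  set.seed(8)
  n <- 10000
  pick <- rbinom(n, 1, 0.5)
  o <- data.frame(alpha = wrap180(ifelse(pick == 1, -20, 40) + rnorm(n, sd = 5)),
                  beta = pmax(-90, pmin(90, rnorm(n, sd = 5))),
                  gamma = wrap180(rnorm(n, sd = 5)))
  g <- build_landscape(o, bin_width = 2, smooth_sigma = 1)
  hs <- find_hotspots(g, percentile = 97.5, min_separation = 10)
  expect_equal(nrow(hs), 2)
  ord <- order(hs$alpha)
  expect_lte(abs(hs$alpha[ord[1]] - (-20)), 2)
  expect_lte(abs(hs$alpha[ord[2]] - 40), 2)
  expect_lte(max(abs(hs$beta)), 2)
  expect_lte(max(abs(hs$gamma)), 2)
})

test_that("restricting alpha narrows the alpha marginal but not its centre profile", {
  comps <- list(scene_component(c(0, 0, 0), sigma = 25, weight = 1))
  free <- simulate_scene(comps, n = 8000, noise_sigma = 1, seed = 10)
  tight <- simulate_scene(comps, n = 8000, noise_sigma = 1, seed = 10,
                          alpha_range = c(-20, 20))
  gf <- build_landscape(compute_orientations(pair_refinements(free$mod, free$cond)))
  gt <- build_landscape(compute_orientations(pair_refinements(tight$mod, tight$cond)))
  vf <- marginal_moments(gf, "alpha")$variance
  vt <- marginal_moments(gt, "alpha")$variance
  expect_lt(vt, vf)
  # beta/gamma marginals stay comparable (not constricted)
  expect_equal(marginal_moments(gt, "beta")$variance,
               marginal_moments(gf, "beta")$variance, tolerance = 0.15)
})

test_that("canonicalized landscapes ignore which expansion copy is supplied", {
  sc <- simulate_scene(list(scene_component(c(25, 10, -40), sigma = 3, weight = 1)),
                       n = 300, noise_sigma = 0, seed = 12, c2_expand = TRUE)
  pr <- pair_refinements(sc$mod, sc$cond)
  g0 <- build_landscape(compute_orientations(pr[pr$expansion_index == 0, ],
                                             canonicalize = TRUE))
  g1 <- build_landscape(compute_orientations(pr[pr$expansion_index == 1, ],
                                             canonicalize = TRUE))
  expect_identical(g0$counts, g1$counts)
})

test_that("rendering writes figures whose marginals reflect the data", {
  set.seed(13)
  o_narrow <- data.frame(alpha = rnorm(2000, 0, 5), beta = rnorm(2000, 0, 5),
                         gamma = rnorm(2000, 0, 5))
  o_broad <- data.frame(alpha = runif(2000, -120, 120), beta = rnorm(2000, 0, 5),
                        gamma = rnorm(2000, 0, 5))
  gn <- build_landscape(o_narrow); gb <- build_landscape(o_broad)
  expect_lt(marginal_moments(gn, "alpha")$variance,
            marginal_moments(gb, "alpha")$variance)
  dir <- withr::local_tempdir()
  files <- render_landscape(gn, file.path(dir, "narrow"), overlay = gb)
  expect_true(all(file.exists(files)))
  expect_length(files, 3)
})
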