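test_that("STAR particle tables read back the angles they contain", {
  f <- withr::local_tempfile(fileext = ".star")
  write_min_star(f, sprintf("%06d@s.mrcs", 1:3),
                 rot = c(0, 90, 0), tilt = c(0, 0, 90), psi = c(0, 0, 0))
  tb <- read_particle_star(f)
  expect_equal(nrow(tb), 3)
  expect_equal(tb$rot, c(0, 90, 0))
  expect_equal(tb$tilt, c(0, 0, 90))
  expect_equal(tb$psi, c(0, 0, 0))
  expect_equal(tb$expansion_index, c(0L, 0L, 0L))
})

test_that("a missing required angle column is reported by name", {
  f <- withr::local_tempfile(fileext = ".star")
  write_min_star(f, sprintf("%06d@s.mrcs", 1:3),
                 rot = 1:3, tilt = 1:3, psi = 1:3,
                 drop_col = "rlnAngleTilt")
  expect_error(read_particle_star(f), "rlnAngleTilt")
})

test_that("an empty particles block reads as an empty table with a warning", {
  f <- withr::local_tempfile(fileext = ".star")
  write_min_star(f, character(0), numeric(0), numeric(0), numeric(0))
  expect_warning(tb <- read_particle_star(f), "empty")
  expect_equal(nrow(tb), 0)
})

test_that("write then read is the identity on identifiers and angles", {
  sc <- simulate_scene(n = 40, noise_sigma = 2, seed = 3,
                       out_prefix = file.path(withr::local_tempdir(), "sc"))
  for (body in c("mod", "cond")) {
    tb <- read_particle_star(sc$files[[body]])
    orig <- sc[[body]]
    expect_equal(tb$particle_id, orig$particle_id)
    expect_equal(tb$rot, orig$rot, tolerance = 1e-6)
    expect_equal(tb$tilt, orig$tilt, tolerance = 1e-6)
    expect_equal(tb$psi, orig$psi, tolerance = 1e-6)
    expect_equal(tb$class, orig$class)
    # second round trip is exact: the formatted decimals are already fixed
    f2 <- withr::local_tempfile(fileext = ".star")
    write_particle_star(tb, f2)
    tb2 <- read_particle_star(f2)
    expect_identical(tb2$rot, tb$rot)
    expect_identical(attr(tb2, "raw"), attr(tb, "raw"))
  }
})

test_that("pairing joins on shared identifiers irrespective of row order", {
  dir <- withr::local_tempdir()
  ids_mod <- sprintf("%06d@s.mrcs", 1:100)
  ids_cond <- sprintf("%06d@s.mrcs", 21:110)   # 80 shared of 100 / 90
  set.seed(42)
  fm <- write_min_star(file.path(dir, "m.star"), ids_mod,
                       rot = 1:100, tilt = rep(10, 100), psi = rep(0, 100))
  shuf <- sample(90)
  fc <- write_min_star(file.path(dir, "c.star"), ids_cond[shuf],
                       rot = (21:110)[shuf], tilt = rep(20, 90), psi = rep(0, 90))
  pr <- pair_refinements(read_particle_star(fm), read_particle_star(fc))
  expect_equal(nrow(pr), 80)
  expect_setequal(pr$particle_id, intersect(ids_mod, ids_cond))
  # condensing rot was built to equal the shared numeric id
  expect_equal(pr$rot_cond, as.numeric(sub("@.*", "", pr$particle_id)))
  expect_equal(unname(attr(pr, "unmatched")), c(20, 10))
})

test_that("swapping the two inputs swaps body roles but not the pair set", {
  dir <- withr::local_tempdir()
  fa <- write_min_star(file.path(dir, "a.star"), sprintf("%03d@s", 1:50),
                       rot = 1:50, tilt = rep(5, 50), psi = rep(0, 50))
  fb <- write_min_star(file.path(dir, "b.star"), sprintf("%03d@s", 26:75),
                       rot = 101:150, tilt = rep(7, 50), psi = rep(0, 50))
  ab <- pair_refinements(read_particle_star(fa), read_particle_star(fb))
  ba <- pair_refinements(read_particle_star(fb), read_particle_star(fa))
  expect_setequal(ab$particle_id, ba$particle_id)
  m <- match(ab$particle_id, ba$particle_id)
  expect_equal(ab$rot_mod, ba$rot_cond[m])
  expect_equal(ab$rot_cond, ba$rot_mod[m])
  expect_lte(nrow(ab), 50)
})

test_that("degenerate pairings fail loudly", {
  dir <- withr::local_tempdir()
  fa <- write_min_star(file.path(dir, "a.star"), sprintf("%03d@s", 1:10),
                       rot = 1:10, tilt = rep(0, 10), psi = rep(0, 10))
  fb <- write_min_star(file.path(dir, "b.star"), sprintf("%03d@s", 11:20),
                       rot = 1:10, tilt = rep(0, 10), psi = rep(0, 10))
  expect_error(pair_refinements(read_particle_star(fa), read_particle_star(fb)),
               "no shared identifiers")
  # duplicate id without an expansion column gets indices 0/1 and still pairs
  fdup <- write_min_star(file.path(dir, "dup.star"),
                         rep(sprintf("%03d@s", 1:5), each = 2),
                         rot = 1:10, tilt = rep(0, 10), psi = rep(0, 10))
  tdup <- read_particle_star(fdup)
  expect_equal(tdup$expansion_index, rep(c(0L, 1L), 5))
  pr <- pair_refinements(tdup, tdup)
  expect_equal(nrow(pr), 10)
  # a genuine duplicate (same id and expansion index) is an error
  tbad <- tdup
  tbad$expansion_index <- rep(0L, 10)
  expect_error(pair_refinements(tbad, tdup), "duplicate")
  expect_error(pair_refinements(tdup[0, ], tdup), "empty")
})

test_that("written subsets carry the selected body's angles verbatim", {
  sc <- simulate_scene(n = 25, noise_sigma = 3, seed = 9)
  pr <- pair_refinements(sc$mod, sc$cond)
  f <- withr::local_tempfile(fileext = ".star")
  write_particle_star(pr, f, body = "condensing")
  back <- read_particle_star(f)
  expect_equal(back$rot, pr$rot_cond, tolerance = 1e-6)
  expect_equal(back$particle_id, pr$particle_id)
  f2 <- withr::local_tempfile(fileext = ".star")
  write_particle_star(pr, f2, body = "modifying")
  expect_equal(read_particle_star(f2)$tilt, pr$tilt_mod, tolerance = 1e-6)
  expect_error(write_particle_star(pr[0, ], f), "empty")
})

test_that("optics blocks pass through a write/read cycle untouched", {
  sc <- simulate_scene(n = 10, seed = 5,
                       out_prefix = file.path(withr::local_tempdir(), "sc"))
  tb <- read_particle_star(sc$files[["cond"]])
  expect_false(is.null(attr(tb, "optics")))
  f <- withr::local_tempfile(fileext = ".star")
  write_particle_star(tb, f)
  expect_identical(attr(read_particle_star(f), "optics"), attr(tb, "optics"))
})
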