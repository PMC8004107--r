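# shared nuclei configuration for registration scenes: a bright nuclear
# dye with many nuclei per field
nuc_cfg <- list(n = 30, radius = 4, level = 5000, background = 10)

test_that("affine algebra: inversion, composition, JSON round trip", {
  m <- diag(3) + matrix(rnorm(9, sd = 0.01), 3, 3)
  t1 <- affine3d(m, c(0.5, -1, 2))
  t2 <- affine3d(diag(3) * 1.01, c(1, 0, -0.5))
  comp <- affine_compose(t1, affine_invert(t1))
  expect_equal(comp$matrix, diag(3), tolerance = 1e-12)
  expect_equal(comp$translation, c(0, 0, 0), tolerance = 1e-12)
  p <- c(3, 4, 5)
  expect_equal(
    as.vector(affine_compose(t1, t2)$matrix %*% p) + affine_compose(t1, t2)$translation,
    as.vector(t1$matrix %*% (as.vector(t2$matrix %*% p) + t2$translation)) + t1$translation
  )
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  write_affine_json(t1, f)
  t1b <- read_affine_json(f)
  expect_equal(t1b$matrix, t1$matrix)
  expect_equal(t1b$translation, t1$translation)
  expect_error(affine3d(matrix(0, 3, 3)), class = "brainfish_config_error")
})

test_that("apply_transform: identity is exact, integer-shift round trip is clean", {
  sc <- render_scene(scene_spec(shape = c(16, 32, 32), nuclei = nuc_cfg, seed = 5))
  img <- sc$truth$clean_calib
  expect_identical(apply_transform(img, affine3d()), img)
  # +1 then -1 integer shift returns the original in the interior
  fwd <- apply_transform(img, affine3d(diag(3), c(0, 1, 0)))
  back <- apply_transform(fwd, affine3d(diag(3), c(0, -1, 0)))
  interior <- img[3:14, 4:29, 4:29]
  expect_lt(max(abs(back[3:14, 4:29, 4:29] - interior)) / diff(range(img)), 1e-6)
  # constant image stays constant in the interior under a fractional shift
  cimg <- array(13, c(10, 20, 20))
  w <- apply_transform(cimg, affine3d(diag(3), c(0.3, -0.4, 0.7)))
  expect_lt(max(abs(w[3:8, 4:17, 4:17] - 13)), 1e-12)
  expect_error(apply_transform(img, structure(list(matrix = matrix(0, 3, 3),
                                                   translation = c(0, 0, 0)),
                                              class = "affine3d")),
               class = "brainfish_config_error")
})

test_that("apply_transform preserves the total intensity of an interior spot", {
  # the stack must be deep enough that the +-5 sigma_z axial tails are
  # fully interior before and after the shift
  spot <- tibble::tibble(z = 20.2, y = 16.4, x = 15.7, photons = 5000)
  sc <- render_scene(scene_spec(shape = c(40, 32, 32), spots = spot,
                                background = 0, seed = 3))
  img <- get_channel(sc$stack, "smFISH")
  w <- apply_transform(img, affine3d(diag(3), c(0.5, 1.3, -0.8)))
  expect_lt(abs(sum(w) - sum(img)) / sum(img), 0.005)
})

test_that("estimating between identical images returns the identity", {
  sc <- render_scene(scene_spec(shape = c(16, 32, 32), nuclei = nuc_cfg, seed = 8))
  ref <- get_channel(sc$stack, "calib_ref")
  est <- estimate_chromatic_shift(ref, ref)
  expect_lt(max(abs(est$translation)), 0.05)
  expect_error(estimate_chromatic_shift(array(5, c(8, 16, 16)), array(5, c(8, 16, 16))),
               class = "brainfish_degenerate_error")
})

test_that("a known injected shift is recovered within 0.1 px", {
  inj <- affine3d(diag(3), c(0.0, 1.5, -2.0))
  sc <- render_scene(scene_spec(shape = c(24, 64, 64), nuclei = nuc_cfg, seed = 11))
  ref <- sc$truth$clean_calib
  mov <- apply_transform(ref, inj)
  est <- estimate_chromatic_shift(ref, mov)
  expect_lt(max(abs(est$translation - affine_invert(inj)$translation)), 0.1)
})

test_that("a 1.01 x-scale is recovered in the linear part within 0.002", {
  m <- diag(3); m[3, 3] <- 1.01
  inj <- affine3d(m, c(0, 0, 0))
  sc <- render_scene(scene_spec(shape = c(24, 64, 64), nuclei = nuc_cfg, seed = 12))
  ref <- sc$truth$clean_calib
  mov <- apply_transform(ref, inj)
  est <- estimate_chromatic_shift(ref, mov)
  truth <- affine_invert(inj)
  # the x-row of the linear part carries the injected effect
  expect_lt(max(abs(est$matrix[3, ] - truth$matrix[3, ])), 0.002)
})

test_that("estimate-apply round trip recovers random affines on noisy nuclei", {
  # injected transforms within +-3 px translation / +-2% scale
  n_seeds <- 12
  for (seed in seq_len(n_seeds)) {
    set.seed(seed * 13)
    m <- diag(3) + diag(runif(3, -0.02, 0.02))
    tr <- runif(3, -3, 3)
    inj <- affine3d(m, tr)
    sc <- render_scene(scene_spec(shape = c(32, 64, 64), nuclei = nuc_cfg,
                                  shift = inj, seed = seed))
    est <- estimate_chromatic_shift(get_channel(sc$stack, "calib_ref"),
                                    get_channel(sc$stack, "calib_moving"))
    truth <- affine_invert(inj)
    expect_lt(max(abs(est$translation - truth$translation)), 0.1)
    # displacement error of the recovered map over an interior grid
    g <- as.matrix(expand.grid(seq(6, 26, 10), seq(8, 56, 16), seq(8, 56, 16)))
    pe <- t(est$matrix %*% t(g)) + matrix(est$translation, nrow(g), 3, byrow = TRUE)
    pt <- t(truth$matrix %*% t(g)) + matrix(truth$translation, nrow(g), 3, byrow = TRUE)
    expect_lt(mean(sqrt(rowSums((pe - pt)^2))), 0.1)
  }
})
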