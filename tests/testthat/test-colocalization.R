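test_that("polygon rasterization matches the hand-counted square", {
  v <- rbind(c(10, 10), c(10, 40), c(40, 40), c(40, 10))
  m <- polygon_to_mask(v, c(64, 64))
  expect_equal(sum(m), 31 * 31)
  expect_error(polygon_to_mask(v[1:2, ], c(64, 64)), class = "brainfish_config_error")
  # polygon covering the whole frame
  big <- rbind(c(0, 0), c(0, 65), c(65, 65), c(65, 0))
  expect_true(all(polygon_to_mask(big, c(16, 16))))
})

test_that("polygon rasterization agrees with a brute-force even-odd oracle", {
  set.seed(19)
  for (i in 1:100) {
    nv <- sample(3:12, 1)
    vy <- runif(nv, 1, 32)
    vx <- runif(nv, 1, 32)
    m <- polygon_to_mask(cbind(vy, vx), c(32, 32))
    # check a random sample of pixels against the per-point oracle
    ys <- sample(1:32, 6)
    xs <- sample(1:32, 6)
    for (k in seq_along(ys)) {
      expect_identical(m[ys[k], xs[k]],
                       point_in_poly_bruteforce(ys[k], xs[k], vy, vx),
                       info = sprintf("polygon %d, pixel (%d,%d)", i, ys[k], xs[k]))
    }
  }
})

test_that("difference of Gaussians annihilates constants and ramps", {
  expect_lt(max(abs(dog_enhance(matrix(25, 40, 40)))), 1e-9 * 25)
  ramp <- outer(1:60, 1:60, function(a, b) 3 * a + 2 * b)
  r <- dog_enhance(ramp)
  expect_lt(max(abs(r[25:35, 25:35])), 1e-9 * max(ramp))
  # single bright pixel: center positive, response sums to ~0
  px <- matrix(0, 41, 41); px[21, 21] <- 1
  resp <- dog_enhance(px)
  expect_gt(resp[21, 21], 0)
  expect_lt(abs(sum(resp)), 1e-9)
  expect_error(dog_enhance(px, s1 = 5, s2 = 1), class = "brainfish_config_error")
})

test_that("sample_std is the N-1 denominator formula", {
  expect_equal(sample_std(c(1, 2, 3)), 1)
  expect_equal(sample_std(c(5, 5, 5, 5)), 0)
  expect_equal(sample_std(c(1, 2, 3, 4)), 1.290994, tolerance = 1e-6)
  expect_error(sample_std(1), class = "brainfish_config_error")
})

test_that("label_mask reproduces the hand-computed stripe and its invariances", {
  A <- matrix(1, 64, 64)
  A[30:35, ] <- 100
  m1 <- matrix(FALSE, 64, 64)
  m1[20:45, 10:50] <- TRUE
  m2 <- label_mask(A, m1)
  # hand computation: the product is 100 on the stripe inside m1, 1 on the
  # rest of m1, 0 outside; mean + sd of the product falls between 1 and 100
  prod <- A * m1
  thr <- mean(prod) + sd(prod)
  expect_true(thr > 1 && thr < 100)
  expect_identical(m2, m1 & (A > 50))
  # scale invariance
  expect_identical(label_mask(100 * A, m1), m2)
  expect_identical(label_mask(0.01 * A, m1), m2)
  # constant A: strict inequality leaves m2 empty
  expect_equal(sum(label_mask(matrix(1, 64, 64), matrix(TRUE, 64, 64))), 0)
})

test_that("m2 is always a subset of m1 on random scenes", {
  set.seed(23)
  for (i in 1:100) {
    A <- matrix(runif(32 * 32, 0, 10), 32, 32)
    A[sample(1024, 40)] <- runif(40, 50, 200)
    m1 <- polygon_to_mask(cbind(runif(5, 1, 32), runif(5, 1, 32)), c(32, 32))
    m2 <- label_mask(dog_enhance(A, 1, 3), m1)
    expect_true(all(m1[m2]))
    # scale invariance under positive rescaling
    m2c <- label_mask(dog_enhance(A * 7.3, 1, 3), m1)
    expect_identical(m2, m2c)
  }
})

test_that("spots are assigned by pixel membership of the working mask", {
  m1 <- array(FALSE, c(3, 20, 20)); m1[, 5:15, 5:15] <- TRUE
  m2 <- array(FALSE, c(3, 20, 20)); m2[, 8:12, 8:12] <- TRUE
  mask <- compartment_mask(m1, m2, "dendrite")
  spots <- tibble::tibble(z = c(1, 2, 3, 1), y = c(10, 8.4, 14, 2),
                          x = c(10, 11.6, 14, 2))
  out <- assign_spots(spots, mask)
  # m2 governs where a label mask exists
  expect_equal(out$colocalized, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(count_colocalized(spots, mask), 2L)
  # calyx/soma: no label mask, m1 governs
  mask1 <- compartment_mask(m1, NULL, "calyx")
  expect_equal(count_colocalized(spots, mask1), 3L)
  # empty mask
  expect_equal(count_colocalized(spots, compartment_mask(array(FALSE, c(3, 20, 20)))), 0L)
  expect_error(compartment_mask(m2, m1), class = "brainfish_config_error")
})

test_that("ROI files round trip through both supported dialects", {
  vy <- c(4L, 4L, 14L, 14L)
  vx <- c(3L, 11L, 11L, 3L)
  pj <- tempfile(fileext = ".json")
  pi <- tempfile(fileext = ".roi")
  on.exit(unlink(c(pj, pi)), add = TRUE)
  jsonlite::write_json(list(name = "calyx", slice = 4,
                            vertices = cbind(vy, vx)), pj)
  rj <- read_roi_json(pj)
  expect_equal(rj$name, "calyx")
  expect_equal(unname(rj$vertices[, 1]), vy)
  write_imagej_roi(pi, vy, vx)
  ri <- read_imagej_roi(pi)
  expect_equal(unname(ri$vertices[, "y"]), vy)
  expect_equal(unname(ri$vertices[, "x"]), vx)
  # the two dialects rasterize identically
  expect_identical(polygon_to_mask(rj$vertices, c(20, 20)),
                   polygon_to_mask(ri$vertices, c(20, 20)))
})

test_that("build_compartment_mask broadcasts polygons and derives m2 per slice", {
  set.seed(31)
  label <- array(rpois(5 * 32 * 32, 2), c(5, 32, 32))
  label[, 14:18, ] <- label[, 14:18, ] + 60  # bright band
  v <- rbind(c(5, 5), c(5, 28), c(28, 28), c(28, 5))
  mk <- build_compartment_mask(c(5, 32, 32), v, label_channel = label,
                               name = "dendrite")
  expect_s3_class(mk, "compartment_mask")
  expect_true(all(mk$m1[mk$m2]))
  # the label band dominates m2
  band_frac <- sum(mk$m2[, 14:18, 5:28]) / sum(mk$m2)
  expect_gt(band_frac, 0.8)
})
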