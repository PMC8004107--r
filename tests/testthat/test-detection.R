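test_that("a constant image yields a null statistic field", {
  img <- array(35, c(14, 24, 24))
  s <- glrt_scan(img)
  expect_true(all(s$glrt_stat < 1e-9))
  expect_true(all(s$p_value > 0.999))
})

test_that("the statistic peaks at an injected spot and grows with amplitude", {
  params <- detection_params()
  pf <- psf_center_fraction()
  stats_at_center <- sapply(c(50, 100, 200), function(amp) {
    spot <- tibble::tibble(z = 10, y = 16, x = 16, photons = amp / pf)
    # noiseless: use the expected image (Poisson lambda) directly
    ey <- render_scene(scene_spec(shape = c(20, 32, 32), spots = spot,
                                  background = 10, seed = 1))
    # rebuild the expected image deterministically (no noise)
    img <- array(10, c(20, 32, 32)) +
      brainfish:::render_spots(c(20, 32, 32), spot, params$sigma_xy, params$sigma_z)
    s <- glrt_scan(img, params)
    peak <- s[which.max(s$glrt_stat), ]
    expect_equal(c(peak$z, peak$y, peak$x), c(10, 16, 16))
    peak$glrt_stat
  })
  expect_true(all(diff(stats_at_center) > 0))
})

test_that("glrt_scan rejects negative images and too-small images", {
  expect_error(glrt_scan(array(-1, c(14, 24, 24))), class = "brainfish_config_error")
  expect_error(glrt_scan(array(1, c(5, 24, 24))), class = "brainfish_range_error")
})

test_that("benjamini_hochberg reproduces the hand-worked step-up example", {
  expect_equal(benjamini_hochberg(c(0.001, 0.02, 0.8), 0.05),
               c(TRUE, TRUE, FALSE))
  expect_equal(benjamini_hochberg(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_equal(benjamini_hochberg(0.04, 0.05), TRUE)
  expect_identical(benjamini_hochberg(numeric(0), 0.05), logical(0))
  expect_error(benjamini_hochberg(c(0.5, 1.2), 0.05), class = "brainfish_config_error")
})

test_that("benjamini_hochberg matches the brute-force all-cutoffs oracle", {
  set.seed(42)
  for (i in 1:1000) {
    m <- sample(1:50, 1)
    p <- round(runif(m), sample(c(1, 2, 3, 6), 1))  # include heavy ties
    alpha <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    expect_identical(benjamini_hochberg(p, alpha), bh_bruteforce(p, alpha))
  }
})

test_that("duplicate suppression keeps one detection per molecule", {
  params <- detection_params()
  # two passed voxels 1 px apart: keep the stronger
  det <- tibble::tibble(z = c(10L, 10L), y = c(16L, 17L), x = c(16L, 16L),
                        glrt_stat = c(50, 40), p_value = c(1e-9, 1e-8))
  out <- suppress_duplicates(det, params)
  expect_equal(nrow(out), 1L)
  expect_equal(out$y, 16L)
  # 12 px apart: both kept
  det2 <- tibble::tibble(z = c(10L, 10L), y = c(16L, 28L), x = c(16L, 16L),
                         glrt_stat = c(50, 40), p_value = c(1e-9, 1e-8))
  expect_equal(nrow(suppress_duplicates(det2, params)), 2L)
  # ties broken lexicographically: equal stats 1 px apart keep the first
  det3 <- tibble::tibble(z = c(10L, 10L), y = c(17L, 16L), x = c(16L, 16L),
                         glrt_stat = c(40, 40), p_value = c(1e-8, 1e-8))
  out3 <- suppress_duplicates(det3, params)
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$y, 16L)
  # empty input passes through
  expect_equal(nrow(suppress_duplicates(det[0, ], params)), 0L)
})

test_that("detection around one injected spot collapses to a single call", {
  sim <- simulate_spot_stack(1, c(20, 48, 48), amplitude = 300,
                             background = 20, seed = 77)
  d <- detect_spots(sim$image)
  expect_equal(nrow(d), 1L)
  expect_lte(min_dist_to_truth(d, sim$truth), 2)
})

test_that("pure Poisson background yields no detections in most runs", {
  # reduced-size null check; the full-scale null behaviour is covered by
  # the FDR acceptance run
  n_runs <- 20
  n_nonzero <- 0L
  for (seed in seq_len(n_runs)) {
    set.seed(seed)
    img <- array(rpois(20 * 128 * 128, 20), c(20, 128, 128))
    d <- detect_spots(img)
    if (nrow(d) > 0) n_nonzero <- n_nonzero + 1L
  }
  expect_lte(n_nonzero, 3L)
})

test_that("detections at alpha = 0.01 are a subset of alpha = 0.05 detections", {
  sim <- simulate_spot_stack(30, c(20, 128, 128), amplitude = 300,
                             background = 20, seed = 31)
  d05 <- detect_spots(sim$image, detection_params(alpha = 0.05))
  d01 <- detect_spots(sim$image, detection_params(alpha = 0.01))
  k05 <- paste(d05$z, d05$y, d05$x)
  k01 <- paste(d01$z, d01$y, d01$x)
  expect_true(all(k01 %in% k05))
})

test_that("the statistic field is invariant under transposing x and y", {
  set.seed(55)
  img <- array(rpois(14 * 26 * 26, 15), c(14, 26, 26))
  img[7, 13, 14] <- img[7, 13, 14] + 60
  s1 <- attr(glrt_scan(img), "stat_array")
  s2 <- attr(glrt_scan(aperm(img, c(1, 3, 2))), "stat_array")
  expect_equal(s1, aperm(s2, c(1, 3, 2)), tolerance = 1e-10)
})

test_that("bright spots are detected with high recall and tight localization", {
  sim <- simulate_spot_stack(50, c(20, 192, 192), amplitude = 300,
                             background = 20, seed = 91)
  d <- detect_spots(sim$image)
  expect_gte(n_truth_matched(d, sim$truth, tol = 2), 45)
})
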