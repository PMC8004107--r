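#' Correct depth-dependent bleaching
#'
#' Fits the per-slice mean intensity to `mu(z) = a * exp(-k * z)` (z in
#' slices, 0 at the first slice) by least squares and divides slice `z` by
#' `exp(-k * z)`, so the first slice is unchanged. `k` may come out
#' negative when there is no bleaching.
#'
#' @param stack_channel 3D array `(z, y, x)` with >= 4 slices.
#' @return The corrected 3D array, with the fitted decay constant and
#'   amplitude attached as attributes `bleach_k` and `bleach_a`.
#' @export
bleach_correct <- function(stack_channel) {
  stopifnot(is.array(stack_channel), length(dim(stack_channel)) == 3L)
  nz <- dim(stack_channel)[1]
  if (nz < 4L) {
    abort("bleach correction needs at least 4 slices", class = "brainfish_range_error")
  }
  mu <- apply(stack_channel, 1, mean)
  if (any(mu <= 0)) {
    abort("non-positive slice means; cannot fit exponential bleaching",
          class = "brainfish_degenerate_error")
  }
  z <- seq_len(nz) - 1
  # log-linear start, then true least squares on the exponential
  lf <- lm(log(mu) ~ z)
  a0 <- exp(coef(lf)[[1]]); k0 <- -coef(lf)[[2]]
  fit <- tryCatch(
    suppressWarnings(nls(mu ~ a * exp(-k * z), start = list(a = a0, k = k0),
                         control = list(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    a_hat <- a0; k_hat <- k0
  } else {
    a_hat <- coef(fit)[["a"]]; k_hat <- coef(fit)[["k"]]
  }
  out <- stack_channel
  for (zi in seq_len(nz)) {
    out[zi, , ] <- stack_channel[zi, , ] / exp(-k_hat * (zi - 1))
  }
  attr(out, "bleach_k") <- k_hat
  attr(out, "bleach_a") <- a_hat
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the slowly varying background of a 2D slice as the grayscale
#' opening with a ball-shaped structuring element of the given radius and
#' subtracts it; output is clipped at 0. Structures much smaller than the
#' ball (smFISH spots, thin neurites) survive; broad background does not.
#'
#' The background is estimated on a mildly Gaussian-smoothed copy of the
#' slice (2 px): a morphological opening is a minimum filter, so on
#' shot-noise-limited data the raw opening sits several noise standard
#' deviations below the true background; smoothing before estimation is
#' the standard remedy (the smoothing stays far below the ball radius, so
#' structures the opening should remove are still removed). A constant
#' image maps to exactly zero.
#'
#' @param image2d 2D matrix.
#' @param radius ball radius in px (default 60).
#' @param presmooth_sigma smoothing width for the background estimate
#'   (default 2 px; 0 disables it).
#' @return Background-subtracted 2D matrix (non-negative).
#' @export
rolling_ball_subtract <- function(image2d, radius = 60, presmooth_sigma = 2) {
  stopifnot(is.matrix(image2d), radius >= 1)
  base <- if (presmooth_sigma > 0) {
    gauss_blur2d_cpp(image2d, presmooth_sigma)
  } else {
    image2d
  }
  bg <- rolling_ball_cpp(base, radius)
  out <- pmax(image2d - bg, 0)
  # suppress floating-point residue so flat regions are exactly zero
  out[out < 1e-9 * (1 + max(abs(image2d)))] <- 0
  out
}

#' Crop the central z-window of a stack
#'
#' Keeps `halfwidth` slices above and below the center slice (center =
#' `floor(depth / 2)` in 0-based terms), i.e. 11 slices by default.
#'
#' @param stack_channel 3D array `(z, y, x)`.
#' @param halfwidth slices on either side of the center (default 5).
#' @return 3D array with `2 * halfwidth + 1` slices.
#' @export
crop_center_z <- function(stack_channel, halfwidth = 5) {
  stopifnot(is.array(stack_channel), length(dim(stack_channel)) == 3L)
  nz <- dim(stack_channel)[1]
  if (nz < 2 * halfwidth + 1) {
    abort(sprintf("stack too shallow: %d slices < %d", nz, 2 * halfwidth + 1),
          class = "brainfish_range_error")
  }
  center <- nz %/% 2L + 1L
  stack_channel[(center - halfwidth):(center + halfwidth), , , drop = FALSE]
}

#' Summed and per-voxel intensity inside a compartment mask
#'
#' Sums the corrected intensity over the mask voxels and divides by the
#' voxel count, giving adu/voxel. Uses M2 where the mask has one
#' (dendrites), M1 otherwise; a 2D mask is broadcast across slices.
#'
#' @param corrected 3D array after bleach and background correction.
#' @param mask a [compartment_mask] or a logical array/matrix.
#' @return One-row tibble: `compartment, n_voxels, total_adu,
#'   adu_per_voxel`.
#' @export
intensity_per_voxel <- function(corrected, mask) {
  stopifnot(is.array(corrected), length(dim(corrected)) == 3L)
  if (inherits(mask, "compartment_mask")) {
    name <- mask$name
    m <- if (is.null(mask$m2)) mask$m1 else mask$m2
  } else {
    name <- "compartment"
    m <- mask > 0
  }
  d <- dim(corrected)
  if (length(dim(m)) == 2L) {
    m <- aperm(array(m, c(dim(m), d[1])), c(3, 1, 2))
  }
  if (!identical(dim(m), d)) {
    abort("mask shape does not match the corrected stack", class = "brainfish_config_error")
  }
  n <- sum(m)
  if (n == 0L) {
    abort("empty compartment mask", class = "brainfish_degenerate_error")
  }
  total <- sum(corrected[m])
  tibble(compartment = name, n_voxels = as.integer(n),
         total_adu = total, adu_per_voxel = total / n)
}

#' Fluorescent-protein intensity pipeline for one compartment
#'
#' Runs the fixed correction order — exponential bleach correction over the
#' full stack, per-slice rolling-ball background subtraction, central
#' z-crop — then records adu/voxel inside the compartment mask. The order
#' is fixed because bleach estimation needs the whole depth range and
#' background subtraction must precede summation.
#'
#' @param stack_channel 3D array of the protein channel (full depth).
#' @param mask a [compartment_mask] matching the cropped frame laterally;
#'   a 3D mask with the full depth is cropped alongside the data.
#' @param radius rolling-ball radius in px.
#' @param halfwidth central-crop half-width in slices.
#' @return One-row tibble as [intensity_per_voxel()], plus `bleach_k`.
#' @export
quantify_protein <- function(stack_channel, mask, radius = 60, halfwidth = 5) {
  corrected <- bleach_correct(stack_channel)
  k <- attr(corrected, "bleach_k")
  for (z in seq_len(dim(corrected)[1])) {
    corrected[z, , ] <- rolling_ball_subtract(corrected[z, , ], radius)
  }
  cropped <- crop_center_z(corrected, halfwidth)
  m <- mask
  if (inherits(mask, "compartment_mask") && length(dim(mask$m1)) == 3L &&
      dim(mask$m1)[1] == dim(stack_channel)[1]) {
    m <- compartment_mask(crop_center_z(mask$m1, halfwidth),
                          if (is.null(mask$m2)) NULL else crop_center_z(mask$m2, halfwidth),
                          mask$name)
  }
  res <- intensity_per_voxel(cropped, m)
  res$bleach_k <- k
  res
}
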