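#' Full width at half maximum of a Gaussian spot
#'
#' `fwhm = 2 * sqrt(2 * ln 2) * sigma`, exact.
#'
#' @param sigma_xy lateral Gaussian width in px (non-negative).
#' @return FWHM in px.
#' @export
fwhm <- function(sigma_xy) {
  if (any(sigma_xy < 0)) {
    abort("sigma must be non-negative", class = "brainfish_config_error")
  }
  2 * sqrt(2 * log(2)) * sigma_xy
}

# smallest odd integer >= 2 * (3 sigma + 1)
roi_side <- function(sigma_xy) {
  s <- ceiling(2 * (3 * sigma_xy + 1))
  as.integer(s + (s %% 2 == 0))
}

#' Extract the fitting ROI around a detection
#'
#' A square 2D box in the x-y plane of nominal size `2 * (3 sigma + 1)` px,
#' rounded up to the nearest odd integer so the detection sits on a center
#' pixel (`sigma = 1.39` gives an 11 px side).
#'
#' @param image2d 2D matrix `(y, x)`.
#' @param center integer `(y, x)` center pixel.
#' @param sigma_xy lateral width used to size the box.
#' @return 2D matrix of odd side length.
#' @export
extract_roi <- function(image2d, center, sigma_xy = 1.39) {
  stopifnot(is.matrix(image2d), length(center) == 2L)
  s <- roi_side(sigma_xy)
  h <- (s - 1L) %/% 2L
  y0 <- center[1] - h; y1 <- center[1] + h
  x0 <- center[2] - h; x1 <- center[2] + h
  if (y0 < 1 || x0 < 1 || y1 > nrow(image2d) || x1 > ncol(image2d)) {
    abort("fitting ROI is clipped by the image border", class = "brainfish_range_error")
  }
  image2d[y0:y1, x0:x1]
}

# expected pixel-integrated 2D Gaussian + background over an s x s ROI
# (local 1-based pixel coordinates)
roi_model <- function(s, x, y, photons, background, sigma) {
  i <- seq_len(s)
  ey <- pnorm((i - y + 0.5) / sigma) - pnorm((i - y - 0.5) / sigma)
  ex <- pnorm((i - x + 0.5) / sigma) - pnorm((i - x - 0.5) / sigma)
  background + photons * outer(ey, ex)
}

neg_loglik_roi <- function(par, dat, side, sigma_fixed = NULL) {
  x <- par[1]; y <- par[2]
  photons <- exp(par[3]); background <- exp(par[4])
  sigma <- if (is.null(sigma_fixed)) exp(par[5]) else sigma_fixed
  mu <- roi_model(side, x, y, photons, background, sigma)
  sum(mu) - sum(dat[dat > 0] * log(mu[dat > 0]))
}

fit_init <- function(d) {
  s <- nrow(d)
  border <- c(d[1, ], d[s, ], d[, 1], d[, s])
  b0 <- max(stats::median(border), 1e-6)
  resid <- pmax(d - b0, 0)
  tot <- sum(resid)
  if (tot > 0) {
    y0 <- sum(row(d) * resid) / tot
    x0 <- sum(col(d) * resid) / tot
  } else {
    y0 <- (s + 1) / 2
    x0 <- (s + 1) / 2
  }
  n0 <- max(tot, 1e-6)
  list(x = x0, y = y0, photons = n0, background = b0)
}

#' Maximum-likelihood refinement of a spot on a 2D cross-section
#'
#' Maximizes the Poisson likelihood of a pixel-integrated 2D Gaussian plus
#' constant background over the ROI, estimating subpixel position, signal
#' photons, background photons per pixel and (unless fixed) the lateral
#' width. Initialization is deterministic: position from the
#' background-subtracted centroid, background from the ROI border median,
#' photons from the residual sum, width from `sigma_init`.
#'
#' @param roi 2D matrix (non-negative counts), odd side length.
#' @param sigma_init initial lateral width (px).
#' @param sigma_fixed if non-`NULL`, the width is held at this value and
#'   only position, photons and background are fitted.
#' @return One-row tibble: `x, y` (subpixel, ROI-local 1-based), `photons`,
#'   `background`, `sigma_xy`, `fwhm`, `signal_background_ratio` (fitted
#'   peak amplitude `photons / (2 pi sigma^2)` over fitted background),
#'   `converged`, `loglik`.
#' @export
mle_fit_spot <- function(roi, sigma_init = 1.39, sigma_fixed = NULL) {
  stopifnot(is.matrix(roi), nrow(roi) == ncol(roi))
  if (any(roi < 0)) {
    abort("ROI must be non-negative", class = "brainfish_config_error")
  }
  s <- nrow(roi)
  init <- fit_init(roi)
  par0 <- c(init$x, init$y, log(init$photons), log(init$background))
  lower <- c(0.5, 0.5, log(1e-9), log(1e-9))
  upper <- c(s + 0.5, s + 0.5, log(1e9), log(1e9))
  if (is.null(sigma_fixed)) {
    par0 <- c(par0, log(sigma_init))
    lower <- c(lower, log(0.2))
    upper <- c(upper, log(s))
  }
  fit <- nlminb(par0, neg_loglik_roi, dat = roi, side = s,
                sigma_fixed = sigma_fixed, lower = lower, upper = upper,
                control = list(iter.max = 500, eval.max = 1000,
                               rel.tol = 1e-12, x.tol = 1e-12))
  sigma <- if (is.null(sigma_fixed)) exp(fit$par[5]) else sigma_fixed
  photons <- exp(fit$par[3])
  background <- exp(fit$par[4])
  # nlminb termination: accept any gradient-based convergence declaration
  # (including "singular convergence", common when the width is weakly
  # identified at low photon counts); reject false convergence / limits
  ok <- fit$convergence == 0 ||
    grepl("relative convergence|absolute function convergence|X-convergence|singular convergence",
          fit$message %||% "")
  tibble(
    x = fit$par[1],
    y = fit$par[2],
    photons = photons,
    background = background,
    sigma_xy = sigma,
    fwhm = fwhm(sigma),
    signal_background_ratio = photons / (2 * pi * sigma^2) / background,
    converged = ok,
    loglik = -fit$objective
  )
}

#' Fit all detected spots on their detection slices
#'
#' For each detection, extracts the fitting ROI on the z-slice where the
#' spot was detected (spots whose ROI is clipped by the border are dropped
#' with a message) and runs [mle_fit_spot()]. Positions are returned in
#' image coordinates.
#'
#' @param image 3D array `(z, y, x)`.
#' @param detections tibble with integer `z, y, x` (from [detect_spots()]).
#' @param params a [detection_params] object (supplies `sigma_xy`).
#' @return A tibble of class `bf_fits`: `z, y, x` (x, y subpixel),
#'   `photons, background, sigma_xy, fwhm, signal_background_ratio,
#'   converged`.
#' @export
fit_spots <- function(image, detections, params = detection_params()) {
  stopifnot(is.array(image), length(dim(image)) == 3L)
  h <- (roi_side(params$sigma_xy) - 1L) %/% 2L
  d <- dim(image)
  rows <- vector("list", nrow(detections))
  n_drop <- 0L
  for (i in seq_len(nrow(detections))) {
    z <- detections$z[i]; yc <- detections$y[i]; xc <- detections$x[i]
    if (yc - h < 1 || xc - h < 1 || yc + h > d[2] || xc + h > d[3]) {
      n_drop <- n_drop + 1L
      next
    }
    roi <- image[z, (yc - h):(yc + h), (xc - h):(xc + h)]
    f <- mle_fit_spot(roi, sigma_init = params$sigma_xy)
    f$x <- f$x + xc - h - 1
    f$y <- f$y + yc - h - 1
    f$z <- z
    rows[[i]] <- f
  }
  if (n_drop > 0) {
    message(sprintf("%d spot(s) too close to the border for fitting; dropped", n_drop))
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(x = numeric(0), y = numeric(0), photons = numeric(0),
                  background = numeric(0), sigma_xy = numeric(0),
                  fwhm = numeric(0), signal_background_ratio = numeric(0),
                  converged = logical(0), loglik = numeric(0), z = integer(0))
  }
  out <- out[, c("z", "y", "x", "photons", "background", "sigma_xy", "fwhm",
                 "signal_background_ratio", "converged", "loglik")]
  class(out) <- c("bf_fits", class(out))
  out
}

#' Discard fits wider than a plausible single molecule
#'
#' Spurious detections (autofluorescent blobs, out-of-focus debris) fit
#' with large widths; all fits with `sigma_xy` strictly greater than
#' `max_width` px are discarded. Non-converged fits are discarded too.
#'
#' @param fits a `bf_fits` tibble.
#' @param max_width width cutoff in px (default 5).
#' @return The filtered tibble (always a subset; idempotent).
#' @export
filter_by_width <- function(fits, max_width = 5) {
  keep <- fits$sigma_xy <= max_width
  if ("converged" %in% names(fits)) keep <- keep & fits$converged
  out <- fits[keep, ]
  class(out) <- unique(c("bf_fits", class(out)))
  out
}

# sum-of-squares fit of the pixel-integrated Gaussian (nonlinear least
# squares), used for transcription-focus widths
lsq_fit_sigma <- function(roi, sigma_init) {
  s <- nrow(roi)
  init <- fit_init(roi)
  par0 <- c(init$x, init$y, log(init$photons), log(init$background), log(sigma_init))
  obj <- function(par) {
    mu <- roi_model(s, par[1], par[2], exp(par[3]), exp(par[4]), exp(par[5]))
    sum((roi - mu)^2)
  }
  fit <- nlminb(par0, obj,
                lower = c(0.5, 0.5, log(1e-9), log(1e-9), log(0.2)),
                upper = c(s + 0.5, s + 0.5, log(1e9), log(1e9), log(s)),
                control = list(iter.max = 500, eval.max = 1000, rel.tol = 1e-12))
  list(x = fit$par[1], y = fit$par[2], sigma = exp(fit$par[5]),
       converged = fit$convergence == 0)
}

#' Characterize the transcription focus of a soma
#'
#' The nuclear transcription site appears as the brightest punctum in the
#' soma, wider than a single mRNA. The spot with the highest fitted photon
#' count is selected; its width is re-estimated by nonlinear least squares
#' on an enlarged ROI (sized for `3 x` the single-molecule width), and
#' brightness and background are then recomputed by the Poisson MLE with
#' that width held fixed.
#'
#' @param soma_spots `bf_fits` tibble of spots inside the soma mask.
#' @param image2d the 2D slice the focus sits on.
#' @param params a [detection_params] (supplies the single-molecule width).
#' @param soma_id optional label carried into the result.
#' @return One-row tibble: `soma_id, z, y, x, sigma_xy, photons,
#'   background, signal_background_ratio, is_focus_width` (`FALSE` flags a
#'   fitted width not exceeding the single-molecule default — a punctum
#'   that does not look like a focus). Zero-row tibble if `soma_spots` is
#'   empty (a no-focus soma, not an error).
#' @export
fit_transcription_focus <- function(soma_spots, image2d,
                                    params = detection_params(),
                                    soma_id = NA_character_) {
  empty <- tibble(soma_id = character(0), z = integer(0), y = numeric(0),
                  x = numeric(0), sigma_xy = numeric(0), photons = numeric(0),
                  background = numeric(0), signal_background_ratio = numeric(0),
                  is_focus_width = logical(0))
  if (nrow(soma_spots) == 0L) return(empty)
  best <- soma_spots[which.max(soma_spots$photons), ]
  sigma_init <- 3 * params$sigma_xy
  h <- (roi_side(sigma_init) - 1L) %/% 2L
  yc <- as.integer(round(best$y)); xc <- as.integer(round(best$x))
  if (yc - h < 1 || xc - h < 1 || yc + h > nrow(image2d) || xc + h > ncol(image2d)) {
    abort("focus ROI is clipped by the image border", class = "brainfish_range_error")
  }
  roi <- image2d[(yc - h):(yc + h), (xc - h):(xc + h)]
  ls <- lsq_fit_sigma(roi, sigma_init)
  mle <- mle_fit_spot(roi, sigma_fixed = ls$sigma)
  tibble(
    soma_id = as.character(soma_id),
    z = if ("z" %in% names(best)) best$z else NA_integer_,
    y = mle$y + yc - h - 1,
    x = mle$x + xc - h - 1,
    sigma_xy = ls$sigma,
    photons = mle$photons,
    background = mle$background,
    signal_background_ratio = mle$signal_background_ratio,
    is_focus_width = ls$sigma > params$sigma_xy
  )
}
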