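#' 3D affine transform
#'
#' A linear map plus translation acting on 1-based voxel coordinates in
#' `(z, y, x)` order: `p' = M p + t`. Used to model the chromatic shift
#' between imaging channels.
#'
#' @param matrix 3x3 linear part (dimensionless), rows/cols ordered (z, y, x).
#' @param translation length-3 translation in voxel units (z, y, x).
#' @return An object of class `affine3d`.
#' @export
affine3d <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L)
  if (abs(det(matrix)) < 1e-12) {
    abort("affine matrix is singular", class = "brainfish_config_error")
  }
  structure(list(matrix = matrix, translation = translation), class = "affine3d")
}

#' @export
print.affine3d <- function(x, ...) {
  cat("<affine3d> translation (z,y,x):", sprintf("%.4f", x$translation), "\n")
  cat("linear part:\n")
  print(round(x$matrix, 6))
  invisible(x)
}

#' Invert an affine transform
#' @param t an [affine3d].
#' @return the inverse [affine3d].
#' @export
affine_invert <- function(t) {
  m_inv <- solve(t$matrix)
  affine3d(m_inv, -as.vector(m_inv %*% t$translation))
}

#' Compose two affine transforms
#'
#' `affine_compose(a, b)` is the map `p -> a(b(p))`.
#' @param a,b [affine3d] objects.
#' @return the composed [affine3d].
#' @export
affine_compose <- function(a, b) {
  affine3d(a$matrix %*% b$matrix,
           as.vector(a$matrix %*% b$translation) + a$translation)
}

#' Serialize / deserialize a transform as JSON
#'
#' Row-major 3x3 linear part plus translation, both in `(z, y, x)` order.
#' @param t an [affine3d].
#' @param path file path.
#' @return `write_affine_json()` returns `path` invisibly;
#'   `read_affine_json()` returns an [affine3d].
#' @export
write_affine_json <- function(t, path) {
  jsonlite::write_json(
    list(matrix = as.vector(t(t$matrix)), translation = t$translation),
    path, auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' @rdname write_affine_json
#' @export
read_affine_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine3d(t(matrix(obj$matrix, 3, 3)), obj$translation)
}

#' Warp a 3D image under an affine transform
#'
#' Pull-warping with trilinear interpolation: the output voxel at `p`
#' samples the input at `M p + t`. Voxels that map outside the input are 0.
#'
#' @param image 3D array `(z, y, x)`.
#' @param t an [affine3d].
#' @return warped 3D array, same shape.
#' @export
apply_transform <- function(image, t) {
  stopifnot(is.array(image), length(dim(image)) == 3L)
  if (abs(det(t$matrix)) < 1e-12) {
    abort("affine matrix is singular", class = "brainfish_config_error")
  }
  if (identical(t$matrix, diag(3)) && all(t$translation == 0)) {
    return(image)
  }
  warp_affine_cpp(image, dim(image), as.vector(t(t$matrix)), t$translation)
}

downsample2 <- function(img) {
  d <- dim(img)
  d2 <- pmax(d %/% 2L, 1L)
  out <- array(0, d2)
  for (z in seq_len(d2[1])) {
    zi <- if (d[1] >= 2 * z) (2 * z - 1):(2 * z) else 2 * z - 1
    sl <- img[zi, , , drop = FALSE]
    sl <- apply(sl, c(2, 3), mean)
    ny2 <- d2[2]; nx2 <- d2[3]
    sl <- sl[seq_len(2 * ny2), seq_len(2 * nx2), drop = FALSE]
    sl <- (sl[seq(1, 2 * ny2, 2), , drop = FALSE] + sl[seq(2, 2 * ny2, 2), , drop = FALSE]) / 2
    sl <- (sl[, seq(1, 2 * nx2, 2), drop = FALSE] + sl[, seq(2, 2 * nx2, 2), drop = FALSE]) / 2
    out[z, , ] <- sl
  }
  out
}

# mild 3D Gaussian smoothing (separable; reflective laterally, clamped
# along z) used to band-limit calibration images before MSE registration
smooth3d <- function(img, sigma) {
  d <- dim(img)
  for (z in seq_len(d[1])) img[z, , ] <- gauss_blur2d_cpp(img[z, , ], sigma)
  r <- ceiling(4 * sigma)
  k <- exp(-0.5 * ((-r):r)^2 / sigma^2)
  k <- k / sum(k)
  out <- array(0, d)
  for (i in (-r):r) {
    zi <- pmin(pmax(seq_len(d[1]) + i, 1), d[1])
    out <- out + k[i + r + 1] * img[zi, , , drop = FALSE]
  }
  out
}

# convert a transform between pyramid levels: p_fine = f * p_coarse - c * 1,
# with c = (f - 1) / 2 (block-averaged levels, 1-based coordinates)
transform_to_level <- function(t, f) {
  cc <- (f - 1) / 2
  affine3d(t$matrix, (t$translation + cc * (1 - as.vector(t$matrix %*% rep(1, 3)))) / f)
}
transform_from_level <- function(t, f) {
  cc <- (f - 1) / 2
  affine3d(t$matrix, f * t$translation - cc * (1 - as.vector(t$matrix %*% rep(1, 3))))
}

# MSE over a fixed interior region (margin sized for the expected shift
# range) so the objective is smooth in the transform parameters
mse_objective <- function(ref, moving, margin = c(6L, 6L, 6L)) {
  d <- dim(ref)
  margin <- pmin(margin, (d - 1L) %/% 3L)
  zi <- (1 + margin[1]):(d[1] - margin[1])
  yi <- (1 + margin[2]):(d[2] - margin[2])
  xi <- (1 + margin[3]):(d[3] - margin[3])
  ref_in <- ref[zi, yi, xi]
  function(m_vec, t_vec) {
    m <- matrix(m_vec, 3, 3)
    if (abs(det(m)) < 1e-12) return(1e30)
    w <- warp_affine_cpp(moving, dim(moving), as.vector(t(m)), t_vec)
    mean((ref_in - w[zi, yi, xi])^2)
  }
}

#' Estimate the chromatic shift between two calibration channels
#'
#' Finds the affine transform minimizing the mean squared intensity error
#' between a reference nuclear-stain image and the warped moving one
#' (`apply_transform(moving, t)` matches `ref`). The optimization is
#' hierarchical (translation, then translation + axis scales, then the full
#' 12-parameter affine) over a 3-level coarse-to-fine pyramid with a fixed
#' iteration budget, so results are deterministic given the inputs. Both
#' images are band-limited with a mild Gaussian (`presmooth_sigma`) first —
#' nuclei are much larger than a voxel, so this suppresses shot noise
#' without moving the registration optimum.
#'
#' @param ref_calib 3D reference calibration image.
#' @param moving_calib 3D moving calibration image, same shape.
#' @param max_iter per-stage iteration cap for the optimizer.
#' @param presmooth_sigma width (voxels) of the band-limiting Gaussian;
#'   0 disables it.
#' @return An [affine3d] mapping reference coordinates into the moving
#'   image (the transform to pass to [apply_transform()] to align
#'   `moving_calib`, and the data channel imaged with it, onto the
#'   reference).
#' @export
estimate_chromatic_shift <- function(ref_calib, moving_calib, max_iter = 200L,
                                     presmooth_sigma = 1) {
  stopifnot(identical(dim(ref_calib), dim(moving_calib)))
  if (sd(ref_calib) < 1e-12 || sd(moving_calib) < 1e-12) {
    abort("calibration image has zero variance; cannot register",
          class = "brainfish_degenerate_error")
  }
  if (presmooth_sigma > 0) {
    ref_calib <- smooth3d(ref_calib, presmooth_sigma)
    moving_calib <- smooth3d(moving_calib, presmooth_sigma)
  }
  # pyramid (coarsest first)
  levels <- list(list(ref = ref_calib, mov = moving_calib, f = 1))
  while (length(levels) < 3L && all(dim(levels[[1]]$ref) >= 16L)) {
    top <- levels[[1]]
    levels <- c(list(list(ref = downsample2(top$ref), mov = downsample2(top$mov),
                          f = top$f * 2)), levels)
  }
  t_cur <- affine3d()
  first <- TRUE
  for (lev in levels) {
    t_lev <- transform_to_level(t_cur, lev$f)
    obj <- mse_objective(lev$ref, lev$mov)
    m0 <- as.vector(t_lev$matrix)
    tr0 <- t_lev$translation
    if (first) {
      # deterministic integer-translation sweep at the coarsest level so
      # the local optimizer starts in the right basin
      grid <- expand.grid(z = -3:3, y = -3:3, x = -3:3)
      vals <- apply(grid, 1, function(g) obj(m0, tr0 + as.numeric(g)))
      tr0 <- tr0 + as.numeric(grid[which.min(vals), ])
      first <- FALSE
    }
    # stage 1: translation only
    r1 <- optim(tr0, function(p) obj(m0, p), method = "Nelder-Mead",
                control = list(maxit = max_iter, reltol = 1e-12))
    tr0 <- r1$par
    # stage 2: translation + per-axis scale
    r2 <- optim(c(tr0, m0[c(1, 5, 9)]),
                function(p) {
                  m <- m0; m[c(1, 5, 9)] <- p[4:6]
                  obj(m, p[1:3])
                },
                method = "Nelder-Mead",
                control = list(maxit = 2L * max_iter, reltol = 1e-12,
                               parscale = c(1, 1, 1, 0.01, 0.01, 0.01)))
    tr0 <- r2$par[1:3]
    m0[c(1, 5, 9)] <- r2$par[4:6]
    # stage 3: full affine; a BFGS restart resets the Hessian approximation
    # and reliably polishes the last fraction of a pixel
    n_polish <- if (lev$f == 1) 2L else 1L
    for (rep_i in seq_len(n_polish)) {
      r3 <- optim(c(tr0, m0),
                  function(p) obj(p[4:12], p[1:3]),
                  method = "BFGS",
                  control = list(maxit = max_iter, reltol = 1e-14,
                                 parscale = c(1, 1, 1, rep(0.01, 9)),
                                 ndeps = rep(1e-4, 12)))
      tr0 <- r3$par[1:3]
      m0 <- r3$par[4:12]
    }
    t_cur <- transform_from_level(affine3d(matrix(m0, 3, 3), tr0), lev$f)
  }
  t_cur
}
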