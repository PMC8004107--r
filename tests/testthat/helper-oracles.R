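# Independent oracles and small utilities shared across the suite.

# pixel-integrated 2D Gaussian + background rendered over an s x s ROI
# (same physical model as the fitter, written independently)
render_roi_2d <- function(s, x, y, photons, background, sigma) {
  i <- seq_len(s)
  ey <- pnorm((i - y + 0.5) / sigma) - pnorm((i - y - 0.5) / sigma)
  ex <- pnorm((i - x + 0.5) / sigma) - pnorm((i - x - 0.5) / sigma)
  background + photons * outer(ey, ex)
}

# Cramer-Rao lower bounds from the numerically differentiated Fisher
# information of the Poisson pixel-integrated Gaussian model
crlb_roi <- function(s, x, y, photons, background, sigma) {
  th <- c(x, y, photons, background, sigma)
  mu_fn <- function(t) render_roi_2d(s, t[1], t[2], t[3], t[4], t[5])
  J <- sapply(seq_along(th), function(j) {
    h <- max(1e-6, 1e-6 * abs(th[j]))
    tp <- th; tp[j] <- th[j] + h
    tm <- th; tm[j] <- th[j] - h
    (mu_fn(tp) - mu_fn(tm)) / (2 * h)
  })
  mu <- as.vector(mu_fn(th))
  fisher <- t(J) %*% (J / mu)
  se <- sqrt(diag(solve(fisher)))
  names(se) <- c("x", "y", "photons", "background", "sigma")
  se
}

# brute-force BH step-up: try every cut-off k explicitly
bh_bruteforce <- function(p, alpha) {
  m <- length(p)
  if (m == 0L) return(logical(0))
  o <- order(p)
  ps <- p[o]
  ks <- which(ps <= seq_len(m) * alpha / m)
  keep <- logical(m)
  if (length(ks)) keep[o[seq_len(max(ks))]] <- TRUE
  keep
}

# per-point even-odd polygon test (boundary-inclusive), one point at a time
point_in_poly_bruteforce <- function(py, px, vy, vx) {
  n <- length(vy)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    y1 <- vy[j]; x1 <- vx[j]; y2 <- vy[i]; x2 <- vx[i]
    # on-segment check
    dy <- y2 - y1; dx <- x2 - x1
    len2 <- dy^2 + dx^2
    if (len2 > 0) {
      tt <- ((py - y1) * dy + (px - x1) * dx) / len2
      tt <- min(max(tt, 0), 1)
      if ((py - (y1 + tt * dy))^2 + (px - (x1 + tt * dx))^2 < 1e-18) return(TRUE)
    } else if ((py - y1)^2 + (px - x1)^2 < 1e-18) {
      return(TRUE)
    }
    if ((y1 > py) != (y2 > py)) {
      xi <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      if (px < xi) inside <- !inside
    }
    j <- i
  }
  inside
}

# minimal ImageJ .roi writer (polygon type) used to exercise the reader;
# binary fixture files are built at test time, never shipped
write_imagej_roi <- function(path, vy, vx) {
  top <- min(vy) - 1L; left <- min(vx) - 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("Iout", con, eos = NULL)
  writeBin(227L, con, size = 2, endian = "big")      # version
  writeBin(as.raw(c(0, 0)), con)                     # type polygon (0) + pad
  writeBin(as.integer(c(top, left, max(vy), max(vx))), con, size = 2, endian = "big")
  writeBin(length(vy), con, size = 2, endian = "big")
  seek(con, 64)
  writeBin(as.integer(vx - 1L - left), con, size = 2, endian = "big")
  writeBin(as.integer(vy - 1L - top), con, size = 2, endian = "big")
  invisible(path)
}

# 3D nearest-truth distance for each detection
min_dist_to_truth <- function(det, truth) {
  vapply(seq_len(nrow(det)), function(i) {
    min(sqrt((truth$z - det$z[i])^2 + (truth$y - det$y[i])^2 +
               (truth$x - det$x[i])^2))
  }, numeric(1))
}

# number of truth spots matched by at least one detection within tol
n_truth_matched <- function(det, truth, tol = 2) {
  sum(vapply(seq_len(nrow(truth)), function(i) {
    any(sqrt((det$z - truth$z[i])^2 + (det$y - truth$y[i])^2 +
               (det$x - truth$x[i])^2) <= tol)
  }, logical(1)))
}
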