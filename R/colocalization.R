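#' Rasterize a closed polygon to a pixel mask
#'
#' A pixel is inside when its center satisfies the even-odd rule for the
#' closed polygon; centers lying exactly on an edge count as inside. This
#' is the M1 mask built from a hand-drawn compartment contour.
#'
#' @param vertices numeric matrix with columns `(y, x)` (>= 3 rows), pixel
#'   coordinates (1-based centers).
#' @param shape integer `(ny, nx)` of the target frame.
#' @return Logical `(ny, nx)` matrix.
#' @export
polygon_to_mask <- function(vertices, shape) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) {
    abort("a polygon needs at least 3 vertices", class = "brainfish_config_error")
  }
  ny <- shape[1]; nx <- shape[2]
  py <- rep(seq_len(ny), times = nx)
  px <- rep(seq_len(nx), each = ny)
  inside <- rep(FALSE, ny * nx)
  on_edge <- rep(FALSE, ny * nx)
  vy <- vertices[, 1]; vx <- vertices[, 2]
  n <- length(vy)
  j <- n
  for (i in seq_len(n)) {
    y1 <- vy[j]; x1 <- vx[j]; y2 <- vy[i]; x2 <- vx[i]
    # even-odd crossing of the horizontal ray towards +x
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xi <- x1 + (py[crosses] - y1) * (x2 - x1) / (y2 - y1)
      hit <- px[crosses] < xi
      inside[crosses][hit] <- !inside[crosses][hit]
    }
    # boundary-inclusive: point on the segment
    dy <- y2 - y1; dx <- x2 - x1
    len2 <- dy * dy + dx * dx
    if (len2 > 0) {
      t_par <- ((py - y1) * dy + (px - x1) * dx) / len2
      t_par <- pmin(pmax(t_par, 0), 1)
      d2 <- (py - (y1 + t_par * dy))^2 + (px - (x1 + t_par * dx))^2
      on_edge <- on_edge | d2 < 1e-18
    } else {
      on_edge <- on_edge | ((py - y1)^2 + (px - x1)^2 < 1e-18)
    }
    j <- i
  }
  matrix(inside | on_edge, ny, nx)
}

#' Difference-of-Gaussians enhancement
#'
#' Band-pass enhancement of the membrane-label channel before
#' thresholding: `Gaussian(s1) - Gaussian(s2)` of the input, with
#' reflective boundary handling. Annihilates constants and (away from the
#' border) linear ramps.
#'
#' @param image2d 2D matrix.
#' @param s1 narrow Gaussian width in px (default 1).
#' @param s2 wide Gaussian width in px (default 5); must exceed `s1`.
#' @return 2D matrix of the band-pass response.
#' @export
dog_enhance <- function(image2d, s1 = 1, s2 = 5) {
  stopifnot(is.matrix(image2d))
  if (s1 >= s2) {
    abort("DoG requires s1 < s2", class = "brainfish_config_error")
  }
  gauss_blur2d_cpp(image2d, s1) - gauss_blur2d_cpp(image2d, s2)
}

#' Sample standard deviation
#'
#' `sqrt(sum((x - mean(x))^2) / (N - 1))`, the N-1 denominator form used
#' in the mask threshold.
#'
#' @param values numeric vector, length >= 2.
#' @return the sample standard deviation.
#' @export
sample_std <- function(values) {
  if (length(values) < 2L) {
    abort("sample_std needs at least 2 values", class = "brainfish_config_error")
  }
  sd(values)
}

#' Threshold the enhanced label image inside a drawn region
#'
#' Computes `M2 = (A o M1) > mean(A o M1) + std(A o M1)` where `o` is the
#' Hadamard product, `A` the DoG-enhanced label image and `M1` the drawn
#' mask; mean and sample standard deviation are taken over all pixels of
#' the product image (`domain = "all"`, the default) or only over pixels
#' inside M1 (`domain = "within_m1"`). The strict inequality is intersected
#' with M1 so `M2` is always a subset of `M1`.
#'
#' @param enhanced 2D matrix `A` (DoG-enhanced label slice).
#' @param m1 logical 2D matrix, the drawn-region mask.
#' @param domain where the threshold statistics are computed.
#' @return Logical 2D matrix `M2`.
#' @export
label_mask <- function(enhanced, m1, domain = c("all", "within_m1")) {
  domain <- match.arg(domain)
  stopifnot(identical(dim(enhanced), dim(m1)))
  prod_img <- enhanced * m1
  vals <- if (domain == "all") as.vector(prod_img) else prod_img[m1]
  thr <- mean(vals) + sample_std(vals)
  (prod_img > thr) & m1
}

#' Compartment mask pair
#'
#' Per-slice masks for one neuronal compartment: `m1` is the hand-drawn
#' region, `m2` the label-positive subset of it (present only where a
#' membrane-label channel exists — dendrites; calyx and soma use `m1`
#' alone).
#'
#' @param m1 logical 2D matrix or 3D array (z, y, x).
#' @param m2 optional logical mask, same shape, subset of `m1`.
#' @param name compartment label (e.g. `"gamma5beta'2a_dendrite"`).
#' @return An object of class `compartment_mask`.
#' @export
compartment_mask <- function(m1, m2 = NULL, name = "compartment") {
  m1 <- m1 > 0
  if (!is.null(m2)) {
    m2 <- m2 > 0
    stopifnot(identical(dim(m1), dim(m2)))
    if (any(m2 & !m1)) {
      abort("m2 must be a voxelwise subset of m1", class = "brainfish_config_error")
    }
  }
  structure(list(m1 = m1, m2 = m2, name = name), class = "compartment_mask")
}

#' @export
print.compartment_mask <- function(x, ...) {
  cat(sprintf("<compartment_mask> '%s': %d px in m1%s\n", x$name, sum(x$m1),
              if (is.null(x$m2)) " (no label mask)" else sprintf(", %d px in m2", sum(x$m2))))
  invisible(x)
}

#' Build a compartment mask from a polygon and (optionally) a label channel
#'
#' Broadcasts the drawn polygon across every slice of the substack to make
#' M1; where a membrane-label channel is given, each slice is DoG-enhanced
#' and thresholded to make M2.
#'
#' @param shape `(nz, ny, nx)` of the analyzed substack.
#' @param vertices polygon vertex matrix `(y, x)`, or a list of per-slice
#'   vertex matrices of length `nz`.
#' @param label_channel optional 3D array of the membrane label.
#' @param name compartment label.
#' @param s1,s2 DoG widths in px.
#' @param domain threshold-statistics domain, see [label_mask()].
#' @return A [compartment_mask] with 3D `m1` (and `m2` when a label
#'   channel is supplied).
#' @export
build_compartment_mask <- function(shape, vertices, label_channel = NULL,
                                   name = "compartment", s1 = 1, s2 = 5,
                                   domain = "all") {
  nz <- shape[1]
  per_slice <- is.list(vertices) && !is.matrix(vertices)
  if (per_slice && length(vertices) != nz) {
    abort("per-slice polygons must match the number of slices",
          class = "brainfish_config_error")
  }
  m1 <- array(FALSE, shape)
  for (z in seq_len(nz)) {
    v <- if (per_slice) vertices[[z]] else vertices
    m1[z, , ] <- polygon_to_mask(v, shape[2:3])
  }
  m2 <- NULL
  if (!is.null(label_channel)) {
    stopifnot(identical(dim(label_channel), as.integer(shape)))
    m2 <- array(FALSE, shape)
    for (z in seq_len(nz)) {
      a <- dog_enhance(label_channel[z, , ], s1, s2)
      m2[z, , ] <- label_mask(a, m1[z, , ], domain = domain)
    }
  }
  compartment_mask(m1, m2, name)
}

#' Assign spots to a compartment
#'
#' A spot co-localizes with the compartment when its rounded `(y, x)`
#' position falls on a `TRUE` pixel of the compartment's working mask on
#' its detection slice — M2 where a label mask exists (dendrites), M1
#' otherwise (calyx, soma).
#'
#' @param spots tibble with `z, y, x` (subpixel allowed).
#' @param mask a [compartment_mask]; 2D masks are broadcast across slices.
#' @return The input tibble with logical `colocalized` and the
#'   `compartment` name added.
#' @export
assign_spots <- function(spots, mask) {
  use <- if (is.null(mask$m2)) mask$m1 else mask$m2
  is3d <- length(dim(use)) == 3L
  ny <- if (is3d) dim(use)[2] else nrow(use)
  nx <- if (is3d) dim(use)[3] else ncol(use)
  coloc <- logical(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    ry <- as.integer(round(spots$y[i]))
    rx <- as.integer(round(spots$x[i]))
    if (ry < 1 || rx < 1 || ry > ny || rx > nx) next
    coloc[i] <- if (is3d) use[spots$z[i], ry, rx] else use[ry, rx]
  }
  out <- spots
  out$colocalized <- coloc
  out$compartment <- mask$name
  out
}

#' Count spots co-localized with a compartment
#' @inheritParams assign_spots
#' @return Integer count.
#' @export
count_colocalized <- function(spots, mask) {
  sum(assign_spots(spots, mask)$colocalized)
}

#' Read a polygon ROI
#'
#' `read_roi_json()` reads the plain JSON dialect
#' `{name, slice?, vertices: [[y, x], ...]}`. `read_imagej_roi()` reads a
#' binary ImageJ `.roi` file of polygon type (coordinates are converted to
#' 1-based pixel centers).
#'
#' @param path file path.
#' @return A list with `name`, `slice` (or `NA`) and a numeric `vertices`
#'   matrix with columns `(y, x)`.
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- obj$vertices
  if (is.null(dim(v))) v <- do.call(rbind, obj$vertices)
  list(name = obj$name %||% basename(path),
       slice = obj$slice %||% NA_integer_,
       vertices = matrix(as.numeric(v), ncol = 2,
                         dimnames = list(NULL, c("y", "x"))))
}

#' @rdname read_roi_json
#' @export
read_imagej_roi <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "Iout")) {
    abort(sprintf("'%s' is not an ImageJ ROI file", path), class = "brainfish_io_error")
  }
  readBin(con, "integer", 1, size = 2, endian = "big")          # version
  type <- readBin(con, "integer", 1, size = 1, signed = FALSE)  # roi type
  readBin(con, "integer", 1, size = 1, signed = FALSE)          # pad
  if (type != 0L) {
    abort("only polygon-type ImageJ ROIs are supported", class = "brainfish_io_error")
  }
  rect <- readBin(con, "integer", 4, size = 2, endian = "big")  # top,left,bottom,right
  n <- readBin(con, "integer", 1, size = 2, endian = "big")
  seek(con, 64)
  xs <- readBin(con, "integer", n, size = 2, endian = "big")
  ys <- readBin(con, "integer", n, size = 2, endian = "big")
  list(name = basename(path), slice = NA_integer_,
       vertices = cbind(y = rect[1] + ys + 1, x = rect[2] + xs + 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
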