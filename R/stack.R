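#' Multi-channel z-stack container
#'
#' Bundles one 3D intensity array per imaging channel with voxel-size
#' metadata. Arrays are indexed `[z, y, x]` (1-based, voxel centers at
#' integer coordinates); intensities are in analog-digital units (adu).
#'
#' @param channels named list of 3D numeric arrays, all with identical
#'   `(z, y, x)` dimensions. Names are the channel labels, e.g.
#'   `"smFISH"`, `"neuron"`, `"calib_smFISH"`, `"calib_neuron"`.
#' @param voxel_size numeric length-3 `(dz, dy, dx)` in nm; must be strictly
#'   positive with `dy == dx` (square lateral pixels).
#'
#' @return An object of class `mc_stack`.
#' @export
mc_stack <- function(channels, voxel_size = c(200, 139, 139)) {
  if (!is.list(channels) || length(channels) < 1L || is.null(names(channels)) ||
      any(names(channels) == "")) {
    abort("`channels` must be a non-empty named list of 3D arrays.",
          class = "brainfish_config_error")
  }
  dims <- lapply(channels, function(a) {
    if (!is.array(a) || length(dim(a)) != 3L) {
      abort("each channel must be a 3D array (z, y, x)",
            class = "brainfish_config_error")
    }
    dim(a)
  })
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    abort("all channels must share an identical (z, y, x) shape",
          class = "brainfish_config_error")
  }
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    abort("voxel_size must be strictly positive", class = "brainfish_config_error")
  }
  if (abs(voxel_size[2] - voxel_size[3]) > 1e-9) {
    abort("lateral voxel size must be isotropic (dy == dx)",
          class = "brainfish_config_error")
  }
  structure(
    list(channels = channels, voxel_size = voxel_size),
    class = "mc_stack"
  )
}

#' @export
print.mc_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<mc_stack> %d channel(s) [%s], %d x %d x %d (z,y,x), voxel %g x %g x %g nm\n",
    length(x$channels), paste(names(x$channels), collapse = ", "),
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]
  ))
  invisible(x)
}

#' @export
dim.mc_stack <- function(x) dim(x$channels[[1]])

#' Channel names of a stack
#' @param stack an [mc_stack].
#' @return character vector of channel labels.
#' @export
channel_names <- function(stack) names(stack$channels)

#' Extract one channel as a 3D array
#' @param stack an [mc_stack].
#' @param channel channel label or index.
#' @return 3D numeric array `(z, y, x)`.
#' @export
get_channel <- function(stack, channel) {
  ch <- stack$channels[[channel]]
  if (is.null(ch)) {
    abort(sprintf("channel '%s' not found", as.character(channel)),
          class = "brainfish_config_error")
  }
  ch
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a multi-channel stack to TIFF
#'
#' Pages are written z-fastest within channel (channel-major). Intensities
#' are stored as 16-bit integers, so integer-valued data in `[0, 65535]`
#' round-trips losslessly. Voxel size and channel labels travel in a JSON
#' sidecar `<path>.json` (plain TIFF carries no pixel-size tags here).
#'
#' @param stack an [mc_stack].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack)
  rng <- range(vapply(stack$channels, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 65535) {
    abort("intensities outside [0, 65535] cannot be stored as 16-bit TIFF",
          class = "brainfish_config_error")
  }
  pages <- list()
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    for (z in seq_len(d[1])) {
      pages[[length(pages) + 1L]] <- a[z, , ] / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "deflate",
                  reduce = FALSE)
  meta <- list(
    channel_names = names(stack$channels),
    n_z = d[1],
    voxel_size_nm = stack$voxel_size
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-channel z-stack from TIFF
#'
#' Pages are interpreted channel-major (all z of channel 1, then channel 2,
#' ...). If a JSON sidecar written by [write_stack()] is present, voxel size
#' and stored channel labels are taken from it; otherwise the voxel size
#' falls back to `(200, 139, 139)` nm (200 nm z-step, 139 nm pixels, the
#' spinning-disk configuration this tool targets) with a warning.
#'
#' @param path TIFF file path.
#' @param channel_names labels for the channels in the file. The page count
#'   must be divisible by `length(channel_names)`; a mismatch against
#'   sidecar metadata is an error.
#' @return An [mc_stack].
#' @export
read_stack <- function(path, channel_names) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read '%s': no such file", path),
          class = "brainfish_io_error")
  }
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) abort(sprintf("cannot read '%s': %s", path, conditionMessage(e)),
                              class = "brainfish_io_error")
  )
  if (is.matrix(pages)) pages <- list(pages)
  n_pages <- length(pages)
  nc <- length(channel_names)
  voxel_size <- c(200, 139, 139)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    voxel_size <- as.numeric(meta$voxel_size_nm)
    if (!is.null(meta$channel_names) && length(meta$channel_names) != nc) {
      abort(sprintf("file has %d channel(s) but %d label(s) given",
                    length(meta$channel_names), nc),
            class = "brainfish_config_error")
    }
  } else {
    warn(sprintf(
      "'%s' has no voxel-size metadata; assuming (dz, dy, dx) = (200, 139, 139) nm",
      path))
  }
  if (n_pages %% nc != 0L) {
    abort(sprintf("page count %d is not divisible by %d channel label(s)",
                  n_pages, nc),
          class = "brainfish_config_error")
  }
  nz <- n_pages %/% nc
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  channels <- list()
  for (c_i in seq_len(nc)) {
    a <- array(0, dim = c(nz, ny, nx))
    for (z in seq_len(nz)) {
      a[z, , ] <- pages[[(c_i - 1L) * nz + z]]
    }
    channels[[channel_names[c_i]]] <- a
  }
  mc_stack(channels, voxel_size)
}

#' Select a contiguous window of z-slices
#'
#' Used to take the analysis substacks (e.g. ten 0.2 um sections around a
#' compartment) out of a full stack. For even `n_slices` the window starts
#' at `center_z - n_slices / 2` so the center slice sits just above the
#' window midpoint.
#'
#' @param image 3D array `(z, y, x)`.
#' @param center_z center slice (1-based index).
#' @param n_slices number of slices in the window.
#' @return 3D array with `n_slices` slices.
#' @export
select_substack <- function(image, center_z, n_slices) {
  stopifnot(is.array(image), length(dim(image)) == 3L, n_slices >= 1)
  nz <- dim(image)[1]
  if (n_slices %% 2L == 0L) {
    z0 <- center_z - n_slices / 2
  } else {
    z0 <- center_z - (n_slices - 1L) / 2
  }
  z1 <- z0 + n_slices - 1L
  if (z0 < 1L || z1 > nz) {
    abort(sprintf("substack [%d, %d] falls outside the %d-slice stack", z0, z1, nz),
          class = "brainfish_range_error")
  }
  image[z0:z1, , , drop = FALSE]
}
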