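#' Synthetic scene specification
#'
#' Describes a ground-truthed imaging scene: diffraction-limited spots on a
#' Poisson background, optional nuclear calibration channel (with an
#' injected chromatic shift), an optional dendrite-like membrane label, and
#' optional depth-dependent exponential bleaching. Defaults mirror the
#' target imaging regime (139 nm pixels, 200 nm z-steps, sigma_xy 1.39 px,
#' sigma_z 3.48 slices); `shape` defaults to a fast test profile, with
#' `c(40, 512, 512)` the full-field option.
#'
#' @param shape integer `(nz, ny, nx)`.
#' @param spots tibble/data.frame with `z, y, x` (voxel coordinates, may be
#'   subpixel) and `photons`; may have zero rows.
#' @param sigma_xy,sigma_z PSF widths (px / slices).
#' @param background background level in photons per voxel.
#' @param gain,offset camera transform `adu = gain * photons + offset`.
#' @param nuclei `NULL` or `list(n, radius, level)` — soft-edged nuclei for
#'   the calibration channel.
#' @param dendrite `NULL` or `list(level, width, y0, amp, period)` — a
#'   sinusoidal ribbon with Gaussian cross-section in y, constant in z.
#' @param bleach_k per-slice exponential decay constant (0 = none).
#' @param shift `NULL` or an [affine3d] injected between the two
#'   calibration channels.
#' @param seed RNG seed (mandatory; every render is replayable).
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(20, 256, 256),
                       spots = NULL,
                       sigma_xy = 1.39, sigma_z = 3.48,
                       background = 20,
                       gain = 1, offset = 0,
                       nuclei = NULL,
                       dendrite = NULL,
                       bleach_k = 0,
                       shift = NULL,
                       seed) {
  if (missing(seed)) {
    abort("a seed is mandatory for reproducible scenes", class = "brainfish_config_error")
  }
  if (is.null(spots)) {
    spots <- tibble(z = numeric(0), y = numeric(0), x = numeric(0), photons = numeric(0))
  }
  spots <- as_tibble(spots)
  stopifnot(all(c("z", "y", "x", "photons") %in% names(spots)))
  if (nrow(spots) > 0) {
    if (any(spots$z < 1 | spots$z > shape[1] | spots$y < 1 | spots$y > shape[2] |
              spots$x < 1 | spots$x > shape[3])) {
      abort("spot positions must lie inside the frame", class = "brainfish_config_error")
    }
    if (any(spots$photons < 0)) {
      abort("spot photon counts must be non-negative", class = "brainfish_config_error")
    }
  }
  stopifnot(background >= 0, gain > 0)
  structure(
    list(shape = as.integer(shape), spots = spots, sigma_xy = sigma_xy,
         sigma_z = sigma_z, background = background, gain = gain,
         offset = offset, nuclei = nuclei, dendrite = dendrite,
         bleach_k = bleach_k, shift = shift, seed = as.integer(seed)),
    class = "scene_spec"
  )
}

#' Place spots uniformly at random inside the frame
#'
#' Positions are uniform over the region at least `margin` voxels away
#' from every face, so every spot is fully measurable by the detector
#' (edge voxels are never tested).
#'
#' @param n number of spots.
#' @param shape `(nz, ny, nx)`.
#' @param photons photon count per spot (scalar or length-n).
#' @param margin `(mz, mxy)` margins in slices / px; defaults to the
#'   detection ROI half-widths for the default PSF.
#' @param seed RNG seed.
#' @return Spot tibble for [scene_spec()].
#' @export
place_spots <- function(n, shape, photons = 300, margin = c(7, 6), seed) {
  set.seed(seed)
  tibble(
    z = stats::runif(n, 1 + margin[1], shape[1] - margin[1]),
    y = stats::runif(n, 1 + margin[2], shape[2] - margin[2]),
    x = stats::runif(n, 1 + margin[2], shape[3] - margin[2]),
    photons = rep_len(photons, n)
  )
}

# expected photon image of the spots (separable pixel-integrated Gaussians,
# local support of +- 5 sigma per spot)
render_spots <- function(shape, spots, sigma_xy, sigma_z) {
  img <- array(0, shape)
  if (nrow(spots) == 0L) return(img)
  hz <- ceiling(5 * sigma_z)
  hxy <- ceiling(5 * sigma_xy)
  for (i in seq_len(nrow(spots))) {
    z0 <- spots$z[i]; y0 <- spots$y[i]; x0 <- spots$x[i]
    zi <- max(1, floor(z0) - hz):min(shape[1], ceiling(z0) + hz)
    yi <- max(1, floor(y0) - hxy):min(shape[2], ceiling(y0) + hxy)
    xi <- max(1, floor(x0) - hxy):min(shape[3], ceiling(x0) + hxy)
    pz <- pnorm((zi - z0 + 0.5) / sigma_z) - pnorm((zi - z0 - 0.5) / sigma_z)
    py <- pnorm((yi - y0 + 0.5) / sigma_xy) - pnorm((yi - y0 - 0.5) / sigma_xy)
    px <- pnorm((xi - x0 + 0.5) / sigma_xy) - pnorm((xi - x0 - 0.5) / sigma_xy)
    img[zi, yi, xi] <- img[zi, yi, xi] +
      spots$photons[i] * outer(pz, outer(py, px))
  }
  img
}

# soft-edged nuclei for the calibration channel (smooth enough for
# subvoxel MSE registration)
render_nuclei <- function(shape, nuclei) {
  img <- array(0, shape)
  ctrs <- nuclei$centers
  r <- nuclei$radius
  soft <- nuclei$soft %||% max(0.15 * r, 0.75)
  for (i in seq_len(nrow(ctrs))) {
    c0 <- ctrs[i, ]
    zi <- max(1, floor(c0[1] - r - 4 * soft)):min(shape[1], ceiling(c0[1] + r + 4 * soft))
    yi <- max(1, floor(c0[2] - r - 4 * soft)):min(shape[2], ceiling(c0[2] + r + 4 * soft))
    xi <- max(1, floor(c0[3] - r - 4 * soft)):min(shape[3], ceiling(c0[3] + r + 4 * soft))
    dz2 <- (zi - c0[1])^2
    dy2 <- (yi - c0[2])^2
    dx2 <- (xi - c0[3])^2
    d <- sqrt(outer(dz2, outer(dy2, dx2, "+"), "+"))
    img[zi, yi, xi] <- img[zi, yi, xi] + nuclei$level / (1 + exp((d - r) / soft))
  }
  img
}

# dendrite-like ribbon: sinusoidal centerline across x, Gaussian cross
# section in y, constant along z
render_dendrite <- function(shape, dendrite) {
  y0 <- dendrite$y0 %||% (shape[2] / 2)
  amp <- dendrite$amp %||% (shape[2] / 8)
  period <- dendrite$period %||% shape[3]
  w <- dendrite$width %||% 3
  x <- seq_len(shape[3])
  yc <- y0 + amp * sin(2 * pi * x / period)
  sl <- outer(seq_len(shape[2]), seq_along(x),
              function(y, ix) dendrite$level * exp(-(y - yc[ix])^2 / (2 * w^2)))
  img <- array(0, shape)
  for (z in seq_len(shape[1])) img[z, , ] <- sl
  mask <- outer(seq_len(shape[2]), seq_along(x), function(y, ix) abs(y - yc[ix]) <= w)
  list(img = img, mask = mask)
}

#' Render a ground-truthed synthetic scene
#'
#' Builds the expected photon image (background + pixel-integrated 3D
#' Gaussian spots, plus nuclei / dendrite label where configured, times
#' the depth bleaching factor), draws Poisson noise with the scene seed,
#' applies the camera transform, and returns the stack together with a
#' manifest of everything that was injected. Identical spec and seed give
#' bit-identical output.
#'
#' Channels produced: `"smFISH"` always; `"neuron"` when a dendrite is
#' configured; `"calib_ref"` and `"calib_moving"` when nuclei are
#' configured (the moving channel is warped by the injected shift before
#' noise).
#'
#' @param spec a [scene_spec].
#' @return A list with `stack` (an [mc_stack]) and `truth` (list:
#'   `spots`, `dendrite_mask`, `shift`, `bleach_k`, `seed`).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  shape <- spec$shape
  expected <- array(spec$background, shape) +
    render_spots(shape, spec$spots, spec$sigma_xy, spec$sigma_z)
  dend <- NULL
  if (!is.null(spec$dendrite)) {
    dend <- render_dendrite(shape, spec$dendrite)
  }
  nuc_expected <- NULL
  nuclei <- spec$nuclei
  if (!is.null(nuclei)) {
    if (is.null(nuclei$centers)) {
      r <- nuclei$radius
      nuclei$centers <- cbind(
        stats::runif(nuclei$n, 1 + r, shape[1] - r),
        stats::runif(nuclei$n, 1 + r, shape[2] - r),
        stats::runif(nuclei$n, 1 + r, shape[3] - r)
      )
    }
    nuc_expected <- render_nuclei(shape, nuclei) + (nuclei$background %||% 2)
  }
  if (spec$bleach_k != 0) {
    decay <- exp(-spec$bleach_k * (seq_len(shape[1]) - 1))
    expected <- expected * decay  # recycles along z (first dimension)
  }
  cam <- function(photon_img) {
    noisy <- array(rpois(length(photon_img), lambda = photon_img), dim(photon_img))
    spec$gain * noisy + spec$offset
  }
  channels <- list(smFISH = cam(expected))
  if (!is.null(dend)) {
    channels$neuron <- cam(dend$img + (spec$dendrite$background %||% 1))
  }
  if (!is.null(nuc_expected)) {
    channels$calib_ref <- cam(nuc_expected)
    mov_expected <- if (is.null(spec$shift)) {
      nuc_expected
    } else {
      # regions shifted in from outside the frame see plain background,
      # as on a real camera, not zeros
      base <- nuclei$background %||% 2
      apply_transform(nuc_expected - base, spec$shift) + base
    }
    channels$calib_moving <- cam(mov_expected)
  }
  truth <- list(
    spots = spec$spots,
    dendrite_mask = if (is.null(dend)) NULL else dend$mask,
    shift = spec$shift,
    bleach_k = spec$bleach_k,
    clean_calib = nuc_expected,
    seed = spec$seed
  )
  list(stack = mc_stack(channels), truth = truth)
}

#' Peak-amplitude to integrated-photon conversion
#'
#' The fraction of a voxel-centered, pixel-integrated 3D Gaussian PSF that
#' falls in the central voxel; dividing a peak amplitude (photons/voxel at
#' the brightest voxel) by it gives the integrated photon count.
#'
#' @param sigma_xy,sigma_z PSF widths (px / slices).
#' @return The central-voxel fraction (about 0.009 for the defaults).
#' @export
psf_center_fraction <- function(sigma_xy = 1.39, sigma_z = 3.48) {
  (2 * pnorm(0.5 / sigma_z) - 1) * (2 * pnorm(0.5 / sigma_xy) - 1)^2
}

#' One-call spot-detection test scene
#'
#' Renders `n_spots` spots of equal brightness on a flat Poisson
#' background with interior margins matching the detection ROI, the
#' configuration used to exercise the detector's FDR guarantee. Brightness
#' is given as the spot's peak amplitude in photons per voxel (what one
#' reads off the image); it is converted to the integrated photon count
#' the renderer uses via [psf_center_fraction()].
#'
#' @param n_spots number of spots.
#' @param shape `(nz, ny, nx)` (default the fast 256 x 256 x 20 profile).
#' @param amplitude peak photons/voxel above background (default 300).
#' @param background photons per voxel (default 20).
#' @param seed RNG seed.
#' @return List with `image` (3D array) and `truth` (spot tibble; the
#'   `photons` column is the integrated count).
#' @export
simulate_spot_stack <- function(n_spots = 100, shape = c(20, 256, 256),
                                amplitude = 300, background = 20, seed) {
  params <- detection_params()
  spots <- place_spots(n_spots, shape,
                       photons = amplitude / psf_center_fraction(params$sigma_xy,
                                                                 params$sigma_z),
                       margin = c(params$roi_halfwidth_z + 1, params$roi_halfwidth_xy + 1),
                       seed = seed)
  sc <- render_scene(scene_spec(shape = shape, spots = spots,
                                background = background, seed = seed + 1L))
  list(image = get_channel(sc$stack, "smFISH"), truth = spots)
}

cube_mesh <- function(center, side, name = "cube") {
  h <- side / 2
  s <- c(-1, 1)
  v <- as.matrix(expand.grid(x = s, y = s, z = s))[c(1, 2, 4, 3, 5, 6, 8, 7), ] * h
  v <- sweep(v, 2, center, "+")
  # outward-wound quads (consistent orientation => valid signed volume)
  quads <- rbind(c(1, 4, 3, 2), c(5, 6, 7, 8), c(1, 2, 6, 5),
                 c(3, 4, 8, 7), c(1, 5, 8, 4), c(2, 3, 7, 6))
  f <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  cmesh(v, f, name)
}

#' Analytic morphology fixtures
#'
#' Toy skeleton/mesh/synapse sets with known ground truth:
#' `"sphere"` — a single 40 nm-radius node (volume `(4/3) pi 40^3` nm^3)
#' inside a generous cube mesh; `"capsule"` — a straight 800 nm, 16 nm
#' radius two-node edge (analytic capsule volume); `"two_compartments"` —
#' two disjoint cube meshes A and B with 12 and 7 planted postsynapses
#' (plus pre synapses and outside points that must not be counted).
#'
#' @param kind fixture name.
#' @return List with `skeleton`, `mesh` (or `mesh_a`/`mesh_b`),
#'   `synapses`, and a `manifest` of the analytic expectations.
#' @export
make_morphology_fixture <- function(kind = c("sphere", "capsule", "two_compartments")) {
  if (!is.character(kind) || !kind[1] %in% c("sphere", "capsule", "two_compartments")) {
    abort(sprintf("unknown fixture kind '%s'", as.character(kind)[1]),
          class = "brainfish_config_error")
  }
  kind <- kind[1]
  if (kind == "sphere") {
    r <- 40
    skel <- skeleton(tibble(id = 1L, type = 1L, x = 100, y = 100, z = 100,
                            radius = r, parent = -1L))
    mesh <- cube_mesh(c(100, 100, 100), 400, "sphere_box")
    syn <- tibble(synapse_id = integer(0), kind = character(0),
                  x = numeric(0), y = numeric(0), z = numeric(0))
    manifest <- list(volume_nm3 = 4 / 3 * pi * r^3, n_post = 0L)
  } else if (kind == "capsule") {
    r <- 16; len <- 800
    skel <- skeleton(tibble(id = c(1L, 2L), type = c(1L, 3L),
                            x = c(100, 100 + len), y = c(100, 100), z = c(100, 100),
                            radius = r, parent = c(-1L, 1L)))
    mesh <- cube_mesh(c(100 + len / 2, 100, 100), 2 * len, "capsule_box")
    syn <- tibble(synapse_id = 1:2, kind = c("post", "pre"),
                  x = c(300, 500), y = c(100, 100), z = c(100, 100))
    manifest <- list(volume_nm3 = pi * r^2 * len + 4 / 3 * pi * r^3, n_post = 1L)
  } else {
    mesh_a <- cube_mesh(c(0, 0, 0), 200, "A")
    mesh_b <- cube_mesh(c(1000, 0, 0), 200, "B")
    skel <- skeleton(tibble(id = 1:2, type = c(1L, 3L),
                            x = c(-50, 50), y = c(0, 0), z = c(0, 0),
                            radius = 10, parent = c(-1L, 1L)))
    set.seed(7)
    rand_in <- function(n, ctr, half) {
      cbind(stats::runif(n, ctr[1] - half, ctr[1] + half),
            stats::runif(n, ctr[2] - half, ctr[2] + half),
            stats::runif(n, ctr[3] - half, ctr[3] + half))
    }
    pa <- rand_in(12, c(0, 0, 0), 90)
    pb <- rand_in(7, c(1000, 0, 0), 90)
    pre <- rand_in(4, c(0, 0, 0), 90)
    outside <- rand_in(5, c(500, 0, 0), 50)
    syn <- tibble(
      synapse_id = seq_len(28),
      kind = c(rep("post", 19), rep("pre", 4), rep("post", 5)),
      x = c(pa[, 1], pb[, 1], pre[, 1], outside[, 1]),
      y = c(pa[, 2], pb[, 2], pre[, 2], outside[, 2]),
      z = c(pa[, 3], pb[, 3], pre[, 3], outside[, 3])
    )
    manifest <- list(n_post_a = 12L, n_post_b = 7L)
    return(list(skeleton = skel, mesh_a = mesh_a, mesh_b = mesh_b,
                synapses = syn, manifest = manifest))
  }
  list(skeleton = skel, mesh = mesh, synapses = syn, manifest = manifest)
}
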