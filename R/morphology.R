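#' Read a neuron skeleton in SWC format
#'
#' Standard 7-column SWC (`id, type, x, y, z, radius, parent`), coordinates
#' in nm. The skeleton must have exactly one root (`parent = -1`) and valid
#' parent references. Missing or negative radii are replaced by
#' `2 * default_voxel_nm` with a warning.
#'
#' @param path SWC file path.
#' @param default_voxel_nm voxel size used for the fallback radius.
#' @return A tibble of class `bf_skeleton` with columns
#'   `id, type, x, y, z, radius, parent`.
#' @export
read_swc <- function(path, default_voxel_nm = 8) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("id", "type", "x", "y", "z", "radius", "parent"))
  skeleton(as_tibble(df), default_voxel_nm)
}

#' Validate a skeleton table
#' @param nodes tibble with columns `id, type, x, y, z, radius, parent`.
#' @param default_voxel_nm voxel size used for the fallback radius.
#' @return the validated tibble, classed `bf_skeleton`.
#' @export
skeleton <- function(nodes, default_voxel_nm = 8) {
  nodes <- as_tibble(nodes)
  stopifnot(all(c("id", "x", "y", "z", "radius", "parent") %in% names(nodes)))
  roots <- sum(nodes$parent == -1)
  if (roots != 1L) {
    abort(sprintf("skeleton must have exactly one root, found %d", roots),
          class = "brainfish_config_error")
  }
  bad_parent <- nodes$parent != -1 & !(nodes$parent %in% nodes$id)
  if (any(bad_parent)) {
    abort("skeleton has dangling parent references", class = "brainfish_config_error")
  }
  if (any(is.na(nodes$radius) | nodes$radius < 0)) {
    warn(sprintf("missing node radii; defaulting to %g nm", 2 * default_voxel_nm))
    nodes$radius[is.na(nodes$radius) | nodes$radius < 0] <- 2 * default_voxel_nm
  }
  class(nodes) <- unique(c("bf_skeleton", class(nodes)))
  nodes
}

#' Edge (segment) representation of a skeleton
#'
#' One row per parent-child edge with both endpoint positions and radii;
#' nodes with neither parent nor children become degenerate (point)
#' segments so isolated somata still contribute volume.
#'
#' @param skel a `bf_skeleton` tibble.
#' @return Tibble with columns `x1, y1, z1, r1, x2, y2, z2, r2`.
#' @export
skeleton_edges <- function(skel) {
  idx <- match(skel$parent, skel$id)
  has_parent <- skel$parent != -1
  e <- tibble(
    x1 = skel$x[has_parent], y1 = skel$y[has_parent], z1 = skel$z[has_parent],
    r1 = skel$radius[has_parent],
    x2 = skel$x[idx[has_parent]], y2 = skel$y[idx[has_parent]],
    z2 = skel$z[idx[has_parent]], r2 = skel$radius[idx[has_parent]]
  )
  isolated <- !has_parent & !(skel$id %in% skel$parent)
  if (any(isolated)) {
    e <- bind_rows(e, tibble(
      x1 = skel$x[isolated], y1 = skel$y[isolated], z1 = skel$z[isolated],
      r1 = skel$radius[isolated],
      x2 = skel$x[isolated], y2 = skel$y[isolated], z2 = skel$z[isolated],
      r2 = skel$radius[isolated]
    ))
  }
  e
}

#' Triangle mesh of a neuropil compartment
#'
#' @param vertices numeric matrix `n x 3` (x, y, z in nm).
#' @param faces integer matrix `m x 3` of 1-based vertex indices
#'   (triangles).
#' @param name compartment label.
#' @return An object of class `cmesh`.
#' @export
cmesh <- function(vertices, faces, name = "mesh") {
  vertices <- matrix(as.numeric(as.matrix(vertices)), ncol = 3)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (max(faces) > nrow(vertices) || min(faces) < 1L) {
    abort("face indices out of range", class = "brainfish_config_error")
  }
  structure(list(vertices = vertices, faces = faces, name = name), class = "cmesh")
}

#' @export
print.cmesh <- function(x, ...) {
  cat(sprintf("<cmesh> '%s': %d vertices, %d faces, volume %.4g nm^3\n",
              x$name, nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

#' Read a Wavefront OBJ triangle mesh
#' @param path OBJ file path (triangular faces; `v` and `f` records).
#' @param name compartment label (defaults to the file name).
#' @return A [cmesh].
#' @export
read_obj <- function(path, name = basename(path)) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(p) as.numeric(p[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"), function(p) {
    as.integer(vapply(strsplit(p[1:3], "/"), function(q) q[1], character(1)))
  }))
  cmesh(v, f, name)
}

#' Is a mesh watertight?
#'
#' Every undirected edge must be shared by exactly two faces, and the two
#' faces must traverse it in opposite directions (consistent orientation).
#' Containment tests, signed volume and volume scaling require this.
#'
#' @param mesh a [cmesh].
#' @return Logical scalar.
#' @export
mesh_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  undirected <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  directed <- paste(e[, 1], e[, 2])
  all(table(undirected) == 2L) && all(table(directed) == 1L)
}

#' Enclosed volume of a watertight mesh
#'
#' Signed-tetrahedron (divergence theorem) sum; the absolute value is
#' returned so face orientation does not matter.
#'
#' @param mesh a [cmesh].
#' @return Volume in nm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(det6)) / 6
}

#' Scale a mesh by a volume factor
#'
#' Isotropic scaling about the vertex centroid by the linear factor
#' `volume_factor^(1/3)`, so the enclosed volume scales by exactly
#' `volume_factor`. Used to enlarge a compartment mesh that does not quite
#' cover the dendrites it should (the 1.35x adjustment).
#'
#' @param mesh a watertight [cmesh].
#' @param volume_factor multiplicative volume change (> 0).
#' @param mode `"volume"` (default) treats the factor as a volume ratio;
#'   `"linear"` applies it directly to coordinates (sensitivity analysis).
#' @return The scaled [cmesh].
#' @export
scale_mesh <- function(mesh, volume_factor, mode = c("volume", "linear")) {
  mode <- match.arg(mode)
  stopifnot(volume_factor > 0)
  if (!mesh_watertight(mesh)) {
    abort("mesh is not watertight", class = "brainfish_config_error")
  }
  lin <- if (mode == "volume") volume_factor^(1 / 3) else volume_factor
  ctr <- colMeans(mesh$vertices)
  v <- sweep(sweep(mesh$vertices, 2, ctr, "-") * lin, 2, ctr, "+")
  cmesh(v, mesh$faces, mesh$name)
}

# fixed, deterministically chosen ray direction unlikely to graze
# axis-aligned edges
.ray_dir <- c(0.2709446, 0.5348650, 0.8003339) / sqrt(sum(c(0.2709446, 0.5348650, 0.8003339)^2))

#' Point-in-mesh containment test
#'
#' Ray casting with a fixed ray direction; a point lying on the surface
#' (within `tol` of a face) counts as inside (documented tie rule).
#'
#' @param points numeric matrix `n x 3` (x, y, z in nm) or length-3 vector.
#' @param mesh a watertight [cmesh].
#' @param tol on-surface tolerance in nm.
#' @return Logical vector of length `n`.
#' @export
point_in_mesh <- function(points, mesh, tol = 1e-9) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  v <- mesh$vertices
  f <- mesh$faces
  v0 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - v0
  e2 <- v[f[, 3], , drop = FALSE] - v0
  d <- .ray_dir
  # p = d x e2 (constant per triangle)
  p1 <- d[2] * e2[, 3] - d[3] * e2[, 2]
  p2 <- d[3] * e2[, 1] - d[1] * e2[, 3]
  p3 <- d[1] * e2[, 2] - d[2] * e2[, 1]
  det <- e1[, 1] * p1 + e1[, 2] * p2 + e1[, 3] * p3
  ok <- abs(det) > 1e-14
  scale_tol <- max(abs(v)) + 1
  out <- logical(nrow(points))
  for (i in seq_len(nrow(points))) {
    tv1 <- points[i, 1] - v0[, 1]
    tv2 <- points[i, 2] - v0[, 2]
    tv3 <- points[i, 3] - v0[, 3]
    u <- (tv1 * p1 + tv2 * p2 + tv3 * p3) / det
    q1 <- tv2 * e1[, 3] - tv3 * e1[, 2]
    q2 <- tv3 * e1[, 1] - tv1 * e1[, 3]
    q3 <- tv1 * e1[, 2] - tv2 * e1[, 1]
    vv <- (d[1] * q1 + d[2] * q2 + d[3] * q3) / det
    tt <- (e2[, 1] * q1 + e2[, 2] * q2 + e2[, 3] * q3) / det
    hit <- ok & u >= 0 & vv >= 0 & (u + vv) <= 1
    if (any(hit & abs(tt) <= tol * scale_tol)) {
      out[i] <- TRUE  # on the surface
      next
    }
    out[i] <- sum(hit & tt > 0) %% 2L == 1L
  }
  out
}

# first crossing parameter t in (0, 1) of segment p1 -> p2 with the mesh
segment_mesh_crossing <- function(p1, p2, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  v0 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - v0
  e2 <- v[f[, 3], , drop = FALSE] - v0
  d <- p2 - p1
  pc1 <- d[2] * e2[, 3] - d[3] * e2[, 2]
  pc2 <- d[3] * e2[, 1] - d[1] * e2[, 3]
  pc3 <- d[1] * e2[, 2] - d[2] * e2[, 1]
  det <- e1[, 1] * pc1 + e1[, 2] * pc2 + e1[, 3] * pc3
  ok <- abs(det) > 1e-14
  tv1 <- p1[1] - v0[, 1]; tv2 <- p1[2] - v0[, 2]; tv3 <- p1[3] - v0[, 3]
  u <- (tv1 * pc1 + tv2 * pc2 + tv3 * pc3) / det
  q1 <- tv2 * e1[, 3] - tv3 * e1[, 2]
  q2 <- tv3 * e1[, 1] - tv1 * e1[, 3]
  q3 <- tv1 * e1[, 2] - tv2 * e1[, 1]
  vv <- (d[1] * q1 + d[2] * q2 + d[3] * q3) / det
  tt <- (e2[, 1] * q1 + e2[, 2] * q2 + e2[, 3] * q3) / det
  hit <- ok & u >= -1e-12 & vv >= -1e-12 & (u + vv) <= 1 + 1e-12 &
    tt > 1e-12 & tt < 1 - 1e-12
  if (!any(hit)) return(NA_real_)
  min(tt[hit])
}

#' Clip a skeleton to a compartment mesh
#'
#' Keeps nodes inside the mesh and edges with both endpoints inside; edges
#' crossing the surface are cut at the surface-intersection point (radius
#' linearly interpolated). Edges with both endpoints outside are dropped.
#'
#' @param skel a `bf_skeleton` tibble or an edge tibble from
#'   [skeleton_edges()].
#' @param mesh a watertight [cmesh].
#' @return Edge-fragment tibble (`x1..r2`), possibly zero rows.
#' @export
clip_skeleton <- function(skel, mesh) {
  if (!mesh_watertight(mesh)) {
    abort("mesh is not watertight", class = "brainfish_config_error")
  }
  edges <- if (inherits(skel, "bf_skeleton")) skeleton_edges(skel) else as_tibble(skel)
  if (nrow(edges) == 0L) return(edges)
  in1 <- point_in_mesh(as.matrix(edges[, c("x1", "y1", "z1")]), mesh)
  in2 <- point_in_mesh(as.matrix(edges[, c("x2", "y2", "z2")]), mesh)
  out <- vector("list", nrow(edges))
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    if (in1[i] && in2[i]) {
      out[[i]] <- e
    } else if (in1[i] || in2[i]) {
      p1 <- c(e$x1, e$y1, e$z1); p2 <- c(e$x2, e$y2, e$z2)
      tc <- segment_mesh_crossing(p1, p2, mesh)
      if (is.na(tc)) {
        if (in1[i]) out[[i]] <- e else next
        next
      }
      pc <- p1 + tc * (p2 - p1)
      rc <- e$r1 + tc * (e$r2 - e$r1)
      out[[i]] <- if (in1[i]) {
        tibble(x1 = e$x1, y1 = e$y1, z1 = e$z1, r1 = e$r1,
               x2 = pc[1], y2 = pc[2], z2 = pc[3], r2 = rc)
      } else {
        tibble(x1 = pc[1], y1 = pc[2], z1 = pc[3], r1 = rc,
               x2 = e$x2, y2 = e$y2, z2 = e$z2, r2 = e$r2)
      }
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    res <- edges[0, ]
  }
  res
}

#' Voxelized volume of skeleton fragments
#'
#' Rasterizes each edge as a capsule (sphere-swept segment, radius
#' linearly interpolated between the node radii) onto a cubic grid and
#' returns `occupied voxels x voxel_nm^3`. Overlapping capsules are not
#' double-counted.
#'
#' @param fragments edge tibble (`x1..r2`) from [clip_skeleton()] or
#'   [skeleton_edges()].
#' @param voxel_nm voxel edge length in nm (default 8).
#' @return A list with `volume_nm3`, `volume_um3` and `n_voxels`.
#' @export
voxelized_volume <- function(fragments, voxel_nm = 8) {
  if (nrow(fragments) == 0L) {
    return(list(volume_nm3 = 0, volume_um3 = 0, n_voxels = 0L))
  }
  keys <- character(0)
  for (i in seq_len(nrow(fragments))) {
    e <- fragments[i, ]
    p1 <- c(e$x1, e$y1, e$z1); p2 <- c(e$x2, e$y2, e$z2)
    rmax <- max(e$r1, e$r2)
    lo <- floor((pmin(p1, p2) - rmax) / voxel_nm)
    hi <- ceiling((pmax(p1, p2) + rmax) / voxel_nm)
    gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
    ctr <- expand.grid(x = (gx + 0.5) * voxel_nm,
                       y = (gy + 0.5) * voxel_nm,
                       z = (gz + 0.5) * voxel_nm)
    dvec <- p2 - p1
    len2 <- sum(dvec^2)
    if (len2 > 0) {
      tpar <- ((ctr$x - p1[1]) * dvec[1] + (ctr$y - p1[2]) * dvec[2] +
                 (ctr$z - p1[3]) * dvec[3]) / len2
      tpar <- pmin(pmax(tpar, 0), 1)
    } else {
      tpar <- rep(0, nrow(ctr))
    }
    qx <- p1[1] + tpar * dvec[1]
    qy <- p1[2] + tpar * dvec[2]
    qz <- p1[3] + tpar * dvec[3]
    rt <- e$r1 + tpar * (e$r2 - e$r1)
    occ <- (ctr$x - qx)^2 + (ctr$y - qy)^2 + (ctr$z - qz)^2 <= rt^2
    if (any(occ)) {
      idx <- which(occ)
      ix <- rep(gx, times = length(gy) * length(gz))[idx]
      iy <- rep(rep(gy, each = length(gx)), times = length(gz))[idx]
      iz <- rep(gz, each = length(gx) * length(gy))[idx]
      keys <- c(keys, paste(ix, iy, iz))
    }
  }
  n <- length(unique(keys))
  list(volume_nm3 = n * voxel_nm^3, volume_um3 = n * voxel_nm^3 / 1e9,
       n_voxels = n)
}

#' Count postsynapses inside a compartment mesh
#'
#' @param table synapse tibble with columns `synapse_id, kind`
#'   (`"pre"`/`"post"`) and `x, y, z` in nm.
#' @param mesh a watertight [cmesh].
#' @return Integer count of `post` rows inside the mesh (on-surface points
#'   count as inside).
#' @export
count_postsynapses <- function(table, mesh) {
  if (!mesh_watertight(mesh)) {
    abort("mesh is not watertight", class = "brainfish_config_error")
  }
  if (nrow(table) == 0L) return(0L)
  bad <- !(table$kind %in% c("pre", "post"))
  if (any(bad)) {
    abort("synapse kind must be 'pre' or 'post'", class = "brainfish_config_error")
  }
  post <- table[table$kind == "post", ]
  if (nrow(post) == 0L) return(0L)
  sum(point_in_mesh(as.matrix(post[, c("x", "y", "z")]), mesh))
}

#' Dendritic morphometry report for one compartment
#'
#' Scales the compartment mesh by the given volume factor, clips the
#' skeleton to it, voxelizes the resulting neurite fragments and counts
#' the postsynapses the mesh contains.
#'
#' @param skel a `bf_skeleton`.
#' @param mesh a watertight [cmesh].
#' @param synapses synapse tibble (see [count_postsynapses()]); may be
#'   `NULL`.
#' @param volume_factor mesh volume scaling applied first (default 1).
#' @param voxel_nm voxelization grid (default 8 nm).
#' @return One-row tibble: `compartment, volume_nm3, volume_um3, n_voxels,
#'   n_post, n_pre`.
#' @export
morphology_report <- function(skel, mesh, synapses = NULL, volume_factor = 1,
                              voxel_nm = 8) {
  m <- if (volume_factor != 1) scale_mesh(mesh, volume_factor) else mesh
  frags <- clip_skeleton(skel, m)
  vol <- voxelized_volume(frags, voxel_nm)
  n_post <- if (is.null(synapses)) NA_integer_ else count_postsynapses(synapses, m)
  n_pre <- if (is.null(synapses)) NA_integer_ else {
    pre <- synapses[synapses$kind == "pre", ]
    if (nrow(pre) == 0L) 0L else sum(point_in_mesh(as.matrix(pre[, c("x", "y", "z")]), m))
  }
  tibble(compartment = m$name, volume_nm3 = vol$volume_nm3,
         volume_um3 = vol$volume_um3, n_voxels = vol$n_voxels,
         n_post = n_post, n_pre = n_pre)
}
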