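#' Triangle surface mesh
#'
#' Vertices are in mm world coordinates; faces index vertices (1-based) and
#' are oriented so normals point outward (total signed volume positive).
#'
#' @param vertices n-by-3 numeric matrix (mm).
#' @param faces m-by-3 integer matrix of vertex indices.
#' @param structure optional structure label code (1, 2 or 3).
#' @param color color name; defaults to the structure's scene color.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, structure = NULL, color = NULL) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || (nrow(faces) && ncol(faces) != 3L))
    stop("vertices must be n-by-3 and faces m-by-3", call. = FALSE)
  if (nrow(faces)) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range", call. = FALSE)
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
      stop("degenerate faces (repeated vertex)", call. = FALSE)
  }
  if (!is.null(structure)) structure <- structure_code(structure)
  if (is.null(color) && !is.null(structure))
    color <- STRUCTURE_COLORS[[structure_name(structure)]]
  structure(list(vertices = vertices, faces = faces,
                 structure = structure, color = color),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  met <- mesh_metrics(x)
  cat(sprintf("<surface_mesh>%s %d vertices, %d faces%s\n",
              if (!is.null(x$structure)) paste0(" ", structure_name(x$structure)) else "",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$color)) paste0(", ", x$color) else ""))
  cat(sprintf("  area %.1f mm^2, volume %.1f mm^3, %swatertight\n",
              met$area_mm2, met$volume_mm3, if (met$watertight) "" else "NOT "))
  invisible(x)
}

#' Extract an isosurface by marching cubes
#'
#' Runs the marching cubes algorithm on a voxel grid and returns a triangle
#' mesh in mm world coordinates. Binary masks are treated as a {0,1} scalar
#' field with the default isovalue 0.5, which places vertices at cube-edge
#' midpoints. The input is padded with one below-isovalue layer on every side
#' so surfaces close at the volume border; the resulting mesh is watertight
#' (every edge shared by exactly two faces).
#'
#' @param mask logical/numeric 3D array (binary mask or scalar field).
#' @param spacing voxel spacing in mm.
#' @param isovalue surface level; must lie strictly between the mask values
#'   for binary input.
#' @param origin world position (mm) of voxel `[1, 1, 1]`.
#' @param structure optional structure code attached to the mesh.
#' @return A [surface_mesh()]; an empty mask yields an empty mesh.
#' @export
marching_cubes <- function(mask, spacing = c(1, 1, 1), isovalue = 0.5,
                           origin = c(0, 0, 0), structure = NULL) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  field <- mask
  storage.mode(field) <- "double"
  d <- dim(field)
  pad_value <- min(min(field), isovalue) - 1
  padded <- array(pad_value, d + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- field
  res <- .mc_extract(as.vector(padded), as.integer(dim(padded)), isovalue)
  v <- res$vertices
  if (nrow(v)) {
    v <- v - 1                                 # undo padding offset
    v <- sweep(sweep(v, 2, spacing, `*`), 2, origin, `+`)
  }
  f <- res$faces
  mesh <- surface_mesh(v, f, structure = structure)
  if (nrow(f) && mesh_signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (!nrow(f)) return(0)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Surface area, enclosed volume and watertightness of a mesh
#'
#' Area is the sum of triangle areas; volume is the divergence-theorem signed
#' sum over faces (positive for outward-oriented closed meshes); a mesh is
#' watertight when every undirected edge is shared by exactly two faces.
#'
#' @param mesh a [surface_mesh()].
#' @return list with `area_mm2`, `volume_mm3` (signed) and `watertight`.
#' @export
mesh_metrics <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  if (!nrow(f))
    return(list(area_mm2 = 0, volume_mm3 = 0, watertight = FALSE))
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  crossp <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
                  ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
                  ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  area <- sum(sqrt(rowSums(crossp^2))) / 2
  nv <- nrow(v)
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (nv + 1) + pmax(e[, 1], e[, 2])
  counts <- table(key)
  list(area_mm2 = area, volume_mm3 = mesh_signed_volume(mesh),
       watertight = all(counts == 2L))
}

#' Taubin mesh smoothing
#'
#' Two-step shrink/inflate smoothing with the uniform-weight graph Laplacian:
#' each iteration moves vertices by `lambda` towards their neighborhood mean
#' and then by `mu` (negative) away from it, which removes voxelization
#' staircase while approximately preserving enclosed volume. The vertex count
#' and the triangulation (hence V, E, F) are unchanged.
#'
#' @param mesh a [surface_mesh()].
#' @param iterations number of shrink/inflate passes; 0 returns the mesh
#'   unchanged.
#' @param lambda shrink factor (0 < lambda < 1).
#' @param mu inflate factor (negative; |mu| slightly > lambda). Set `mu = 0`
#'   for pure Laplacian (shrink-only) smoothing.
#' @return The smoothed [surface_mesh()].
#' @export
smooth_mesh <- function(mesh, iterations = 20L, lambda = 0.5, mu = -0.53) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (iterations == 0L || !nrow(mesh$faces)) return(mesh)
  if (!mesh_metrics(mesh)$watertight)
    warning("mesh is not watertight; smoothing applied anyway")
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- unique(rbind(e, e[, 2:1]))
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1, dims = c(nv, nv))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  W <- Matrix::Diagonal(x = 1 / deg) %*% A    # row-normalized adjacency
  V <- mesh$vertices
  for (it in seq_len(iterations)) {
    V <- V + lambda * (as.matrix(W %*% V) - V)
    if (mu != 0) V <- V + mu * (as.matrix(W %*% V) - V)
  }
  out <- mesh
  out$vertices <- V
  out
}

#' Assemble the colored multi-structure 3D scene
#'
#' Extracts one smoothed mesh per structure from a label map: the uterine
#' body (red) as the filled outer surface of everything it encloses, the
#' endometrium (yellow) as its filled cavity surface, and each 26-connected
#' fibroid component (green) as its own mesh.
#'
#' @param labelmap a [labelmap()].
#' @param smooth apply [smooth_mesh()] to every mesh.
#' @param iterations,lambda,mu smoothing parameters.
#' @param min_fibroid_voxels fibroid components smaller than this are not
#'   rendered.
#' @return An object of class `scene`: a list of [surface_mesh()] objects.
#' @export
assemble_scene <- function(labelmap, smooth = TRUE, iterations = 20L,
                           lambda = 0.5, mu = -0.53, min_fibroid_voxels = 5L) {
  stopifnot(inherits(labelmap, "labelmap"))
  lab <- labelmap$labels
  sp <- labelmap$spacing; or <- labelmap$origin
  meshes <- list()
  maybe_smooth <- function(m)
    if (smooth) smooth_mesh(m, iterations, lambda, mu) else m

  body_region <- fill_holes3d(lab > 0L)
  if (any(body_region))
    meshes <- c(meshes, list(maybe_smooth(
      marching_cubes(body_region, sp, origin = or, structure = 1L))))
  endo_region <- fill_holes3d(lab == 2L)
  if (any(endo_region))
    meshes <- c(meshes, list(maybe_smooth(
      marching_cubes(endo_region, sp, origin = or, structure = 2L))))
  fib <- lab == 3L
  if (any(fib)) {
    cc <- label_components(fib, 26L)
    sizes <- tabulate(cc[cc > 0L])
    for (comp in which(sizes >= min_fibroid_voxels))
      meshes <- c(meshes, list(maybe_smooth(
        marching_cubes(cc == comp, sp, origin = or, structure = 3L))))
  }
  structure(meshes, class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d mesh(es)\n", length(x)))
  for (m in x)
    cat(sprintf("  %s (%s): %d faces, volume %.0f mm^3\n",
                structure_name(m$structure), m$color, nrow(m$faces),
                abs(mesh_signed_volume(m))))
  invisible(x)
}

#' Export meshes
#'
#' `write_ply()` writes ASCII PLY with per-vertex RGB color (a whole scene is
#' merged into one file, colors preserved); `write_stl()` writes ASCII STL
#' (geometry only); `write_obj()` writes OBJ with a companion MTL carrying
#' per-structure material colors.
#'
#' @param x a [surface_mesh()] or `scene`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(x, path) {
  meshes <- if (inherits(x, "surface_mesh")) list(x) else x
  nv <- sum(vapply(meshes, function(m) nrow(m$vertices), integer(1)))
  nf <- sum(vapply(meshes, function(m) nrow(m$faces), integer(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nv),
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green", "property uchar blue",
               paste("element face", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  off <- 0L
  vlines <- character(0); flines <- character(0)
  for (m in meshes) {
    rgb <- if (!is.null(m$structure)) STRUCTURE_RGB[[structure_name(m$structure)]]
           else c(200L, 200L, 200L)
    if (nrow(m$vertices))
      vlines <- c(vlines, paste(
        format(m$vertices[, 1], trim = TRUE), format(m$vertices[, 2], trim = TRUE),
        format(m$vertices[, 3], trim = TRUE), rgb[1], rgb[2], rgb[3]))
    if (nrow(m$faces))
      flines <- c(flines, paste(3L, m$faces[, 1] - 1L + off,
                                m$faces[, 2] - 1L + off, m$faces[, 3] - 1L + off))
    off <- off + nrow(m$vertices)
  }
  writeLines(vlines, con)
  writeLines(flines, con)
  invisible(path)
}

#' @rdname write_ply
#' @export
write_stl <- function(x, path) {
  meshes <- if (inherits(x, "surface_mesh")) list(x) else x
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid scene", con)
  for (m in meshes) {
    v <- m$vertices; f <- m$faces
    for (i in seq_len(nrow(f))) {
      a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
      n <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
             (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
             (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
      nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
      writeLines(c(sprintf("facet normal %g %g %g", n[1], n[2], n[3]),
                   "  outer loop",
                   sprintf("    vertex %g %g %g", a[1], a[2], a[3]),
                   sprintf("    vertex %g %g %g", b[1], b[2], b[3]),
                   sprintf("    vertex %g %g %g", cc[1], cc[2], cc[3]),
                   "  endloop", "endfacet"), con)
    }
  }
  writeLines("endsolid scene", con)
  invisible(path)
}

#' @rdname write_ply
#' @export
write_obj <- function(x, path) {
  meshes <- if (inherits(x, "surface_mesh")) list(x) else x
  mtl_path <- sub("\\.obj$", ".mtl", path)
  if (identical(mtl_path, path)) mtl_path <- paste0(path, ".mtl")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("mtllib", basename(mtl_path)), con)
  off <- 0L
  mats <- character(0)
  for (idx in seq_along(meshes)) {
    m <- meshes[[idx]]
    nm <- if (!is.null(m$structure))
      paste0(structure_name(m$structure), "_", idx) else paste0("mesh_", idx)
    mats <- c(mats, nm)
    writeLines(paste("o", nm), con)
    writeLines(paste("usemtl", nm), con)
    if (nrow(m$vertices))
      writeLines(paste("v", m$vertices[, 1], m$vertices[, 2], m$vertices[, 3]), con)
    if (nrow(m$faces))
      writeLines(paste("f", m$faces[, 1] + off, m$faces[, 2] + off,
                       m$faces[, 3] + off), con)
    off <- off + nrow(m$vertices)
  }
  mcon <- file(mtl_path, "w")
  for (idx in seq_along(meshes)) {
    m <- meshes[[idx]]
    rgb <- if (!is.null(m$structure)) STRUCTURE_RGB[[structure_name(m$structure)]]
           else c(200L, 200L, 200L)
    writeLines(c(paste("newmtl", mats[idx]),
                 sprintf("Kd %.3f %.3f %.3f", rgb[1] / 255, rgb[2] / 255,
                         rgb[3] / 255)), mcon)
  }
  close(mcon)
  invisible(path)
}
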