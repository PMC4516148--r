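#' Closed planar contour on one slice
#'
#' A `contour` is an operator-traced (or machine-generated) closed polygon on
#' one slice of one structure. Vertices are in-plane world coordinates in mm
#' (first two grid axes); closure is implicit (the first vertex is not
#' repeated). Vertices are stored counterclockwise; the interior is decided by
#' the even-odd rule at rasterization time.
#'
#' @param structure one of `"body"`, `"endometrium"`, `"fibroid"` or the
#'   corresponding label code 1, 2, 3.
#' @param slice_index 0-based index of the slice along the third (sagittal
#'   stack) axis.
#' @param vertices_mm n-by-2 numeric matrix of (x, y) mm positions, n >= 3.
#' @param check validate simplicity (no self-intersection). Validation is
#'   O(n^2) in the number of vertices.
#' @return An object of class `contour`.
#' @export
contour <- function(structure, slice_index, vertices_mm, check = TRUE) {
  structure <- structure_code(structure)
  v <- as.matrix(vertices_mm)
  dimnames(v) <- NULL
  if (!is.numeric(v) || ncol(v) != 2L)
    stop("`vertices_mm` must be an n-by-2 numeric matrix", call. = FALSE)
  # drop an explicitly repeated closing vertex
  if (nrow(v) > 1L && all(abs(v[1, ] - v[nrow(v), ]) < 1e-12))
    v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3L)
    stop("a closed contour needs at least 3 vertices", call. = FALSE)
  if (any(!is.finite(v)))
    stop("contour vertices must be finite", call. = FALSE)
  if (isTRUE(check) && polygon_self_intersects(v))
    stop("contour polygon is self-intersecting", call. = FALSE)
  if (polygon_area_signed(v) < 0)          # normalize to counterclockwise
    v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  slice_index <- as.integer(slice_index)
  if (is.na(slice_index) || slice_index < 0L)
    stop("`slice_index` must be a non-negative integer", call. = FALSE)
  structure(list(structure = structure, slice_index = slice_index,
                 vertices_mm = v),
            class = "contour")
}

structure_code <- function(x) {
  if (is.character(x)) {
    if (!x %in% names(STRUCTURE_LABELS)[-1])
      stop("unknown structure: ", x, call. = FALSE)
    return(unname(STRUCTURE_LABELS[x]))
  }
  x <- as.integer(x)
  if (!x %in% STRUCTURE_LABELS[-1])
    stop("structure label must be 1 (body), 2 (endometrium) or 3 (fibroid)",
         call. = FALSE)
  x
}

structure_name <- function(code) names(STRUCTURE_LABELS)[match(code, STRUCTURE_LABELS)]

polygon_area_signed <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# proper-crossing test over all non-adjacent segment pairs
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1), , drop = FALSE]
  cross2 <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]   # segment n is adjacent to segment 1
    if (!length(js)) next
    d1 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[js, 1], a[js, 2])
    d2 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[js, 1], b[js, 2])
    d3 <- cross2(a[js, 1], a[js, 2], b[js, 1], b[js, 2], rep(a[i, 1], length(js)), rep(a[i, 2], length(js)))
    d4 <- cross2(a[js, 1], a[js, 2], b[js, 1], b[js, 2], rep(b[i, 1], length(js)), rep(b[i, 2], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> %s, slice %d, %d vertices, area %.1f mm^2\n",
              structure_name(x$structure), x$slice_index,
              nrow(x$vertices_mm), abs(polygon_area_signed(x$vertices_mm))))
  invisible(x)
}

#' Key-slice contour set
#'
#' Bundles operator contours for all structures with the grid geometry they
#' were traced on. A structure may have several contours on one slice
#' (multi-part regions); their rasterizations are unioned.
#'
#' @param contours list of [contour()] objects.
#' @param dim integer length-3 grid dimensions.
#' @param spacing,origin grid geometry in mm.
#' @return An object of class `keyslice_set`.
#' @export
keyslice_set <- function(contours, dim, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(all(vapply(contours, inherits, logical(1), "contour")))
  dim <- as.integer(dim)
  ks <- vapply(contours, function(ct) ct$slice_index, integer(1))
  if (length(ks) && (min(ks) < 0L || max(ks) >= dim[3]))
    stop("key slice index outside the grid (0..", dim[3] - 1L, ")", call. = FALSE)
  structure(list(contours = contours, dim = dim,
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "keyslice_set")
}

#' @export
print.keyslice_set <- function(x, ...) {
  st <- vapply(x$contours, function(ct) structure_name(ct$structure), character(1))
  cat(sprintf("<keyslice_set> %d contours on a %s grid\n",
              length(x$contours), paste(x$dim, collapse = "x")))
  print(table(st))
  invisible(x)
}

#' Write / read contours as JSON
#'
#' The interchange dialect is a JSON array of records
#' `{structure, slice_index, vertices_mm: [[x, y], ...]}` plus a `grid`
#' header carrying `dim`, `spacing` and `origin`.
#'
#' @param keyset a [keyslice_set()].
#' @param path file path.
#' @return `write_contours`: `path` invisibly; `read_contours`: a
#'   [keyslice_set()].
#' @export
write_contours <- function(keyset, path) {
  stopifnot(inherits(keyset, "keyslice_set"))
  recs <- lapply(keyset$contours, function(ct) {
    list(structure = structure_name(ct$structure),
         slice_index = ct$slice_index,
         vertices_mm = unname(ct$vertices_mm))
  })
  obj <- list(grid = list(dim = keyset$dim, spacing = keyset$spacing,
                          origin = keyset$origin),
              contours = recs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  recs <- obj$contours
  if (is.data.frame(recs)) {
    contours <- lapply(seq_len(nrow(recs)), function(i)
      contour(recs$structure[i], recs$slice_index[i],
              recs$vertices_mm[[i]], check = FALSE))
  } else {
    contours <- lapply(recs, function(r)
      contour(r$structure, r$slice_index,
              do.call(rbind, lapply(r$vertices_mm, unlist)), check = FALSE))
  }
  keyslice_set(contours, obj$grid$dim, obj$grid$spacing, obj$grid$origin)
}

#' Rasterize a contour onto a slice grid
#'
#' A voxel belongs to the interior iff its center is inside the polygon by
#' the even-odd rule; centers lying exactly on the boundary count as
#' interior.
#'
#' @param ct a [contour()] (or bare n-by-2 vertex matrix in mm).
#' @param dim integer length-2 (or 3) grid dimensions; the first two are used.
#' @param spacing,origin grid geometry in mm (in-plane components used).
#' @return logical `dim[1]` x `dim[2]` matrix.
#' @export
rasterize_contour <- function(ct, dim, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- if (inherits(ct, "contour")) ct$vertices_mm else contour(1L, 0L, ct)$vertices_mm
  if (nrow(v) < 3L) stop("contour needs at least 3 vertices", call. = FALSE)
  nx <- dim[1]; ny <- dim[2]
  sx <- spacing[1]; sy <- spacing[2]
  ox <- origin[1]; oy <- origin[2]
  out <- matrix(FALSE, nx, ny)

  n <- nrow(v)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- v[c(2:n, 1), 1]; y2 <- v[c(2:n, 1), 2]

  # candidate index window (0-based indices)
  i0 <- max(0L, floor((min(x1) - ox) / sx) - 1L)
  i1 <- min(nx - 1L, ceiling((max(x1) - ox) / sx) + 1L)
  j0 <- max(0L, floor((min(y1) - oy) / sy) - 1L)
  j1 <- min(ny - 1L, ceiling((max(y1) - oy) / sy) + 1L)
  if (i0 > i1 || j0 > j1) return(out)

  xs <- ox + (i0:i1) * sx
  tol <- 1e-9
  for (j in j0:j1) {
    yc <- oy + j * sy
    crossing <- (y1 > yc) != (y2 > yc)
    inside <- rep(FALSE, length(xs))
    if (any(crossing)) {
      xc <- x1[crossing] + (yc - y1[crossing]) / (y2[crossing] - y1[crossing]) *
        (x2[crossing] - x1[crossing])
      # even-odd: count crossings strictly to the right of the center
      cnt <- rowSums(outer(xs, xc, function(px, q) px < q))
      inside <- (cnt %% 2L) == 1L
    }
    # boundary ties -> interior
    on_edge <- rep(FALSE, length(xs))
    for (e in seq_len(n)) {
      ex1 <- x1[e]; ey1 <- y1[e]; ex2 <- x2[e]; ey2 <- y2[e]
      if (yc < min(ey1, ey2) - tol || yc > max(ey1, ey2) + tol) next
      len2 <- (ex2 - ex1)^2 + (ey2 - ey1)^2
      if (len2 == 0) next
      cr <- abs((ex2 - ex1) * (yc - ey1) - (ey2 - ey1) * (xs - ex1))
      t <- ((xs - ex1) * (ex2 - ex1) + (yc - ey1) * (ey2 - ey1)) / len2
      on_edge <- on_edge | (cr < tol * sqrt(len2) & t >= -tol & t <= 1 + tol)
    }
    out[(i0:i1) + 1L, j + 1L] <- inside | on_edge
  }
  out
}

#' Shape-based interpolation between two slice masks
#'
#' Reconstructs the masks of the slices strictly between two key slices by
#' linearly blending the signed Euclidean distance fields of the endpoint
#' masks and thresholding at zero (<= 0 is interior). If one endpoint is
#' empty its field is replaced by a uniformly positive field (the other
#' mask's field raised by its maximum interior depth plus half a voxel), so
#' the structure erodes linearly to extinction towards the empty end.
#'
#' @param maskA,maskB logical matrices on the same grid; at least one
#'   non-empty.
#' @param n_between number of intermediate slices to reconstruct (the gap is
#'   `n_between + 1` slices wide).
#' @param spacing in-plane spacing (mm), length 2.
#' @return list of `n_between` logical matrices, ordered from the A side to
#'   the B side.
#' @export
interpolate_between <- function(maskA, maskB, n_between, spacing = c(1, 1)) {
  stopifnot(is.matrix(maskA), is.matrix(maskB),
            all(dim(maskA) == dim(maskB)))
  n_between <- as.integer(n_between)
  if (n_between < 1L) return(list())
  emptyA <- !any(maskA); emptyB <- !any(maskB)
  if (emptyA && emptyB)
    stop("both endpoint masks are empty; nothing to interpolate", call. = FALSE)
  taper_field <- function(f) f - min(f) + min(spacing[1:2]) / 2
  fA <- if (emptyA) NULL else signed_distance2d(maskA, spacing)
  fB <- if (emptyB) NULL else signed_distance2d(maskB, spacing)
  if (emptyA) fA <- taper_field(fB)
  if (emptyB) fB <- taper_field(fA)
  lapply(seq_len(n_between), function(s) {
    t <- s / (n_between + 1)
    ((1 - t) * fA + t * fB) <= 0
  })
}

#' Propagate key-slice contours to a full label map
#'
#' The semi-automatic segmentation: key slices reproduce their rasterized
#' manual contours exactly; every slice strictly between two consecutive key
#' slices of a structure is reconstructed by [interpolate_between()]; slices
#' beyond a structure's first/last key slice stay empty. Where structures
#' overlap, labels are resolved by priority fibroid > endometrium > body.
#'
#' @param keyset a [keyslice_set()].
#' @return A [labelmap()] on the key set's grid.
#' @export
propagate_segmentation <- function(keyset) {
  stopifnot(inherits(keyset, "keyslice_set"))
  d <- keyset$dim
  labels <- array(0L, d)
  # painter's order realizes the fibroid > endometrium > body priority
  for (code in c(1L, 2L, 3L)) {
    cts <- Filter(function(ct) ct$structure == code, keyset$contours)
    if (!length(cts)) next
    ks <- sort(unique(vapply(cts, function(ct) ct$slice_index, integer(1))))
    vol <- array(FALSE, d)
    key_masks <- list()
    for (k in ks) {
      m <- matrix(FALSE, d[1], d[2])
      for (ct in cts) if (ct$slice_index == k)
        m <- m | rasterize_contour(ct, d, keyset$spacing, keyset$origin)
      key_masks[[as.character(k)]] <- m
      vol[, , k + 1L] <- m
    }
    if (length(ks) > 1L) {
      for (q in seq_len(length(ks) - 1L)) {
        a <- ks[q]; b <- ks[q + 1L]
        if (b - a < 2L) next
        mids <- interpolate_between(key_masks[[as.character(a)]],
                                    key_masks[[as.character(b)]],
                                    b - a - 1L, keyset$spacing[1:2])
        for (s in seq_along(mids)) vol[, , a + s + 1L] <- mids[[s]]
      }
    }
    labels[vol] <- code
  }
  labelmap(labels, keyset$spacing, keyset$origin)
}

#' Cross-direction validation and correction of a segmentation
#'
#' Removes false-positive voxels by 3D geometric consistency: the uterine
#' body and endometrium keep only their largest 26-connected component;
#' fibroid components below a minimum size are dropped; finally, endometrium
#' voxels outside the filled interior of the body are removed (nesting rule).
#' The output never contains a voxel absent from the input.
#'
#' @param labelmap a [labelmap()].
#' @param min_fibroid_voxels fibroid components smaller than this many voxels
#'   are discarded (default 5).
#' @return The corrected [labelmap()].
#' @export
cross_plane_correct <- function(labelmap, min_fibroid_voxels = 5L) {
  stopifnot(inherits(labelmap, "labelmap"))
  lab <- labelmap$labels
  out <- array(0L, dim(lab))

  for (code in c(1L, 2L)) {
    m <- lab == code
    if (!any(m)) next
    cc <- label_components(m, 26L)
    sizes <- tabulate(cc[cc > 0L])
    keep <- which.max(sizes)
    out[cc == keep] <- code
  }
  fib <- lab == 3L
  if (any(fib)) {
    cc <- label_components(fib, 26L)
    sizes <- tabulate(cc[cc > 0L])
    keep <- which(sizes >= min_fibroid_voxels)
    out[cc %in% keep & fib] <- 3L
  }
  # nesting: endometrium must lie inside the body's filled interior
  body_filled <- fill_holes3d(out == 1L)
  drop <- out == 2L & !body_filled
  out[drop] <- 0L
  labelmap(out, labelmap$spacing, labelmap$origin)
}

#' Trace the contours of a binary slice
#'
#' Extracts closed boundary polygons of a 2D mask by marching squares at the
#' 0.5 level (vertices at pixel-edge midpoints, ambiguous saddle cells split
#' so that diagonally-touching foreground stays separated). Combining the
#' rasterizations of the returned polygons by even-odd parity (XOR; interior
#' holes are traced as their own loops) reproduces the mask exactly; for
#' hole-free regions, as traced by [simulate_key_slice_tracing()], the plain
#' union does the same.
#'
#' @param mask2d logical matrix.
#' @param spacing,origin in-plane geometry in mm.
#' @return list of n-by-2 vertex matrices (mm), one per closed loop.
#' @export
trace_slice_contours <- function(mask2d, spacing = c(1, 1), origin = c(0, 0)) {
  m <- matrix(FALSE, nrow(mask2d) + 2L, ncol(mask2d) + 2L)
  m[2:(nrow(mask2d) + 1L), 2:(ncol(mask2d) + 1L)] <- mask2d
  nx <- nrow(m); ny <- ncol(m)
  if (!any(m)) return(list())

  # cell corners: (i,j), (i+1,j), (i+1,j+1), (i,j+1) with 0-based padded idx
  a <- m[-nx, -ny]; b <- m[-1, -ny]; cc <- m[-1, -1]; dd <- m[-nx, -1]
  case <- a + 2L * b + 4L * cc + 8L * dd
  active <- which(case > 0L & case < 15L, arr.ind = TRUE)

  # segment endpoints as half-grid keys: edge between corner centers;
  # key encodes midpoint at doubled coordinates to stay integer
  segs_from <- character(0); segs_to <- character(0)
  pts <- new.env(parent = emptyenv())
  mid <- function(i1, j1, i2, j2) {
    kx <- i1 + i2; ky <- j1 + j2          # doubled coordinates (integer)
    key <- paste0(kx, "_", ky)
    assign(key, c(kx / 2, ky / 2), envir = pts)
    key
  }
  from <- character(0); to <- character(0)
  for (r in seq_len(nrow(active))) {
    i <- active[r, 1] - 1L; j <- active[r, 2] - 1L   # 0-based padded corner
    cs <- case[active[r, 1], active[r, 2]]
    # edges of the cell: bottom (a-b), right (b-c), top (d-c), left (a-d)
    eB <- function() mid(i, j, i + 1L, j)
    eR <- function() mid(i + 1L, j, i + 1L, j + 1L)
    eT <- function() mid(i, j + 1L, i + 1L, j + 1L)
    eL <- function() mid(i, j, i, j + 1L)
    # segments oriented with foreground on the left (consistent chaining)
    seg <- switch(as.character(cs),
      "1"  = list(c(eL(), eB())),
      "2"  = list(c(eB(), eR())),
      "3"  = list(c(eL(), eR())),
      "4"  = list(c(eR(), eT())),
      "5"  = list(c(eL(), eB()), c(eR(), eT())),   # saddle: separate
      "6"  = list(c(eB(), eT())),
      "7"  = list(c(eL(), eT())),
      "8"  = list(c(eT(), eL())),
      "9"  = list(c(eT(), eB())),
      "10" = list(c(eB(), eR()), c(eT(), eL())),   # saddle: separate
      "11" = list(c(eT(), eR())),
      "12" = list(c(eR(), eL())),
      "13" = list(c(eR(), eB())),
      "14" = list(c(eB(), eL())))
    for (s in seg) { from <- c(from, s[1]); to <- c(to, s[2]) }
  }
  if (!length(from)) return(list())

  # with inside-on-one-side orientation every midpoint has exactly one
  # outgoing and one incoming segment, so loops chain deterministically
  nxt <- setNames(to, from)
  used <- new.env(parent = emptyenv())
  loops <- list()
  for (start in from) {
    if (!is.null(used[[start]])) next
    loop_keys <- character(0)
    cur <- start
    repeat {
      loop_keys <- c(loop_keys, cur)
      used[[cur]] <- TRUE
      cur <- unname(nxt[cur])
      if (is.na(cur) || identical(cur, start)) break
    }
    if (length(loop_keys) >= 3L) {
      vm <- do.call(rbind, lapply(loop_keys, function(k) get(k, envir = pts)))
      # padded half-grid -> original 0-based indices -> mm
      vm <- vm - 1
      vm[, 1] <- origin[1] + vm[, 1] * spacing[1]
      vm[, 2] <- origin[2] + vm[, 2] * spacing[2]
      loops[[length(loops) + 1L]] <- vm
    }
  }
  loops
}
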