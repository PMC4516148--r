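# Small voxel-morphology helpers shared across modules. All operate on plain
# logical arrays; geometry (spacing/origin) is carried by the callers.

#' Label connected components of a 3D mask
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (face) or 26 (face+edge+corner) neighborhood.
#' @return integer array of the same shape; 0 background, components 1..K.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L,
            connectivity %in% c(6L, 26L))
  .cc_label3d(as.logical(mask), as.integer(dim(mask)), as.integer(connectivity))
}

# fill enclosed background cavities: background components not reaching the
# array border are interior holes
fill_holes3d <- function(mask) {
  bg <- !mask
  lab <- .cc_label3d(bg, as.integer(dim(mask)), 6L)
  d <- dim(mask)
  border <- unique(c(
    lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
    lab[, , 1], lab[, , d[3]]
  ))
  border <- setdiff(border, 0L)
  mask | (lab != 0L & !(lab %in% border))
}

fill_holes2d <- function(mask2d) {
  m3 <- array(mask2d, c(dim(mask2d), 1L))
  out <- fill_holes3d(m3)
  out[, , 1]
}

# dilation by one voxel, 26-neighborhood, via index shifts
dilate1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    zs <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
    out <- out | mask[xs, ys, zs]
  }
  out
}

# signed Euclidean distance field of a 2D mask (mm): negative inside,
# positive outside; an empty mask gives a uniformly (hugely) positive field
signed_distance2d <- function(mask2d, spacing = c(1, 1)) {
  m <- mask2d
  storage.mode(m) <- "logical"
  d_in <- sqrt(.edt2d_sq(m, spacing[1], spacing[2]))
  d_out <- sqrt(.edt2d_sq(!m, spacing[1], spacing[2]))
  d_in - d_out
}

# boundary voxels of a 3D mask: mask voxels with a 6-neighbor (or the array
# border) outside the mask
boundary_voxels <- function(mask) {
  d <- dim(mask)
  inner <- mask
  for (ax in 1:3) for (dir in c(-1L, 1L)) {
    if (d[ax] == 1L) { inner[] <- FALSE; next }
    shifted <- array(FALSE, d)
    src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    if (dir == 1L) { dst[[ax]] <- seq_len(d[ax] - 1L); src[[ax]] <- seq(2L, d[ax]) }
    else           { dst[[ax]] <- seq(2L, d[ax]); src[[ax]] <- seq_len(d[ax] - 1L) }
    shifted[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
    inner <- inner & shifted
  }
  mask & !inner
}
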