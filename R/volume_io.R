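#' 3D scalar volume with voxel spacing
#'
#' A `volume3d` is a numeric 3D array plus the grid geometry every other
#' function in the package relies on: per-axis voxel spacing in mm and a world
#' origin in mm. Voxel indices are 0-based in world-coordinate arithmetic
#' (R's 1-based array index `[i, j, k]` sits at
#' `origin + (c(i, j, k) - 1) * spacing`); voxel centers carry the
#' coordinates; the third index `k` is the slice axis (the sagittal stack).
#'
#' @param data numeric 3D array, all values finite.
#' @param spacing numeric length-3, voxel spacing in mm; strictly positive.
#' @param origin numeric length-3, world position (mm) of voxel `[1, 1, 1]`.
#' @return An object of class `volume3d`: a list with elements `data`,
#'   `spacing`, `origin`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 4)), spacing = c(0.6, 0.6, 2))
#' dim(v$data)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (!all(dim(data) >= 1L))
    stop("all dimensions must be >= 1", call. = FALSE)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("volume contains non-finite values", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Integer label map over a volume grid
#'
#' Labels are restricted to `0` background, `1` uterine body, `2` endometrium,
#' `3` fibroid. A label map shares the grid (dimensions, spacing, origin) of
#' the volume it segments.
#'
#' @param labels integer 3D array with values in `{0, 1, 2, 3}`.
#' @param spacing,origin grid geometry, as in [volume3d()].
#' @return An object of class `labelmap`.
#' @examples
#' lm <- labelmap(array(0L, c(4, 4, 4)))
#' @export
labelmap <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  if (any(is.na(labels)))
    stop("labels contain missing values", call. = FALSE)
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), STRUCTURE_LABELS)
  if (length(bad))
    stop("label values outside {0,1,2,3}: ", paste(bad, collapse = ", "),
         call. = FALSE)
  geom <- volume3d(array(0, dim(labels)), spacing, origin)  # validates geometry
  structure(list(labels = labels, spacing = geom$spacing, origin = geom$origin),
            class = "labelmap")
}

#' @export
print.labelmap <- function(x, ...) {
  d <- dim(x$labels)
  tab <- table(factor(as.vector(x$labels), levels = STRUCTURE_LABELS,
                      labels = names(STRUCTURE_LABELS)))
  cat(sprintf("<labelmap> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  print(tab)
  invisible(x)
}

#' World coordinates of voxel indices
#'
#' Maps 0-based voxel indices `(i, j, k)` to mm world coordinates
#' `origin + index * spacing`, componentwise.
#'
#' @param index integer vector of length 3 or an n-by-3 matrix of 0-based
#'   voxel indices.
#' @param geom a `volume3d` or `labelmap` (only `spacing`/`origin` are used).
#' @return n-by-3 numeric matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(index, geom) {
  idx <- if (is.matrix(index)) index else matrix(index, ncol = 3)
  sweep(sweep(idx, 2, geom$spacing, `*`), 2, geom$origin, `+`)
}

#' Read a 3D volume from disk
#'
#' Reads a NIfTI-1 volume (`.nii` or `.nii.gz`) into a [volume3d()]. Spacing
#' is taken from the header `pixdim`; orientation metadata beyond
#' spacing/origin (direction cosines) is accepted but normalized to identity
#' with a warning, because the pipeline is orientation-agnostic at desk scale.
#'
#' @param path file path.
#' @param format currently only `"nifti"`. DICOM series import is not
#'   available in this build.
#' @return A [volume3d()].
#' @export
read_volume <- function(path, format = c("nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "dicom")
    stop("DICOM series import is not supported by this build; ",
         "convert the series to NIfTI first", call. = FALSE)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume, got ", length(dim(arr)), "D data", call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- c(0, 0, 0)
  if (!inherits(xf, "try-error") && is.matrix(xf)) {
    rot <- xf[1:3, 1:3]
    off_diag <- rot - diag(diag(rot))
    if (any(abs(off_diag) > 1e-6) || any(diag(rot) < 0))
      warning("non-identity direction cosines in NIfTI header; ",
              "orientation normalized to identity (spacing kept)")
    origin <- xf[1:3, 4]
  }
  volume3d(arr, spacing = spacing, origin = origin)
}

#' Write a volume to NIfTI
#'
#' @param volume a [volume3d()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume3d"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a label map from NIfTI
#'
#' @param path file path to an integer-valued NIfTI volume.
#' @return A [labelmap()]. Values outside `{0,1,2,3}` are a validation error.
#' @export
read_labelmap <- function(path) {
  vol <- read_volume(path)
  lab <- round(vol$data)
  if (max(abs(lab - vol$data)) > 1e-6)
    stop("file does not contain integer labels: ", path, call. = FALSE)
  labelmap(array(as.integer(lab), dim(lab)), vol$spacing, vol$origin)
}

#' Write a label map to NIfTI (lossless integer round-trip)
#'
#' @param labelmap a [labelmap()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_labelmap <- function(labelmap, path) {
  stopifnot(inherits(labelmap, "labelmap"))
  img <- RNifti::asNifti(labelmap$labels)
  RNifti::pixdim(img) <- labelmap$spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

# shared geometry check used across modules
same_grid <- function(a, b) {
  da <- dim(if (!is.null(a$labels)) a$labels else a$data)
  db <- dim(if (!is.null(b$labels)) b$labels else b$data)
  identical(da, db) && all(abs(a$spacing - b$spacing) < 1e-9)
}
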