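#' Identify individual fibroids in a label map
#'
#' Fibroid voxels (label 3) are grouped into 26-connected components; each
#' component above the minimum size becomes one record. Sizes use the
#' anisotropic voxel spacing: volume is voxel count times voxel volume, and
#' the maximum diameter is the largest pairwise distance between component
#' voxel centers in mm.
#'
#' @param labelmap a [labelmap()].
#' @param min_voxels components smaller than this many voxels are ignored.
#' @return data frame with one row per fibroid: `id`, `n_voxels`,
#'   `volume_mm3`, `max_diameter_mm`, `centroid_x/y/z` (mm) and a `type`
#'   column of `NA` to be filled by [classify_fibroids()].
#' @export
find_fibroids <- function(labelmap, min_voxels = 5L) {
  stopifnot(inherits(labelmap, "labelmap"))
  lab <- labelmap$labels
  sp <- labelmap$spacing
  voxvol <- prod(sp)
  cc <- label_components(lab == 3L, 26L)
  k <- max(cc)
  empty <- data.frame(id = integer(0), n_voxels = integer(0),
                      volume_mm3 = numeric(0), max_diameter_mm = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      centroid_z = numeric(0), type = character(0),
                      stringsAsFactors = FALSE)
  if (k == 0L) return(empty)
  recs <- list()
  id <- 0L
  for (comp in seq_len(k)) {
    idx <- which(cc == comp, arr.ind = TRUE)
    if (nrow(idx) < min_voxels) next
    id <- id + 1L
    pts <- voxel_to_world(idx - 1L, labelmap)
    recs[[id]] <- data.frame(
      id = id, n_voxels = nrow(idx),
      volume_mm3 = nrow(idx) * voxvol,
      max_diameter_mm = .max_pairwise_dist(pts),
      centroid_x = mean(pts[, 1]), centroid_y = mean(pts[, 2]),
      centroid_z = mean(pts[, 3]),
      type = NA_character_, stringsAsFactors = FALSE
    )
    attr(recs[[id]], "component") <- comp
  }
  if (!length(recs)) return(empty)
  out <- do.call(rbind, recs)
  attr(out, "component_labels") <- cc
  attr(out, "kept_components") <- vapply(recs, attr, integer(1), "component")
  out
}

#' Classify one fibroid as intramural, subserosal or submucosal
#'
#' Decision rules (evaluated in priority order):
#' 1. submucosal - the fibroid dilated by one voxel intersects the
#'    endometrium;
#' 2. subserosal - more than `exterior_fraction` of its voxels lie outside
#'    the filled interior of the uterine body;
#' 3. intramural - otherwise.
#'
#' The body mask is hole-filled internally, so fibroids fully embedded in the
#' myometrium count as inside even though they displace the body label.
#'
#' @param fibroid_mask logical 3D array of one fibroid component.
#' @param body_mask logical 3D array of the uterine body (label 1).
#' @param endometrium_mask logical 3D array of the endometrium (label 2).
#' @param exterior_fraction subserosal threshold (default 0.1).
#' @return `"submucosal"`, `"subserosal"` or `"intramural"`.
#' @export
classify_fibroid <- function(fibroid_mask, body_mask, endometrium_mask,
                             exterior_fraction = 0.1) {
  if (!any(fibroid_mask))
    stop("empty fibroid mask", call. = FALSE)
  if (any(dilate1(fibroid_mask) & endometrium_mask)) return("submucosal")
  body_filled <- fill_holes3d(body_mask)
  if (mean(!body_filled[fibroid_mask]) > exterior_fraction) return("subserosal")
  "intramural"
}

#' Classify all fibroids of a label map
#'
#' @param labelmap a [labelmap()].
#' @param records optionally, the output of [find_fibroids()] (recomputed
#'   otherwise).
#' @param exterior_fraction subserosal threshold, see [classify_fibroid()].
#' @param min_voxels passed to [find_fibroids()].
#' @return The records data frame with the `type` column filled in.
#' @export
classify_fibroids <- function(labelmap, records = NULL,
                              exterior_fraction = 0.1, min_voxels = 5L) {
  stopifnot(inherits(labelmap, "labelmap"))
  if (is.null(records)) records <- find_fibroids(labelmap, min_voxels)
  if (!nrow(records)) return(records)
  cc <- attr(records, "component_labels")
  comps <- attr(records, "kept_components")
  body <- labelmap$labels == 1L
  endo <- labelmap$labels == 2L
  body_filled <- fill_holes3d(body)
  for (r in seq_len(nrow(records))) {
    fm <- cc == comps[r]
    ty <- if (any(dilate1(fm) & endo)) "submucosal"
      else if (mean(!body_filled[fm]) > exterior_fraction) "subserosal"
      else "intramural"
    records$type[r] <- ty
  }
  records
}

#' Build a surgical-planning report
#'
#' Applies the removal heuristic: all submucosal and subserosal fibroids are
#' flagged for removal, intramural fibroids only when their maximum diameter
#' reaches `intramural_removal_mm`. The suggested procedure follows the
#' pattern of the reader-study gold standard: removals that are exclusively
#' submucosal suggest transcervical resection (TCR); any subserosal removal
#' suggests laparoscopically assisted myomectomy (LAM); any other non-empty
#' removal set suggests total laparoscopic myomectomy (TLM); no removals, no
#' procedure. Abdominal myomectomy (AM) is never auto-suggested. These rules
#' are geometric heuristics, not clinical judgments.
#'
#' @param records classified fibroid records (from [classify_fibroids()]).
#' @param intramural_removal_mm diameter threshold (mm) above which an
#'   intramural fibroid is flagged for removal (default 25).
#' @return An object of class `planning_report`: list with the augmented
#'   `records` (column `removal_recommended`), `total`, `by_type`,
#'   `n_removal` and `procedure` (`NA` when no removal is recommended).
#' @export
build_report <- function(records, intramural_removal_mm = 25) {
  if (nrow(records) && any(is.na(records$type)))
    stop("records must be classified first (see classify_fibroids)",
         call. = FALSE)
  rec <- records
  rec$removal_recommended <- if (nrow(rec)) {
    rec$type %in% c("submucosal", "subserosal") |
      (rec$type == "intramural" & rec$max_diameter_mm >= intramural_removal_mm)
  } else logical(0)
  by_type <- vapply(c("intramural", "subserosal", "submucosal"),
                    function(t) sum(rec$type == t), integer(1))
  removed <- rec$type[rec$removal_recommended]
  procedure <- if (!length(removed)) NA_character_
    else if (all(removed == "submucosal")) "TCR"
    else if (any(removed == "subserosal")) "LAM"
    else "TLM"
  structure(list(records = rec, total = nrow(rec), by_type = by_type,
                 n_removal = sum(rec$removal_recommended),
                 procedure = procedure,
                 intramural_removal_mm = intramural_removal_mm),
            class = "planning_report")
}

#' @export
print.planning_report <- function(x, ...) {
  cat(sprintf("<planning_report> %d fibroid(s): %d intramural, %d subserosal, %d submucosal\n",
              x$total, x$by_type[["intramural"]], x$by_type[["subserosal"]],
              x$by_type[["submucosal"]]))
  cat(sprintf("  recommended for removal: %d; suggested procedure: %s\n",
              x$n_removal, ifelse(is.na(x$procedure), "none", x$procedure)))
  invisible(x)
}

#' Write a planning report to CSV or JSON
#'
#' @param report a [build_report()] result.
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "planning_report"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(total = report$total, by_type = as.list(report$by_type),
           n_removal = report$n_removal, procedure = report$procedure,
           records = report$records),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    write.csv(report$records, path, row.names = FALSE)
  }
  invisible(path)
}
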