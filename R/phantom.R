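#' Configuration for a synthetic pelvic MR phantom
#'
#' Describes a sagittal T2-like phantom: an ellipsoidal uterine body of
#' intermediate intensity, a nested hyperintense endometrial cavity, and
#' hypointense spherical fibroids, over a dark background with additive
#' Gaussian noise. Defaults emulate a typical desk-scale case: a uterus of
#' roughly 90 x 64 x 76 mm with three intramural fibroids and one subserosal
#' fibroid in the 6-24 mm diameter range, on an anisotropic grid with 2 mm
#' slice thickness.
#'
#' @param dim grid dimensions (voxels), length 3; third axis is the slice
#'   stack.
#' @param spacing voxel spacing in mm.
#' @param body_semiaxes,endo_semiaxes semi-axes (mm) of the axis-aligned body
#'   and endometrium ellipsoids, both centered at `center`.
#' @param center ellipsoid center in mm; default is the grid center.
#' @param fibroids list of fibroid specs `list(center =, radius =, type =)`
#'   with `center` in mm, `radius` in mm and `type` one of `"intramural"`,
#'   `"subserosal"`, `"submucosal"`.
#' @param intensities named mean intensities for `background`, `body`,
#'   `endometrium`, `fibroid`.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param exterior_fraction the subserosal decision threshold the phantom is
#'   validated against: a conforming subserosal fibroid must have more than
#'   this fraction of its voxels outside the body ellipsoid (with margin, see
#'   [generate_phantom()]).
#' @param seed integer random seed; identical configurations (including the
#'   seed) generate bit-identical phantoms.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(dim = c(96, 96, 64),
                           spacing = c(1.5, 1.5, 2),
                           body_semiaxes = c(45, 32, 38),
                           endo_semiaxes = c(18, 7, 22),
                           center = NULL,
                           fibroids = NULL,
                           intensities = c(background = 30, body = 100,
                                           endometrium = 200, fibroid = 40),
                           noise_sd = 8,
                           exterior_fraction = 0.1,
                           seed = 1L) {
  dim <- as.integer(dim); spacing <- as.numeric(spacing)
  stopifnot(length(dim) == 3L, all(dim >= 1L),
            length(spacing) == 3L, all(spacing > 0))
  if (is.null(center)) center <- (dim - 1) / 2 * spacing
  if (!all(endo_semiaxes < body_semiaxes))
    stop("endometrium ellipsoid must lie strictly inside the body ellipsoid",
         call. = FALSE)
  if (is.null(fibroids)) {
    fibroids <- list(
      list(center = center + c(26, 14, 0),  radius = 8, type = "intramural"),
      list(center = center + c(-24, 10, 10), radius = 7, type = "intramural"),
      list(center = center + c(0, -16, -19), radius = 6, type = "intramural"),
      list(center = center + c(0, 0, 0),     radius = 9, type = "subserosal")
    )
    # subserosal default sits on the body surface along +x
    fibroids[[4]]$center <- center + c(body_semiaxes[1], 0, 0) * 0.98
  }
  for (f in fibroids) {
    stopifnot(length(f$center) == 3L, is.numeric(f$radius), f$radius > 0)
    if (!f$type %in% c("intramural", "subserosal", "submucosal"))
      stop("unknown fibroid type: ", f$type, call. = FALSE)
  }
  req <- c("background", "body", "endometrium", "fibroid")
  if (!all(req %in% names(intensities)))
    stop("`intensities` must name ", paste(req, collapse = ", "), call. = FALSE)
  structure(list(dim = dim, spacing = spacing, center = as.numeric(center),
                 body_semiaxes = as.numeric(body_semiaxes),
                 endo_semiaxes = as.numeric(endo_semiaxes),
                 fibroids = fibroids, intensities = intensities,
                 noise_sd = noise_sd,
                 exterior_fraction = exterior_fraction,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

ellipsoid_mask <- function(dim, spacing, center, semiaxes, origin = c(0, 0, 0)) {
  xs <- ((origin[1] + (seq_len(dim[1]) - 1) * spacing[1] - center[1]) / semiaxes[1])^2
  ys <- ((origin[2] + (seq_len(dim[2]) - 1) * spacing[2] - center[2]) / semiaxes[2])^2
  zs <- ((origin[3] + (seq_len(dim[3]) - 1) * spacing[3] - center[3]) / semiaxes[3])^2
  outer(outer(xs, ys, `+`), zs, `+`) <= 1
}

sphere_mask <- function(dim, spacing, center, radius, origin = c(0, 0, 0)) {
  ellipsoid_mask(dim, spacing, center, rep(radius, 3), origin)
}

#' Generate a synthetic uterine phantom with ground truth
#'
#' Builds the label map (priority fibroid > endometrium > body where
#' structures overlap), checks that each fibroid's realized geometry is
#' consistent with its intended anatomical type, and synthesizes a noisy
#' T2-like intensity volume.
#'
#' Conformity rules, evaluated on the voxelized geometry:
#' * `submucosal` - the sphere intersects the endometrial cavity;
#' * `subserosal` - more than `exterior_fraction + 0.05` of its voxels lie
#'   outside the body ellipsoid, and it does not touch the endometrium;
#' * `intramural` - entirely inside the body ellipsoid and, after dilation by
#'   one voxel, disjoint from the endometrium.
#'
#' Fibroids must not touch one another (each remains its own 26-connected
#' component).
#'
#' @param config a [phantom_config()].
#' @return A list with elements `volume` (a [volume3d()]) and `truth` (class
#'   `phantom_truth`: a list with the ground-truth [labelmap()] and a
#'   `fibroids` data frame with id, center, radius and intended type).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$dim; sp <- config$spacing
  body <- ellipsoid_mask(d, sp, config$center, config$body_semiaxes)
  endo <- ellipsoid_mask(d, sp, config$center, config$endo_semiaxes)

  fib_masks <- lapply(config$fibroids, function(f)
    sphere_mask(d, sp, f$center, f$radius))
  fib_all <- Reduce(`|`, fib_masks, array(FALSE, d))

  # intended-type conformity
  for (i in seq_along(config$fibroids)) {
    f <- config$fibroids[[i]]
    m <- fib_masks[[i]]
    if (!any(m))
      stop("fibroid ", i, " rasterizes to zero voxels", call. = FALSE)
    outside_frac <- mean(!body[m])
    touches_endo <- any(m & endo)
    dm <- dilate1(m)
    dilated_touches_endo <- any(dm & endo)
    # "strictly inside" carries a one-voxel margin: otherwise the fibroid
    # abuts the serosal surface and its anatomical position is ambiguous
    ok <- switch(f$type,
      submucosal = touches_endo,
      subserosal = outside_frac > config$exterior_fraction + 0.05 &&
                   !dilated_touches_endo,
      intramural = all(body[dm]) && !dilated_touches_endo)
    if (!ok)
      stop("fibroid ", i, " geometry contradicts its intended type '",
           f$type, "'", call. = FALSE)
    for (j in seq_len(i - 1L))
      if (any(m & dilate1(fib_masks[[j]])))
        stop("fibroids ", j, " and ", i, " touch or overlap", call. = FALSE)
  }

  labels <- array(0L, d)
  labels[body] <- 1L
  labels[endo] <- 2L
  labels[fib_all] <- 3L           # fibroid wins over endometrium and body
  lm <- labelmap(labels, sp)

  mu <- config$intensities
  base <- array(mu[["background"]], d)
  base[labels == 1L] <- mu[["body"]]
  base[labels == 2L] <- mu[["endometrium"]]
  base[labels == 3L] <- mu[["fibroid"]]
  vol <- withr::with_seed(config$seed, {
    base + array(rnorm(prod(d), 0, config$noise_sd), d)
  })

  fdf <- data.frame(
    id = seq_along(config$fibroids),
    center_x = vapply(config$fibroids, function(f) f$center[1], numeric(1)),
    center_y = vapply(config$fibroids, function(f) f$center[2], numeric(1)),
    center_z = vapply(config$fibroids, function(f) f$center[3], numeric(1)),
    radius_mm = vapply(config$fibroids, function(f) f$radius, numeric(1)),
    type = vapply(config$fibroids, function(f) f$type, character(1)),
    stringsAsFactors = FALSE
  )
  truth <- structure(list(labelmap = lm, fibroids = fdf), class = "phantom_truth")
  list(volume = volume3d(vol, sp), truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d fibroid(s): %s\n", nrow(x$fibroids),
              paste(x$fibroids$type, collapse = ", ")))
  print(x$labelmap)
  invisible(x)
}

#' Randomized conforming phantom configuration
#'
#' Places the requested numbers of fibroids by seeded rejection sampling so
#' that every fibroid conforms to its intended type with a margin (see
#' [generate_phantom()]) and no two fibroids touch. Radii are drawn uniformly
#' from `radius_range` (default 3-12 mm, i.e. diameters 6-24 mm).
#'
#' @param seed integer seed driving both placement and the phantom noise.
#' @param n_intramural,n_subserosal,n_submucosal fibroid counts by type.
#' @param radius_range radius range in mm.
#' @param ... further arguments passed to [phantom_config()].
#' @return A [phantom_config()].
#' @export
random_phantom_config <- function(seed, n_intramural = 3L, n_subserosal = 1L,
                                  n_submucosal = 1L, radius_range = c(3, 12),
                                  ...) {
  base <- phantom_config(fibroids = list(
    list(center = c(0, 0, 0), radius = 5, type = "intramural")), seed = seed, ...)
  d <- base$dim; sp <- base$spacing
  body <- ellipsoid_mask(d, sp, base$center, base$body_semiaxes)
  endo <- ellipsoid_mask(d, sp, base$center, base$endo_semiaxes)
  endo_dil <- dilate1(endo)

  types <- c(rep("intramural", n_intramural), rep("subserosal", n_subserosal),
             rep("submucosal", n_submucosal))
  fibroids <- withr::with_seed(seed, {
    placed <- list()
    occupied <- array(FALSE, d)
    for (ty in types) {
      success <- FALSE
      for (attempt in 1:500) {
        r <- runif(1, radius_range[1], radius_range[2])
        if (ty == "subserosal") {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          rb <- 1 / sqrt(sum((u / base$body_semiaxes)^2))
          ctr <- base$center + u * rb
        } else if (ty == "submucosal") {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          re <- 1 / sqrt(sum((u / base$endo_semiaxes)^2))
          ctr <- base$center + u * (re + 0.3 * r)
        } else {
          ctr <- base$center + (runif(3) * 2 - 1) * base$body_semiaxes
        }
        m <- sphere_mask(d, sp, ctr, r)
        if (!any(m)) next
        outside_frac <- mean(!body[m])
        md <- dilate1(m)
        ok <- switch(ty,
          intramural = all(body[md]) && !any(md & endo_dil),
          subserosal = outside_frac > base$exterior_fraction + 0.05 &&
                       outside_frac < 0.8 && !any(md & endo_dil),
          submucosal = any(m & endo) && outside_frac < 0.05)
        if (ok && !any(md & occupied)) {
          occupied <- occupied | m
          placed[[length(placed) + 1L]] <-
            list(center = ctr, radius = r, type = ty)
          success <- TRUE
          break
        }
      }
      if (!success)
        stop("could not place a conforming ", ty, " fibroid", call. = FALSE)
    }
    placed
  })
  phantom_config(fibroids = fibroids, seed = seed, ...)
}

#' Simulate manual key-slice tracing on a phantom
#'
#' Emulates the operator's sparse manual tracing: for each structure the
#' traced region is its anatomically filled extent (the body includes
#' everything it encloses, the endometrium includes submucosal in-growth,
#' fibroids are traced as themselves), contours are extracted on slices whose
#' 0-based index is a multiple of `slice_step` plus the last occupied slice,
#' and optional seeded boundary jitter perturbs the vertices to mimic
#' imperfect hand tracing. With `jitter = 0` the contours rasterize back to
#' the traced regions exactly.
#'
#' @param truth a `phantom_truth` (from [generate_phantom()]) or a
#'   [labelmap()].
#' @param slice_step key-slice stride (>= 1).
#' @param jitter standard deviation (mm) of the smoothed radial vertex
#'   perturbation; 0 disables it.
#' @param seed seed for the jitter noise.
#' @return A [keyslice_set()].
#' @export
simulate_key_slice_tracing <- function(truth, slice_step = 5L, jitter = 0,
                                       seed = 1L) {
  lm <- if (inherits(truth, "phantom_truth")) truth$labelmap else truth
  stopifnot(inherits(lm, "labelmap"), slice_step >= 1L)
  lab <- lm$labels
  d <- dim(lab)

  region_for <- function(code, k) {
    sl <- lab[, , k]
    switch(as.character(code),
      "1" = fill_holes2d(sl > 0L),
      "2" = fill_holes2d(sl == 2L),
      "3" = sl == 3L)
  }

  contours <- list()
  for (code in c(1L, 2L, 3L)) {
    present <- if (code == 1L) apply(lab > 0L, 3, any) else
      apply(lab == code, 3, any)
    occ <- which(present)                      # 1-based
    if (!length(occ)) next                     # absent structure: no contours
    keys <- occ[(occ - 1L) %% slice_step == 0L]
    keys <- sort(unique(c(keys, max(occ))))
    for (k in keys) {
      loops <- trace_slice_contours(region_for(code, k), lm$spacing[1:2],
                                    lm$origin[1:2])
      for (vm in loops) {
        if (jitter > 0)
          vm <- jitter_polygon(vm, jitter, seed + 1000L * code + k)
        contours[[length(contours) + 1L]] <-
          contour(code, k - 1L, vm, check = FALSE)
      }
    }
  }
  keyslice_set(contours, d, lm$spacing, lm$origin)
}

# smoothed seeded radial perturbation of a closed polygon
jitter_polygon <- function(v, sd_mm, seed) {
  n <- nrow(v)
  ctr <- colMeans(v)
  noise <- withr::with_seed(seed, rnorm(n, 0, sd_mm))
  # circular moving average keeps the perturbation low-frequency so the
  # polygon stays simple
  w <- 7L
  kern <- rep(1 / w, w)
  ext <- c(tail(noise, w), noise, head(noise, w))
  sm <- stats::filter(ext, kern, circular = FALSE)[(w + 1):(w + n)]
  sm <- sm * sd_mm / max(stats::sd(sm), 1e-9)
  dir <- sweep(v, 2, ctr)
  len <- sqrt(rowSums(dir^2)); len[len < 1e-9] <- 1
  v + dir / len * sm
}
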