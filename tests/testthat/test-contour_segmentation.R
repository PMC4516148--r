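test_that("contour validation rejects degenerate and tangled polygons", {
  expect_error(contour("body", 0, rbind(c(0, 0), c(1, 1))), "3 vertices")
  bowtie <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(contour("body", 0, bowtie), "self-intersecting")
  # orientation normalized to counterclockwise
  cw <- rbind(c(0, 0), c(0, 2), c(2, 2), c(2, 0))
  ct <- contour("body", 0, cw)
  expect_gt(uterusSR:::polygon_area_signed(ct$vertices_mm), 0)
})

test_that("rasterization follows the center-inclusion rule with boundary ties interior", {
  # 10 mm square with corners on the grid: 11x11 centers inside-or-on-boundary
  sq <- contour("body", 0, rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  m <- rasterize_contour(sq, c(20, 20), c(1, 1, 1))
  expect_equal(sum(m), 121L)
  expect_true(all(which(m, arr.ind = TRUE) >= 1 & which(m, arr.ind = TRUE) <= 11))

  # same square shifted off-grid by half a voxel: exactly 10x10 centers
  sq2 <- contour("body", 0, rbind(c(0.5, 0.5), c(10.5, 0.5), c(10.5, 10.5), c(0.5, 10.5)))
  expect_equal(sum(rasterize_contour(sq2, c(20, 20), c(1, 1, 1))), 100L)

  # circle r = 10 mm on a 1 mm grid: area within 3% of pi r^2
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  circ <- contour("body", 0, cbind(15 + 10 * cos(th), 15 + 10 * sin(th)))
  a <- sum(rasterize_contour(circ, c(31, 31), c(1, 1, 1)))
  expect_lt(abs(a - pi * 100) / (pi * 100), 0.03)
})

test_that("contour sets round-trip through the JSON dialect", {
  ph <- default_phantom()
  ks <- simulate_key_slice_tracing(ph$truth, slice_step = 8L)
  path <- withr::local_tempfile(fileext = ".json")
  write_contours(ks, path)
  ks2 <- read_contours(path)
  expect_equal(length(ks2$contours), length(ks$contours))
  expect_equal(ks2$dim, ks$dim)
  expect_equal(ks2$spacing, ks$spacing)
  for (i in seq_along(ks$contours)) {
    expect_equal(ks2$contours[[i]]$vertices_mm, ks$contours[[i]]$vertices_mm)
    expect_equal(ks2$contours[[i]]$structure, ks$contours[[i]]$structure)
  }
  # propagation from the reloaded set is identical
  expect_identical(propagate_segmentation(ks2)$labels,
                   propagate_segmentation(ks)$labels)
})

test_that("tracing a slice and rasterizing the loops reconstructs the mask", {
  for (s in c(2, 9, 22)) {
    set.seed(s)
    m <- matrix(runif(20 * 17) < 0.45, 20, 17)
    loops <- trace_slice_contours(m, spacing = c(1.3, 0.8))
    r <- matrix(FALSE, 20, 17)
    for (vm in loops)
      r <- xor(r, rasterize_contour(vm, c(20, 17), c(1.3, 0.8, 1)))
    expect_identical(r, m)
  }
})

test_that("shape-based interpolation blends signed distance fields", {
  # identical endpoints reproduce themselves on every intermediate slice
  d10 <- disk_mask(50, 10)
  mids <- interpolate_between(d10, d10, 4)
  expect_true(all(vapply(mids, identical, logical(1), d10)))

  # concentric disks: midpoint slice is the mean-radius disk within 1 voxel
  d20 <- disk_mask(50, 20)
  mid <- interpolate_between(d10, d20, 3)[[2]]
  expect_lt(abs(sum(mid) - pi * 15^2), pi * (16^2 - 15^2))  # radius 15 +- 1
  # interpolated areas are ordered
  areas <- vapply(interpolate_between(d10, d20, 3), sum, numeric(1))
  expect_true(all(diff(areas) > 0))

  # tapering towards an empty slice strictly shrinks
  tap <- vapply(interpolate_between(d20, matrix(FALSE, 50, 50), 3), sum, numeric(1))
  expect_true(all(diff(tap) < 0))
  expect_true(all(tap > 0))

  expect_error(interpolate_between(matrix(FALSE, 5, 5), matrix(FALSE, 5, 5), 2),
               "empty")
})

test_that("1D-profile interpolation matches per-column boundary interpolation", {
  # masks constant along rows: each column is an interval; for overlapping
  # intervals (as successive slices of a smooth organ are) shape-based
  # interpolation must match direct linear interpolation of the interval
  # endpoints to within one voxel
  mk <- function(lo, hi) { m <- matrix(FALSE, 40, 9); m[lo:hi, ] <- TRUE; m }
  A <- mk(5, 15); B <- mk(11, 25)
  n_mid <- 4L
  mids <- interpolate_between(A, B, n_mid)
  for (s in seq_len(n_mid)) {
    t <- s / (n_mid + 1)
    lo_exp <- (1 - t) * 5 + t * 11
    hi_exp <- (1 - t) * 15 + t * 25
    got <- range(which(mids[[s]][, 5]))
    expect_lt(abs(got[1] - lo_exp), 1.01)
    expect_lt(abs(got[2] - hi_exp), 1.01)
  }
})

test_that("propagation honors key slices, gaps and label priority", {
  ph <- default_phantom()
  lab <- ph$truth$labelmap$labels

  # a single key slice per structure fills only that slice
  ks1 <- simulate_key_slice_tracing(ph$truth, slice_step = 1000L)
  lm1 <- propagate_segmentation(ks1)
  filled <- which(apply(lm1$labels > 0L, 3, any))
  keyed <- sort(unique(vapply(ks1$contours, function(ct) ct$slice_index,
                              integer(1)))) + 1L
  expect_identical(filled, keyed)

  # key slices of a sparse tracing reproduce the truth slice exactly
  ks5 <- simulate_key_slice_tracing(ph$truth, slice_step = 5L)
  lm5 <- propagate_segmentation(ks5)
  body_keys <- vapply(Filter(function(ct) ct$structure == 1L, ks5$contours),
                      function(ct) ct$slice_index, integer(1))
  for (k in unique(body_keys) + 1L)
    expect_identical(lm5$labels[, , k], lab[, , k])

  # sparse tracing recovers the smooth body well
  d <- segmentation_metrics(lm5$labels == 1L, lab == 1L,
                            ph$truth$labelmap$spacing)$dice
  expect_gte(d, 0.95)

  # out-of-grid key slice is a bounds error
  ct <- contour("body", 70, rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  expect_error(keyslice_set(list(ct), c(96, 96, 64), c(1.5, 1.5, 2)),
               "outside the grid")
})

test_that("segmentation accuracy converges with tracing density", {
  for (seed in 1:3) {
    ph <- generate_phantom(random_phantom_config(seed))
    lab <- ph$truth$labelmap$labels
    dices <- vapply(c(10L, 5L, 2L, 1L), function(st) {
      lm <- propagate_segmentation(
        simulate_key_slice_tracing(ph$truth, slice_step = st))
      segmentation_metrics(lm$labels == 1L, lab == 1L,
                           ph$truth$labelmap$spacing)$dice
    }, numeric(1))
    expect_false(is.unsorted(dices))
  }
})

test_that("cross-plane correction removes specks and enforces nesting monotonically", {
  ph <- default_phantom()
  lm <- ph$truth$labelmap

  # idempotent on a clean, consistent segmentation
  expect_identical(cross_plane_correct(lm)$labels, lm$labels)

  # a 2-voxel satellite speck of body disappears; main component unchanged
  lab2 <- lm$labels
  lab2[2, 2, 2] <- 1L; lab2[2, 3, 2] <- 1L
  expect_identical(cross_plane_correct(labelmap(lab2, lm$spacing))$labels,
                   lm$labels)

  # sub-threshold fibroid specks disappear, larger ones survive
  lab3 <- lm$labels
  lab3[1:2, 1, 1] <- 3L
  corrected <- cross_plane_correct(labelmap(lab3, lm$spacing),
                                   min_fibroid_voxels = 5L)
  expect_identical(corrected$labels, lm$labels)

  # endometrium fully outside the body is emptied
  lab4 <- array(0L, c(30, 30, 20))
  lab4[5:15, 5:15, 5:10] <- 1L
  lab4[25:28, 25:28, 12:15] <- 2L
  cc4 <- cross_plane_correct(labelmap(lab4))
  expect_equal(sum(cc4$labels == 2L), 0L)
  expect_equal(sum(cc4$labels == 1L), sum(lab4 == 1L))

  # correction never adds voxels (per label, output subset of input)
  set.seed(99)
  noisy <- array(sample(0:3, 20^3, TRUE, prob = c(0.9, 0.05, 0.03, 0.02)),
                 c(20, 20, 20))
  out <- cross_plane_correct(labelmap(noisy))$labels
  for (code in 1:3)
    expect_true(all(noisy[out == code] == code))
})
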