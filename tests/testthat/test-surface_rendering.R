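# enclosed volumes of the same 20 seeded random smooth blobs (unions of 1-2
# random ellipsoids, anatomy-like masks where the isosurface is unambiguous)
# computed with an independent marching-cubes implementation (scikit-image,
# classic tables)
SKIMAGE_MC_VOLUMES <- c(
  669.166687, 643.291687, 452.166656, 948.708313, 520.833313, 1010.916687,
  757.541687, 704.458313, 358.166656, 271.333344, 666.625000, 732.416687,
  1110.166626, 842.916687, 729.916687, 410.875000, 779.625000, 687.000000,
  334.250000, 901.458313)

random_blob_mask <- function(seed) {
  set.seed(seed)
  m <- array(FALSE, c(18, 18, 18))
  for (b in seq_len(sample(1:2, 1))) {
    ctr <- runif(3, 6, 13); ax <- runif(3, 3.5, 6.5)
    idx <- which(array(TRUE, c(18, 18, 18)), arr.ind = TRUE)
    v <- rowSums(sweep(idx, 2, ctr)^2 / matrix(ax^2, nrow(idx), 3, byrow = TRUE))
    m[idx[v <= 1, , drop = FALSE]] <- TRUE
  }
  m
}

test_that("a single voxel yields a closed topological sphere", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  m <- marching_cubes(one)
  V <- nrow(m$vertices); F <- nrow(m$faces); E <- mesh_edge_count(m)
  expect_equal(V - E + F, 2L)
  expect_true(mesh_metrics(m)$watertight)
  expect_gt(uterusSR:::mesh_signed_volume(m), 0)   # outward orientation
})

test_that("marching cubes recovers sphere volume and closes at volume borders", {
  ball <- ball_mask(25, 10, c(12, 12, 12))
  m <- marching_cubes(ball, spacing = c(1, 1, 1))
  met <- mesh_metrics(m)
  expect_true(met$watertight)
  analytic_v <- 4 / 3 * pi * 10^3
  expect_lt(abs(met$volume_mm3 - analytic_v) / analytic_v, 0.03)
  # raw binary-mask extraction carries staircase area; smoothing (below)
  # brings it to the analytic value
  expect_lt(abs(met$area_mm2 - 4 * pi * 100) / (4 * pi * 100), 0.12)

  # a ball touching the array border still closes (padding)
  edge_ball <- ball_mask(12, 6, c(1, 6, 6))
  expect_true(mesh_metrics(marching_cubes(edge_ball))$watertight)

  expect_equal(nrow(marching_cubes(array(FALSE, c(4, 4, 4)))$faces), 0L)
})

test_that("anisotropic spacing scales mesh volume correctly", {
  ball <- ball_mask(25, 10, c(12, 12, 12))
  m <- marching_cubes(ball, spacing = c(1.5, 1.5, 2))
  met <- mesh_metrics(m)
  expect_lt(abs(met$volume_mm3 - 4 / 3 * pi * 1000 * 1.5 * 1.5 * 2) /
              (4 / 3 * pi * 1000 * 4.5), 0.03)
})

test_that("meshes stay watertight on 50 random masks", {
  for (s in 1:50) {
    set.seed(s)
    m <- array(runif(6 * 6 * 6) < 0.4, c(6, 6, 6))
    mesh <- marching_cubes(m)
    if (nrow(mesh$faces))
      expect_true(mesh_metrics(mesh)$watertight)
  }
})

test_that("enclosed volume agrees with an independent implementation within 1%", {
  for (s in 1:20) {
    m <- random_blob_mask(s)
    vol <- abs(mesh_metrics(marching_cubes(m))$volume_mm3)
    expect_lt(abs(vol - SKIMAGE_MC_VOLUMES[s]) / SKIMAGE_MC_VOLUMES[s], 0.01)
  }
})

test_that("smoothing preserves topology and volume while relaxing staircase", {
  ball <- ball_mask(25, 10, c(12, 12, 12))
  m <- marching_cubes(ball)

  expect_identical(smooth_mesh(m, iterations = 0L), m)

  sm <- smooth_mesh(m, 20L)
  expect_identical(dim(sm$vertices), dim(m$vertices))
  expect_identical(sm$faces, m$faces)            # V, E, F unchanged
  v0 <- mesh_metrics(m); v1 <- mesh_metrics(sm)
  expect_lt(abs(v1$volume_mm3 - v0$volume_mm3) / abs(v0$volume_mm3), 0.02)
  expect_lte(v1$area_mm2, v0$area_mm2)
  # smoothed surface approaches the analytic sphere area
  expect_lt(abs(v1$area_mm2 - 4 * pi * 100) / (4 * pi * 100), 0.05)

  # pure shrink steps contract strictly towards the centroid
  cube <- marching_cubes(ball_mask(10, 4, c(5, 5, 5)))
  dev <- numeric(10)
  mm <- cube
  for (i in 1:10) {
    mm <- smooth_mesh(mm, 1L, lambda = 0.5, mu = 0)
    ctr <- colMeans(mm$vertices)
    dev[i] <- max(sqrt(rowSums(sweep(mm$vertices, 2, ctr)^2)))
  }
  expect_true(all(diff(dev) < 0))

  expect_warning(
    smooth_mesh(surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                             rbind(c(1L, 2L, 3L))), 1L),
    "watertight")
})

test_that("mesh metrics are exact on an analytic cube", {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  colnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),    # z = 0
    c(5, 6, 7), c(6, 8, 7),    # z = 1
    c(1, 2, 5), c(2, 6, 5),    # y = 0
    c(3, 7, 4), c(4, 7, 8),    # y = 1
    c(1, 5, 3), c(3, 5, 7),    # x = 0
    c(2, 4, 6), c(4, 8, 6))    # x = 1
  cube <- surface_mesh(v, f)
  met <- mesh_metrics(cube)
  expect_equal(met$area_mm2, 6)
  expect_equal(met$volume_mm3, 1)
  expect_true(met$watertight)

  holed <- surface_mesh(v, f[-1, ])
  expect_false(mesh_metrics(holed)$watertight)

  expect_error(surface_mesh(v, rbind(c(1L, 1L, 2L))), "degenerate")
  expect_error(surface_mesh(v, rbind(c(1L, 2L, 9L))), "out of range")
})

test_that("the assembled scene has one colored mesh per structure component", {
  ph <- default_phantom()
  sc <- assemble_scene(ph$truth$labelmap)
  cols <- vapply(sc, function(m) m$color, character(1))
  expect_equal(sum(cols == "red"), 1L)
  expect_equal(sum(cols == "yellow"), 1L)
  expect_equal(sum(cols == "green"), 4L)

  # green mesh volumes agree with the fibroid voxel volume within 5%
  gv <- sum(vapply(Filter(function(m) m$structure == 3L, sc),
                   function(m) abs(uterusSR:::mesh_signed_volume(m)), numeric(1)))
  vv <- sum(ph$truth$labelmap$labels == 3L) * prod(ph$truth$labelmap$spacing)
  expect_lt(abs(gv - vv) / vv, 0.05)

  empty <- assemble_scene(labelmap(array(0L, c(5, 5, 5))))
  expect_length(empty, 0L)
})

test_that("mesh exports carry geometry and structure colors", {
  ph <- default_phantom()
  sc <- assemble_scene(ph$truth$labelmap, smooth = FALSE,
                       min_fibroid_voxels = 500L)
  ply <- withr::local_tempfile(fileext = ".ply")
  write_ply(sc, ply)
  lines <- readLines(ply)
  nv <- sum(vapply(sc, function(m) nrow(m$vertices), integer(1)))
  nf <- sum(vapply(sc, function(m) nrow(m$faces), integer(1)))
  expect_true(paste("element vertex", nv) %in% lines)
  expect_true(paste("element face", nf) %in% lines)
  body_line <- lines[which(lines == "end_header") + 1L]
  expect_match(body_line, " 255 0 0$")            # body is red

  stl <- withr::local_tempfile(fileext = ".stl")
  write_stl(sc[[1]], stl)
  expect_equal(sum(grepl("^facet", readLines(stl))), nrow(sc[[1]]$faces))

  obj <- withr::local_tempfile(fileext = ".obj")
  write_obj(sc, obj)
  expect_true(any(grepl("^usemtl body", readLines(obj))))
  expect_true(file.exists(sub("\\.obj$", ".mtl", obj)))
})
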