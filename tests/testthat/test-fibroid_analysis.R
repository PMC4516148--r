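test_that("fibroid components are counted with 26-connectivity", {
  ph <- default_phantom()
  recs <- find_fibroids(ph$truth$labelmap)
  expect_equal(nrow(recs), 4L)
  expect_equal(recs$volume_mm3, recs$n_voxels * prod(ph$truth$labelmap$spacing))
  # loose sanity bound: diameter at least the cube root of volume
  expect_true(all(recs$max_diameter_mm >= recs$volume_mm3^(1 / 3)))

  # two spheres touching face-to-face merge into one component
  lab <- array(0L, c(30, 30, 30))
  lab[5:10, 10:15, 10:15] <- 3L
  lab[11:16, 10:15, 10:15] <- 3L
  expect_equal(nrow(find_fibroids(labelmap(lab))), 1L)
  # ... and diagonally-touching voxels as well (26-connectivity)
  lab2 <- array(0L, c(10, 10, 10))
  lab2[2:4, 2:4, 2:4] <- 3L
  lab2[5, 5, 5] <- 3L; lab2[5:7, 5:7, 5:7] <- 3L
  expect_equal(nrow(find_fibroids(labelmap(lab2))), 1L)

  expect_equal(nrow(find_fibroids(labelmap(array(0L, c(5, 5, 5))))), 0L)
})

test_that("maximum diameter is measured in mm on the anisotropic grid", {
  # sphere of radius 12 mm (24 mm diameter, the top of the clinical range)
  cfg <- phantom_config(dim = c(48, 48, 44), spacing = c(1.5, 1.5, 2),
                        body_semiaxes = c(34, 33, 40),
                        endo_semiaxes = c(4, 3, 4),
                        fibroids = list(list(center = c(35.25, 35.25, 63),
                                             radius = 12, type = "intramural")))
  ph <- generate_phantom(cfg)
  recs <- find_fibroids(ph$truth$labelmap)
  voxel_diag <- sqrt(sum(c(1.5, 1.5, 2)^2))
  expect_lt(abs(recs$max_diameter_mm - 24), voxel_diag)

  # exact agreement with a brute-force all-pairs oracle
  lab <- ph$truth$labelmap$labels
  idx <- which(lab == 3L, arr.ind = TRUE)
  pts <- sweep(idx - 1L, 2, c(1.5, 1.5, 2), `*`)
  expect_lte(nrow(pts), 5000L)
  oracle <- max(stats::dist(pts))
  expect_equal(recs$max_diameter_mm, oracle)
})

test_that("anatomical type classification follows the geometric rules", {
  ph <- default_phantom()
  lab <- ph$truth$labelmap$labels
  cc <- label_components(lab == 3L, 26L)
  body <- lab == 1L; endo <- lab == 2L

  # the phantom's subserosal fibroid (about half outside) is recovered
  recs <- classify_fibroids(ph$truth$labelmap)
  truth_types <- ph$truth$fibroids
  for (r in seq_len(nrow(recs))) {
    ctr <- c(recs$centroid_x[r], recs$centroid_y[r], recs$centroid_z[r])
    d <- sqrt(rowSums(sweep(as.matrix(truth_types[, c("center_x", "center_y",
                                                      "center_z")]), 2, ctr)^2))
    expect_equal(recs$type[r], truth_types$type[which.min(d)])
  }

  # hand-built cases for each rule
  expect_equal(classify_fibroid(cc == 1L, body, endo), recs$type[1])
  expect_error(classify_fibroid(array(FALSE, dim(lab)), body, endo), "empty")
})

test_that("intended types are recovered perfectly on conforming phantoms", {
  n_total <- 0L
  for (seed in 1:5) {
    cfg <- random_phantom_config(seed, n_intramural = 4L, n_subserosal = 1L,
                                 n_submucosal = 1L)
    ph <- generate_phantom(cfg)
    recs <- classify_fibroids(ph$truth$labelmap)
    truth <- ph$truth$fibroids
    expect_equal(nrow(recs), nrow(truth))
    for (r in seq_len(nrow(recs))) {
      ctr <- c(recs$centroid_x[r], recs$centroid_y[r], recs$centroid_z[r])
      d <- sqrt(rowSums(sweep(as.matrix(truth[, c("center_x", "center_y",
                                                  "center_z")]), 2, ctr)^2))
      expect_equal(recs$type[r], truth$type[which.min(d)])
    }
    n_total <- n_total + nrow(recs)
  }
  expect_gte(n_total, 30L)
})

test_that("the planning report applies the removal and procedure heuristics", {
  mk_rec <- function(types, diam) data.frame(
    id = seq_along(types), n_voxels = rep(100L, length(types)),
    volume_mm3 = rep(450, length(types)), max_diameter_mm = diam,
    centroid_x = rep(0, length(types)), centroid_y = rep(0, length(types)),
    centroid_z = rep(0, length(types)), type = types, stringsAsFactors = FALSE)

  # single submucosal fibroid -> TCR
  r1 <- build_report(mk_rec("submucosal", 10))
  expect_equal(r1$procedure, "TCR")
  expect_equal(r1$n_removal, 1L)

  # 3 large intramural + 1 subserosal -> LAM
  r2 <- build_report(mk_rec(c(rep("intramural", 3), "subserosal"),
                            c(30, 28, 26, 15)))
  expect_equal(r2$procedure, "LAM")
  expect_equal(r2$n_removal, 4L)
  expect_equal(unname(r2$by_type), c(3L, 1L, 0L))

  # intramural-only removals -> TLM; small intramural not removed
  r3 <- build_report(mk_rec(c("intramural", "intramural"), c(30, 10)))
  expect_equal(r3$procedure, "TLM")
  expect_equal(r3$n_removal, 1L)
  expect_false(r3$records$removal_recommended[2])

  # no fibroids -> empty report, no procedure
  r0 <- build_report(mk_rec(character(0), numeric(0)))
  expect_equal(r0$total, 0L)
  expect_true(is.na(r0$procedure))

  # counts by type always sum to the total
  set.seed(5)
  for (i in 1:10) {
    tys <- sample(c("intramural", "subserosal", "submucosal"), i, TRUE)
    rep_i <- build_report(mk_rec(tys, runif(i, 5, 40)))
    expect_equal(sum(rep_i$by_type), rep_i$total)
  }

  expect_error(build_report(mk_rec(NA_character_, 10)), "classified")
})

test_that("reports serialize to CSV and JSON", {
  ph <- default_phantom()
  rep <- build_report(classify_fibroids(ph$truth$labelmap))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), rep$total)
  expect_true("removal_recommended" %in% names(back))

  js <- withr::local_tempfile(fileext = ".json")
  write_report(rep, js)
  obj <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(obj$total, rep$total)
  expect_equal(obj$procedure, rep$procedure)
})
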