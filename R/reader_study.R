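# md5 of the packaged reader-study transcription; guards against silent
# corruption of the fixture
READER_STUDY_MD5 <- "f65b2a18ced21da209effc2d3d6b66b3"

#' Load the packaged reader-study table
#'
#' Returns the transcription of the 10-case reader study: the gold-standard
#' procedure and per-type removal counts, both observers' interpretations
#' (procedure choice and fibroid count, each read from sagittal and from
#' surface-rendered images), and the required-time / difficulty-score summary
#' statistics. The file's checksum is verified on load.
#'
#' @param path optional path to an alternative fixture file (checksum then
#'   not enforced).
#' @return An object of class `reader_study_table`: list with `cases` (data
#'   frame, one row per case), `summaries` (data frame of mean/sd/n) and
#'   `n_cases`.
#' @export
load_reader_study <- function(path = NULL) {
  builtin <- is.null(path)
  if (builtin) {
    path <- system.file("extdata", "reader_study.json", package = "uterusSR")
    if (!nzchar(path) || !file.exists(path))
      stop("packaged reader-study fixture not found", call. = FALSE)
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, READER_STUDY_MD5))
      stop("reader-study fixture integrity check failed (md5 ", md5, ")",
           call. = FALSE)
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cases <- obj$cases
  summaries <- obj$summaries
  stopifnot(is.data.frame(cases), is.data.frame(summaries))
  if (any(!cases$gold_procedure %in% c("AM", "LAM", "TLM", "TCR")))
    stop("invalid procedure code in fixture", call. = FALSE)
  structure(list(cases = cases, summaries = summaries,
                 n_cases = obj$n_cases),
            class = "reader_study_table")
}

#' @export
print.reader_study_table <- function(x, ...) {
  cat(sprintf("<reader_study_table> %d cases, 2 observers x 2 methods\n",
              x$n_cases))
  invisible(x)
}

#' Concordance rate with the gold standard
#'
#' The accuracy measure of the reader study: the fraction of cases in which
#' an observer's interpretation equals the gold standard exactly.
#'
#' @param observed,gold equal-length vectors.
#' @return The fraction of exactly matching positions.
#' @export
concordance_rate <- function(observed, gold) {
  if (length(observed) != length(gold))
    stop("observed and gold-standard vectors differ in length", call. = FALSE)
  if (!length(observed))
    stop("empty input", call. = FALSE)
  mean(observed == gold)
}

#' Two-sample t test from summary statistics
#'
#' Student's pooled-variance unpaired t test (default) or Welch's test,
#' computed from group means, standard deviations and sizes rather than raw
#' values — the form needed when only published summary statistics are
#' available.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @param var_equal pooled-variance (Student) test if `TRUE` (default),
#'   Welch-Satterthwaite otherwise.
#' @return list with `statistic` (t), `df` and `p.value` (two-sided).
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                var_equal = TRUE) {
  if (n1 < 2 || n2 < 2)
    stop("both groups need n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0)
    stop("standard deviations must be non-negative", call. = FALSE)
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- (sd1^2 / n1 + sd2^2 / n2)^2 /
      ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  t <- if (se == 0) 0 else (mean1 - mean2) / se
  list(statistic = t, df = df, p.value = 2 * pt(-abs(t), df))
}

#' Accuracy table of the reader study
#'
#' Recomputes all eight concordance rates (2 observers x 2 reading methods x
#' 2 measures) of the reader study from the per-case interpretations against
#' the gold standard.
#'
#' @param table a [load_reader_study()] result.
#' @return data frame with columns `measure` (`procedure`/`count`),
#'   `observer`, `method` (`sagittal`/`sr`), `n_correct`, `n`, `percent`.
#' @export
make_table4 <- function(table = load_reader_study()) {
  stopifnot(inherits(table, "reader_study_table"))
  ca <- table$cases
  rows <- list()
  for (measure in c("procedure", "count")) {
    gold <- if (measure == "procedure") ca$gold_procedure else ca$gold_count
    for (obs in 1:2) for (method in c("sagittal", "sr")) {
      col <- paste0(measure, "_o", obs, "_", method)
      rate <- concordance_rate(ca[[col]], gold)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = measure, observer = obs, method = method,
        n_correct = as.integer(round(rate * nrow(ca))), n = nrow(ca),
        percent = 100 * rate, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Reader-study t tests from the published summary statistics
#'
#' Compares sagittal versus surface-rendered reading per observer for the
#' required time and the difficulty score, using [t_test_from_summary()].
#'
#' @param table a [load_reader_study()] result.
#' @param var_equal pooled-variance test if `TRUE` (default).
#' @return data frame with `observer`, `measure`, group summaries, `t`, `df`
#'   and `p.value`.
#' @export
reader_study_ttests <- function(table = load_reader_study(), var_equal = TRUE) {
  stopifnot(inherits(table, "reader_study_table"))
  s <- table$summaries
  rows <- list()
  for (measure in unique(s$measure)) for (obs in sort(unique(s$observer))) {
    g1 <- s[s$measure == measure & s$observer == obs & s$method == "sagittal", ]
    g2 <- s[s$measure == measure & s$observer == obs & s$method == "sr", ]
    tt <- t_test_from_summary(g1$mean, g1$sd, g1$n, g2$mean, g2$sd, g2$n,
                              var_equal = var_equal)
    rows[[length(rows) + 1L]] <- data.frame(
      observer = obs, measure = measure,
      mean_sagittal = g1$mean, sd_sagittal = g1$sd,
      mean_sr = g2$mean, sd_sr = g2$sd, n = g1$n,
      t = tt$statistic, df = tt$df, p.value = tt$p.value,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Removal-count arithmetic of the gold standard
#'
#' @param table a [load_reader_study()] result.
#' @return list with `total` fibroids to be removed, `by_type` (intramural,
#'   subserosal, submucosal) and `per_patient_mean`.
#' @export
gold_standard_summary <- function(table = load_reader_study()) {
  stopifnot(inherits(table, "reader_study_table"))
  ca <- table$cases
  by_type <- c(intramural = sum(ca$gold_intramural),
               subserosal = sum(ca$gold_subserosal),
               submucosal = sum(ca$gold_submucosal))
  list(total = sum(by_type), by_type = by_type,
       per_patient_mean = sum(by_type) / nrow(ca))
}

#' Overlap and surface-distance metrics between two segmentations
#'
#' Dice coefficient `2|A n B| / (|A| + |B|)` and the symmetric Hausdorff
#' distance (max of the two directed max-min voxel-center distances, in mm).
#' Two empty masks agree perfectly (Dice 1, Hausdorff 0).
#'
#' @param pred,truth logical 3D arrays on the same grid (or [labelmap()]s,
#'   compared as `labels > 0`).
#' @param spacing voxel spacing in mm (taken from `pred` if it is a
#'   [labelmap()]).
#' @return list with `dice` and `hausdorff_mm`.
#' @export
segmentation_metrics <- function(pred, truth, spacing = c(1, 1, 1)) {
  if (inherits(pred, "labelmap")) { spacing <- pred$spacing; pred <- pred$labels > 0L }
  if (inherits(truth, "labelmap")) truth <- truth$labels > 0L
  if (!identical(dim(pred), dim(truth)))
    stop("masks are on different grids", call. = FALSE)
  na <- sum(pred); nb <- sum(truth)
  if (na == 0 && nb == 0) return(list(dice = 1, hausdorff_mm = 0))
  inter <- sum(pred & truth)
  dice <- 2 * inter / (na + nb)
  if (na == 0 || nb == 0) return(list(dice = 0, hausdorff_mm = Inf))

  coords <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    sweep(idx - 1L, 2, spacing, `*`)
  }
  # d(a, B) is 0 inside B and attained against B's boundary otherwise
  bA <- coords(boundary_voxels(pred))
  bB <- coords(boundary_voxels(truth))
  onlyA <- coords(pred & !truth)
  onlyB <- coords(truth & !pred)
  h1 <- if (nrow(onlyA)) .directed_hausdorff(onlyA, bB) else 0
  h2 <- if (nrow(onlyB)) .directed_hausdorff(onlyB, bA) else 0
  list(dice = dice, hausdorff_mm = max(h1, h2))
}
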