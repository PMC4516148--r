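# Shared geometric fixtures, built in code at test time.

# voxelized ball: TRUE where the voxel center lies within radius r (voxels
# are unit-index here; callers supply spacing to the functions under test)
ball_mask <- function(n, r, center = rep((n + 1) / 2, 3)) {
  idx <- which(array(TRUE, c(n, n, n)), arr.ind = TRUE)
  m <- array(FALSE, c(n, n, n))
  m[idx[rowSums(sweep(idx, 2, center)^2) <= r^2, , drop = FALSE]] <- TRUE
  m
}

disk_mask <- function(n, r, center = c((n + 1) / 2, (n + 1) / 2)) {
  xs <- (seq_len(n) - center[1])^2
  ys <- (seq_len(n) - center[2])^2
  outer(xs, ys, `+`) <= r^2
}

# undirected edge count of a triangle mesh
mesh_edge_count <- function(mesh) {
  e <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  nrow(unique(t(apply(e, 1, sort))))
}

# the default phantom is used by several files; generate it once
phantom_cache <- new.env(parent = emptyenv())
default_phantom <- function() {
  if (is.null(phantom_cache$ph))
    phantom_cache$ph <- generate_phantom(phantom_config())
  phantom_cache$ph
}

# run the installed command-line script in a fresh R session; paths in args
# should be absolute
run_cli <- function(args) {
  cli <- system.file("scripts", "uterusSR", package = "uterusSR")
  res <- suppressWarnings(system2(
    "Rscript", c(shQuote(cli), args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  list(status = attr(res, "status") %||% 0L, output = res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
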