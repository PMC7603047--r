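# Shared phantoms and lazily computed (memoised) fixtures. Everything is
# generated in code; the heavier fixtures are computed once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

ball_array <- function(dims, center, radius) {
  x <- seq_len(dims[1]) - 1
  y <- seq_len(dims[2]) - 1
  z <- seq_len(dims[3]) - 1
  outer(outer((x - center[1])^2, (y - center[2])^2, "+"),
        (z - center[3])^2, "+") <= radius^2
}

torus_array <- function(dims, center, R0, r0) {
  x <- seq_len(dims[1]) - 1
  y <- seq_len(dims[2]) - 1
  z <- seq_len(dims[3]) - 1
  g <- expand.grid(i = x, j = y, k = z)
  arr <- (sqrt((g$i - center[1])^2 + (g$j - center[2])^2) - R0)^2 +
    (g$k - center[3])^2 <= r0^2
  array(arr, dims)
}

# standard 64^3 synthetic trabecular volume and derived masks
fx_vol64 <- function()
  memo("vol64", generate_trabecular_volume(
    synth_spec(dims = c(64, 64, 64), target_bvtv = 0.20, seed = 3)))

fx_bone64 <- function() memo("bone64", segment_bone(fx_vol64()))

fx_contour64 <- function()
  memo("contour64", suppressWarnings(bone_contour_mask(fx_bone64(), 8)))

fx_grid64 <- function() memo("grid64", build_grid(c(64, 64, 64), 39, 16))

# 1% uniform axial compression of the standard volume, registered
fx_vd64 <- function()
  memo("vd64", apply_virtual_deformation(fx_vol64(), deformation_uniform(-0.01)))

fx_field64 <- function()
  memo("field64", suppressWarnings(
    dvc_register(fx_vol64(), fx_vd64()$volume, fx_grid64())))

# zero-strain NS sweep on a noisy repeated pair (78 um resampled scale)
fx_sweep104 <- function()
  memo("sweep104", {
    v <- generate_trabecular_volume(
      synth_spec(dims = c(104, 104, 104), target_bvtv = 0.20, seed = 11,
                 voxel_size = 78))
    n1 <- add_imaging_noise(v, 5, seed = 21)
    n2 <- add_imaging_noise(v, 5, seed = 22)
    suppressWarnings(zero_strain_study(n1, n2, ns_list = c(13, 25, 35, 50)))
  })

# analytically prescribed nodal displacement field u(x) = A x + b (um)
analytic_field <- function(grid, A, b = c(0, 0, 0)) {
  counts <- grid$counts
  u <- array(0, c(counts, 3))
  for (k in seq_len(counts[3]))
    for (j in seq_len(counts[2]))
      for (i in seq_len(counts[1])) {
        pos <- c(grid$coords[[1]][i], grid$coords[[2]][j],
                 grid$coords[[3]][k]) * grid$voxel_size
        u[i, j, k, ] <- as.numeric(A %*% pos) + b
      }
  structure(list(grid = grid, u = u, u_vox = u / grid$voxel_size,
                 converged = TRUE, residual_rms = 0,
                 smoothing_weight = 0,
                 low_confidence = array(FALSE, counts),
                 node_coverage = array(1, counts), iterations = 0),
            class = "displacement_field")
}

# minimal hand-built strain field for metric contract tests
manual_strain_field <- function(grid, E, keep = NULL) {
  counts <- grid$counts
  stopifnot(identical(dim(E), as.integer(c(counts, 6))))
  dimnames(E) <- list(NULL, NULL, NULL,
                      c("ex", "ey", "ez", "exy", "eyz", "exz"))
  principal <- array(0, c(counts, 3))
  eqv <- array(0, counts)
  for (k in seq_len(counts[3]))
    for (j in seq_len(counts[2]))
      for (i in seq_len(counts[1])) {
        p <- principal_strains(E[i, j, k, ])
        principal[i, j, k, ] <- p
        eqv[i, j, k] <- von_mises_strain(p)
      }
  if (is.null(keep)) keep <- array(TRUE, counts)
  structure(list(grid = grid, E = E, principal = principal, eqv = eqv,
                 keep = keep, boundary = array(FALSE, counts),
                 u = array(0, c(counts, 3)), converged = TRUE),
            class = "strain_field")
}

random_symmetric_tensor <- function() {
  m <- matrix(rnorm(9, sd = 5000), 3, 3)
  (m + t(m)) / 2
}
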