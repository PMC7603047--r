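# Strain differentiation on the hexahedral grid, tensor invariants, and
# node masking.

test_that("differentiating analytic linear fields gives exact constant strain", {
  g <- build_grid(c(64, 64, 64), 39, 16)

  # uniform axial compression: u_z = -0.01 z
  A1 <- matrix(0, 3, 3); A1[3, 3] <- -0.01
  s1 <- differentiate_strain(analytic_field(g, A1))
  expect_equal(max(abs(s1$E[, , , "ez"] - (-10000))), 0, tolerance = 1e-6)
  for (comp in c("ex", "ey", "exy", "eyz", "exz"))
    expect_lt(max(abs(s1$E[, , , comp])), 1e-9)

  # simple shear u_x = c y, u_y = c x -> tensor shear exy = c
  c0 <- 0.004
  A2 <- matrix(0, 3, 3); A2[1, 2] <- c0; A2[2, 1] <- c0
  s2 <- differentiate_strain(analytic_field(g, A2))
  expect_equal(max(abs(s2$E[, , , "exy"] - c0 * 1e6)), 0, tolerance = 1e-6)
  expect_lt(max(abs(s2$E[, , , "ez"])), 1e-9)

  # random linear field: strain = sym(A) at every node, via central-difference
  # oracle on the displacement samples
  set.seed(4)
  A3 <- matrix(rnorm(9, sd = 0.005), 3, 3)
  f3 <- analytic_field(g, A3)
  s3 <- differentiate_strain(f3)
  sym <- (A3 + t(A3)) / 2 * 1e6
  comps <- c("ex", "ey", "ez", "exy", "eyz", "exz")
  want <- c(sym[1, 1], sym[2, 2], sym[3, 3], sym[1, 2], sym[2, 3], sym[1, 3])
  for (m in 1:6)
    expect_equal(max(abs(s3$E[, , , comps[m]] - want[m])) / max(abs(want)), 0,
                 tolerance = 1e-9)
  # central-difference oracle on nodal samples reproduces the same gradient
  h <- g$spacing_um
  cd <- (f3$u[3, 2, 2, 1] - f3$u[1, 2, 2, 1]) / (2 * h) * 1e6
  expect_equal(unname(s3$E[2, 2, 2, "ex"]), cd, tolerance = 1e-9)
})

test_that("rigid translation produces no strain", {
  g <- build_grid(c(64, 64, 64), 39, 16)
  f <- analytic_field(g, matrix(0, 3, 3), b = c(120, -45, 77))
  s <- differentiate_strain(f)
  expect_lt(max(abs(s$E)), 10)
})

test_that("principal strains match the characteristic-polynomial oracle", {
  expect_equal(principal_strains(diag(c(-0.01, 0, 0)))[3], -0.01)
  expect_equal(principal_strains(diag(3) * 0.002), rep(0.002, 3))
  set.seed(11)
  for (i in 1:25) {
    Tm <- random_symmetric_tensor()
    p <- principal_strains(Tm)
    expect_true(p[1] >= p[2] && p[2] >= p[3])
    # roots of det(T - x I) via polyroot (independent of eigen)
    c2 <- -sum(diag(Tm))
    c1 <- sum(diag(Tm)[c(1, 1, 2)] * diag(Tm)[c(2, 3, 3)]) -
      Tm[1, 2]^2 - Tm[1, 3]^2 - Tm[2, 3]^2
    c0 <- -det(Tm)
    roots <- sort(Re(polyroot(c(c0, c1, c2, 1))), decreasing = TRUE)
    expect_equal(p, roots, tolerance = 1e-10)
  }
  expect_error(principal_strains(matrix(c(NA, rep(0, 8)), 3, 3)), "finite")
})

test_that("von Mises strain is a rotation-invariant deviatoric measure", {
  expect_equal(von_mises_strain(diag(3) * 0.01), 0)
  expect_equal(von_mises_strain(diag(c(-0.01, 0, 0))), 2 / 3 * 0.01,
               tolerance = 1e-12)
  expect_equal(round(von_mises_strain(diag(c(-10000, 0, 0)))), 6667)
  set.seed(21)
  for (i in 1:10) {
    Tm <- random_symmetric_tensor()
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    expect_equal(von_mises_strain(Q %*% Tm %*% t(Q)), von_mises_strain(Tm),
                 tolerance = 1e-10)
  }
  # nu = 0.3 scaling convention
  expect_equal(von_mises_strain(diag(c(1, 0, 0)), nu = 0.3),
               (2 / 3) * 1.5 / 1.3, tolerance = 1e-12)
})

test_that("trace identity holds at every node of a measured field", {
  s <- differentiate_strain(fx_field64())
  tr6 <- s$E[, , , "ex"] + s$E[, , , "ey"] + s$E[, , , "ez"]
  trp <- s$principal[, , , 1] + s$principal[, , , 2] + s$principal[, , , 3]
  expect_equal(as.vector(tr6), as.vector(trp),
               tolerance = 1e-6)
})

test_that("mask_nodes drops exactly the low-coverage nodes", {
  g <- fx_grid64()
  s <- differentiate_strain(fx_field64())
  # mask: everything except a cyst-like hole swallowing node (2,2,2)
  m <- array(TRUE, c(64, 64, 64))
  hole <- ball_array(c(64, 64, 64), c(16, 16, 16), 14)
  m[hole] <- FALSE
  msk <- binary_mask(m, 39)
  sm <- mask_nodes(s, msk, coverage_cutoff = 0.05)
  expect_false(sm$keep[2, 2, 2])

  # brute-force per-node coverage oracle
  half <- floor(g$ns / 2)
  cov_oracle <- array(0, g$counts)
  for (k in seq_len(g$counts[3]))
    for (j in seq_len(g$counts[2]))
      for (i in seq_len(g$counts[1])) {
        px <- g$coords[[1]][i]; py <- g$coords[[2]][j]; pz <- g$coords[[3]][k]
        xr <- max(px - half, 0):min(px + half, 63) + 1
        yr <- max(py - half, 0):min(py + half, 63) + 1
        zr <- max(pz - half, 0):min(pz + half, 63) + 1
        cov_oracle[i, j, k] <- mean(m[xr, yr, zr])
      }
  expect_equal(sum(!sm$keep), sum(cov_oracle < 0.05))

  # full mask leaves the field unchanged
  sfull <- mask_nodes(s, binary_mask(array(TRUE, c(64, 64, 64)), 39))
  expect_true(all(sfull$keep))

  expect_error(mask_nodes(s, binary_mask(array(FALSE, c(64, 64, 64)), 39)),
               "removed")
})

test_that("boundary-layer exclusion flags the outer z node layers", {
  s <- differentiate_strain(fx_field64())
  s2 <- exclude_boundary_layers(s, 1)
  expect_false(any(s2$keep[, , 1]))
  expect_false(any(s2$keep[, , 4]))
  expect_true(all(s2$keep[, , 2:3]))
  expect_error(exclude_boundary_layers(s, 2), "every node layer")
})

test_that("strain CSV export is complete and supports engineering shear", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  s <- differentiate_strain(fx_field64())
  df <- export_strain_csv(s, tmp)
  expect_equal(nrow(df), prod(s$grid$counts))
  back <- utils::read.csv(tmp)
  expect_equal(back$ez, as.vector(s$E[, , , "ez"]), tolerance = 1e-6)
  df2 <- export_strain_csv(s, tmp, shear = "engineering")
  expect_equal(df2$exy, 2 * df$exy)
})
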