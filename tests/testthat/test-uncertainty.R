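# Zero-strain and virtual-deformation uncertainty quantification.

test_that("error metrics follow the MAER/SDER definitions", {
  g <- build_grid(c(8, 8, 8), 39, 4)           # 2 x 2 x 2 nodes
  counts <- g$counts
  E <- array(0, c(counts, 6))

  # every node, every component at 100 ue -> MAER 100, SDER 0
  E[] <- 100
  r <- error_metrics(manual_strain_field(g, E))
  expect_equal(r$maer, 100)
  expect_equal(r$sder, 0)
  expect_equal(unname(r$systematic["ex"]), 100)

  # two kept nodes with per-node averages 100 and 300 -> MAER 200, SDER 141.4
  E <- array(0, c(counts, 6))
  E[1, 1, 1, ] <- 100
  E[2, 1, 1, ] <- 300
  keep <- array(FALSE, counts); keep[1:2, 1, 1] <- TRUE
  r2 <- error_metrics(manual_strain_field(g, E, keep))
  expect_equal(r2$maer, 200)
  expect_equal(r2$sder, sqrt(2) * 100, tolerance = 1e-12)
  expect_equal(round(r2$sder, 1), 141.4)

  expect_error(error_metrics(manual_strain_field(
    g, array(0, c(counts, 6)), array(FALSE, counts))), "kept nodes")
})

test_that("MAER recomputed by brute force equals the reported MAER", {
  s <- differentiate_strain(fx_field64())
  rep0 <- error_metrics(s)
  Em <- matrix(s$E, ncol = 6)
  brute <- rowMeans(abs(Em))[as.vector(s$keep)]
  expect_equal(rep0$maer, mean(brute), tolerance = 1e-9)
  expect_equal(rep0$sder, sd(brute), tolerance = 1e-9)

  # against a constant nonzero reference
  ref <- list(strain = c(-10000, 0, 0, 0, 0, 0))
  rep1 <- error_metrics(s, ref)
  brute1 <- rowMeans(abs(sweep(Em, 2, c(-10000, 0, 0, 0, 0, 0))))[
    as.vector(s$keep)]
  expect_equal(rep1$maer, mean(brute1), tolerance = 1e-9)
})

test_that("identical repeat images give zero measured error at every NS", {
  v <- generate_trabecular_volume(
    synth_spec(dims = c(52, 52, 52), target_bvtv = 0.2, seed = 13))
  reps <- zero_strain_study(v, v, ns_list = c(13, 25))
  for (r in reps) {
    expect_lte(r$maer, 10)
    expect_lte(max(abs(r$systematic)), 10)
    expect_lte(max(abs(r$random)), 10)
  }
})

test_that("noise raises MAER and MAER decreases with nodal spacing", {
  reps <- fx_sweep104()
  maer <- vapply(reps, function(r) r$maer, 1.0)
  expect_true(all(maer > 0))
  expect_true(all(diff(maer) <= 0))            # non-increasing over 13..50
  expect_equal(vapply(reps, function(r) r$spacing_um, 1.0),
               c(1014, 1950, 2730, 3900))
})

test_that("virtual deformation studies recover applied strain and report errors", {
  v <- fx_vol64()
  out <- suppressWarnings(virtual_deformation_study(
    v, strain_levels = -0.01, ns_list = 16, exclude_slices = 1))
  r <- out[[1]][[1]]
  expect_equal(r$applied_strain, -0.01)
  expect_lt(abs(r$recovered_mean_ez - (-10000)) / 10000, 0.10)
  expect_lt(abs(r$systematic["ez"]), 1000)

  # level 0 reduces to the zero-strain study on the identical pair
  out0 <- suppressWarnings(virtual_deformation_study(
    v, strain_levels = 0, ns_list = 16, exclude_slices = 0))
  z0 <- suppressWarnings(zero_strain_study(v, v, ns_list = 16))
  expect_equal(out0[[1]][[1]]$maer, z0[[1]]$maer, tolerance = 1e-9)
})

test_that("excluding boundary layers reduces the axial error under black fill", {
  v <- fx_vol64()
  vd <- apply_virtual_deformation(v, deformation_uniform(-0.01), fill = 0)
  f <- suppressWarnings(dvc_register(v, vd$volume, fx_grid64()))
  s <- differentiate_strain(f)
  ref <- list(strain = c(0, 0, -10000, 0, 0, 0),
              displacement = vd$displacement)
  r_all <- error_metrics(s, ref)
  r_excl <- error_metrics(exclude_boundary_layers(s, 1), ref)
  expect_lt(r_excl$random["ez"], r_all$random["ez"])
})

test_that("ns_tradeoff recommends by threshold and fits the log model", {
  mk <- function(ns, maer) structure(list(ns = ns, spacing_um = ns * 78,
                                          n_nodes = 64, maer = maer,
                                          sder = maer / 2,
                                          systematic = c(ez = 0),
                                          random = c(ez = 0)),
                                     class = "uncertainty_report")
  reps <- mapply(mk, c(13, 25, 35, 50), c(2000, 900, 500, 300),
                 SIMPLIFY = FALSE)
  rec <- ns_tradeoff(reps, threshold = 1000)
  expect_equal(rec$recommended_ns, 25)          # first NS at or below 1000 ue
  expect_true(rec$monotone)
  expect_lt(rec$fit$b, 0)

  # all below threshold -> smallest NS
  reps2 <- mapply(mk, c(13, 25, 35, 50), c(800, 700, 600, 500),
                  SIMPLIFY = FALSE)
  expect_equal(ns_tradeoff(reps2, 1000)$recommended_ns, 13)

  # non-monotone data flagged, threshold rule still applied empirically
  reps3 <- mapply(mk, c(13, 25, 35, 50), c(2000, 900, 1100, 300),
                  SIMPLIFY = FALSE)
  rec3 <- ns_tradeoff(reps3, 1000)
  expect_false(rec3$monotone)
  expect_equal(rec3$recommended_ns, 25)

  # log fit on the measured synthetic sweep explains the decay
  recm <- ns_tradeoff(fx_sweep104())
  expect_gt(recm$fit$r_squared, 0.8)
  expect_error(ns_tradeoff(list(mk(25, 100))), "at least 2")
})

test_that("uncertainty_table flattens nested report lists", {
  df <- uncertainty_table(list(fx_sweep104()), labels = "zero strain")
  expect_equal(nrow(df), 4)
  expect_equal(df$case, rep("zero strain", 4))
  expect_true(all(c("maer", "sder", "sys_ez", "rand_ez") %in% names(df)))
})
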