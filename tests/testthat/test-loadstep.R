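# Load-step statistics: summaries, yield fraction, histograms, Spearman
# correlation and the strain-vs-morphometry table.

grid8 <- function() build_grid(c(12, 12, 12), 39, 4)   # 3 x 3 x 3 nodes

uniform_ep3_field <- function(ep3_values) {
  # axial field: ez per node = ep3 value, other components 0
  g <- grid8()
  counts <- g$counts
  E <- array(0, c(counts, 6))
  E[, , , 3] <- array(ep3_values, counts)
  manual_strain_field(g, E)
}

test_that("summaries report medians, extremes and yield fractions", {
  s <- uniform_ep3_field(rep(-12000, 27))
  out <- summarize_strain(s)
  expect_equal(out$percent_above_yield, 100)
  expect_equal(out$med_ep3_magnitude, 12000)
  tab <- out$table
  expect_true(all(tab$min <= tab$median & tab$median <= tab$max))

  # half the nodes at -12000, half at -2000 (even count):
  # 50% above yield and midpoint median magnitude 7000
  vals <- rep(c(-12000, -2000), each = 18)
  g <- build_grid(c(12, 12, 16), 39, 4)        # 3 x 3 x 4 = 36 nodes
  E <- array(0, c(g$counts, 6))
  E[, , , 3] <- array(vals, g$counts)
  out2 <- summarize_strain(manual_strain_field(g, E))
  expect_equal(out2$percent_above_yield, 50)
  expect_equal(out2$med_ep3_magnitude, 7000)

  # strict inequality at the threshold
  s3 <- uniform_ep3_field(rep(-10000, 27))
  expect_equal(summarize_strain(s3)$percent_above_yield, 0)
})

test_that("histograms conserve node counts in half-open bins", {
  s <- uniform_ep3_field(rep(0, 27))
  h0 <- strain_histogram(s, "ep3", 500)
  expect_equal(sum(h0$count), 27)
  expect_equal(sum(h0$count > 0), 1)

  s2 <- uniform_ep3_field(rep(c(-12000, -2000), c(13, 14)))
  for (bw in c(100, 1000, 3777)) {
    h <- strain_histogram(s2, "ep3", bw)
    expect_equal(sum(h$count), 27)
  }
  h2 <- strain_histogram(s2, "ep3", 1000)
  expect_equal(sum(h2$count > 0), 2)           # exactly two occupied bins
  expect_error(strain_histogram(s2, "ep3", 0), "positive")
})

test_that("spearman reproduces the morphometric worked example", {
  tb_th <- c(243, 250, 271, 269, 304)
  conn_d <- c(8.26, 6.41, 5.23, 5.06, 3.20)
  ct <- spearman_rank(tb_th, conn_d)
  expect_equal(ct$r_s, -0.9, tolerance = 1e-12)
  # rank-formula oracle: 1 - 6 sum(d^2) / (n (n^2 - 1))
  d <- rank(tb_th) - rank(conn_d)
  expect_equal(ct$r_s, 1 - 6 * sum(d^2) / (5 * 24), tolerance = 1e-12)
  # agreement with the stats implementation as cross-check
  expect_equal(ct$r_s, unname(cor(tb_th, conn_d, method = "spearman")))
})

test_that("p-value conventions: t approximation vs exact permutation", {
  # r_s = 0.90, n = 5: the t approximation prints 0.037
  x <- 1:5; y <- c(1, 2, 3, 5, 4)              # rho = 0.9
  ct <- spearman_rank(x, y)
  expect_equal(ct$r_s, 0.9)
  expect_equal(round(ct$p_two_tailed, 3), 0.037)
  # ... while the exact permutation test gives 0.083 two-tailed
  expect_equal(ct$p_exact, 10 / 120, tolerance = 1e-12)

  # perfectly monotone: r_s = 1, exact two-tailed p = 2/120
  ct1 <- spearman_rank(1:5, c(10, 20, 30, 40, 50))
  expect_equal(ct1$r_s, 1)
  expect_equal(ct1$p_exact, 2 / 120, tolerance = 1e-12)
  expect_lt(ct1$p_two_tailed, 0.01)

  # symmetry and monotone-transform invariance
  set.seed(3)
  a <- rnorm(7); b <- rnorm(7)
  expect_equal(spearman_rank(a, b)$r_s, spearman_rank(b, a)$r_s)
  expect_equal(spearman_rank(exp(a), b)$r_s, spearman_rank(a, b)$r_s)

  expect_error(spearman_rank(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rank(1:2, 1:2), "at least 3")
})

test_that("correlate_morphometry builds the full strain-vs-morphometry grid", {
  g <- grid8()
  summaries <- lapply(c(-2000, -4000, -6000, -9000, -12000), function(v)
    summarize_strain(uniform_ep3_field(rep(v, 27))))
  morpho <- data.frame(tb_bvtv = c(17.7, 24.6, 25.7, 21.3, 22.5),
                       tb_th = c(243, 250, 271, 269, 304),
                       tb_sp = c(1297, 743, 801, 1075, 1098),
                       tb_n = c(0.728, 0.983, 0.949, 0.793, 0.740),
                       conn_d = c(8.26, 6.41, 5.23, 5.06, 3.20))
  tab <- correlate_morphometry(summaries, morpho)
  expect_equal(nrow(tab), 10)                  # 2 strain x 5 morphometric
  # med ep3 magnitude is monotone in specimen order; Tb.Th nearly so
  cell <- tab[tab$strain_parameter == "med_ep3" &
                tab$morpho_parameter == "conn_d", ]
  expect_equal(cell$r_s, -1)
  # consistency with spearman_rank called cell-wise
  med <- vapply(summaries, function(s) s$med_ep3_magnitude, 1.0)
  ct <- spearman_rank(med, morpho$tb_th)
  cell2 <- tab[tab$strain_parameter == "med_ep3" &
                 tab$morpho_parameter == "tb_th", ]
  expect_equal(cell2$r_s, ct$r_s)
  expect_equal(cell2$p_t, ct$p_two_tailed)
  expect_true(all(tab$p_bonferroni >= tab$p_t, na.rm = TRUE))
  # constant strain vector gives NA cells instead of failing
  const_sum <- lapply(1:5, function(i)
    summarize_strain(uniform_ep3_field(rep(-5000, 27))))
  tab2 <- correlate_morphometry(const_sum, morpho)
  expect_true(all(is.na(tab2$r_s)))
})

test_that("the synthetic stepwise-loading pipeline runs end to end", {
  res <- suppressWarnings(run_pipeline(list(
    n_specimens = 3, dims = c(48, 48, 48), ns = 12,
    load_steps = c(-0.005, -0.012, -0.03), seed = 4)))
  expect_s3_class(res, "pipeline_result")
  expect_equal(nrow(res$morphometry), 3)
  expect_equal(length(res$summaries), 3)
  # percent above yield is non-decreasing in applied load for every specimen
  py <- sapply(res$summaries, function(ls)
    vapply(ls, function(s) s$percent_above_yield, 1.0))
  expect_true(all(apply(py, 1, function(r) all(diff(r) >= 0))))
  # median compressive strain magnitude grows with load
  med <- sapply(res$summaries, function(ls)
    vapply(ls, function(s) s$med_ep3_magnitude, 1.0))
  expect_true(all(apply(med, 1, function(r) all(diff(r) > 0))))
  expect_equal(length(res$correlations), 3)
})
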