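# The inferential battery.

test_that("paired t matches the closed form and stats::t.test", {
  set.seed(1)
  x <- stats::rnorm(10, 1); y <- stats::rnorm(10)
  r <- paired_t(x, y)
  d <- x - y
  expect_equal(r$statistic, mean(d) / (stats::sd(d) / sqrt(10)),
               tolerance = 1e-12)
  tt <- stats::t.test(x, y, paired = TRUE)
  expect_equal(r$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p_raw, tt$p.value, tolerance = 1e-12)
  expect_equal(r$dof, 9)
  up <- paired_t(x, y, "upper")
  expect_equal(up$p_raw,
               stats::t.test(x, y, paired = TRUE,
                             alternative = "greater")$p.value,
               tolerance = 1e-12)
  # identical inputs: t = 0 is undefined (zero variance) -> error
  expect_error(paired_t(c(1, 2, 3, 4), c(0, 1, 2, 3)), "zero-variance")
  null_case <- paired_t(c(1, 2, 3), c(2, 2, 2))  # differences -1, 0, 1
  expect_equal(null_case$statistic, 0)
  expect_equal(null_case$p_raw, 1)
})

test_that("BH adjustment reproduces hand arithmetic and is idempotent", {
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.2, 0.04, 0.9, 0.05)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(bh_fdr(adj) >= adj - 1e-15))
  expect_error(bh_fdr(c(0.1, 1.2)))
})

test_that("the four-test family reproduces the printed FDR column", {
  p_raw <- c(stats::pt(-1.29, 11),           # CAP size, lower
             2 * stats::pt(-2.03, 11),       # CAP latency, two-tailed
             stats::pt(-0.19, 27, lower.tail = FALSE),  # wave V size, upper
             2 * stats::pt(-1.65, 27))       # wave V latency, two-tailed
  expect_equal(round(bh_fdr(p_raw), 2), c(0.15, 0.15, 0.57, 0.15))
})

test_that("JZS Bayes factors behave and match an independent quadrature", {
  # independent oracle: trapezoid rule over a dense grid
  bf_trap <- function(t, n, r = 0.707) {
    df <- n - 1
    d <- seq(-60, 60, length.out = 120001)
    dens <- suppressWarnings(stats::dt(t, df, ncp = d * sqrt(n)))
    m1 <- sum(dens * stats::dcauchy(d, 0, r)) * (d[2] - d[1])
    stats::dt(t, df) / m1
  }
  expect_equal(jzs_bf01(-1.65, 28), bf_trap(-1.65, 28), tolerance = 1e-4)
  expect_equal(jzs_bf01(2.5, 15), bf_trap(2.5, 15), tolerance = 1e-4)
  # monotone decrease in |t|
  bfs <- vapply(c(2, 4, 8), function(t) jzs_bf01(t, 20), numeric(1))
  expect_true(all(diff(bfs) < 0))
  # prior mixture identity: two-sided marginal = mean of one-sided marginals
  t <- -1.2; n <- 14
  m0 <- stats::dt(t, n - 1)
  m_two <- m0 / jzs_bf01(t, n, "two_tailed")
  m_up <- m0 / jzs_bf01(t, n, "upper")
  m_lo <- m0 / jzs_bf01(t, n, "lower")
  expect_equal(m_two, (m_up + m_lo) / 2, tolerance = 1e-6)
})

test_that("Bayes factors reproduce the peak-comparison values", {
  expect_equal(round(jzs_bf01(-0.19, 28, "upper"), 1), 5.7)
  expect_equal(round(jzs_bf01(-1.65, 28, "two_tailed"), 1), 1.5)
  expect_equal(round(jzs_bf01(-1.29, 12, "lower"), 1), 1.0)
  expect_equal(round(jzs_bf01(-2.03, 12, "two_tailed"), 1), 0.8)
})

test_that("exact binomial test is symmetric and matches printed values", {
  expect_equal(binomial_two_sided(14, 28), 1.0)
  expect_equal(round(binomial_two_sided(22, 28), 3), 0.004)
  expect_equal(round(binomial_two_sided(16, 28), 2), 0.57)
  for (k in 0:10) {
    expect_equal(binomial_two_sided(k, 10), binomial_two_sided(10 - k, 10))
  }
})

test_that("ratio-versus-unity tests match hand computation", {
  r <- c(1.2, 1.3, 1.1, 1.4)
  out <- ratio_gt_one_t(r)
  x <- r - 1
  expect_equal(out$statistic, mean(x) / (stats::sd(x) / sqrt(4)),
               tolerance = 1e-12)
  expect_equal(out$direction, "upper")
  lg <- ratio_gt_one_t(c(2, 0.5, 2, 0.5), use_log = TRUE)
  expect_equal(lg$statistic, 0, tolerance = 1e-12)
  expect_error(ratio_gt_one_t(c(1, 1, 1)), "zero-variance")
  expect_error(ratio_gt_one_t(c(1, -1, 2)), "positive")
})

test_that("pointwise FDR flags a strong shift and nothing under identity", {
  set.seed(2)
  lags <- seq(0, 15, by = 0.5)
  a <- matrix(stats::rnorm(10 * length(lags)), 10)
  res0 <- pointwise_paired_t_fdr(a, a, lags)  # identical conditions
  expect_true(all(res0$t == 0))
  expect_false(any(res0$significant))
  res1 <- pointwise_paired_t_fdr(a + 10, a, lags)
  expect_true(all(res1$significant))
  expect_error(pointwise_paired_t_fdr(a[1:2, ], a[1:2, ], lags), "3 subjects")
})

test_that("pointwise FDR controls the any-discovery rate under the null", {
  lags <- seq(0, 15, by = 0.5)
  any_sig <- vapply(1:500, function(s) {
    set.seed(s)
    a <- matrix(stats::rnorm(8 * length(lags)), 8)
    b <- matrix(stats::rnorm(8 * length(lags)), 8)
    any(pointwise_paired_t_fdr(a, b, lags)$significant)
  }, logical(1))
  expect_lte(mean(any_sig), 0.07)
})

test_that("cluster test finds nothing when conditions are identical", {
  set.seed(3)
  a <- array(stats::rnorm(8 * 4 * 20), c(8, 4, 20))
  res <- spatiotemporal_cluster_test(a, a + array(stats::rnorm(8 * 4 * 20,
                                                               0, 1e-8),
                                                  c(8, 4, 20)),
                                     chain_adjacency(4), n_perm = 200,
                                     seed = 1)
  sig <- vapply(res$clusters, function(cl) cl$p_cluster < 0.05, logical(1))
  expect_true(length(sig) == 0 || !any(sig))
})

test_that("cluster test recovers an injected spatiotemporal effect", {
  hits <- 0; coverage_ok <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 12; C <- 6; nt <- 30
    a <- array(stats::rnorm(n * C * nt), c(n, C, nt))
    b <- array(stats::rnorm(n * C * nt), c(n, C, nt))
    a[, 2:4, 11:20] <- a[, 2:4, 11:20] + 2       # large effect
    res <- spatiotemporal_cluster_test(a, b, chain_adjacency(C),
                                       n_perm = 1000, seed = s)
    ps <- vapply(res$clusters, `[[`, numeric(1), "p_cluster")
    if (length(ps) && min(ps) < 0.05) {
      hits <- hits + 1
      inj <- matrix(FALSE, C, nt); inj[2:4, 11:20] <- TRUE
      if (sum(res$significant_mask & inj) / sum(inj) >= 0.8) {
        coverage_ok <- coverage_ok + 1
      }
    }
  }
  expect_gte(hits, 18)
  expect_gte(coverage_ok, 18)
})

test_that("cluster test type-I error is controlled under the full null", {
  any_sig <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    n <- 20; C <- 4; nt <- 20
    a <- array(stats::rnorm(n * C * nt), c(n, C, nt))
    b <- array(stats::rnorm(n * C * nt), c(n, C, nt))
    res <- spatiotemporal_cluster_test(a, b, chain_adjacency(C),
                                       n_perm = 1000, seed = s)
    ps <- vapply(res$clusters, `[[`, numeric(1), "p_cluster")
    length(ps) > 0 && min(ps) < 0.05
  }, logical(1))
  expect_gte(mean(any_sig), 0.02)
  expect_lte(mean(any_sig), 0.09)
})

test_that("cluster p values are invariant to channel relabeling", {
  set.seed(4)
  n <- 10; C <- 5; nt <- 15
  a <- array(stats::rnorm(n * C * nt), c(n, C, nt))
  b <- array(stats::rnorm(n * C * nt), c(n, C, nt))
  a[, 2, 5:10] <- a[, 2, 5:10] + 1.5
  adj <- chain_adjacency(C)
  perm <- c(3, 1, 5, 2, 4)
  res1 <- spatiotemporal_cluster_test(a, b, adj, n_perm = 500, seed = 9)
  res2 <- spatiotemporal_cluster_test(a[, perm, ], b[, perm, ],
                                      adj[perm, perm], n_perm = 500,
                                      seed = 9)
  p1 <- sort(vapply(res1$clusters, `[[`, numeric(1), "p_cluster"))
  p2 <- sort(vapply(res2$clusters, `[[`, numeric(1), "p_cluster"))
  expect_equal(p1, p2)
})

test_that("small cohorts use the exhaustive sign-flip null", {
  set.seed(5)
  n <- 6
  a <- array(stats::rnorm(n * 3 * 10), c(n, 3, 10))
  b <- array(stats::rnorm(n * 3 * 10), c(n, 3, 10))
  a[, 2, 3:7] <- a[, 2, 3:7] + 3
  res <- spatiotemporal_cluster_test(a, b, chain_adjacency(3), seed = 1)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 2^6)
  expect_error(spatiotemporal_cluster_test(a[1:4, , ], b[1:4, , ],
                                           chain_adjacency(3)),
               "5 subjects")
})

test_that("the peak-test battery assembles the full result table", {
  set.seed(6)
  comparisons <- list(
    up = list(x = stats::rnorm(10, 0.5), y = stats::rnorm(10),
              direction = "upper"),
    two = list(x = stats::rnorm(10), y = stats::rnorm(10),
               direction = "two_tailed"))
  tab <- peak_test_battery(comparisons)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$p_fdr >= tab$p_raw - 1e-15))
  expect_true(all(tab$bf01 > 0))
  expect_equal(tab$dof, c(9, 9))
})
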