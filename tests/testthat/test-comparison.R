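test_that("weighted Kendall matches the hand-worked three-node example", {
  wk <- weighted_kendall(c(0.5, 0.3, 0.2), c(0.5, 0.2, 0.3))
  expect_equal(wk$P, 0.12)
  expect_equal(wk$Q, 0.01)
  expect_equal(wk$tau, 11 / 13)
  expect_false(wk$undefined)
})

test_that("weighted Kendall equals the brute-force pair enumeration", {
  set.seed(19)
  for (rep in 1:300) {
    n <- sample(3:12, 1)
    a <- round(stats::rnorm(n), 2)  # rounding provokes occasional ties
    b <- round(stats::rnorm(n), 2)
    expect_equal(weighted_kendall(a, b)$tau, kendall_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("weighted Kendall has the degenerate and symmetry properties", {
  a <- c(0.9, 0.4, 0.1, 0.7)
  expect_equal(weighted_kendall(a, a)$tau, 1)
  expect_equal(weighted_kendall(a, -a)$tau, -1)
  # symmetric in its arguments
  b <- c(0.2, 0.8, 0.5, 0.1)
  expect_equal(weighted_kendall(a, b)$tau, weighted_kendall(b, a)$tau)
  # invariant under separate positive affine maps
  expect_equal(weighted_kendall(3 * a + 2, 0.1 * b - 5)$tau,
               weighted_kendall(a, b)$tau)
  # constant list: no rankable pair
  wk <- weighted_kendall(rep(0.3, 4), b)
  expect_true(wk$undefined)
  expect_true(is.na(wk$tau))
  expect_error(weighted_kendall(a, b[1:3]), "length")
  expect_error(weighted_kendall(1, 2), "at least 2")
})

test_that("unit weights reduce the statistic to classical Kendall tau-a", {
  set.seed(23)
  for (rep in 1:50) {
    n <- sample(3:10, 1)
    a <- stats::rnorm(n)
    b <- stats::rnorm(n)
    expect_equal(weighted_kendall(a, b, weights = 1)$tau,
                 stats::cor(a, b, method = "kendall"), tolerance = 1e-12)
  }
})

test_that("top-k restriction keeps the k most ictogenic reference nodes", {
  a <- c(0.9, 0.8, 0.7, 0.2, 0.1)
  b <- c(0.85, 0.75, 0.65, 0.1, 0.2)  # head agrees, tail disagrees
  expect_equal(top_k_kendall(a, b, 5)$tau, weighted_kendall(a, b)$tau)
  expect_gt(top_k_kendall(a, b, 3)$tau, weighted_kendall(a, b)$tau)
  expect_equal(top_k_kendall(a, b, 3)$tau, 1)
  # reference list selects which head is kept
  a2 <- c(1, 0.5, 0); b2 <- c(0, 0.5, 1)
  expect_equal(top_k_kendall(a2, b2, 2, reference = "a")$n_pairs, 1)
  expect_error(top_k_kendall(a, b, 1), "at least 2")
  expect_error(top_k_kendall(a, b, 9), "exceeds")
})

make_ni_table <- function(ni_by_model_net) {
  do.call(rbind, lapply(names(ni_by_model_net), function(m) {
    nets <- ni_by_model_net[[m]]
    do.call(rbind, lapply(names(nets), function(id) {
      data.frame(network_id = id, model = m,
                 node = seq_along(nets[[id]]), ni = nets[[id]])
    }))
  }))
}

test_that("heterogeneity analysis bins, filters and correlates correctly", {
  set.seed(31)
  n_net <- 12
  nets <- paste0("g", sprintf("%02d", seq_len(n_net)))
  # identical NI under both models, spread increasing across networks
  base <- lapply(seq_len(n_net), function(k) k / n_net * c(0, 0.3, 0.6, 1))
  names(base) <- nets
  tab <- make_ni_table(list(alpha_model = base, beta_model = base))
  stats_tab <- data.frame(network_id = nets,
                          normalized_sd = seq(0.1, 1, length.out = n_net))
  res <- heterogeneity_analysis(tab, stats_tab)
  expect_true(all(res$tau$tau == 1))
  expect_true(all(res$bins$mean_tau == 1))
  expect_equal(res$pair_summary$mean_tau, 1)
  # delta NI is monotone in k and so is the degree spread: rho = 1
  expect_true(all(res$spearman$rho == 1))
  # normalization attains 0 and 1 per model
  for (m in unique(res$heterogeneity$model)) {
    v <- res$heterogeneity$delta_ni_norm[res$heterogeneity$model == m]
    expect_equal(range(v), c(0, 1))
  }
  # 8 networks survive a 0.3 filter -> 4 bins of exactly 2
  res2 <- heterogeneity_analysis(tab, stats_tab, filter = 4 / 12)
  expect_true(all(res2$bins$n_networks == 2))
  # too few survivors is an error
  expect_error(heterogeneity_analysis(tab, stats_tab, filter = 0.95),
               "fewer than")
})

test_that("equal-occupancy bins differ by at most one when uneven", {
  idx <- ictonet:::bin_assign(10, 4)
  expect_equal(as.vector(table(idx)), c(3, 3, 2, 2))
  expect_equal(ictonet:::bin_assign(8, 4), rep(1:4, each = 2))
})
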