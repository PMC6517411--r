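test_that("ictal fraction marks spike windows on constructed fixtures", {
  cl <- ictal_classifier("theta")  # spike window half-width 0.5
  th_s <- theta_steady_state(-0.5)
  # one spike at step 100 of 200 (dt = 0.01 -> 50-step half window):
  # covered steps 50..150, fraction 101/200
  tr <- matrix(c(rep(th_s, 101), rep(th_s + 2 * pi + 0.1, 100)), ncol = 1)
  expect_equal(ictal_fraction(tr, cl, model = "theta", theta_s = th_s,
                              dt = 0.01)$node[[1]], 101 / 200)
  # two immediate spikes: overlapping windows are not double counted
  tr2 <- matrix(c(rep(th_s, 101), rep(th_s + 4 * pi + 0.1, 100)), ncol = 1)
  expect_equal(ictal_fraction(tr2, cl, model = "theta", theta_s = th_s,
                              dt = 0.01)$node[[1]], 101 / 200)
  # pinned at the steady state: never ictal
  pinned <- matrix(th_s, 100, 2)
  expect_equal(ictal_fraction(pinned, cl, model = "theta", theta_s = th_s,
                              dt = 0.01)$network, 0)
  # sustained fast spiking is marked contiguously (ISI ~ window width)
  net1 <- make_network(matrix(0L, 1, 1), check = FALSE)
  fast <- simulate_dynamics(net1, theta_params(p = 9, alpha = 0, sigma = 0),
                            sim_config(1e-3, 14, 1), init = 0)
  expect_gt(ictal_fraction(fast, cl)$network, 0.9)
  # slow isolated spiking (ISI = 2 pi) leaves most samples non-ictal
  slow <- simulate_dynamics(net1,
                            theta_params(p = 0.25, alpha = 0, sigma = 0),
                            sim_config(1e-3, 14, 1), init = 0)
  frac <- ictal_fraction(slow, cl)$network
  expect_gt(frac, 0.1)
  expect_lt(frac, 0.25)
  expect_error(ictal_fraction(matrix(0, 0, 1), cl, model = "theta",
                              theta_s = th_s, dt = 0.01), "empty")
})

test_that("escape-time BNI censors and averages first passages", {
  t_ref <- 8; dt <- 0.01
  n_samp <- t_ref / dt + 1
  u <- matrix(0, n_samp, 2)
  u[(0.25 * t_ref / dt + 1):n_samp, 1] <- 1.5   # escapes at 0.25 t_ref
  u[(0.75 * t_ref / dt + 1):n_samp, 2] <- 1.5   # escapes at 0.75 t_ref
  res <- escape_time_bni(u, t_ref = t_ref, dt = dt)
  expect_equal(res$bni, 0.5)
  expect_equal(unname(res$escape_times), c(2, 6))
  # nobody escapes -> BNI = 0; everybody escapes immediately -> BNI ~ 1
  expect_equal(escape_time_bni(matrix(0, n_samp, 3), t_ref = t_ref,
                               dt = dt)$bni, 0)
  expect_equal(escape_time_bni(matrix(2, n_samp, 3), t_ref = t_ref,
                               dt = dt)$bni, 1 - dt / t_ref)
  expect_error(escape_time_bni(matrix(0, 10, 1), t_ref = 1, dt = 0.01),
               "shorter")
})

test_that("fused BNI sweeps equal the per-cell simulate-and-classify route", {
  net <- net_cycle3()
  # theta
  g <- parameter_grid("theta", resolution = 3, p_range = c(-2, -0.5),
                      alpha_range = c(0, 6))
  cfg <- sim_config(2e-3, 6, 2, seed = 9)
  map <- compute_bni_map(net, theta_params(), g, cfg, net_id = 7L,
                         removed_id = 2L)
  for (ip in 1:3) for (ia in 1:3) {
    cfg2 <- cfg
    cfg2$net_id <- 7L; cfg2$removed_id <- 2L
    cfg2$cell_index <- (ip - 1L) * 3L + (ia - 1L)
    sim <- simulate_dynamics(net, theta_params(p = g$p[ip],
                                               alpha = g$alpha[ia]), cfg2)
    expect_equal(ictal_fraction(sim)$network, map$bni[ip, ia],
                 tolerance = 1e-12)
  }
  # bistable
  gb <- parameter_grid("bistable", resolution = 2, p_range = c(-0.6, -0.1),
                       alpha_range = c(0, 6))
  cfgb <- sim_config(1e-3, 6, 0, seed = 9)
  mapb <- compute_bni_map(net, bistable_params(), gb, cfgb, net_id = 7L)
  for (ip in 1:2) for (ia in 1:2) {
    cfg2 <- cfgb
    cfg2$net_id <- 7L
    cfg2$cell_index <- (ip - 1L) * 2L + (ia - 1L)
    sim <- simulate_dynamics(net, bistable_params(p = gb$p[ip],
                                                  alpha = gb$alpha[ia]), cfg2)
    expect_equal(escape_time_bni(sim)$bni, mapb$bni[ip, ia])
  }
  # physiological (explicit threshold; baseline from the noise-free run)
  gp <- parameter_grid("physiological", resolution = 2,
                       p_range = c(90, 110), alpha_range = c(0, 500))
  cfgp <- sim_config(2e-3, 3, 1, seed = 9)
  cl <- ictal_classifier("physiological", phys_threshold = 3)
  mapp <- compute_bni_map(net, physiological_params(), gp, cfgp, cl,
                          net_id = 7L)
  for (ip in 1:2) for (ia in 1:2) {
    cfg2 <- cfgp
    cfg2$net_id <- 7L
    cfg2$cell_index <- (ip - 1L) * 2L + (ia - 1L)
    pp <- physiological_params(p = gp$p[ip], alpha = gp$alpha[ia])
    base <- ictonet:::phys_baseline(net, pp, cfg2)
    sim <- simulate_dynamics(net, pp, cfg2)
    expect_equal(ictal_fraction(sim, cl, baseline = base)$network,
                 mapp$bni[ip, ia])
  }
})

test_that("map means are invariant under node relabeling up to MC noise", {
  net <- net_cycle3()
  perm <- c(2, 3, 1)
  relab <- make_network(net$adjacency[perm, perm])
  g <- parameter_grid("theta", resolution = 8)
  cfg <- sim_config(2e-3, 14, 2, seed = 21)
  m1 <- map_mean(compute_bni_map(net, theta_params(), g, cfg))
  m2 <- map_mean(compute_bni_map(relab, theta_params(), g, cfg))
  expect_lt(abs(m1 - m2), 0.05)
})

test_that("NI distribution detects a reverberating pair and degenerate maps", {
  pair <- net_mutual_pair()
  g <- parameter_grid("theta", resolution = 6, p_range = c(-1.5, -1),
                      alpha_range = c(8, 10))
  nd <- compute_ni(pair, theta_params(), g, sim_config(2e-3, 14, 2, seed = 2))
  # each node alone sits far below threshold: removal abolishes nearly all
  # ictal activity, NI ~ 1
  expect_true(all(nd$ni > 0.9))
  expect_true(all(nd$ni <= 1))
  expect_true(all(nd$bni_removed < 0.05))
  expect_gte(delta_ni(nd), 0)
  # deep sub-threshold window: the map is identically zero and NI undefined
  gz <- parameter_grid("theta", resolution = 4, p_range = c(-4, -3.5),
                       alpha_range = c(8, 10))
  expect_error(compute_ni(pair, theta_params(), gz,
                          sim_config(2e-3, 14, 2, seed = 2)),
               "undefined")
})

test_that("coupling calibration bisects to the target operating point", {
  # deterministic linear stub: BNI(alpha) = alpha / 10
  stub <- calibrate_coupling_for_bni(NULL, theta_params(), c(0, 10),
                                     target = 0.5, tol = 1e-6,
                                     bni_fn = function(a) a / 10)
  expect_equal(stub$alpha, 5, tolerance = 1e-4)
  expect_true(stub$converged)
  # flat bracket fails loudly
  expect_error(calibrate_coupling_for_bni(NULL, theta_params(), c(0, 1),
                                          bni_fn = function(a) 0.01),
               "straddle")
  # self-consistency on the complete 3-node digraph (theta model)
  net <- net_complete(3)
  cal <- calibrate_coupling_for_bni(net, theta_params(p = -0.3), c(0, 10),
                                    target = 0.5,
                                    config = sim_config(2e-3, 14, 2,
                                                        seed = 5),
                                    tol = 0.05, n_rep = 2)
  g <- parameter_grid("theta", resolution = 1, p_range = c(-0.3, -0.3),
                      alpha_range = c(cal$alpha, cal$alpha))
  fresh <- mean(vapply(11:14, function(s) {
    map_mean(compute_bni_map(net, theta_params(), g,
                             sim_config(2e-3, 14, 2, seed = s)))
  }, numeric(1)))
  expect_lt(abs(fresh - 0.5), 0.1)
})

test_that("BNI maps export losslessly to tidy CSV", {
  net <- net_cycle3()
  map <- compute_bni_map(net, theta_params(),
                         parameter_grid("theta", resolution = 4),
                         sim_config(2e-3, 6, 2, seed = 1))
  path <- tempfile(fileext = ".csv")
  write_bni_map_csv(map, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 16)
  expect_equal(matrix(back$bni, 4, 4), map$bni)
  expect_equal(sort(unique(back$p)), map$p)
})
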