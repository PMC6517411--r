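test_that("sigmoid has the printed midpoint, saturation and shape", {
  p <- physiological_params()
  expect_equal(sigmoid(6), 2.5)
  expect_equal(sigmoid(1e6), 5)
  expect_equal(sigmoid(0), 2 * 2.5 / (1 + exp(0.56 * 6)))
  v <- seq(-20, 40, by = 0.5)
  expect_true(all(diff(sigmoid(v)) > 0))
})

test_that("theta steady state solves the deterministic fixed-point equation", {
  expect_equal(theta_steady_state(0), 0)
  expect_equal(theta_steady_state(-1), -pi / 2)
  expect_equal(theta_steady_state(-4), -acos(-3 / 5))
  for (p in c(-0.1, -0.7, -2, -4)) {
    th <- theta_steady_state(p)
    expect_true(th >= -pi && th <= 0)
    drift <- (1 - cos(th)) + (1 + cos(th)) * p
    expect_lt(abs(drift), 1e-12)
  }
  expect_error(theta_steady_state(0.2), "SNIC")
})

test_that("bistable cycle amplitudes follow the normal form", {
  expect_equal(unname(bistable_cycle_amplitude(0)), c(2, 0))
  expect_equal(unname(bistable_cycle_amplitude(-1)), c(1, 1))
  expect_error(bistable_cycle_amplitude(-1.5), "p < -1")
  # settled amplitude of a noise-free run matches the closed form
  expect_lt(abs(bistable_settled_amplitude(-0.5) - (1 + sqrt(0.5))), 1e-3)
})

test_that("noise-free fixed points are preserved by the integrators", {
  net1 <- make_network(matrix(0L, 1, 1), check = FALSE)
  s <- simulate_dynamics(net1, theta_params(p = -1, alpha = 0, sigma = 0),
                         sim_config(2e-3, 4, 0))
  expect_equal(max(abs(s$theta - (-pi / 2))), 0)
  sb <- simulate_dynamics(net1, bistable_params(p = -0.5, alpha = 0,
                                                sigma = 0),
                          sim_config(1e-3, 4, 0))
  expect_equal(max(sb$mod2), 0)
  # physiological node at the low-excitability end settles to a fixed point
  sp <- simulate_dynamics(net1,
                          physiological_params(p = 50, alpha = 0, sigma = 0),
                          sim_config(1e-3, 4, 0))
  tail_out <- sp$output[3001:4001, 1]
  expect_lt(stats::var(tail_out), 1e-10)
})

test_that("theta spiking period matches the closed form pi/sqrt(p)", {
  expect_lt(abs(theta_spike_period(0.25) - pi / sqrt(0.25)) / (pi / sqrt(0.25)),
            0.01)
  expect_lt(abs(theta_spike_period(1) - pi) / pi, 0.01)
})

test_that("bistable basins of attraction separate at the unstable cycle", {
  net1 <- make_network(matrix(0L, 1, 1), check = FALSE)
  amp <- bistable_cycle_amplitude(-0.5)
  # inside the unstable cycle -> fixed point
  inside <- simulate_dynamics(net1,
                              bistable_params(p = -0.5, alpha = 0, sigma = 0),
                              sim_config(1e-4, 20, 0),
                              init = complex(real = 0.9 * sqrt(amp["unstable"])))
  expect_lt(tail(inside$mod2[, 1], 1), 1e-4)
  # outside -> stable cycle
  outside <- simulate_dynamics(net1,
                               bistable_params(p = -0.5, alpha = 0, sigma = 0),
                               sim_config(1e-4, 20, 0),
                               init = complex(real = 2))
  expect_lt(abs(tail(outside$mod2[, 1], 1) - amp["stable"]), 0.05)
  # below the saddle-node of cycles everything collapses
  collapse <- simulate_dynamics(net1,
                                bistable_params(p = -1.2, alpha = 0,
                                                sigma = 0),
                                sim_config(1e-4, 60, 0),
                                init = complex(real = 2))
  expect_lt(tail(collapse$mod2[, 1], 1), 1e-3)
})

test_that("identical seeds give bit-identical trajectories", {
  net <- net_cycle3()
  cfg <- sim_config(2e-3, 2, 0, seed = 77)
  s1 <- simulate_dynamics(net, theta_params(p = -0.5, alpha = 2), cfg)
  s2 <- simulate_dynamics(net, theta_params(p = -0.5, alpha = 2), cfg)
  expect_identical(s1$theta, s2$theta)
  b1 <- simulate_dynamics(net, bistable_params(p = -0.2, alpha = 2), cfg)
  b2 <- simulate_dynamics(net, bistable_params(p = -0.2, alpha = 2), cfg)
  expect_identical(b1$x, b2$x)
  p1 <- simulate_dynamics(net, physiological_params(p = 90, alpha = 100), cfg)
  p2 <- simulate_dynamics(net, physiological_params(p = 90, alpha = 100), cfg)
  expect_identical(p1$output, p2$output)
  cfg2 <- sim_config(2e-3, 2, 0, seed = 78)
  s3 <- simulate_dynamics(net, theta_params(p = -0.5, alpha = 2), cfg2)
  expect_false(identical(s1$theta, s3$theta))
})

test_that("halving dt leaves the mean ictal fraction within Monte-Carlo error", {
  net1 <- make_network(matrix(0L, 1, 1), check = FALSE)
  frac_at <- function(dt, seeds) {
    vapply(seeds, function(s) {
      sim <- simulate_dynamics(net1, theta_params(p = -0.4, alpha = 0),
                               sim_config(dt, 12, 2, seed = s))
      ictal_fraction(sim)$network
    }, numeric(1))
  }
  coarse <- frac_at(2e-3, 1:40)
  fine <- frac_at(1e-3, 101:140)
  se <- sqrt(stats::var(coarse) / 40 + stats::var(fine) / 40)
  expect_lt(abs(mean(coarse) - mean(fine)), 4 * se)
})

test_that("blown-up states are reported, not returned", {
  net1 <- make_network(matrix(0L, 1, 1), check = FALSE)
  expect_error(simulate_dynamics(net1,
                                 bistable_params(p = 0, alpha = 0, sigma = 0),
                                 sim_config(0.5, 10, 0),
                                 init = complex(real = 3)),
               "non-finite")
})
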