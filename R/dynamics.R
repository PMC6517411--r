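#' Model parameter sets
#'
#' Constructors for the three node-dynamics models.  Each model has an
#' excitability parameter `p` (distance from the transition that separates
#' background from seizure-like dynamics) and a global coupling strength
#' `alpha` scaling the network input.
#'
#' * `physiological_params()`: a modified Jansen-Rit neural mass model with
#'   twelve state variables per node describing pyramidal cells, excitatory
#'   interneurons and slow/fast inhibitory interneurons, plus a delayed
#'   efferent loop (`y11`, `y12`) through which nodes are coupled.  Gains
#'   are in mV, inverse time constants in 1/s; the model runs in seconds.
#'   Defaults: A = 5, B = 44, G = 20, A_d = 3.25, a = 100, b = 50, g = 500,
#'   a_d = 100, C1 = 135, C2 = 0.8 C1, C3 = C4 = C7 = 0.25 C1, C5 = 0.3 C1,
#'   C6 = 0.1 C1, nu0 = 6 mV, e0 = 2.5 1/s, r = 0.56 1/mV, noise sd 1.85.
#'   Near its SNIC bifurcation, noise triggers transitions from a fixed
#'   point to large-amplitude oscillations.
#' * `theta_params()`: the Ermentrout-Kopell canonical (theta-neuron) model,
#'   the normal form of the SNIC bifurcation; one phase variable per node,
#'   noise sd 8.  The single-node bifurcation is at `p = 0`.
#' * `bistable_params()`: the subcritical-Hopf normal form in which a stable
#'   fixed point (z = 0) coexists with a stable limit cycle for
#'   `-1 <= p <= 0`; `omega = 20` sets the cycle frequency and noise enters
#'   both components with amplitude `beta * sigma` (`beta = 0.01`,
#'   `sigma = 1.85`).  Coupling acts on the real part only.
#'
#' @param p excitability.
#' @param alpha global coupling strength.
#' @param sigma noise standard deviation.
#' @param omega angular frequency of the bistable limit cycle.
#' @param beta noise scale multiplier of the bistable model.
#' @param A,B,G,A_d gains (mV).
#' @param a,b,g,a_d inverse time constants (1/s).
#' @param C1,C2,C3,C4,C5,C6,C7 connectivity constants.
#' @param nu0,e0,r sigmoid parameters (mV, 1/s, 1/mV).
#' @return a parameter object of class `theta_params`, `bistable_params` or
#'   `physiological_params` (all also `model_params`).
#' @name model-params
NULL

#' @rdname model-params
#' @param native_dt the theta model's native integration step: the printed
#'   noise level `sigma` is the per-step standard deviation of the
#'   stochastic input current at this step, so the model's white-noise
#'   intensity is `sigma * sqrt(native_dt)` (stored as `sigma_w`).  This
#'   keeps the integrated dynamics consistent when the solver step is
#'   refined.
#' @export
theta_params <- function(p = -0.5, alpha = 1, sigma = 8, native_dt = 2e-3) {
  structure(list(model = "theta", p = p, alpha = alpha, sigma = sigma,
                 sigma_w = sigma * sqrt(native_dt)),
            class = c("theta_params", "model_params"))
}

#' @rdname model-params
#' @export
bistable_params <- function(p = -0.5, alpha = 1, omega = 20,
                            beta = 0.01, sigma = 1.85) {
  structure(list(model = "bistable", p = p, alpha = alpha, omega = omega,
                 beta = beta, sigma = sigma),
            class = c("bistable_params", "model_params"))
}

#' @rdname model-params
#' @export
physiological_params <- function(p = 80, alpha = 100, sigma = 1.85,
                                 A = 5, B = 44, G = 20, A_d = 3.25,
                                 a = 100, b = 50, g = 500, a_d = 100,
                                 C1 = 135, C2 = 0.8 * C1,
                                 C3 = 0.25 * C1, C4 = 0.25 * C1,
                                 C5 = 0.3 * C1, C6 = 0.1 * C1,
                                 C7 = 0.25 * C1,
                                 nu0 = 6, e0 = 2.5, r = 0.56) {
  stopifnot(a > 0, b > 0, g > 0, a_d > 0)
  structure(list(model = "physiological", p = p, alpha = alpha, sigma = sigma,
                 constants = c(A = A, B = B, G = G, A_d = A_d, a = a, b = b,
                               g = g, a_d = a_d, C1 = C1, C2 = C2, C3 = C3,
                               C4 = C4, C5 = C5, C6 = C6, C7 = C7,
                               nu0 = nu0, e0 = e0, r = r)),
            class = c("physiological_params", "model_params"))
}

model_of <- function(params) params$model

#' Sigmoid firing-rate function
#'
#' `S(nu) = 2 e0 / (1 + exp(r (nu0 - nu)))`: converts a net post-synaptic
#' potential (mV) into an afferent firing rate (1/s).  Strictly increasing
#' with range (0, 2 e0); `S(nu0) = e0`.
#'
#' @param nu membrane potential (mV).
#' @param params a `physiological_params` object supplying `nu0`, `e0`, `r`.
#' @export
sigmoid <- function(nu, params = physiological_params()) {
  k <- params$constants
  2 * k[["e0"]] / (1 + exp(k[["r"]] * (k[["nu0"]] - nu)))
}

#' Steady state of an uncoupled theta node
#'
#' For `p <= 0` the deterministic single-node theta model has a stable fixed
#' point at `theta_s = -acos((1 + p) / (1 - p))`, in `[-pi, 0]`.  Beyond the
#' SNIC bifurcation (`p > 0`) no steady state exists.
#'
#' @param p excitability, must be `<= 0`.
#' @export
theta_steady_state <- function(p) {
  if (any(p > 0)) stop("no steady state beyond SNIC (p > 0)")
  -acos((1 + p) / (1 - p))
}

#' Limit-cycle amplitudes of the bistable model
#'
#' For `p >= -1` the deterministic single-node bistable model has a stable
#' limit cycle of squared amplitude `1 + sqrt(1 + p)`; for `-1 <= p <= 0`
#' an unstable cycle of squared amplitude `1 - sqrt(1 + p)` separates the
#' basins of the fixed point and the stable cycle (the separatrix used by
#' the escape-time detector).
#'
#' @param p excitability, must be `>= -1`.
#' @return named vector `c(stable = , unstable = )`; `unstable` is `NA` for
#'   `p > 0` (no coexistence).
#' @export
bistable_cycle_amplitude <- function(p) {
  if (any(p < -1)) stop("no limit cycle for p < -1")
  c(stable = 1 + sqrt(1 + p),
    unstable = if (p <= 0) 1 - sqrt(1 + p) else NA_real_)
}

#' Simulation configuration
#'
#' Fixed-step Euler-Maruyama settings.  Time is in model units (seconds for
#' the physiological model, dimensionless for theta and bistable).  Samples
#' in `[0, t_burn)` are flagged as transient and excluded from statistics.
#' The random stream is a pure function of `(seed, net_id, removed_id,
#' cell_index)`, so any grid cell of any map can be reproduced in isolation.
#'
#' @param dt time step; the sweep default band is `[1e-3, 5e-3]`.
#' @param t_total total simulated time.
#' @param t_burn transient discarded before statistics (0 for the bistable
#'   escape-time protocol, which starts at the fixed point).
#' @param seed master seed (non-negative integer-valued).
#' @param net_id,removed_id,cell_index seed-derivation context.
#' @export
sim_config <- function(dt = 2e-3, t_total = 44, t_burn = 4, seed = 1,
                       net_id = 0L, removed_id = 0L, cell_index = 0L) {
  stopifnot(dt > 0, t_total > t_burn, t_burn >= 0, seed >= 0)
  structure(list(dt = dt, t_total = t_total, t_burn = t_burn,
                 seed = as.numeric(seed), net_id = as.integer(net_id),
                 removed_id = as.integer(removed_id),
                 cell_index = as.integer(cell_index)),
            class = "sim_config")
}

n_steps_of <- function(config) round(config$t_total / config$dt)
burn_steps_of <- function(config) round(config$t_burn / config$dt)

#' Simulation presets
#'
#' Named problem sizes for the BNI sweeps.  `full` is the full-fidelity
#' setting (192 x 192 grid, long reference time); `desk` is a
#' medium-resolution setting for interactive work (24 x 24); `mini` is the
#' small setting used by the test suite (12 x 12, short reference time).
#' Reference times trade Monte-Carlo error against run time; the map-level
#' statistics used downstream average over all grid cells, which damps
#' per-cell noise.
#'
#' @param model `"theta"`, `"bistable"` or `"physiological"`.
#' @param preset `"full"`, `"desk"` or `"mini"`.
#' @param seed master seed stored in the returned config.
#' @return list with `config` (a [sim_config()]) and `resolution`.
#' @export
sim_preset <- function(model = c("theta", "bistable", "physiological"),
                       preset = c("desk", "full", "mini"), seed = 1) {
  model <- match.arg(model)
  preset <- match.arg(preset)
  res <- switch(preset, full = 192L, desk = 24L, mini = 12L)
  cfg <- switch(model,
    theta = switch(preset,
      full = sim_config(2e-3, 44, 4, seed),
      desk = sim_config(2e-3, 22, 2, seed),
      mini = sim_config(2e-3, 14, 2, seed)),
    bistable = switch(preset,
      full = sim_config(1e-3, 40, 0, seed),
      desk = sim_config(1e-3, 20, 0, seed),
      mini = sim_config(1e-3, 12, 0, seed)),
    physiological = switch(preset,
      full = sim_config(1e-3, 24, 4, seed),
      desk = sim_config(2e-3, 7, 1, seed),
      mini = sim_config(2e-3, 5, 1, seed)))
  list(config = cfg, resolution = res)
}

#' Simulate a model on a network
#'
#' Integrates one Euler-Maruyama trajectory of the given model on the
#' network, with per-step Gaussian increments of standard deviation
#' `sigma * sqrt(dt)` on each noise channel (the bistable model perturbs
#' both components with amplitude `beta * sigma` from independent streams;
#' the physiological model perturbs only the pyramidal input equation).
#' Coupling terms are the model-specific sums over in-neighbours.
#'
#' Initial conditions follow each model's ictogenicity protocol: all state
#' variables zero (physiological), the single-node steady state `theta_s`
#' (theta; falls back to `pi` with a warning when `p > 0`), and `z = 0`
#' exactly (bistable).  Override via `init`.
#'
#' @param net an `icto_network` (a single isolated node is permitted).
#' @param params a `model_params` object.
#' @param config a [sim_config()].
#' @param init optional initial condition: vector of phases (theta), complex
#'   vector or list(x, y) (bistable), or n x 12 matrix (physiological).
#' @return object of class `icto_sim`: list with `model`, `time`, `series`
#'   (time x node observable matrix: phase, pyramidal output y3 - y5 - y7,
#'   or Re z), `retained` (logical index of post-transient samples),
#'   model-specific state, `params`, `config`.
#' @export
simulate_dynamics <- function(net, params, config = sim_config(),
                              init = NULL) {
  stopifnot(inherits(net, "icto_network"), inherits(params, "model_params"),
            inherits(config, "sim_config"))
  n <- net$n_nodes
  ns <- n_steps_of(config)
  time <- seq(0, by = config$dt, length.out = ns + 1)
  retained <- time >= config$t_burn
  out <- switch(model_of(params),
    theta = {
      fallback <- params$p > 0
      th_s <- if (fallback) pi else theta_steady_state(params$p)
      if (fallback && is.null(init))
        warning("p > 0: no steady state, initializing phases at pi")
      th0 <- if (is.null(init)) rep(th_s, n) else rep_len(init, n)
      th <- cpp_sim_theta(net$adjacency, params$p, params$alpha,
                          params$sigma_w, config$dt, ns, th_s, th0,
                          config$seed, config$net_id, config$removed_id,
                          config$cell_index)
      list(series = th, theta = th, theta_s = th_s)
    },
    bistable = {
      if (is.null(init)) init <- complex(real = rep(0, n))
      if (is.list(init)) { x0 <- rep_len(init$x, n); y0 <- rep_len(init$y, n) }
      else { x0 <- rep_len(Re(init), n); y0 <- rep_len(Im(init), n) }
      zz <- cpp_sim_bistable(net$adjacency, params$p, params$omega,
                             params$alpha, params$beta * params$sigma,
                             config$dt, ns, x0, y0, config$seed,
                             config$net_id, config$removed_id,
                             config$cell_index)
      list(series = zz$x, x = zz$x, y = zz$y, mod2 = zz$x^2 + zz$y^2)
    },
    physiological = {
      y0 <- if (is.null(init)) matrix(0, n, 12) else init
      o <- cpp_sim_phys(net$adjacency, params$p, params$alpha, params$sigma,
                        config$dt, ns, params$constants, y0, config$seed,
                        config$net_id, config$removed_id, config$cell_index)
      list(series = o, output = o)
    })
  structure(c(list(model = model_of(params), time = time,
                   retained = retained, params = params, config = config),
              out),
            class = "icto_sim")
}

# single noise-free uncoupled node of the given model
single_node_sim <- function(params, dt, t_max, init = NULL) {
  net1 <- make_network(matrix(0L, 1, 1), check = FALSE)
  params$sigma <- 0
  if (!is.null(params$sigma_w)) params$sigma_w <- 0
  simulate_dynamics(net1, params, sim_config(dt, t_max, 0), init = init)
}

#' Numerical bifurcation diagnostics of the single-node models
#'
#' `theta_snic_point()` locates, by bisection on the excitability `p`, the
#' onset of sustained spiking of a noise-free uncoupled theta node (a
#' trajectory started at the slow point `theta = 0` spikes iff its
#' unwrapped phase crosses `pi` within `t_max`); the SNIC bifurcation puts
#' the true onset at `p = 0`.
#'
#' `theta_spike_period()` measures the inter-spike interval of a spiking
#' node (`p > 0`) from successive upward crossings of `pi` (mod `2 pi`) of
#' the unwrapped phase; the closed form is `pi / sqrt(p)`.
#'
#' `bistable_coexistence_lower()` locates, by bisection on `p`, the lower
#' endpoint of the excitability interval on which the deterministic
#' bistable node retains a nonzero attractor: a noise-free trajectory
#' started well outside the unstable cycle either settles on the stable
#' cycle (coexistence) or collapses to `z = 0`; the saddle-node of limit
#' cycles puts the true endpoint at `p = -1`.
#'
#' `bistable_settled_amplitude()` returns the tail-averaged `|z|^2` of a
#' noise-free trajectory started outside the unstable cycle; on the stable
#' cycle this equals `1 + sqrt(1 + p)`.
#'
#' The two bistable diagnostics integrate the deterministic node with Heun
#' (RK2) steps: an explicit Euler step injects radial energy at rate
#' `omega^2 dt / 2`, which at `omega = 20` would bias the located
#' saddle-node of limit cycles by far more than the bisection tolerance.
#'
#' @param bracket bisection bracket on `p`.
#' @param tol bisection tolerance on `p`.
#' @param dt integration step.
#' @param t_max integration horizon per evaluation.
#' @param p excitability.
#' @param z0 initial radius for the bistable runs.
#' @name bifurcation-diagnostics
NULL

#' @rdname bifurcation-diagnostics
#' @export
theta_snic_point <- function(bracket = c(-0.5, 0.5), tol = 1e-3,
                             dt = 1e-3, t_max = 300) {
  spikes <- function(p) {
    sim <- single_node_sim(theta_params(p = p, alpha = 0), dt, t_max,
                           init = 0)
    any(sim$theta[, 1] >= pi)
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (spikes(lo) || !spikes(hi)) stop("bracket does not straddle the onset")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (spikes(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' @rdname bifurcation-diagnostics
#' @export
theta_spike_period <- function(p, dt = 1e-4, t_max = NULL) {
  stopifnot(p > 0)
  if (is.null(t_max)) t_max <- 3 * pi / sqrt(p) + 1
  sim <- single_node_sim(theta_params(p = p, alpha = 0), dt, t_max,
                         init = 0)
  th <- sim$theta[, 1]
  cross1 <- which(th >= pi)[1]
  cross2 <- which(th >= 3 * pi)[1]
  if (is.na(cross1) || is.na(cross2)) stop("no two spikes within t_max")
  (cross2 - cross1) * dt
}

#' @rdname bifurcation-diagnostics
#' @export
bistable_coexistence_lower <- function(bracket = c(-1.5, -0.5), tol = 1e-3,
                                       dt = 1e-4, t_max = 300, z0 = 2) {
  persists <- function(p) {
    det <- cpp_bistable_det(p, 20, dt, round(t_max / dt), z0, 0, 0.1)
    det$u_final > 0.5
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (persists(lo) || !persists(hi))
    stop("bracket does not straddle the saddle-node of limit cycles")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (persists(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' @rdname bifurcation-diagnostics
#' @export
bistable_settled_amplitude <- function(p, dt = 1e-4, t_max = 50, z0 = 2) {
  cpp_bistable_det(p, 20, dt, round(t_max / dt), z0, 0, 0.1)$u_tail_mean
}
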