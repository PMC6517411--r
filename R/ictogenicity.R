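#' Excitability-by-coupling parameter grid
#'
#' Regular grid over which BNI is evaluated, one simulation per cell.  The
#' default ranges per model are: physiological `p` in \[50, 110\], `alpha`
#' in \[0, 1000\]; theta `p` in \[-4, -0.1\], `alpha` in \[0, 10\]; bistable
#' `p` in \[-1, 0\], `alpha` in \[0, 10\].  The full-fidelity resolution is
#' 192 points per axis.
#'
#' @param model model name.
#' @param resolution points per axis.
#' @param p_range,alpha_range optional `c(min, max)` overrides.
#' @export
parameter_grid <- function(model = c("theta", "bistable", "physiological"),
                           resolution = 192L, p_range = NULL,
                           alpha_range = NULL) {
  model <- match.arg(model)
  defaults <- switch(model,
    physiological = list(p = c(50, 110), alpha = c(0, 1000)),
    theta = list(p = c(-4, -0.1), alpha = c(0, 10)),
    bistable = list(p = c(-1, 0), alpha = c(0, 10)))
  if (is.null(p_range)) p_range <- defaults$p
  if (is.null(alpha_range)) alpha_range <- defaults$alpha
  structure(list(model = model,
                 p = seq(p_range[1], p_range[2], length.out = resolution),
                 alpha = seq(alpha_range[1], alpha_range[2],
                             length.out = resolution),
                 resolution = as.integer(resolution)),
            class = "parameter_grid")
}

#' Ictal-state classifier configuration
#'
#' The models' ictal states are detected as follows.  Theta: a node is ictal
#' at a sample iff a spike — an upward crossing of `theta_s + pi` (mod
#' `2 pi`) by the unwrapped phase — occurs within `theta_spike_halfwidth`
#' time units of it, so sustained spiking is marked contiguously while a
#' quiescent node, or one merely displaced from its steady state without
#' completing an oscillation, contributes nothing.  (Marking residence
#' outside a phase band instead turns slow non-oscillatory stalls near the
#' unstable fixed point into "ictal" time and misorders strongly coupled
#' networks; the ictal state stands for large-amplitude oscillation, i.e.
#' firing.)  Physiological: a node is ictal
#' while its pyramidal output deviates from the noise-free baseline output
#' of the same cell by more than `phys_threshold` mV; when `NULL` the
#' threshold is calibrated once per sweep as `phys_threshold_factor` times
#' the robust standard deviation (1.4826 MAD) of a noise-driven
#' sub-threshold reference trajectory (uncoupled node at the low end of the
#' excitability range).  Bistable: a node becomes ictal on first passage to
#' `|z|^2 >= escape_radius2`; the default 1 is at least the unstable-cycle
#' separatrix `1 - sqrt(1 + p)` for every `p` in \[-1, 0\].
#'
#' @param model model name.
#' @param theta_spike_halfwidth half-width (time units) of the ictal window
#'   marked around each theta spike; the default 0.5 is about half the
#'   inter-spike interval at the strongly driven end of the sweep window.
#' @param phys_threshold output deviation threshold (mV) or `NULL` for
#'   automatic calibration.
#' @param phys_threshold_factor multiplier of the robust noise SD.
#' @param escape_radius2 squared escape radius.
#' @export
ictal_classifier <- function(model = c("theta", "bistable", "physiological"),
                             theta_spike_halfwidth = 0.5,
                             phys_threshold = NULL,
                             phys_threshold_factor = 6, escape_radius2 = 1) {
  model <- match.arg(model)
  stopifnot(theta_spike_halfwidth > 0, escape_radius2 > 0,
            phys_threshold_factor > 0,
            is.null(phys_threshold) || phys_threshold > 0)
  structure(list(model = model,
                 theta_spike_halfwidth = theta_spike_halfwidth,
                 phys_threshold = phys_threshold,
                 phys_threshold_factor = phys_threshold_factor,
                 escape_radius2 = escape_radius2),
            class = "ictal_classifier")
}

# per-node fraction of retained steps covered by spike windows; mirrors the
# fused C++ sweep exactly (steps are rows 2..N of the series; spikes found
# anywhere, coverage clipped to steps > burn_steps)
theta_spike_fraction <- function(series, theta_s, half_steps, burn_steps) {
  n_steps <- nrow(series) - 1L
  vapply(seq_len(ncol(series)), function(i) {
    cm <- cummax(series[-1, i])
    n_spk <- floor((cm[n_steps] - (theta_s + pi)) / (2 * pi)) + 1
    covered <- 0; last <- burn_steps
    if (n_spk >= 1) {
      thresholds <- theta_s + pi + 2 * pi * (seq_len(n_spk) - 1)
      spike_steps <- findInterval(thresholds - 1e-12, cm) + 1L
      for (s in spike_steps) {
        lo <- max(s - half_steps, last + 1)
        hi <- min(s + half_steps, n_steps)
        if (hi >= lo) { covered <- covered + hi - lo + 1; last <- hi }
      }
    }
    covered / (n_steps - burn_steps)
  }, numeric(1))
}

# deterministic reference-cell calibration of the physiological threshold
phys_calibrate_threshold <- function(params, config, grid, classifier) {
  p_ref <- min(grid$p)
  ref_params <- params
  ref_params$p <- p_ref
  ref_params$alpha <- 0
  ref_cfg <- config
  ref_cfg$net_id <- 0L
  ref_cfg$removed_id <- 1048576L  # reserved context, outside any map
  ref_cfg$cell_index <- 0L
  net1 <- make_network(matrix(0L, 1, 1), check = FALSE)
  sim <- simulate_dynamics(net1, ref_params, ref_cfg)
  keep <- seq(burn_steps_of(config) + 2, n_steps_of(config) + 1)
  classifier$phys_threshold <-
    classifier$phys_threshold_factor * stats::mad(sim$output[keep, 1])
  classifier
}

phys_baseline_windows <- function(config) {
  bs <- burn_steps_of(config)
  list(base_steps = bs, base_avg = max(1L, as.integer(round(bs / 4))))
}

# per-node baseline outputs from a noise-free run, mirroring the fused sweep
phys_baseline <- function(net, params, config) {
  w <- phys_baseline_windows(config)
  params$sigma <- 0
  cfg <- config
  cfg$t_total <- w$base_steps * config$dt
  cfg$t_burn <- 0
  sim <- simulate_dynamics(net, params, cfg)
  rows <- seq(w$base_steps - w$base_avg + 2, w$base_steps + 1)
  colMeans(sim$output[rows, , drop = FALSE])
}

#' Fraction of time in the ictal state
#'
#' Applies the classifier to a simulated trajectory (theta or physiological
#' models) and returns per-node fractions of retained (post-transient)
#' samples classified ictal; the network-level value is the mean over
#' nodes, which is the time-fraction definition of BNI.
#'
#' @param x an `icto_sim` object, or a samples-by-nodes matrix of the
#'   model's observable whose first row is the initial condition (unwrapped
#'   phases for theta; outputs, classified against `baseline`, for
#'   physiological).
#' @param classifier an [ictal_classifier()].
#' @param model,theta_s,baseline,config,dt needed only when `x` is a bare
#'   matrix: model name, steady-state phase, per-node baseline outputs, the
#'   [sim_config()] defining the transient window (no transient when
#'   omitted), and the sampling step.
#' @return list with `node` (per-node fractions) and `network` (mean).
#' @export
ictal_fraction <- function(x, classifier = NULL, model = NULL,
                           theta_s = NULL, baseline = NULL, config = NULL,
                           dt = NULL) {
  if (inherits(x, "icto_sim")) {
    model <- x$model
    config <- x$config
    theta_s <- x$theta_s
    series <- if (model == "theta") x$theta else x$output
  } else series <- x
  if (is.null(classifier)) classifier <- ictal_classifier(model)
  if (is.null(dt) && !is.null(config)) dt <- config$dt
  bs <- if (is.null(config)) 0L else burn_steps_of(config)
  if (nrow(series) - 1 - bs < 1) stop("empty retained window")
  node <- switch(model,
    theta = {
      if (is.null(dt)) stop("dt is required for the theta spike classifier")
      theta_spike_fraction(series, theta_s,
                           round(classifier$theta_spike_halfwidth / dt), bs)
    },
    physiological = {
      rows <- seq(bs + 2, nrow(series))
      dev <- sweep(series[rows, , drop = FALSE], 2, baseline)
      colMeans(abs(dev) > classifier$phys_threshold)
    },
    stop("ictal_fraction applies to the theta and physiological models"))
  list(node = node, network = mean(node))
}

#' Escape-time BNI for the bistable model
#'
#' Per-node first-passage time from `z = 0` to `|z|^2 >= escape_radius2`,
#' censored at the reference time (non-escaping nodes contribute the full
#' reference time); `BNI = 1 - mean(first passage) / t_ref`, in \[0, 1\].
#'
#' @param x an `icto_sim` of the bistable model, or a samples-by-nodes
#'   matrix of `|z|^2` whose first row is time 0.
#' @param classifier an [ictal_classifier()].
#' @param t_ref reference time; defaults to the simulated duration.
#' @param dt time step (required for a bare matrix).
#' @return list with `escape_times` (per node) and `bni`.
#' @export
escape_time_bni <- function(x, classifier = ictal_classifier("bistable"),
                            t_ref = NULL, dt = NULL) {
  if (inherits(x, "icto_sim")) {
    mod2 <- x$mod2
    dt <- x$config$dt
    if (is.null(t_ref)) t_ref <- x$config$t_total
  } else mod2 <- x
  stopifnot(!is.null(dt), !is.null(t_ref))
  n_avail <- (nrow(mod2) - 1) * dt
  if (n_avail < t_ref - 1e-9) stop("trajectory shorter than t_ref")
  times <- apply(mod2, 2, function(u) {
    hit <- which(u[-1] >= classifier$escape_radius2)
    if (length(hit) == 0) t_ref else min(hit[1] * dt, t_ref)
  })
  list(escape_times = times, bni = 1 - mean(times) / t_ref)
}

#' Compute a BNI map
#'
#' Simulates the model once per grid cell (deterministic per-cell seed
#' derived from the master seed, network id, removed-node id and cell
#' index) and evaluates BNI with the time-fraction definition (theta,
#' physiological) or the escape-time definition (bistable).
#'
#' @param net an `icto_network`.
#' @param params a `model_params` object (its `p` and `alpha` are swept,
#'   the remaining fields are used as is).
#' @param grid a [parameter_grid()].
#' @param config a [sim_config()]; its `net_id`/`removed_id`/`cell_index`
#'   fields are overridden by `net_id` and `removed_id`.
#' @param classifier an [ictal_classifier()].
#' @param net_id,removed_id integers identifying the network and the
#'   removed node (0 = none) in the seed derivation.
#' @return object of class `bni_map`: `p`, `alpha`, `bni` (p-by-alpha
#'   matrix, every entry in \[0, 1\]), plus metadata.
#' @export
compute_bni_map <- function(net, params,
                            grid = parameter_grid(model_of(params)),
                            config = sim_preset(model_of(params))$config,
                            classifier = ictal_classifier(model_of(params)),
                            net_id = 1L, removed_id = 0L) {
  stopifnot(inherits(net, "icto_network"), grid$model == model_of(params))
  ns <- n_steps_of(config)
  bs <- burn_steps_of(config)
  bni <- switch(model_of(params),
    theta = cpp_bni_map_theta(net$adjacency, grid$p, grid$alpha,
                              params$sigma_w, config$dt, bs, ns - bs,
                              as.integer(round(
                                classifier$theta_spike_halfwidth /
                                  config$dt)),
                              config$seed,
                              as.integer(net_id), as.integer(removed_id)),
    bistable = cpp_bni_map_bistable(net$adjacency, grid$p, grid$alpha,
                                    params$omega,
                                    params$beta * params$sigma, config$dt,
                                    ns, classifier$escape_radius2,
                                    config$seed, as.integer(net_id),
                                    as.integer(removed_id)),
    physiological = {
      if (is.null(classifier$phys_threshold))
        classifier <- phys_calibrate_threshold(params, config, grid,
                                               classifier)
      w <- phys_baseline_windows(config)
      cpp_bni_map_phys(net$adjacency, grid$p, grid$alpha, params$sigma,
                       config$dt, bs, ns - bs, w$base_steps, w$base_avg,
                       classifier$phys_threshold, params$constants,
                       config$seed, as.integer(net_id),
                       as.integer(removed_id))
    })
  structure(list(model = model_of(params), p = grid$p, alpha = grid$alpha,
                 bni = bni, net_id = as.integer(net_id),
                 removed_id = as.integer(removed_id), config = config,
                 classifier = classifier, n_nodes = net$n_nodes),
            class = "bni_map")
}

#' Mean BNI of a map
#' @param map a `bni_map`.
#' @export
map_mean <- function(map) mean(map$bni)

#' Node ictogenicity distribution
#'
#' For each node `i`, removes the node, recomputes the full BNI map over the
#' *same* parameter ranges, and evaluates
#' `NI_i = (<BNI>_0 - <BNI>_i) / <BNI>_0`, the fractional reduction in
#' map-averaged BNI.  `NI_i <= 1` always; it is negative when removing the
#' node increases the remaining network's ictogenicity.  The spread
#' `delta_ni = max NI - min NI` is the network's NI heterogeneity.
#'
#' @inheritParams compute_bni_map
#' @return object of class `ni_distribution`: data frame with columns
#'   `node`, `ni`, `bni_removed`, and attributes `bni0`, `delta_ni`,
#'   `model`, `net_id`.
#' @export
compute_ni <- function(net, params,
                       grid = parameter_grid(model_of(params)),
                       config = sim_preset(model_of(params))$config,
                       classifier = ictal_classifier(model_of(params)),
                       net_id = 1L) {
  if (model_of(params) == "physiological" &&
      is.null(classifier$phys_threshold))
    classifier <- phys_calibrate_threshold(params, config, grid, classifier)
  full <- compute_bni_map(net, params, grid, config, classifier,
                          net_id = net_id, removed_id = 0L)
  m0 <- map_mean(full)
  if (m0 <= 0)
    stop("NI undefined: map-averaged BNI of network ", net_id, " is zero")
  res <- vapply(net$labels, function(lbl) {
    sub <- remove_node(net, lbl)
    map_mean(compute_bni_map(sub, params, grid, config, classifier,
                             net_id = net_id, removed_id = lbl))
  }, numeric(1))
  ni <- (m0 - res) / m0
  out <- data.frame(node = net$labels, ni = ni, bni_removed = res)
  structure(out, bni0 = m0, delta_ni = max(ni) - min(ni),
            model = model_of(params), net_id = as.integer(net_id),
            class = c("ni_distribution", "data.frame"))
}

#' NI heterogeneity of a distribution
#' @param x an `ni_distribution`.
#' @export
delta_ni <- function(x) attr(x, "delta_ni")

#' Calibrate coupling to a target BNI operating point
#'
#' Bisection on the global coupling strength `alpha` at fixed excitability
#' until the (seed-averaged) BNI of the full network reaches `target`; this
#' supports the single-operating-point NI variant in which the unperturbed
#' network is placed at `BNI = 0.5` before nodes are removed.
#'
#' @param net an `icto_network`.
#' @param params a `model_params` object; `params$p` is the fixed
#'   excitability.
#' @param bracket `c(alpha_lo, alpha_hi)`; BNI must straddle `target`.
#' @param target target BNI.
#' @param config a [sim_config()].
#' @param classifier an [ictal_classifier()].
#' @param tol stop when `|BNI - target| <= tol`.
#' @param n_rep simulations averaged per evaluation (distinct seeds).
#' @param max_iter bisection iteration cap.
#' @param bni_fn optional function `alpha -> BNI`, replacing simulation
#'   (used for deterministic self-tests).
#' @return list with `alpha`, `bni`, `converged`.
#' @export
calibrate_coupling_for_bni <- function(net, params, bracket, target = 0.5,
                                       config = sim_preset(model_of(params))$config,
                                       classifier = ictal_classifier(model_of(params)),
                                       tol = 0.05, n_rep = 3, max_iter = 40,
                                       bni_fn = NULL) {
  if (is.null(bni_fn)) {
    if (model_of(params) == "physiological" &&
        is.null(classifier$phys_threshold))
      classifier <- phys_calibrate_threshold(
        params, config, parameter_grid(model_of(params)), classifier)
    bni_fn <- function(alpha) {
      g <- parameter_grid(model_of(params), resolution = 1L,
                          p_range = c(params$p, params$p),
                          alpha_range = c(alpha, alpha))
      mean(vapply(seq_len(n_rep), function(r) {
        cfg <- config
        cfg$seed <- config$seed + r - 1
        map_mean(compute_bni_map(net, params, g, cfg, classifier,
                                 net_id = 0L, removed_id = 0L))
      }, numeric(1)))
    }
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- bni_fn(lo); f_hi <- bni_fn(hi)
  if ((f_lo - target) * (f_hi - target) > 0)
    stop("bracket [", lo, ", ", hi, "] does not straddle target BNI ",
         target, " (endpoint values ", signif(f_lo, 3), ", ",
         signif(f_hi, 3), ")")
  increasing <- f_hi > f_lo
  mid <- (lo + hi) / 2; f_mid <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- bni_fn(mid)
    if (abs(f_mid - target) <= tol)
      return(list(alpha = mid, bni = f_mid, converged = TRUE))
    if ((f_mid > target) == increasing) hi <- mid else lo <- mid
  }
  list(alpha = mid, bni = f_mid, converged = FALSE)
}

#' @export
print.bni_map <- function(x, ...) {
  cat("<bni_map> ", x$model, " model, ", length(x$p), "x", length(x$alpha),
      " grid, mean BNI ", round(mean(x$bni), 4), "\n", sep = "")
  invisible(x)
}

#' Export a BNI map as tidy CSV
#'
#' Long format with columns `p`, `alpha`, `bni`, one row per grid cell.
#' @param map a `bni_map`.
#' @param path output file.
#' @export
write_bni_map_csv <- function(map, path) {
  df <- data.frame(p = rep(map$p, times = length(map$alpha)),
                   alpha = rep(map$alpha, each = length(map$p)),
                   bni = as.vector(map$bni))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
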