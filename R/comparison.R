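#' Weighted Kendall rank agreement between two NI distributions
#'
#' Over all unordered node pairs (i, j), a pair ranked in the same order by
#' both NI lists adds the product of absolute NI differences under the two
#' models, `abs(NI_i^A - NI_j^A) * abs(NI_i^B - NI_j^B)`, to the concordant
#' mass `P`; a pair ranked in the inverse order adds it to
#' the discordant mass `Q`; a tie in either list (equality within `tol`)
#' carries zero weight.  `tau = (P - Q) / (P + Q)`, in \[-1, 1\]; when
#' `P + Q = 0` tau is undefined (`NA` with `undefined = TRUE`).  With unit
#' weights this reduces to the classical Kendall tau-a.
#'
#' @param ni_a,ni_b numeric vectors of per-node NI, aligned by node, of
#'   length at least 2.
#' @param weights optional pair-weight override: `NULL` (the NI-difference
#'   product above) or a single number / vector over pairs in
#'   `combn(n, 2)` order.
#' @param tol absolute tolerance for treating two NI values as tied.
#' @return list of class `weighted_kendall`: `tau`, `P`, `Q`, `n_pairs`,
#'   `undefined`.
#' @export
weighted_kendall <- function(ni_a, ni_b, weights = NULL, tol = 1e-12) {
  n <- length(ni_a)
  if (length(ni_b) != n) stop("NI lists have different lengths")
  if (n < 2) stop("need at least 2 nodes")
  pr <- utils::combn(n, 2)
  da <- ni_a[pr[1, ]] - ni_a[pr[2, ]]
  db <- ni_b[pr[1, ]] - ni_b[pr[2, ]]
  w <- if (is.null(weights)) abs(da) * abs(db) else rep_len(weights, ncol(pr))
  tied <- abs(da) <= tol | abs(db) <= tol
  w[tied] <- 0
  s <- sign(da) * sign(db)
  P <- sum(w[s > 0])
  Q <- sum(w[s < 0])
  tau <- if (P + Q > 0) (P - Q) / (P + Q) else NA_real_
  structure(list(tau = tau, P = P, Q = Q, n_pairs = ncol(pr),
                 undefined = P + Q <= 0),
            class = "weighted_kendall")
}

#' Weighted Kendall agreement restricted to the most ictogenic nodes
#'
#' Restricts the comparison to the `k` nodes with the largest NI in the
#' reference list (ties broken by node order), then applies
#' [weighted_kendall()] to the restriction.
#'
#' @inheritParams weighted_kendall
#' @param k number of top-ranked nodes to keep (`2 <= k <= n`).
#' @param reference which list defines "most ictogenic": `"a"` or `"b"`.
#' @export
top_k_kendall <- function(ni_a, ni_b, k, reference = c("a", "b")) {
  reference <- match.arg(reference)
  n <- length(ni_a)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k exceeds the number of nodes")
  ref <- if (reference == "a") ni_a else ni_b
  keep <- order(ref, decreasing = TRUE)[seq_len(k)]
  weighted_kendall(ni_a[keep], ni_b[keep])
}

#' Cross-model agreement versus NI heterogeneity
#'
#' Takes per-network, per-model NI values for a common network ensemble and
#' (1) computes the weighted Kendall tau for every network and model pair,
#' with the ensemble mean tau per pair (networks with undefined tau are
#' excluded and counted); (2) min-max normalizes each model's `delta NI`
#' across the ensemble, keeps networks with normalized `delta NI` >
#' `filter`, sorts them by the reference model's `delta NI` and splits them
#' into `n_bins` equal-occupancy bins (remainders assigned to the lowest
#' bins), reporting the bin-wise mean tau and its standard error for each
#' (pair, reference model); and (3) reports, per model, the Spearman
#' correlation between the networks' normalized out-degree spread
#' `sd(k_out)/mean(k_out)` and `delta NI`.
#'
#' @param ni_table data frame with columns `network_id`, `model`, `node`,
#'   `ni` covering every (network, model) combination.
#' @param stats_table optional data frame with columns `network_id`,
#'   `n_edges`, `normalized_sd` (from [network_stats()]); required for the
#'   Spearman correlations.
#' @param n_bins number of equal-occupancy heterogeneity bins.
#' @param filter keep networks with normalized delta NI above this value.
#' @return list of class `comparison_result`: `heterogeneity` (per network
#'   and model: `delta_ni`, `delta_ni_norm`), `tau` (per network and pair),
#'   `pair_summary` (ensemble mean tau, SEM, counts incl. undefined),
#'   `bins` (pair, reference model, bin, mean delta NI, mean tau, SEM, n),
#'   `spearman` (per model rho between degree spread and delta NI).
#' @export
heterogeneity_analysis <- function(ni_table, stats_table = NULL,
                                   n_bins = 4L, filter = 0.05) {
  need <- c("network_id", "model", "node", "ni")
  if (!all(need %in% names(ni_table)))
    stop("ni_table must have columns ", paste(need, collapse = ", "))
  models <- sort(unique(ni_table$model))
  nets <- unique(ni_table$network_id)
  if (length(models) < 2) stop("need at least two models to compare")

  # per-network, per-model delta NI and min-max normalization per model
  het <- do.call(rbind, lapply(models, function(m) {
    sub <- ni_table[ni_table$model == m, ]
    d <- tapply(sub$ni, sub$network_id, function(v) max(v) - min(v))
    data.frame(network_id = names(d), model = m,
               delta_ni = as.numeric(d), row.names = NULL)
  }))
  het$delta_ni_norm <- ave(het$delta_ni, het$model, FUN = function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  })

  # tau per network and model pair
  pairs <- utils::combn(models, 2, simplify = FALSE)
  tau_df <- do.call(rbind, lapply(pairs, function(pp) {
    do.call(rbind, lapply(nets, function(id) {
      a <- ni_table[ni_table$network_id == id & ni_table$model == pp[1], ]
      b <- ni_table[ni_table$network_id == id & ni_table$model == pp[2], ]
      a <- a[order(a$node), ]; b <- b[order(b$node), ]
      if (!identical(a$node, b$node))
        stop("node sets differ between models for network ", id)
      wk <- weighted_kendall(a$ni, b$ni)
      data.frame(network_id = id, model_a = pp[1], model_b = pp[2],
                 tau = wk$tau, undefined = wk$undefined)
    }))
  }))
  pair_summary <- do.call(rbind, lapply(pairs, function(pp) {
    sub <- tau_df[tau_df$model_a == pp[1] & tau_df$model_b == pp[2], ]
    ok <- sub$tau[!sub$undefined]
    data.frame(model_a = pp[1], model_b = pp[2],
               mean_tau = mean(ok), sem_tau = sd(ok) / sqrt(length(ok)),
               n_networks = length(ok), n_undefined = sum(sub$undefined))
  }))

  # equal-occupancy binning by the reference model's delta NI
  bins <- do.call(rbind, lapply(pairs, function(pp) {
    do.call(rbind, lapply(pp, function(ref) {
      h <- het[het$model == ref, ]
      keep <- h$network_id[h$delta_ni_norm > filter]
      tt <- tau_df[tau_df$model_a == pp[1] & tau_df$model_b == pp[2] &
                     tau_df$network_id %in% keep & !tau_df$undefined, ]
      h <- h[match(tt$network_id, h$network_id), ]
      if (nrow(tt) < n_bins)
        stop("fewer than ", n_bins, " networks survive the delta-NI filter ",
             "for reference model ", ref)
      ord <- order(h$delta_ni_norm)  # stable sort keeps ties in place
      idx <- bin_assign(length(ord), n_bins)
      do.call(rbind, lapply(seq_len(n_bins), function(b) {
        sel <- ord[idx == b]
        data.frame(model_a = pp[1], model_b = pp[2], reference = ref,
                   bin = b,
                   delta_ni_mid = mean(h$delta_ni_norm[sel]),
                   mean_tau = mean(tt$tau[sel]),
                   sem_tau = sd(tt$tau[sel]) / sqrt(length(sel)),
                   n_networks = length(sel))
      }))
    }))
  }))

  spearman <- NULL
  if (!is.null(stats_table)) {
    spearman <- do.call(rbind, lapply(models, function(m) {
      h <- het[het$model == m, ]
      s <- stats_table[match(h$network_id, stats_table$network_id), ]
      data.frame(model = m,
                 rho = cor(s$normalized_sd, h$delta_ni,
                           method = "spearman"))
    }))
  }
  structure(list(heterogeneity = het, tau = tau_df,
                 pair_summary = pair_summary, bins = bins,
                 spearman = spearman),
            class = "comparison_result")
}

# equal-occupancy bin labels for m sorted items; remainders go to the
# lowest bins so occupancies differ by at most one
bin_assign <- function(m, n_bins) {
  base <- m %/% n_bins
  extra <- m %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1, extra), rep(0, n_bins - extra))
  rep(seq_len(n_bins), times = sizes)
}
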