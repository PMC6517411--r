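#' Binary directed networks
#'
#' A network is a simple binary digraph without self-loops, stored as an
#' adjacency matrix `M` with the receiver convention `M[i, j] = 1` iff node
#' `i` receives an edge from node `j` (the convention used by the coupling
#' sums of all three dynamical models).  Node labels are stable integer
#' identifiers that survive node removal, so that per-node quantities can be
#' aligned before and after a virtual resection.
#'
#' @param adjacency square binary matrix with zero diagonal.
#' @param labels integer node labels; default `1:n`.
#' @param check validate invariants (square, binary, zero diagonal).
#' @return An object of class `icto_network` with fields `adjacency`,
#'   `n_nodes` and `labels`.
#' @examples
#' net <- make_network(rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)))  # 3-cycle
#' network_stats(net)
#' @export
make_network <- function(adjacency, labels = NULL, check = TRUE) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "integer"
  n <- nrow(adjacency)
  if (is.null(labels)) labels <- seq_len(n)
  labels <- as.integer(labels)
  if (check) {
    if (ncol(adjacency) != n) stop("adjacency must be square")
    if (!all(adjacency %in% c(0L, 1L))) stop("adjacency must be binary")
    if (any(diag(adjacency) != 0L)) stop("self-loops are not allowed")
    if (length(labels) != n || anyDuplicated(labels))
      stop("labels must be ", n, " distinct integers")
  }
  dimnames(adjacency) <- list(labels, labels)
  structure(list(adjacency = adjacency, n_nodes = n, labels = labels),
            class = "icto_network")
}

#' @export
print.icto_network <- function(x, ...) {
  cat("<icto_network> ", x$n_nodes, " nodes, ",
      sum(x$adjacency), " directed edges\n", sep = "")
  invisible(x)
}

as_igraph <- function(net) {
  # igraph's adjacency convention is row = source; ours is row = receiver
  igraph::graph_from_adjacency_matrix(t(net$adjacency), mode = "directed")
}

#' Is a network weakly connected?
#'
#' Weak connectivity (connectivity of the underlying undirected graph) is the
#' generation criterion for all network ensembles used here.
#' @param net an `icto_network`.
#' @export
is_weakly_connected <- function(net) {
  igraph::is_connected(as_igraph(net), mode = "weak")
}

#' Enumerate nonisomorphic weakly connected digraphs
#'
#' Exhaustively generates one representative per isomorphism class of simple
#' weakly connected digraphs without self-loops on `n_nodes` nodes, by
#' scanning all zero-diagonal binary adjacency matrices and deduplicating
#' with an exact canonical form (minimum of the adjacency bit string over all
#' node permutations).  Output order is deterministic: ascending edge count,
#' then canonical key.  There are 2 such digraphs on 2 nodes, 13 on 3 nodes
#' and 199 on 4 nodes.
#'
#' @param n_nodes number of nodes, between 2 and 5 (exhaustive search).
#' @return list of `icto_network` objects.
#' @export
enumerate_digraphs <- function(n_nodes) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1 ||
      n_nodes < 2 || n_nodes > 5)
    stop("unsupported size: exhaustive enumeration requires 2 <= n_nodes <= 5")
  lapply(cpp_enumerate_digraphs(as.integer(n_nodes)), make_network)
}

#' Exact digraph isomorphism test
#'
#' Uses the exact canonical form for up to 7 nodes and, for larger networks,
#' a degree-sequence fingerprint with an exact VF2 permutation search (via
#' igraph) on fingerprint collisions.
#'
#' @param a,b `icto_network` objects.
#' @return `TRUE` iff some node relabeling maps `a`'s adjacency onto `b`'s.
#' @export
are_isomorphic <- function(a, b) {
  if (a$n_nodes != b$n_nodes) return(FALSE)
  if (sum(a$adjacency) != sum(b$adjacency)) return(FALSE)
  if (a$n_nodes <= 7)
    return(cpp_canonical_key(a$adjacency) == cpp_canonical_key(b$adjacency))
  if (!identical(iso_fingerprint(a), iso_fingerprint(b))) return(FALSE)
  igraph::isomorphic(as_igraph(a), as_igraph(b), method = "vf2")
}

# invariant fingerprint used to prune the exact isomorphism search
iso_fingerprint <- function(net) {
  M <- net$adjacency
  outdeg <- colSums(M)  # edges sent by each node (column = source)
  indeg <- rowSums(M)
  joint <- paste(sort(paste(indeg, outdeg, sep = ",")), collapse = ";")
  nbr <- vapply(seq_len(net$n_nodes), function(i) {
    paste(sort(outdeg[M[i, ] == 1]), collapse = ",")
  }, character(1))
  paste(joint, paste(sort(nbr), collapse = "|"), sep = "#")
}

#' Sample weakly connected nonisomorphic random digraphs
#'
#' Draws networks with an approximately uniform distribution of edge counts:
#' for each network a target edge count is drawn uniformly from
#' `edge_range`, that many directed edges are placed uniformly at random
#' (directed Erdos-Renyi conditioned on edge count), and the draw is
#' rejected unless the result is weakly connected and nonisomorphic to all
#' previously accepted networks.
#'
#' @param n_nodes number of nodes.
#' @param n_networks number of networks to return.
#' @param edge_range integer vector `c(min, max)`; must lie within
#'   `[n_nodes - 1, n_nodes * (n_nodes - 1)]`.
#' @param seed integer seed; the same call with the same seed returns
#'   identical networks.
#' @param max_tries rejection budget per network.
#' @return list of `icto_network` objects.
#' @export
sample_random_digraphs <- function(n_nodes, n_networks, edge_range,
                                   seed = 1L, max_tries = 1000L) {
  n <- as.integer(n_nodes)
  stopifnot(n >= 2, n_networks >= 1, length(edge_range) == 2)
  lo <- as.integer(edge_range[1]); hi <- as.integer(edge_range[2])
  if (lo > hi || lo < n - 1L || hi > n * (n - 1L))
    stop("infeasible edge_range [", lo, ", ", hi, "] for ", n, " nodes")
  slots <- which(diag(n) == 0)  # linear indices of off-diagonal entries
  with_local_seed(seed, {
    nets <- vector("list", n_networks)
    keys <- character(n_networks)
    for (k in seq_len(n_networks)) {
      m <- if (lo == hi) lo else sample(seq(lo, hi), 1L)
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        M <- matrix(0L, n, n)
        M[sample(slots, m)] <- 1L
        net <- make_network(M, check = FALSE)
        if (!is_weakly_connected(net)) next
        if (any(vapply(nets[seq_len(k - 1)], function(old) {
          !is.null(old) && are_isomorphic(old, net)
        }, logical(1)))) next
        nets[[k]] <- net
        ok <- TRUE
        break
      }
      if (!ok)
        stop("failed to sample network ", k, " (edge-count stratum ", m,
             ") within ", max_tries, " tries")
    }
    nets
  })
}

#' Remove a node from a network
#'
#' Returns the induced subnetwork on the remaining nodes (the corresponding
#' row and column of the adjacency matrix are deleted).  Remaining labels
#' are unchanged; the result is allowed to be disconnected.
#'
#' @param net an `icto_network`.
#' @param node a node label present in `net$labels`.
#' @export
remove_node <- function(net, node) {
  if (net$n_nodes < 2) stop("cannot remove a node from a 1-node network")
  idx <- match(node, net$labels)
  if (is.na(idx)) stop("unknown node label: ", node)
  make_network(net$adjacency[-idx, -idx, drop = FALSE],
               labels = net$labels[-idx], check = FALSE)
}

#' Degree statistics of a network
#'
#' Out-degree spread is summarized by the population standard deviation of
#' out-degrees divided by the mean out-degree (the normalized standard
#' deviation of outdegree used as the heterogeneity covariate).
#'
#' @param net an `icto_network`.
#' @return list with `n_edges`, `outdegree_mean`, `outdegree_sd`
#'   (population convention, divide by N), `normalized_sd`, and per-node
#'   `total_degree` (in + out).
#' @export
network_stats <- function(net) {
  M <- net$adjacency
  outdeg <- colSums(M)
  indeg <- rowSums(M)
  mu <- mean(outdeg)
  sd_pop <- sqrt(mean((outdeg - mu)^2))
  list(n_edges = sum(M),
       outdegree_mean = mu,
       outdegree_sd = sd_pop,
       normalized_sd = if (mu > 0) sd_pop / mu else NA_real_,
       total_degree = stats::setNames(as.numeric(indeg + outdeg),
                                      net$labels))
}

#' Network edge-list I/O
#'
#' Edge lists are TSV files with columns `source` and `target` (0-based
#' labels, one directed edge per line); `write_adjacency_csv` writes the
#' dense adjacency matrix (receiver rows).
#'
#' @param net an `icto_network`.
#' @param path file path.
#' @param n_nodes node count for `read_edgelist` (needed when isolated
#'   labels could be absent from the edge list); default: max label + 1.
#' @name network-io
NULL

#' @rdname network-io
#' @export
write_edgelist <- function(net, path) {
  idx <- which(net$adjacency == 1, arr.ind = TRUE)
  df <- data.frame(source = net$labels[idx[, "col"]] - 1L,
                   target = net$labels[idx[, "row"]] - 1L)
  df <- df[order(df$source, df$target), , drop = FALSE]
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname network-io
#' @export
read_edgelist <- function(path, n_nodes = NULL) {
  df <- read.delim(path)
  if (is.null(n_nodes)) n_nodes <- max(df$source, df$target) + 1L
  M <- matrix(0L, n_nodes, n_nodes)
  M[cbind(df$target + 1L, df$source + 1L)] <- 1L
  make_network(M)
}

#' @rdname network-io
#' @export
write_adjacency_csv <- function(net, path) {
  write.csv(net$adjacency, path, row.names = FALSE)
  invisible(path)
}
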