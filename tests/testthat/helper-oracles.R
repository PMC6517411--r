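# fixtures and independent oracles used across test files

net_cycle3 <- function() {
  make_network(rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)))
}

net_complete <- function(n) {
  make_network(matrix(1L, n, n) - diag(n))
}

net_mutual_pair <- function() make_network(rbind(c(0, 1), c(1, 0)))

# all permutations of 1:n (recursive; n <= 6 in tests)
all_perms <- function(n) {
  perm_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (sub in perm_of(v[-i]))
        out[[length(out) + 1L]] <- c(v[i], sub)
    out
  }
  perm_of(seq_len(n))
}

# brute-force digraph isomorphism: try every node relabeling
brute_force_isomorphic <- function(a, b) {
  if (a$n_nodes != b$n_nodes) return(FALSE)
  A <- a$adjacency
  B <- b$adjacency
  for (perm in all_perms(a$n_nodes))
    if (all(A[perm, perm] == B)) return(TRUE)
  FALSE
}

# independent weighted-Kendall oracle: explicit double loop over node pairs
kendall_oracle <- function(a, b) {
  P <- 0; Q <- 0
  n <- length(a)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (a[i] == a[j] || b[i] == b[j]) next
      w <- abs(a[i] - a[j]) * abs(b[i] - b[j])
      if ((a[i] - a[j]) * (b[i] - b[j]) > 0) P <- P + w else Q <- Q + w
    }
  }
  if (P + Q == 0) NA_real_ else (P - Q) / (P + Q)
}

random_connected_digraph <- function(n, m) {
  repeat {
    M <- matrix(0L, n, n)
    M[sample(which(diag(n) == 0), m)] <- 1L
    net <- make_network(M, check = FALSE)
    if (is_weakly_connected(net)) return(net)
  }
}
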