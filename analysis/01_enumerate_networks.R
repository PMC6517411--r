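#!/usr/bin/env Rscript
# Build the network ensembles for the node-removal study:
#   (1) every weakly connected nonisomorphic digraph on 3 and 4 nodes
#       (13 and 199 isomorphism classes),
#   (2) a stratified sample of 19-node random digraphs whose edge counts are
#       approximately uniform over [18, 342].
# Edge lists, per-network degree statistics and a JSON manifest go to
# results/networks/.  N_19 is 25 here to keep a desk run short; the
# full-scale ensemble uses 125.

suppressMessages(library(ictonet))

out_dir <- "results/networks"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

seed <- 101L
n_19 <- 25L

manifest <- list(seed = seed)
stats_rows <- list()

# enumerated families are summarized (they regenerate in milliseconds);
# only the sampled 19-node ensemble is persisted as edge lists
for (n in c(3L, 4L)) {
  nets <- enumerate_digraphs(n)
  cat(sprintf("%d-node weakly connected digraph classes: %d\n",
              n, length(nets)))
  manifest[[paste0("n", n, "_classes")]] <- length(nets)
  for (k in seq_along(nets)) {
    id <- sprintf("enum%d_%03d", n, k)
    st <- network_stats(nets[[k]])
    stats_rows[[id]] <- data.frame(network_id = id, n_nodes = n,
                                   n_edges = st$n_edges,
                                   normalized_sd = st$normalized_sd)
  }
}

nets19 <- sample_random_digraphs(19, n_19, c(18, 342), seed = seed)
counts <- vapply(nets19, function(x) network_stats(x)$n_edges, integer(1))
cat(sprintf("19-node sample: %d networks, edge counts %d-%d (target 18-342)\n",
            length(nets19), min(counts), max(counts)))
manifest$n19_sampled <- length(nets19)
manifest$n19_edge_range <- range(counts)
for (k in seq_along(nets19)) {
  id <- sprintf("rand19_%03d", k)
  write_edgelist(nets19[[k]], file.path(out_dir, paste0(id, ".tsv")))
  st <- network_stats(nets19[[k]])
  stats_rows[[id]] <- data.frame(network_id = id, n_nodes = 19L,
                                 n_edges = st$n_edges,
                                 normalized_sd = st$normalized_sd)
}

stats_table <- do.call(rbind, stats_rows)
write.csv(stats_table, file.path(out_dir, "network_stats.csv"),
          row.names = FALSE)
jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                     auto_unbox = TRUE, digits = NA)
cat("wrote", length(nets19), "edge lists and network_stats.csv (",
    nrow(stats_table), "networks )\n")
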