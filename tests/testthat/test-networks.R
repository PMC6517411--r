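test_that("exhaustive enumeration reproduces the digraph class counts", {
  expect_length(enumerate_digraphs(2), 2)
  nets3 <- enumerate_digraphs(3)
  expect_length(nets3, 13)
  expect_length(enumerate_digraphs(4), 199)
  expect_true(all(vapply(nets3, is_weakly_connected, logical(1))))
  # pairwise nonisomorphic
  for (i in seq_along(nets3))
    for (j in seq_len(i - 1))
      expect_false(are_isomorphic(nets3[[i]], nets3[[j]]))
  expect_error(enumerate_digraphs(1), "unsupported")
  expect_error(enumerate_digraphs(6), "unsupported")
})

test_that("isomorphism test is exact and matches brute force", {
  cyc <- net_cycle3()
  cyc_relabeled <- make_network(rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)))
  chain <- make_network(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_true(are_isomorphic(cyc, cyc_relabeled))
  expect_true(are_isomorphic(cyc, cyc))
  expect_false(are_isomorphic(cyc, chain))
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:5, 1)
    a <- random_connected_digraph(n, sample(n:(n * (n - 1)), 1))
    b <- random_connected_digraph(n, sample(n:(n * (n - 1)), 1))
    perm <- sample(n)
    a_perm <- make_network(a$adjacency[perm, perm])
    expect_true(are_isomorphic(a, a_perm))
    expect_identical(are_isomorphic(a, b), brute_force_isomorphic(a, b))
  }
})

test_that("node removal deletes the right row/column and keeps labels", {
  cyc <- net_cycle3()
  sub <- remove_node(cyc, 2)
  expect_identical(sub$labels, c(1L, 3L))
  # the surviving edge is 1 -> 3 (receiver convention: row 3 reads from col 1)
  expect_identical(unname(sub$adjacency), rbind(c(0L, 0L), c(1L, 0L)))
  # complete digraph minus any node is a mutual pair
  sub2 <- remove_node(net_complete(3), 1)
  expect_identical(unname(sub2$adjacency), rbind(c(0L, 1L), c(1L, 0L)))
  # removing the hub of a star disconnects the leaves (still a valid network)
  star <- make_network(rbind(c(0, 0, 0, 0), c(1, 0, 0, 0),
                             c(1, 0, 0, 0), c(1, 0, 0, 0)))
  leaves <- remove_node(star, 1)
  expect_identical(sum(leaves$adjacency), 0L)
  expect_false(is_weakly_connected(leaves))
  # removals of distinct labels commute
  n4 <- enumerate_digraphs(4)[[100]]
  ab <- remove_node(remove_node(n4, 2), 4)
  ba <- remove_node(remove_node(n4, 4), 2)
  expect_identical(ab$adjacency, ba$adjacency)
  expect_error(remove_node(cyc, 9), "unknown")
  one <- make_network(matrix(0L, 1, 1))
  expect_error(remove_node(one, 1), "1-node")
})

test_that("network statistics use the population out-degree convention", {
  expect_identical(network_stats(net_complete(19))$n_edges, 342L)
  expect_equal(network_stats(net_cycle3())$normalized_sd, 0)
  # out-degrees (2, 1, 1): mean 4/3, population sd sqrt(2/9)
  net <- make_network(rbind(c(0, 1, 1), c(1, 0, 0), c(1, 0, 0)))
  st <- network_stats(net)
  expect_equal(sort(unname(colSums(net$adjacency))), c(1, 1, 2))
  expect_equal(st$outdegree_sd, sqrt(2 / 9))
  expect_equal(st$normalized_sd, sqrt(2) / 4)
  # invariant under relabeling
  perm <- c(3, 1, 2)
  st2 <- network_stats(make_network(net$adjacency[perm, perm]))
  expect_equal(st$normalized_sd, st2$normalized_sd)
  expect_identical(st$n_edges, st2$n_edges)
})

test_that("random digraph sampler is stratified, connected and reproducible", {
  # only one 3-node digraph has all 6 edges
  full <- sample_random_digraphs(3, 1, c(6, 6), seed = 3)[[1]]
  expect_identical(full$adjacency, net_complete(3)$adjacency)
  a <- sample_random_digraphs(19, 6, c(18, 342), seed = 42)
  b <- sample_random_digraphs(19, 6, c(18, 342), seed = 42)
  expect_identical(lapply(a, `[[`, "adjacency"),
                   lapply(b, `[[`, "adjacency"))
  expect_true(all(vapply(a, is_weakly_connected, logical(1))))
  for (i in seq_along(a))
    for (j in seq_len(i - 1))
      expect_false(are_isomorphic(a[[i]], a[[j]]))
  counts <- vapply(a, function(x) network_stats(x)$n_edges, integer(1))
  expect_true(all(counts >= 18 & counts <= 342))
  expect_error(sample_random_digraphs(3, 1, c(1, 2)), "infeasible")
})

test_that("edge-list round trip preserves the adjacency matrix", {
  net <- enumerate_digraphs(4)[[77]]
  path <- tempfile(fileext = ".tsv")
  write_edgelist(net, path)
  back <- read_edgelist(path, n_nodes = 4)
  expect_identical(back$adjacency, net$adjacency)
})
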