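test_that("Hamming matrix matches a site-by-site loop", {
  set.seed(2)
  for (k in 1:10) {
    n <- sample(2:8, 1); L <- sample(3:10, 1)
    calls <- matrix(sample(c("A", "G", "A/G"), n * L, replace = TRUE), n, L)
    rownames(calls) <- paste0("h", 1:n)
    D <- hamming_matrix(calls)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- 0
      for (s in 1:L) if (calls[i, s] != calls[j, s]) d <- d + 1
      expect_equal(D[i, j], d)
      expect_equal(D[j, i], d)
    }
    expect_true(all(diag(D) == 0))
  }
})

test_that("UPGMA reconstructs ultrametric examples exactly", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(d)
  expect_true(ape::write.tree(tr) %in%
                c("((A:1,B:1):1,C:2);", "(C:2,(A:1,B:1):1);"))
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- upgma(d2)
  expect_equal(sort(tr2$edge.length), c(1.5, 1.5))
  expect_error(upgma(matrix(0, 1, 1)), "at least 2")
})

test_that("UPGMA output is ultrametric and recovers simulated clock trees", {
  set.seed(14)
  for (k in 1:5) {
    true <- ape::rcoal(8)
    D <- ape::cophenetic.phylo(true)
    tr <- upgma(D)
    depths <- ape::node.depth.edgelength(tr)[seq_len(8)]
    expect_lt(diff(range(depths)), 1e-9)  # leaves equidistant from root
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                           ape::unroot(true))), 0)
  }
})

test_that("newick export is deterministic and byte-identical across runs", {
  cfg <- sim_config(seed = 19, n_samples = 20, dropout_rate = 0)
  sim <- simulate_patrilines(cfg)
  hs <- collapse_haplotypes(sim$genotypes)
  f1 <- tempfile(); f2 <- tempfile()
  write_newick(upgma(hamming_matrix(hs$calls)), f1)
  write_newick(upgma(hamming_matrix(hs$calls)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

binmat <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- vapply(rows, identity, "")
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

test_that("median joining reproduces the canonical small cases", {
  # chain: no median needed
  net <- mjn(binmat("00", "01", "11"))
  expect_equal(sum(net$nodes$type == "median"), 0L)
  expect_equal(nrow(net$edges), 2L)
  expect_equal(sum(net$edges$length), 2)

  # three haplotypes pairwise distance 2: single Steiner point 111
  net <- mjn(binmat("011", "101", "110"))
  med <- net$nodes$id[net$nodes$type == "median"]
  expect_equal(length(med), 1L)
  expect_equal(paste(net$calls[med, ], collapse = ""), "111")
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$length == 1))

  # star genealogy: root + k one-mutation descendants stays a star
  root <- "0000"
  leaves <- c("1000", "0100", "0010", "0001")
  net <- mjn(binmat(root, leaves[1], leaves[2], leaves[3], leaves[4]))
  expect_equal(sum(net$nodes$type == "median"), 0L)
  deg <- table(c(net$edges$from, net$edges$to))
  expect_equal(unname(deg[root]), 4L)
})

test_that("median joining is deterministic", {
  set.seed(33)
  calls <- matrix(sample(c("0", "1"), 8 * 6, replace = TRUE), 8, 6)
  calls <- calls[!duplicated(apply(calls, 1, paste, collapse = "")), ]
  rownames(calls) <- paste0("h", seq_len(nrow(calls)))
  colnames(calls) <- paste0("s", 1:6)
  n1 <- mjn(calls); n2 <- mjn(calls)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$nodes, n2$nodes)
})

test_that("the MJN contains a minimum spanning structure over observed haplotypes", {
  set.seed(44)
  for (k in 1:5) {
    calls <- matrix(sample(c("0", "1"), 7 * 6, replace = TRUE), 7, 6)
    calls <- calls[!duplicated(apply(calls, 1, paste, collapse = "")), ,
                   drop = FALSE]
    rownames(calls) <- paste0("h", seq_len(nrow(calls)))
    colnames(calls) <- paste0("s", 1:6)
    net <- mjn(calls)
    # network is connected and spans at most the observed MST length
    g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                       vertices = net$nodes$id)
    expect_true(igraph::is_connected(g))
    D_obs <- hamming_matrix(calls)
    obs_mst <- mst_length_igraph(D_obs)
    net_mst <- mst_length_igraph(hamming_matrix(net$calls))
    expect_lte(net_mst, obs_mst + 1e-9)
  }
})

test_that("MP pruning keeps exactly the minimum-tree links (Steiner oracle)", {
  # already-minimal path network is unchanged
  net <- mjn(binmat("00", "01", "11"))
  pruned <- mp_prune(net)
  expect_identical(pruned$edges, net$edges)

  set.seed(55)
  for (k in 1:6) {
    nh <- sample(4:8, 1)
    calls <- matrix(sample(c("0", "1"), nh * 5, replace = TRUE), nh, 5)
    calls <- calls[!duplicated(apply(calls, 1, paste, collapse = "")), ,
                   drop = FALSE]
    rownames(calls) <- paste0("h", seq_len(nrow(calls)))
    colnames(calls) <- paste0("s", 1:5)
    net <- mjn(calls)
    if (nrow(net$calls) > 12) next
    pruned <- mp_prune(net)
    D <- hamming_matrix(net$calls)
    obs <- which(net$nodes$type == "observed")
    med <- which(net$nodes$type == "median")
    oracle <- steiner_oracle(D, obs, med)
    expect_equal(sum(pruned$edges$length) >= oracle$length, TRUE)
    expect_setequal(rownames(pruned$calls), net$nodes$id[oracle$nodes])
    got <- sort(paste(pmin(match(pruned$edges$from, net$nodes$id),
                           match(pruned$edges$to, net$nodes$id)),
                      pmax(match(pruned$edges$from, net$nodes$id),
                           match(pruned$edges$to, net$nodes$id)),
                      sep = "-"))
    expect_equal(got, oracle$edges)
    # retained medians have degree >= 3
    deg <- table(c(pruned$edges$from, pruned$edges$to))
    meds <- pruned$nodes$id[pruned$nodes$type == "median"]
    if (length(meds)) expect_true(all(deg[meds] >= 3))
  }
})

test_that("on perfect-phylogeny data MJN+MP yields a tree of length = segregating sites", {
  for (seed in c(3, 9, 27)) {
    cfg <- sim_config(seed = seed, n_samples = 25, dropout_rate = 0,
                      p_partial = 0)  # pure single-base infinite sites
    sim <- simulate_patrilines(cfg)
    hs <- collapse_haplotypes(sim$genotypes)
    S <- count_segregating_sites(hs$calls)
    net <- mp_prune(mjn(hs$calls, counts = hs$haplotypes$count))
    expect_equal(nrow(net$edges), nrow(net$calls) - 1L)  # a tree
    expect_equal(sum(net$edges$length), S)
  }
})

test_that("network export writes edge list and GML that round-trip", {
  net <- mjn(binmat("011", "101", "110"))
  edges_tsv <- tempfile(fileext = ".tsv")
  gml <- tempfile(fileext = ".gml")
  g <- export_network(net, edges_tsv, gml,
                      groups = c(`011` = "SC", `101` = "NC", `110` = "SC"))
  tab <- read.delim(edges_tsv)
  expect_equal(nrow(tab), nrow(net$edges))
  g2 <- igraph::read_graph(gml, format = "gml")
  expect_equal(igraph::vcount(g2), nrow(net$nodes))
  expect_setequal(igraph::vertex_attr(g2, "type"), net$nodes$type)
  expect_equal(sort(igraph::vertex_attr(g2, "count")),
               sort(net$nodes$count))
})
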