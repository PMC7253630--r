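# Shared builders for the test suite. All fixtures are constructed in code.

# two-locus toy panel: one multi-copy (G/A), one single-copy (C/T)
toy_panel <- function() {
  marker_panel(
    locus("9", c("G", "A"), multi_copy = TRUE, cn_ladder = c(1, 2, 5, 10, 20)),
    locus("AMELY", c("C", "T"))
  )
}

# genotype table from a call matrix (rows = samples)
make_genotypes <- function(calls, population = "P1", group = "SC") {
  tab <- data.frame(sample_id = rownames(calls),
                    population = rep_len(population, nrow(calls)),
                    group = rep_len(group, nrow(calls)),
                    stringsAsFactors = FALSE)
  for (j in colnames(calls)) tab[[j]] <- calls[, j]
  tab
}

# qPCR triplicate rows for one sample/locus with given mean delta-Ct
make_triplicate <- function(sample_id, locus_id, cn, sd = 0, ref_mean = 20) {
  data.frame(sample_id = sample_id, locus_id = locus_id, rep = 1:3,
             ct_target = ref_mean - log2(cn / 2) + rnorm(3, 0, sd),
             ct_reference = rnorm(3, ref_mean, sd),
             stringsAsFactors = FALSE)
}

# all partitions of n into exactly k positive non-increasing parts
partitions_k <- function(n, k, max_part = n) {
  if (k == 1L) {
    if (n <= max_part) return(list(n)) else return(list())
  }
  out <- list()
  for (first in seq(min(max_part, n - k + 1L), 1L)) {
    for (rest in partitions_k(n - first, k - 1L, first))
      out[[length(out) + 1L]] <- c(first, rest)
  }
  out
}

# all partitions of n (any number of parts)
partitions_all <- function(n) {
  unlist(lapply(seq_len(n), function(k) partitions_k(n, k)),
         recursive = FALSE)
}

# brute-force unbiased gene diversity: fraction of unequal ordered pairs
h_bruteforce <- function(counts) {
  pop <- rep(seq_along(counts), counts)
  n <- length(pop)
  sum(outer(pop, pop, "!=")) / (n * (n - 1))
}

# independent MST length via igraph, for cross-checks
mst_length_igraph <- function(D) {
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE)
  sum(igraph::E(igraph::mst(g, algorithm = "prim"))$weight)
}

# minimum Steiner-tree length and edge/node union over subsets of medians,
# independent oracle: edge membership tested by forcing the edge into the
# tree (contract it) and comparing lengths, igraph MSTs throughout
steiner_oracle <- function(D, obs, med) {
  subsets <- list(integer(0))
  for (m in med) subsets <- c(subsets, lapply(subsets, c, m))
  lens <- vapply(subsets, function(S) {
    idx <- c(obs, S)
    mst_length_igraph(D[idx, idx, drop = FALSE])
  }, 0)
  Lstar <- min(lens)
  opt <- which(lens <= Lstar + 1e-9)
  minimal <- opt[vapply(opt, function(a) !any(vapply(opt, function(b)
    length(subsets[[b]]) < length(subsets[[a]]) &&
      all(subsets[[b]] %in% subsets[[a]]), TRUE)), TRUE)]
  edges <- character(0); nodes <- integer(0)
  for (a in minimal) {
    idx <- sort(c(obs, subsets[[a]]))
    nodes <- union(nodes, idx)
    Dm <- D[idx, idx, drop = FALSE]
    base <- mst_length_igraph(Dm)
    for (i in seq_len(length(idx) - 1L)) for (j in (i + 1L):length(idx)) {
      # edge is in some MST iff forcing it keeps the total length minimal:
      # contract i-j (set distance 0) and add its weight back
      Dc <- Dm; Dc[i, j] <- Dc[j, i] <- 1e-9
      if (mst_length_igraph(Dc) + Dm[i, j] <= base + 1e-6)
        edges <- union(edges, paste(idx[i], idx[j], sep = "-"))
    }
  }
  list(length = Lstar, edges = sort(edges), nodes = sort(nodes))
}
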