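#' UPGMA dendrogram from a distance matrix
#'
#' Standard unweighted pair-group average-linkage agglomeration; node
#' height is half the merge distance, so leaves are equidistant from the
#' root (ultrametric). Labels are sorted lexicographically before
#' clustering so that ties merge the lexicographically smallest pair —
#' output is a deterministic function of the distances.
#'
#' @param d Symmetric distance matrix with labelled rows/columns (or a
#'   `dist`).
#' @return An `ape` `"phylo"` tree with branch lengths.
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2L) stop("UPGMA needs at least 2 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tr <- ape::as.phylo(stats::hclust(stats::as.dist(d), method = "average"))
  stats::reorder(tr, "cladewise")
}

#' Write a tree in Newick format
#'
#' @param tree A `"phylo"` tree.
#' @param path Output path; the file ends with a newline.
#' @return The Newick string, invisibly.
#' @export
write_newick <- function(tree, path) {
  nwk <- ape::write.tree(tree)
  writeLines(nwk, path)
  invisible(nwk)
}

## ---- internal graph machinery (plain matrices, deterministic) ----

# all unordered pairs i<j with Hamming weights, ordered by (w, i, j)
pair_table <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(data.frame(i = integer(), j = integer(), w = numeric()))
  idx <- which(upper.tri(D), arr.ind = TRUE)
  out <- data.frame(i = idx[, 1L], j = idx[, 2L], w = D[idx])
  out[order(out$w, out$i, out$j), , drop = FALSE]
}

# Kruskal MST length over full distance matrix; deterministic
mst_length <- function(D) {
  pt <- pair_table(D)
  parent <- seq_len(nrow(D))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  total <- 0; used <- 0L
  for (r in seq_len(nrow(pt))) {
    a <- find(pt$i[r]); b <- find(pt$j[r])
    if (a != b) { parent[a] <- b; total <- total + pt$w[r]; used <- used + 1L }
    if (used == nrow(D) - 1L) break
  }
  total
}

# edges present in at least one MST of the complete weighted graph
# (the minimum spanning network): (i,j) with weight w qualifies iff i and
# j are disconnected using only pairs of weight < w. With eps > 0 the
# criterion relaxes to < w - eps, admitting near-minimal alternative links.
min_span_edges <- function(D, eps = 0) {
  pt <- pair_table(D)
  if (!nrow(pt)) return(pt)
  keep <- logical(nrow(pt))
  for (w in unique(pt$w)) {
    sub <- pt[pt$w < w - eps, , drop = FALSE]
    parent <- seq_len(nrow(D))
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    if (nrow(sub)) for (s in seq_len(nrow(sub))) {
      a <- find(sub$i[s]); b <- find(sub$j[s])
      if (a != b) parent[a] <- b
    }
    comp <- vapply(seq_len(nrow(D)), find, 0L)
    rows <- which(pt$w == w)
    keep[rows] <- comp[pt$i[rows]] != comp[pt$j[rows]]
  }
  pt[keep, , drop = FALSE]
}

# quasi-median(s) of three call vectors: site-wise majority where one
# exists, otherwise all distinct states at that site are kept and the
# candidate set expands over their combinations
quasi_medians <- function(u, v, w) {
  opts <- lapply(seq_along(u), function(s) {
    states <- c(u[s], v[s], w[s])
    tab <- table(states)
    if (max(tab) >= 2L) names(tab)[which.max(tab)] else sort(unique(states))
  })
  if (prod(lengths(opts)) > 729) return(matrix(character(), 0, length(u)))
  grid <- expand.grid(opts, stringsAsFactors = FALSE)
  as.matrix(grid)
}

node_key <- function(m) apply(m, 1L, paste, collapse = "\x1f")

#' Median-joining haplotype network
#'
#' Bandelt-Forster-Roehl median joining: (i) build the epsilon-relaxed
#' minimum spanning network over the current node set (epsilon 0, the
#' default, keeps exactly the links lying on some minimum spanning tree);
#' (ii) for every triplet connected by at least two links, compute
#' quasi-medians (site-wise majority where one exists, otherwise all
#' combinations of the tied states); (iii) add, one at a time, the median
#' vector that most reduces the minimum-spanning-tree length, until no
#' candidate reduces it; (iv) drop median vectors that end up with network
#' degree below 2. Median vectors are unsampled haplotypes inferred to
#' shorten the network.
#'
#' @param calls Character matrix of haplotype call vectors (rownames are
#'   haplotype names), e.g. `hs$calls` from [collapse_haplotypes()].
#' @param counts Optional integer carrier counts per haplotype (default 1).
#' @param epsilon Non-negative relaxation of the spanning criterion,
#'   default 0.
#' @param max_medians Safety cap on inferred vectors, default 200.
#' @return Object of class `"haplonet"`: list with `nodes` (`data.frame`:
#'   `id`, `type` observed/median, `count`), `edges` (`data.frame`: `from`,
#'   `to`, `length`, `sites`), and `calls` (matrix over all nodes).
#' @export
mjn <- function(calls, counts = NULL, epsilon = 0, max_medians = 200L) {
  stopifnot(is.matrix(calls), nrow(calls) >= 1L)
  if (is.null(rownames(calls))) rownames(calls) <- paste0("H", seq_len(nrow(calls)))
  if (anyDuplicated(node_key(calls))) stop("duplicate haplotype vectors")
  if (is.null(counts)) counts <- rep(1L, nrow(calls))
  obs_counts <- stats::setNames(as.integer(counts), rownames(calls))
  mat <- calls
  n_med <- 0L
  repeat {
    D <- hamming_matrix(mat)
    E <- min_span_edges(D, epsilon)
    if (nrow(mat) < 3L) break
    # triples with >= 2 of their 3 pairs linked
    adj <- matrix(FALSE, nrow(mat), nrow(mat))
    adj[cbind(E$i, E$j)] <- TRUE; adj <- adj | t(adj)
    keys <- node_key(mat)
    cand <- character()
    combs <- utils::combn(nrow(mat), 3L)
    for (c_i in seq_len(ncol(combs))) {
      tri <- combs[, c_i]
      nlink <- adj[tri[1], tri[2]] + adj[tri[1], tri[3]] + adj[tri[2], tri[3]]
      if (nlink < 2L) next
      qm <- quasi_medians(mat[tri[1], ], mat[tri[2], ], mat[tri[3], ])
      if (nrow(qm)) cand <- c(cand, setdiff(node_key(qm), keys))
    }
    cand <- sort(unique(cand))
    if (!length(cand)) break
    L0 <- mst_length(D)
    best_key <- NULL; best_len <- L0
    for (k in cand) {
      v <- strsplit(k, "\x1f", fixed = TRUE)[[1L]]
      newcol <- vapply(seq_len(nrow(mat)), function(i)
        as.numeric(sum(mat[i, ] != v)), 0)
      dd <- rbind(cbind(D, newcol), 0)
      dd[nrow(dd), ] <- dd[, ncol(dd)]
      L1 <- mst_length(dd)
      if (L1 < best_len - 1e-9) { best_len <- L1; best_key <- k }
    }
    if (is.null(best_key)) break
    n_med <- n_med + 1L
    if (n_med > max_medians) { warning("median cap reached"); break }
    newv <- strsplit(best_key, "\x1f", fixed = TRUE)[[1L]]
    mat <- rbind(mat, newv)
    rownames(mat)[nrow(mat)] <- paste0("mv", n_med)
  }
  # prune medians of degree <= 1 (obsolete), recomputing the network
  repeat {
    D <- hamming_matrix(mat)
    E <- min_span_edges(D, epsilon)
    deg <- tabulate(c(E$i, E$j), nbins = nrow(mat))
    drop <- which(deg <= 1L & !rownames(mat) %in% names(obs_counts))
    if (!length(drop)) break
    mat <- mat[-drop[1L], , drop = FALSE]
  }
  build_haplonet(mat, obs_counts, E)
}

build_haplonet <- function(mat, obs_counts, E) {
  labels <- rownames(mat)
  type <- ifelse(labels %in% names(obs_counts), "observed", "median")
  count <- ifelse(type == "observed", obs_counts[labels], 0L)
  nodes <- data.frame(id = labels, type = type, count = as.integer(count),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  sites <- vapply(seq_len(nrow(E)), function(r) {
    diff <- which(mat[E$i[r], ] != mat[E$j[r], ])
    paste(colnames(mat)[diff], collapse = ",")
  }, "")
  edges <- data.frame(from = labels[E$i], to = labels[E$j],
                      length = E$w, sites = sites, stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, calls = mat),
            class = "haplonet")
}

#' @export
print.haplonet <- function(x, ...) {
  cat(sprintf("haplotype network: %d observed + %d median vectors, %d links (total length %g)\n",
              sum(x$nodes$type == "observed"), sum(x$nodes$type == "median"),
              nrow(x$edges), sum(x$edges$length)))
  invisible(x)
}

#' Maximum-parsimony pruning of a median-joining network
#'
#' Keeps exactly the links and median vectors lying on at least one
#' minimum-length tree spanning the observed haplotypes (a Steiner tree
#' through the admissible median vectors, under full Hamming distances).
#' For networks of at most `exact_max` nodes the optimum is found by
#' enumerating median subsets; subsets that attain the minimum length but
#' contain a removable median (a proper subset attains it too) are
#' discarded, so retained medians have degree >= 3. Larger networks are
#' pruned greedily: medians whose removal leaves the spanning length
#' unchanged are deleted in label order, then links are restricted to the
#' union of minimum spanning trees.
#'
#' @param net A `"haplonet"` from [mjn()].
#' @param exact_max Node-count threshold for exact enumeration, default 12.
#' @return A pruned `"haplonet"`.
#' @export
mp_prune <- function(net, exact_max = 12L) {
  stopifnot(inherits(net, "haplonet"))
  mat <- net$calls
  obs <- which(net$nodes$type == "observed")
  med <- which(net$nodes$type == "median")
  if (length(obs) < 2L) return(net)
  D_all <- hamming_matrix(mat)
  if (nrow(mat) <= exact_max && length(med) <= 20L) {
    subsets <- lapply(0:(2^length(med) - 1L), function(mask)
      med[bitwAnd(mask, bitwShiftL(1L, seq_along(med) - 1L)) != 0L])
    lens <- vapply(subsets, function(S)
      mst_length(D_all[c(obs, S), c(obs, S), drop = FALSE]), 0)
    Lstar <- min(lens)
    optimal <- which(lens <= Lstar + 1e-9)
    # discard non-minimal optimal subsets (they carry removable medians)
    minimal <- optimal[vapply(optimal, function(a) {
      !any(vapply(optimal, function(b)
        length(subsets[[b]]) < length(subsets[[a]]) &&
          all(subsets[[b]] %in% subsets[[a]]), TRUE))
    }, TRUE)]
    keep_nodes <- sort(unique(c(obs, unlist(subsets[minimal]))))
    edge_keys <- character()
    for (a in minimal) {
      idx <- c(obs, subsets[[a]])
      E <- min_span_edges(D_all[idx, idx, drop = FALSE], 0)
      if (nrow(E))
        edge_keys <- c(edge_keys, paste(idx[E$i], idx[E$j], sep = "-"))
    }
    edge_keys <- sort(unique(edge_keys))
    idx <- keep_nodes
    em <- do.call(rbind, strsplit(edge_keys, "-", fixed = TRUE))
    E <- data.frame(i = match(as.integer(em[, 1L]), idx),
                    j = match(as.integer(em[, 2L]), idx))
    E$w <- D_all[cbind(idx[E$i], idx[E$j])]
  } else {
    keep_med <- med
    base_len <- mst_length(D_all[c(obs, keep_med), c(obs, keep_med),
                                 drop = FALSE])
    repeat {
      removed <- FALSE
      for (m in keep_med[order(net$nodes$id[keep_med])]) {
        trial <- setdiff(keep_med, m)
        if (mst_length(D_all[c(obs, trial), c(obs, trial), drop = FALSE]) <=
            base_len + 1e-9) {
          keep_med <- trial; removed <- TRUE; break
        }
      }
      if (!removed) break
    }
    idx <- sort(c(obs, keep_med))
    E <- min_span_edges(D_all[idx, idx, drop = FALSE], 0)
  }
  sub <- mat[idx, , drop = FALSE]
  obs_counts <- stats::setNames(net$nodes$count[obs], net$nodes$id[obs])
  build_haplonet(sub, obs_counts, E)
}

#' Export a haplotype network
#'
#' Writes a deterministic edge-list TSV (`node1`, `node2`, `length`,
#' `sites`) and a GML file with node attributes (`type`, `count`, optional
#' `group`) readable by igraph and standard network viewers.
#'
#' @param net A `"haplonet"`.
#' @param edges_path Path for the edge-list TSV.
#' @param gml_path Optional path for the GML export.
#' @param groups Optional named vector of group labels per observed node.
#' @return Invisibly, the igraph object.
#' @export
export_network <- function(net, edges_path, gml_path = NULL, groups = NULL) {
  stopifnot(inherits(net, "haplonet"))
  utils::write.table(
    data.frame(node1 = net$edges$from, node2 = net$edges$to,
               length = net$edges$length, sites = net$edges$sites),
    edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to")], directed = FALSE,
    vertices = net$nodes[, c("id", "type", "count")])
  igraph::E(g)$length <- net$edges$length
  igraph::E(g)$sites <- net$edges$sites
  if (!is.null(groups))
    igraph::V(g)$group <- ifelse(is.na(groups[net$nodes$id]), "",
                                 groups[net$nodes$id])
  if (!is.null(gml_path)) igraph::write_graph(g, gml_path, format = "gml")
  invisible(g)
}
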