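#' Configuration for the synthetic patriline generator
#'
#' Defines the study conditions the generator emulates: a patrilineal
#' genealogy carrying infinite-sites SNP mutations over a fixed number of
#' segregating sites, stepwise copy-number evolution on a geometric ladder
#' for loci in repeated fragments, asymmetric allele splits where a lineage
#' carries both alleles among its repeats, Gaussian Ct noise on qPCR
#' triplicates, and bounded uniform noise on pyrosequencing allele ratios.
#'
#' @param seed Integer seed; mandatory — every random draw flows from it.
#' @param n_samples Number of stallions, default 96 (the size of the
#'   initially screened discovery panel).
#' @param n_snp_loci Number of segregating sites placed on the genealogy,
#'   default 14; capped by the panel size.
#' @param panel Marker panel, default [horse_y_panel()].
#' @param populations Named character vector population -> group; samples
#'   are assigned populations uniformly.
#' @param p_partial Probability that a mutation at a multi-copy locus hits
#'   only part of the repeats, creating a double-call lineage, default 0.5.
#' @param cn_step_rate Expected stepwise ladder moves per branch per
#'   multi-copy locus, default 0.05.
#' @param root_cn Named integer vector of root copy numbers per multi-copy
#'   locus; defaults mimic the observed medians (loci 165/17/103/9 at 5,
#'   102 at 10, 12 at 2, the rest single-copy).
#' @param ct_noise_sd Ct noise standard deviation in cycles, default 0.1.
#' @param ct_reference_mean Mean reference-channel Ct, default 20.
#' @param rbv_noise_halfwidth Half-width of the uniform RBV noise; default
#'   `NA` means 1/(4 CN), a quarter of the spacing between adjacent splits.
#' @param dropout_rate Per-call probability of a missing genotype, default
#'   0.01.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       n_samples = 96L,
                       n_snp_loci = 14L,
                       panel = horse_y_panel(),
                       populations = c(DB = "SC", YN = "SC", LJ = "SC",
                                       KZK = "NC", IMG = "NC", TB = "IN"),
                       p_partial = 0.5,
                       cn_step_rate = 0.05,
                       root_cn = NULL,
                       ct_noise_sd = 0.1,
                       ct_reference_mean = 20,
                       rbv_noise_halfwidth = NA_real_,
                       dropout_rate = 0.01) {
  if (missing(seed) || !is.finite(seed))
    stop("a seed is mandatory for reproducibility")
  stopifnot(n_samples >= 2L, n_snp_loci >= 1L, p_partial >= 0, p_partial <= 1,
            cn_step_rate >= 0, ct_noise_sd >= 0, dropout_rate >= 0,
            dropout_rate < 1)
  mc <- panel_ids(panel)[vapply(panel, `[[`, TRUE, "multi_copy")]
  if (is.null(root_cn)) {
    root_cn <- stats::setNames(rep(1L, length(mc)), mc)
    preset <- c("165" = 5L, "17" = 5L, "102" = 10L, "103" = 5L, "9" = 5L,
                "12" = 2L)
    hit <- intersect(names(preset), mc)
    root_cn[hit] <- preset[hit]
  }
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 n_snp_loci = min(as.integer(n_snp_loci), length(panel)),
                 panel = panel, populations = populations,
                 p_partial = p_partial, cn_step_rate = cn_step_rate,
                 root_cn = root_cn, ct_noise_sd = ct_noise_sd,
                 ct_reference_mean = ct_reference_mean,
                 rbv_noise_halfwidth = rbv_noise_halfwidth,
                 dropout_rate = dropout_rate),
            class = "sim_config")
}

# step k times from position i on a ladder, reflecting at the ends
ladder_walk <- function(i, k, len) {
  for (s in seq_len(k)) {
    move <- sample(c(-1L, 1L), 1L)
    i <- i + move
    if (i < 1L) i <- 2L
    if (i > len) i <- len - 1L
  }
  i
}

#' Simulate a synthetic patriline dataset with truth
#'
#' Simulates (i) a random bifurcating genealogy; (ii) SNP mutations placed
#' on edges with probability proportional to branch length, one edge per
#' site (infinite sites, so a perfect phylogeny holds); (iii) stepwise
#' copy-number evolution along branches on each multi-copy locus's ladder;
#' (iv) partial mutations at multi-copy loci creating double-call lineages
#' with a true allele split per carrier; (v) qPCR Ct triplicates with
#' Gaussian noise, `ct_target = ct_ref_mean - log2(CN/2) + noise`; (vi)
#' pyrosequencing RBVs `a/CN` plus bounded uniform noise; (vii) genotype
#' dropout. All outputs are deterministic functions of the config seed.
#'
#' @param config A `"sim_config"`.
#' @param dir Optional directory; when given, writes `genotypes.tsv`,
#'   `qpcr.tsv`, `pyro.tsv`, `truth_lines.tsv`, `truth_cn.tsv`.
#' @return List with `genotypes`, `qpcr`, `pyro` data frames and `truth`
#'   (list: `tree`, `haplotype` true class per sample, `cn` matrix,
#'   `split_a` matrix of true first-allele copies at double-call sites,
#'   `lines` true layered line id per sample).
#' @export
simulate_patrilines <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  panel <- config$panel
  ids <- panel_ids(panel)
  n <- config$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))
  pops <- sample(names(config$populations), n, replace = TRUE)
  groups <- unname(config$populations[pops])

  tree <- ape::rtree(n, rooted = TRUE)
  tree$tip.label <- sample_ids
  n_edge <- nrow(tree$edge)
  below <- phangorn::Descendants(tree, tree$edge[, 2L], type = "tips")

  # one mutation edge per SNP site, weighted by branch length
  site_ids <- sample(ids, config$n_snp_loci)
  mut_edge <- sample.int(n_edge, config$n_snp_loci, replace = TRUE,
                         prob = tree$edge.length)
  names(mut_edge) <- site_ids

  # copy-number evolution per multi-copy locus (preorder down the edges)
  mc <- ids[vapply(panel, `[[`, TRUE, "multi_copy")]
  cn <- matrix(NA_integer_, n, length(mc), dimnames = list(sample_ids, mc))
  for (lid in mc) {
    ladder <- panel[[lid]]$cn_ladder
    pos_root <- match(config$root_cn[[lid]], ladder)
    if (is.na(pos_root)) pos_root <- 1L
    pos <- rep(NA_integer_, max(tree$edge))
    root_node <- n + 1L
    pos[root_node] <- pos_root
    ord <- stats::reorder(tree, "cladewise")$edge
    for (e in seq_len(nrow(ord))) {
      k <- stats::rpois(1L, config$cn_step_rate)
      pos[ord[e, 2L]] <- ladder_walk(pos[ord[e, 1L]], k, length(ladder))
    }
    cn[, lid] <- ladder[pos[seq_len(n)]]
  }

  # genotype calls: ancestral allele_set[1]; mutation flips the clade below
  # the mutation edge, fully (single derived call) or partially (double
  # call with a drawn split fraction)
  calls <- matrix(NA_character_, n, length(ids),
                  dimnames = list(sample_ids, ids))
  for (lid in ids) calls[, lid] <- panel[[lid]]$allele_set[1L]
  split_a <- matrix(NA_integer_, n, length(mc),
                    dimnames = list(sample_ids, mc))
  for (lid in site_ids) {
    loc <- panel[[lid]]
    anc <- loc$allele_set[1L]
    der <- if (length(loc$allele_set) > 1L) loc$allele_set[2L] else next
    carriers <- match(tree$tip.label[below[[mut_edge[[lid]]]]], sample_ids)
    partial <- loc$multi_copy && stats::runif(1L) < config$p_partial
    if (!partial) {
      calls[carriers, lid] <- der
    } else {
      f <- stats::runif(1L, 0.2, 0.8)  # derived fraction of the repeats
      for (i in carriers) {
        total <- cn[i, lid]
        if (total < 2L) { calls[i, lid] <- der; next }
        a_der <- max(1L, min(total - 1L, as.integer(round(f * total))))
        calls[i, lid] <- paste(anc, der, sep = "/")
        split_a[i, lid] <- total - a_der  # copies of the first allele
      }
    }
  }

  true_hap <- apply(calls, 1L, paste, collapse = "\x1f")
  cn_string <- apply(cn, 1L, paste, collapse = ",")
  sp_string <- apply(split_a, 1L, function(v)
    paste(ifelse(is.na(v), "?", v), collapse = ","))
  true_line <- paste(true_hap, cn_string, sp_string, sep = "|")

  # qPCR triplicates at every multi-copy locus
  qpcr <- do.call(rbind, lapply(mc, function(lid) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      ct_ref <- stats::rnorm(3L, config$ct_reference_mean, config$ct_noise_sd)
      ct_tar <- config$ct_reference_mean - log2(cn[i, lid] / 2) +
        stats::rnorm(3L, 0, config$ct_noise_sd)
      data.frame(sample_id = sample_ids[i], locus_id = lid, rep = 1:3,
                 ct_target = ct_tar, ct_reference = ct_ref,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(qpcr) <- NULL

  # pyrosequencing RBVs at true double-call sites
  het <- which(!is.na(split_a), arr.ind = TRUE)
  pyro <- if (nrow(het)) {
    do.call(rbind, lapply(seq_len(nrow(het)), function(r) {
      i <- het[r, 1L]; lid <- mc[het[r, 2L]]
      total <- cn[i, lid]
      hw <- config$rbv_noise_halfwidth
      if (is.na(hw)) hw <- 1 / (4 * total)
      rbv <- split_a[i, lid] / total + stats::runif(1L, -hw, hw)
      data.frame(sample_id = sample_ids[i], locus_id = lid,
                 rbv = min(max(rbv, 0.01), 0.99), stringsAsFactors = FALSE)
    }))
  } else data.frame(sample_id = character(), locus_id = character(),
                    rbv = numeric())
  pyro <- pyro[order(pyro$sample_id, pyro$locus_id), , drop = FALSE]
  rownames(pyro) <- NULL

  # dropout applied last, to the emitted genotype table only
  emitted <- calls
  if (config$dropout_rate > 0) {
    miss <- stats::runif(length(emitted)) < config$dropout_rate
    emitted[miss] <- NA_character_
  }
  genotypes <- data.frame(sample_id = sample_ids, population = pops,
                          group = groups, stringsAsFactors = FALSE)
  for (lid in ids) genotypes[[lid]] <- emitted[, lid]
  attr(genotypes, "panel") <- panel
  class(genotypes) <- c("genotype_table", "data.frame")

  truth <- list(tree = tree, haplotype = stats::setNames(true_hap, sample_ids),
                cn = cn, split_a = split_a,
                lines = stats::setNames(true_line, sample_ids),
                mutated_sites = site_ids)
  res <- list(genotypes = genotypes, qpcr = qpcr, pyro = pyro, truth = truth,
              config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    prov <- sprintf("patrilineR simulate seed=%d n=%d", config$seed, n)
    write_genotype_table(genotypes, file.path(dir, "genotypes.tsv"), prov)
    write_tsv_prov(qpcr, file.path(dir, "qpcr.tsv"), prov)
    write_tsv_prov(pyro, file.path(dir, "pyro.tsv"), prov)
    truth_lines <- data.frame(sample_id = sample_ids, line = true_line,
                              haplotype = true_hap)
    write_tsv_prov(truth_lines, file.path(dir, "truth_lines.tsv"), prov)
    write_tsv_prov(data.frame(sample_id = sample_ids, cn),
                   file.path(dir, "truth_cn.tsv"), prov)
  }
  res
}

write_tsv_prov <- function(d, path, provenance = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reference fixtures from the published summary tables
#'
#' Small in-memory datasets used for validation:
#' \describe{
#'   \item{table1_spectra}{Per-population haplotype frequency spectra.
#'     These are *derived* fixtures: each is the unique integer partition
#'     of the published sample size, with the published haplotype count,
#'     that reproduces the published haplotype diversity and its standard
#'     error under Nei's unbiased estimator.}
#'   \item{table4_patterns}{Published AS-CNV combination patterns (`"a:b"`)
#'     per double-call locus, with the assayed base-variant pair.}
#'   \item{amely_counts}{AMELY intron-2 allele counts among successfully
#'     genotyped indigenous samples: 9 C-carriers, 225 T-carriers.}
#' }
#'
#' @param name One of `"table1_spectra"`, `"table4_patterns"`,
#'   `"amely_counts"`.
#' @return The fixture object.
#' @export
table_fixture <- function(name = c("table1_spectra", "table4_patterns",
                                   "amely_counts")) {
  name <- match.arg(name)
  switch(name,
    table1_spectra = list(
      YQ = c(8L),
      IMG = c(6L, 1L),
      KZK = c(8L, 4L),
      YN = c(2L, 1L, 1L, 1L, 1L, 1L, 1L),
      `GZ-JC` = c(3L, 3L, 3L, 2L, 1L, 1L)),
    table4_patterns = list(
      `165` = list(alleles = c("G", "A"), patterns = "4:1"),
      `103` = list(alleles = c("C", "A"), patterns = "4:1"),
      `1`   = list(alleles = c("A", "G"), patterns = "1:1"),
      `17`  = list(alleles = c("G", "A"),
                   patterns = c("1:1", "1:4", "2:1", "2:3", "3:2", "4:1")),
      `9`   = list(alleles = c("G", "A"),
                   patterns = c("1:1", "1:2", "1:4", "2:1", "2:3", "3:2")),
      `102` = list(alleles = c("G", "T"),
                   patterns = c("3:2", "4:1", "7:3"))),
    amely_counts = c(C = 9L, T = 225L))
}
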