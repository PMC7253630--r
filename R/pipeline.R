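#' Run the full three-layer patriline pipeline
#'
#' End-to-end orchestration in dependency order: read and validate the
#' three input tables, collapse SNP haplotypes, compute per-population
#' diversity, call integer copy numbers, summarise CNVs per group, resolve
#' allele-specific splits and their pattern census, refine the layered
#' lines, and build the UPGMA dendrogram and the MP-pruned median-joining
#' network. When `outdir` is given, every output file carries a provenance
#' header (package version and parameters) as leading `#` lines.
#'
#' @param genotypes Genotype table path or `"genotype_table"` data frame.
#' @param qpcr qPCR table path or data frame (NULL skips layers 2-3).
#' @param pyro Pyro table path or data frame (NULL skips layer 3).
#' @param panel A `"ypanel"`.
#' @param L Sites analysed for the per-site nucleotide diversity scaling,
#'   default 53000 (the approximate screened male-specific length).
#' @param weights Layer weights for the joint layered tree.
#' @param outdir Optional output directory.
#' @return List with `haploset`, `diversity`, `cn_calls`, `cn_summary`,
#'   `cn_polymorphism`, `splits`, `census`, `lines`, `upgma_haplotypes`,
#'   `upgma_layered`, `network` (MP-pruned), `network_raw`.
#' @export
run_pipeline <- function(genotypes, qpcr = NULL, pyro = NULL,
                         panel = horse_y_panel(), L = 53000,
                         weights = c(snp = 1, cnv = 1, ascnv = 1),
                         outdir = NULL) {
  tab <- if (is.character(genotypes)) read_genotype_table(genotypes, panel)
         else genotypes
  hs <- collapse_haplotypes(tab, panel)
  div <- diversity_table(hs, L = L)
  groups <- stats::setNames(tab$group, tab$sample_id)

  cn_calls <- cn_sum <- cn_poly <- splits <- census <- NULL
  if (!is.null(qpcr)) {
    q <- if (is.character(qpcr)) read_qpcr_table(qpcr) else qpcr
    cn_calls <- call_copy_number(q, panel)
    cn_sum <- cn_summary(cn_calls, groups)
    cn_poly <- cnv_polymorphism_table(cn_calls, groups)
    if (!is.null(pyro)) {
      p <- if (is.character(pyro)) read_pyro_table(pyro) else pyro
      splits <- resolve_splits(p, cn_calls, panel)
      census <- pattern_census(splits)
    }
  }
  lines <- if (!is.null(cn_calls))
    refine(hs, cn_calls, splits, panel) else NULL

  tree_h <- if (nrow(hs$calls) >= 2L) upgma(hamming_matrix(hs$calls)) else NULL
  tree_l <- if (!is.null(lines) && nrow(lines) >= 2L)
    upgma(layered_distance_matrix(hs, lines, weights)) else NULL
  net_raw <- if (nrow(hs$calls) >= 2L)
    mjn(hs$calls, counts = hs$haplotypes$count) else NULL
  net <- if (!is.null(net_raw)) mp_prune(net_raw) else NULL

  res <- list(haploset = hs, diversity = div, cn_calls = cn_calls,
              cn_summary = cn_sum, cn_polymorphism = cn_poly,
              splits = splits, census = census, lines = lines,
              upgma_haplotypes = tree_h, upgma_layered = tree_l,
              network = net, network_raw = net_raw)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir, groups)
  res
}

write_pipeline_outputs <- function(res, outdir, groups) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- sprintf("patrilineR %s pipeline",
                  as.character(utils::packageVersion("patrilineR")))
  hs <- res$haploset
  write_tsv_prov(cbind(hs$haplotypes,
                       as.data.frame(hs$calls)[hs$haplotypes$name, ,
                                               drop = FALSE]),
                 file.path(outdir, "haplotypes.tsv"), prov)
  write_tsv_prov(res$diversity, file.path(outdir, "diversity.tsv"), prov)
  if (!is.null(res$cn_calls))
    write_tsv_prov(res$cn_calls, file.path(outdir, "cn_calls.tsv"), prov)
  if (!is.null(res$cn_summary))
    write_tsv_prov(res$cn_summary, file.path(outdir, "cn_summary.tsv"), prov)
  if (!is.null(res$cn_polymorphism))
    write_tsv_prov(res$cn_polymorphism,
                   file.path(outdir, "cn_polymorphism.tsv"), prov)
  if (!is.null(res$splits))
    write_tsv_prov(res$splits, file.path(outdir, "ascnv_splits.tsv"), prov)
  if (!is.null(res$lines))
    write_tsv_prov(as.data.frame(res$lines),
                   file.path(outdir, "layered_lines.tsv"), prov)
  if (!is.null(res$upgma_haplotypes))
    write_newick(res$upgma_haplotypes,
                 file.path(outdir, "upgma_haplotypes.nwk"))
  if (!is.null(res$upgma_layered))
    write_newick(res$upgma_layered, file.path(outdir, "upgma_layered.nwk"))
  if (!is.null(res$network)) {
    export_network(res$network, file.path(outdir, "network_edges.tsv"),
                   file.path(outdir, "network.gml"))
    to_fasta(hs, file.path(outdir, "haplotypes.fasta"))
  }
  invisible(outdir)
}
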