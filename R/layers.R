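#' Refine SNP haplotypes with CNV and AS-CNV layers
#'
#' Hierarchical patriline refinement: samples sharing a layer-1 SNP
#' haplotype are split into distinct paternal lines when their integer
#' copy-number vectors (layer 2) differ, and further when their
#' allele-specific splits (layer 3) differ — e.g. `G3A2` vs `G2A3` carriers
#' with the same heterozygous genotype and the same total copy number are
#' different lines. Unknown layer entries (withheld CN calls, unresolved
#' splits) never split a group: a sample with unknowns is merged into the
#' unique known-layer line compatible with it, and keeps a `?`-marked name
#' of its own only when zero or several lines are compatible.
#'
#' @param hs A `"haploset"` (layer 1).
#' @param cn_calls `"cn_calls"` data frame (layer 2); retest/ambiguous rows
#'   count as unknown.
#' @param splits Output of [resolve_splits()] (layer 3); ambiguous rows
#'   count as unknown.
#' @param panel A `"ypanel"`; panel order canonicalises the name strings.
#' @return `data.frame` of class `"layered_lines"`: `sample_id`,
#'   `base_name`, `cn_string`, `split_string`, `full_name`, plus attributes
#'   `cn_matrix` and `split_matrix` (per-sample layer values, `NA` =
#'   unknown).
#' @export
refine <- function(hs, cn_calls, splits, panel = hs$panel) {
  stopifnot(inherits(hs, "haploset"))
  samples <- names(hs$assignment)
  mc <- panel_ids(panel)[vapply(panel, `[[`, TRUE, "multi_copy")]
  cn_mat <- matrix(NA_integer_, length(samples), length(mc),
                   dimnames = list(samples, mc))
  ok <- cn_calls$qc_flag == "pass" & !is.na(cn_calls$cn_integer) &
    !cn_calls$ambiguous & cn_calls$sample_id %in% samples &
    cn_calls$locus_id %in% mc
  cn_mat[cbind(cn_calls$sample_id[ok], cn_calls$locus_id[ok])] <-
    cn_calls$cn_integer[ok]
  # split layer: "-" where not applicable (single-base call at the locus),
  # NA where a double call's split is unknown/unresolved
  call_mat <- hs$calls[hs$assignment[samples], mc, drop = FALSE]
  rownames(call_mat) <- samples
  split_mat <- matrix(ifelse(grepl("/", call_mat, fixed = TRUE),
                             NA_character_, "-"),
                      length(samples), length(mc),
                      dimnames = list(samples, mc))
  if (!is.null(splits) && nrow(splits)) {
    sok <- !is.na(splits$label) & !splits$ambiguous &
      splits$sample_id %in% samples & splits$locus_id %in% mc
    for (i in which(sok)) {
      sid <- splits$sample_id[i]; lid <- splits$locus_id[i]
      # a split is only meaningful at this sample's double-call sites,
      # and must be consistent with the layer-2 total
      call <- hs$calls[hs$assignment[sid], lid]
      if (!grepl("/", call, fixed = TRUE)) next
      total <- splits$a_copies[i] + splits$b_copies[i]
      if (!is.na(cn_mat[sid, lid]) && total != cn_mat[sid, lid])
        stop("split ", splits$label[i], " inconsistent with copy number ",
             cn_mat[sid, lid], " for sample ", sid, " at locus ", lid)
      split_mat[sid, lid] <- splits$label[i]
    }
  }
  layer_string <- function(v)
    paste(paste0(colnames(cn_mat), "=",
                 ifelse(is.na(v), "?", as.character(v))), collapse = ",")
  base <- unname(hs$assignment)
  cn_str <- apply(cn_mat, 1L, layer_string)
  sp_str <- apply(split_mat, 1L, layer_string)

  # merge unknown-bearing profiles into the unique compatible known line
  profile <- data.frame(sample_id = samples, base_name = base,
                        stringsAsFactors = FALSE)
  key <- paste(base, cn_str, sp_str, sep = "|")
  compatible <- function(j, i) {
    if (base[i] != base[j]) return(FALSE)
    cn_ok <- cn_mat[i, ] == cn_mat[j, ]
    sp_ok <- split_mat[i, ] == split_mat[j, ]
    all(cn_ok | is.na(cn_ok)) && all(sp_ok | is.na(sp_ok))
  }
  has_unknown <- apply(cn_mat, 1L, anyNA) | apply(split_mat, 1L, anyNA)
  complete_keys <- unique(key[!has_unknown])
  for (i in which(has_unknown)) {
    cands <- unique(key[!has_unknown][vapply(which(!has_unknown),
                                             compatible, TRUE, i = i)])
    if (length(cands) == 1L) key[i] <- cands
  }
  profile$cn_string <- cn_str
  profile$split_string <- sp_str
  profile$full_name <- key
  attr(profile, "cn_matrix") <- cn_mat
  attr(profile, "split_matrix") <- split_mat
  attr(profile, "panel") <- panel
  class(profile) <- c("layered_lines", "data.frame")
  profile
}

#' Layered distance between two refined patriline profiles
#'
#' Weighted sum of a SNP Hamming term, a multiplicative copy-number term
#' \eqn{\sum |\log_2 CN_x - \log_2 CN_y|} (copy-number evolution is
#' multiplicative: the observed ladder is geometric), and a count of
#' allele-split label mismatches. Loci unknown in either profile contribute
#' zero (agnostic, never infinite): the study only resolved AS-CNVs for a
#' subset of carriers.
#'
#' @param snp_x,snp_y Character call vectors over a common panel.
#' @param cn_x,cn_y Integer CN vectors over common multi-copy loci (`NA` =
#'   unknown).
#' @param split_x,split_y Character split-label vectors (`NA` = unknown).
#' @param weights Numeric `c(snp, cnv, ascnv)`, defaults `c(1, 1, 1)`; at
#'   least one must be positive.
#' @return Non-negative number; zero iff the profiles agree on all
#'   jointly-known layers.
#' @export
layered_distance <- function(snp_x, snp_y, cn_x, cn_y, split_x, split_y,
                             weights = c(snp = 1, cnv = 1, ascnv = 1)) {
  if (all(weights <= 0)) stop("at least one layer weight must be positive")
  d_snp <- sum(snp_x != snp_y)
  both <- !is.na(cn_x) & !is.na(cn_y)
  d_cnv <- sum(abs(log2(cn_x[both]) - log2(cn_y[both])))
  bothp <- !is.na(split_x) & !is.na(split_y)
  d_asc <- sum(split_x[bothp] != split_y[bothp])
  unname(weights[1L] * d_snp + weights[2L] * d_cnv + weights[3L] * d_asc)
}

#' Layered distance matrix over samples
#'
#' @param hs A `"haploset"`.
#' @param lines A `"layered_lines"` data frame from [refine()].
#' @param weights Layer weights, see [layered_distance()].
#' @return Symmetric matrix over the included samples.
#' @export
layered_distance_matrix <- function(hs, lines,
                                    weights = c(snp = 1, cnv = 1, ascnv = 1)) {
  samples <- lines$sample_id
  snp <- hs$calls[hs$assignment[samples], , drop = FALSE]
  rownames(snp) <- samples
  cn <- attr(lines, "cn_matrix")
  sp <- attr(lines, "split_matrix")
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- layered_distance(
      snp[i, ], snp[j, ], cn[i, ], cn[j, ], sp[i, ], sp[j, ], weights)
  }
  d
}
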