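#' Collapse genotyped samples into Y haplotypes
#'
#' A haplotype is a distinct multi-locus vector of call strings over the
#' panel. Samples with any missing panel call are excluded (and reported in
#' the result), matching the practice of computing haplotypes from
#' successfully genotyped samples only. Names are assigned in descending
#' carrier frequency, ties broken lexicographically by call vector, so that
#' naming is a deterministic function of the data.
#'
#' @param tab A genotype table (see [read_genotype_table()]).
#' @param panel A `"ypanel"`; defaults to the table's attached panel.
#' @param prefix Name prefix, default `"SHT"`.
#' @return An object of class `"haploset"`: a list with
#'   \describe{
#'     \item{haplotypes}{`data.frame` of `name`, `count`}
#'     \item{calls}{character matrix, one row per haplotype (rownames are
#'       haplotype names), one column per panel locus}
#'     \item{assignment}{named character vector mapping included sample ids
#'       to haplotype names}
#'     \item{samples}{`data.frame` of `sample_id`, `population`, `group`,
#'       `haplotype` for included samples}
#'     \item{excluded}{character vector of excluded sample ids}
#'   }
#' @export
collapse_haplotypes <- function(tab, panel = attr(tab, "panel"),
                                prefix = "SHT") {
  if (is.null(panel)) stop("no panel supplied or attached to the table")
  ids <- intersect(panel_ids(panel), names(tab))
  if (!length(ids)) stop("genotype table has no panel locus columns")
  calls <- as.matrix(as.data.frame(tab)[, ids, drop = FALSE])
  rownames(calls) <- tab$sample_id
  complete <- stats::complete.cases(calls)
  excluded <- tab$sample_id[!complete]
  if (length(excluded))
    message("excluding ", length(excluded),
            " sample(s) with missing panel calls: ",
            paste(excluded, collapse = ", "))
  calls <- calls[complete, , drop = FALSE]
  if (!nrow(calls)) {
    warning("no samples with complete panel calls")
    return(structure(list(
      haplotypes = data.frame(name = character(), count = integer()),
      calls = calls, assignment = character(),
      samples = data.frame(sample_id = character(), population = character(),
                           group = character(), haplotype = character()),
      excluded = excluded, panel = panel), class = "haploset"))
  }
  key <- apply(calls, 1L, paste, collapse = "\x1f")
  counts <- table(key)
  ord <- order(-as.integer(counts), names(counts))
  keys <- names(counts)[ord]
  nm <- paste0(prefix, seq_along(keys))
  names(nm) <- keys
  assignment <- nm[key]
  names(assignment) <- rownames(calls)
  hap_calls <- do.call(rbind, strsplit(keys, "\x1f", fixed = TRUE))
  dimnames(hap_calls) <- list(unname(nm), ids)
  samples <- data.frame(sample_id = rownames(calls),
                        population = tab$population[complete],
                        group = tab$group[complete],
                        haplotype = unname(assignment),
                        stringsAsFactors = FALSE)
  structure(list(
    haplotypes = data.frame(name = unname(nm),
                            count = as.integer(counts)[ord]),
    calls = hap_calls, assignment = assignment, samples = samples,
    excluded = excluded, panel = panel), class = "haploset")
}

#' @export
print.haploset <- function(x, ...) {
  cat(sprintf("%d Y haplotypes from %d samples (%d excluded)\n",
              nrow(x$haplotypes), length(x$assignment), length(x$excluded)))
  print(utils::head(x$haplotypes, 10L))
  invisible(x)
}

#' Export haplotype pseudo-sequences as FASTA
#'
#' Concatenates each haplotype's site characters in panel order; double base
#' calls are emitted as IUPAC ambiguity codes (G/A -> R, G/T -> K, C/A -> M,
#' C/T -> Y, C/G -> S, A/T -> W), giving pseudo-sequences usable by external
#' alignment or network tools.
#'
#' @param hs A `"haploset"`.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
to_fasta <- function(hs, path) {
  stopifnot(inherits(hs, "haploset"))
  if (!nrow(hs$calls)) stop("no haplotypes to export")
  seqs <- apply(hs$calls, 1L, function(v) {
    paste(vapply(v, function(call) {
      bases <- strsplit(call, "/", fixed = TRUE)[[1L]]
      if (length(bases) == 2L) iupac_code(bases[1L], bases[2L]) else bases
    }, ""), collapse = "")
  })
  xs <- Biostrings::DNAStringSet(seqs)
  names(xs) <- rownames(hs$calls)
  Biostrings::writeXStringSet(xs, filepath = path)
  invisible(path)
}
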