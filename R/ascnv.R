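#' Enumerate admissible allele splits of a total copy number
#'
#' A double base call on the haploid Y means divergent repeat copies carry
#' two different bases, so a heterozygous multi-copy site with total copy
#' number N admits the splits (a, b) with a + b = N and a, b >= 1 — each
#' allele must occupy at least one copy.
#'
#' @param total_cn Integer total copy number, >= 2.
#' @return Two-column integer matrix of `(a, b)` pairs in descending `a`;
#'   `total_cn - 1` rows.
#' @export
enumerate_splits <- function(total_cn) {
  total_cn <- as.integer(total_cn)
  if (is.na(total_cn) || total_cn < 2L)
    stop("a heterozygous site needs total_cn >= 2 (one copy of each allele)")
  a <- (total_cn - 1L):1L
  cbind(a = a, b = total_cn - a)
}

#' Resolve an allele-specific copy-number split from a pyrosequencing ratio
#'
#' The ratio of base variants (RBV) is the fractional pyrosequencing signal
#' of the locus's first allele; the integer split (a, b) is the admissible
#' pair minimising `|a/total_cn - rbv|`. If the runner-up candidate is
#' within `tolerance` of the best in that objective, the call is flagged
#' ambiguous and both candidates are reported. The label concatenates
#' allele and copy count, e.g. `"G3A2"` for 3 G-copies + 2 A-copies.
#'
#' @param total_cn Integer total copy number at the locus for this sample.
#' @param rbv Signal fraction of the first allele, strictly in (0, 1).
#' @param alleles Character(2): first and second allele.
#' @param tolerance Objective-gap threshold for the ambiguity flag,
#'   default 0.02 (pyrosequencing allele quantification is accurate to a
#'   few percent).
#' @return List of class `"allele_split"`: `a_copies`, `b_copies`, `label`,
#'   `pattern` (`"a:b"`), `ambiguous`, `candidates` (matrix of tied/near
#'   pairs).
#' @export
resolve_split <- function(total_cn, rbv, alleles = c("A", "B"),
                          tolerance = 0.02) {
  if (!is.finite(rbv) || rbv <= 0 || rbv >= 1)
    stop("rbv must lie strictly in (0, 1)")
  splits <- enumerate_splits(total_cn)
  obj <- abs(splits[, "a"] / total_cn - rbv)
  ord <- order(obj, -splits[, "a"])
  best <- ord[1L]
  ambiguous <- length(ord) > 1L && obj[ord[2L]] - obj[best] <= tolerance
  # exact ties resolve to the larger a (reported first), both kept
  cand <- if (ambiguous) splits[ord[1:2], , drop = FALSE]
          else splits[best, , drop = FALSE]
  a <- splits[best, "a"]; b <- splits[best, "b"]
  structure(list(
    a_copies = unname(a), b_copies = unname(b),
    allele_a = alleles[1L], allele_b = alleles[2L],
    label = paste0(alleles[1L], a, alleles[2L], b),
    pattern = paste0(a, ":", b),
    ambiguous = ambiguous, candidates = cand), class = "allele_split")
}

#' @export
print.allele_split <- function(x, ...) {
  cat(sprintf("AS-CNV split %s (%s)%s\n", x$label, x$pattern,
              if (x$ambiguous) " [ambiguous]" else ""))
  invisible(x)
}

#' Read a pyrosequencing RBV table
#'
#' TSV with columns `sample_id`, `locus_id`, `rbv`; `#` lines skipped.
#'
#' @param path TSV path.
#' @return `data.frame` with those columns.
#' @export
read_pyro_table <- function(path) {
  if (!file.exists(path)) stop("pyro table not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           check.names = FALSE, quote = "",
                           colClasses = c(sample_id = "character",
                                          locus_id = "character"))
  need <- c("sample_id", "locus_id", "rbv")
  if (!all(need %in% names(tab)))
    stop("pyro table must have columns ", paste(need, collapse = ", "))
  tab
}

#' Resolve allele splits for a whole pyrosequencing table
#'
#' Joins each RBV measurement with the sample's integer copy-number call at
#' the same locus and resolves the split. Samples whose copy-number call is
#' withheld (retest) or missing block AS-CNV resolution and are returned
#' with `NA` fields.
#'
#' @param pyro Pyro `data.frame` (see [read_pyro_table()]).
#' @param cn_calls `"cn_calls"` data frame from [call_copy_number()].
#' @param panel A `"ypanel"` supplying allele order per locus.
#' @param tolerance Passed to [resolve_split()].
#' @return `data.frame`: `sample_id`, `locus_id`, `total_cn`, `rbv`,
#'   `a_copies`, `b_copies`, `label`, `pattern`, `ambiguous`.
#' @export
resolve_splits <- function(pyro, cn_calls, panel = horse_y_panel(),
                           tolerance = 0.02) {
  if (!nrow(pyro))
    return(data.frame(sample_id = character(), locus_id = character(),
                      total_cn = integer(), rbv = numeric(),
                      a_copies = integer(), b_copies = integer(),
                      label = character(), pattern = character(),
                      ambiguous = logical()))
  cn_key <- paste(cn_calls$sample_id, cn_calls$locus_id, sep = "\x1f")
  rows <- lapply(seq_len(nrow(pyro)), function(i) {
    sid <- pyro$sample_id[i]; lid <- pyro$locus_id[i]
    loc <- panel[[lid]]
    if (is.null(loc) || !loc$multi_copy)
      stop("pyro measurement at non-multi-copy locus ", lid)
    j <- match(paste(sid, lid, sep = "\x1f"), cn_key)
    cn <- if (is.na(j)) NA_integer_ else cn_calls$cn_integer[j]
    base <- data.frame(sample_id = sid, locus_id = lid, total_cn = cn,
                       rbv = pyro$rbv[i], stringsAsFactors = FALSE)
    if (is.na(cn) || cn < 2L)
      return(cbind(base, a_copies = NA_integer_, b_copies = NA_integer_,
                   label = NA_character_, pattern = NA_character_,
                   ambiguous = NA))
    s <- resolve_split(cn, pyro$rbv[i], loc$allele_set, tolerance)
    cbind(base, a_copies = s$a_copies, b_copies = s$b_copies,
          label = s$label, pattern = s$pattern, ambiguous = s$ambiguous)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Census of AS-CNV combination patterns per locus
#'
#' Distinct `"a:b"` patterns per locus among unambiguously resolved splits.
#' Patterns are keyed by allele order as given in the locus allele set, so
#' `"3:2"` and `"2:3"` are distinct patterns (the two orientations are
#' different paternal lines).
#'
#' @param splits Output of [resolve_splits()] (or any data frame with
#'   `locus_id`, `pattern`, `ambiguous`).
#' @return Named list: locus_id -> sorted character vector of patterns.
#' @export
pattern_census <- function(splits) {
  if (is.null(splits) || !nrow(splits))
    return(structure(list(), names = character()))
  ok <- !is.na(splits$pattern) & !is.na(splits$ambiguous) & !splits$ambiguous
  d <- splits[ok, , drop = FALSE]
  if (!nrow(d)) return(structure(list(), names = character()))
  lapply(split(d$pattern, d$locus_id), function(p) {
    u <- unique(p)
    u[order(as.integer(sub(":.*", "", u)), as.integer(sub(".*:", "", u)))]
  })
}
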