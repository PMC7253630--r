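#' Define a male-specific Y-chromosome marker locus
#'
#' A locus is a single assayed site on the male-specific region of the Y
#' chromosome. Loci residing in repeated fragments (`multi_copy = TRUE`) can
#' show "double base calls" — an apparent heterozygote on the haploid Y,
#' caused by divergent repeat copies carrying different bases — and carry an
#' integer copy number drawn from an admissible ladder.
#'
#' @param locus_id Short identifier, e.g. `"9"`, `"17"`, `"AMELY"`.
#' @param allele_set Character vector of 1 or 2 single-base alleles, in a
#'   fixed reference order. For multi-copy loci the first allele is the one
#'   whose pyrosequencing signal fraction is reported as the RBV.
#' @param multi_copy Logical; `TRUE` if the locus lies on repeated fragments
#'   and may legally show double base calls.
#' @param cn_ladder Strictly increasing integer vector of admissible copy
#'   numbers (default `1:20`; single-copy loci are fixed at 1).
#' @return An object of class `"ylocus"`.
#' @examples
#' locus("9", c("G", "A"), multi_copy = TRUE, cn_ladder = c(1, 2, 5, 10, 20))
#' @export
locus <- function(locus_id, allele_set, multi_copy = FALSE,
                  cn_ladder = if (multi_copy) 1:20 else 1L) {
  stopifnot(is.character(locus_id), length(locus_id) == 1L, nzchar(locus_id))
  allele_set <- as.character(allele_set)
  if (length(allele_set) < 1L || length(allele_set) > 2L)
    stop("allele_set must have 1 or 2 entries at a biallelic site, locus ",
         locus_id)
  if (anyDuplicated(allele_set))
    stop("duplicate alleles at locus ", locus_id)
  cn_ladder <- as.integer(cn_ladder)
  if (length(cn_ladder) < 1L || any(cn_ladder < 1L) ||
      is.unsorted(cn_ladder, strictly = TRUE))
    stop("cn_ladder must be strictly increasing with minimum >= 1, locus ",
         locus_id)
  structure(list(locus_id = locus_id, allele_set = allele_set,
                 multi_copy = isTRUE(multi_copy), cn_ladder = cn_ladder),
            class = "ylocus")
}

#' @export
print.ylocus <- function(x, ...) {
  cat(sprintf("Y locus %s [%s]%s, CN ladder %s\n", x$locus_id,
              paste(x$allele_set, collapse = "/"),
              if (x$multi_copy) " multi-copy" else "",
              paste(x$cn_ladder, collapse = ",")))
  invisible(x)
}

#' Assemble a marker panel from loci
#'
#' @param ... `"ylocus"` objects (or a single list of them).
#' @return Named list of loci, class `"ypanel"`; names are locus ids and fix
#'   the site order used for haplotype call vectors, pseudo-sequences and
#'   canonical layered names.
#' @export
marker_panel <- function(...) {
  loci <- list(...)
  if (length(loci) == 1L && !inherits(loci[[1L]], "ylocus")) loci <- loci[[1L]]
  if (!length(loci) || !all(vapply(loci, inherits, TRUE, "ylocus")))
    stop("marker_panel() takes ylocus objects")
  ids <- vapply(loci, `[[`, "", "locus_id")
  if (anyDuplicated(ids)) stop("duplicate locus ids in panel")
  names(loci) <- ids
  class(loci) <- "ypanel"
  loci
}

#' @export
print.ypanel <- function(x, ...) {
  cat(sprintf("Y marker panel: %d loci (%d multi-copy)\n", length(x),
              sum(vapply(x, `[[`, TRUE, "multi_copy"))))
  invisible(x)
}

#' Default 14-site horse Y-chromosome panel
#'
#' The screened panel: 11 loci on repeated fragments (admitting copy-number
#' variation and double base calls) plus three single-copy sites including
#' the AMELY intron-2 C/T polymorphism that anchors the most ancient
#' haplogroup (C is the ancestral, Przewalski-like state). Allele pairs at
#' the six double-call loci follow the assayed base variants
#' (165 G:A, 103 C:A, 1 A:G, 17 G:A, 9 G:A, 102 G:T); at each the first
#' allele is the RBV-reported one. Multi-copy loci use the geometric copy
#' ladder 1,2,5,10,20 observed across populations.
#'
#' @return A `"ypanel"` of 14 loci.
#' @export
horse_y_panel <- function() {
  geo <- c(1L, 2L, 5L, 10L, 20L)
  marker_panel(
    locus("165", c("G", "A"), multi_copy = TRUE, cn_ladder = geo),
    locus("17",  c("G", "A"), multi_copy = TRUE, cn_ladder = geo),
    locus("102", c("G", "T"), multi_copy = TRUE, cn_ladder = geo),
    locus("103", c("C", "A"), multi_copy = TRUE, cn_ladder = geo),
    locus("9",   c("G", "A"), multi_copy = TRUE, cn_ladder = geo),
    locus("14",  c("C", "T"), multi_copy = TRUE, cn_ladder = geo),
    locus("1",   c("A", "G"), multi_copy = TRUE, cn_ladder = geo),
    locus("12",  c("T", "C"), multi_copy = TRUE, cn_ladder = geo),
    locus("132", c("A", "C"), multi_copy = TRUE, cn_ladder = geo),
    locus("133", c("G", "C"), multi_copy = TRUE, cn_ladder = geo),
    locus("4",   c("T", "G"), multi_copy = TRUE, cn_ladder = geo),
    locus("AMELY", c("C", "T")),
    locus("Y288",  c("A", "T")),
    locus("Y997",  c("C", "G"))
  )
}

panel_ids <- function(panel) vapply(panel, `[[`, "", "locus_id")

# IUPAC ambiguity code for an unordered base pair
iupac_code <- function(a, b) {
  key <- paste(sort(c(a, b)), collapse = "")
  code <- c(AG = "R", CT = "Y", GT = "K", AC = "M", CG = "S", AT = "W")[key]
  if (is.na(code)) stop("no IUPAC code for base pair ", a, "/", b)
  unname(code)
}
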