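#' @section Call strings:
#' A call is a single base (`"G"`), a double base call (`"G/A"`, only legal
#' at multi-copy loci), or missing (`"."`). Double calls are treated as
#' atomic third states of a site throughout: `"G"`, `"A"` and `"G/A"` are
#' three distinct haplotype states, mirroring how MassARRAY genotypes on the
#' haploid Y distinguish them.
#' @name call-strings
#' @keywords internal
NULL

MISSING_CALL <- "."

# Validate one call string against its locus; returns the canonical call
# (double calls reordered to allele_set order) or stops with sample context.
validate_call <- function(call, loc, sample_id = "?") {
  if (is.na(call) || call == MISSING_CALL) return(NA_character_)
  bases <- strsplit(call, "/", fixed = TRUE)[[1L]]
  if (any(!nzchar(bases)) || length(bases) > 2L)
    stop("malformed call '", call, "' for sample ", sample_id,
         " at locus ", loc$locus_id)
  if (!all(bases %in% loc$allele_set))
    stop("call '", call, "' for sample ", sample_id, " at locus ",
         loc$locus_id, " uses bases outside the allele set {",
         paste(loc$allele_set, collapse = ","), "}")
  if (length(bases) == 2L) {
    if (!loc$multi_copy)
      stop("illegal double base call '", call, "' for sample ", sample_id,
           " at single-copy locus ", loc$locus_id)
    if (bases[1L] == bases[2L])
      stop("degenerate double call '", call, "' for sample ", sample_id,
           " at locus ", loc$locus_id)
    bases <- loc$allele_set[loc$allele_set %in% bases]
    return(paste(bases, collapse = "/"))
  }
  call
}

#' Read a sample-by-locus genotype table
#'
#' Expects a UTF-8 TSV with header columns `sample_id`, `population`,
#' `group`, then one column per panel locus id. Missing calls are encoded
#' `"."` (kept as `NA` internally). Lines starting with `#` (provenance
#' headers) are skipped. Call legality is enforced per locus: bases must
#' belong to the locus allele set and double calls are only accepted at
#' multi-copy loci.
#'
#' @param path Path to the TSV file.
#' @param panel A `"ypanel"`.
#' @return A `data.frame` (class `"genotype_table"`) with columns
#'   `sample_id`, `population`, `group` and one character column per locus,
#'   plus the panel stored in `attr(, "panel")`.
#' @export
read_genotype_table <- function(path, panel = horse_y_panel()) {
  if (!file.exists(path)) stop("genotype table not found: ", path)
  tab <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                      colClasses = "character", check.names = FALSE,
                      na.strings = NULL, quote = ""),
    error = function(e) stop("malformed genotype TSV '", path, "': ",
                             conditionMessage(e)))
  meta <- c("sample_id", "population", "group")
  if (!all(meta %in% names(tab)))
    stop("genotype table must have columns sample_id, population, group")
  locus_cols <- setdiff(names(tab), meta)
  unknown <- setdiff(locus_cols, panel_ids(panel))
  if (length(unknown))
    stop("unknown locus columns in genotype table: ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in genotype table")
  for (id in locus_cols) {
    loc <- panel[[id]]
    tab[[id]] <- vapply(seq_len(nrow(tab)), function(i)
      validate_call(tab[[id]][i], loc, tab$sample_id[i]), "")
  }
  tab <- tab[, c(meta, intersect(panel_ids(panel), locus_cols))]
  attr(tab, "panel") <- panel
  class(tab) <- c("genotype_table", "data.frame")
  tab
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]: emits the same TSV dialect, with `NA`
#' calls written as `"."`. An optional provenance header is written as
#' leading `#` comment lines; the file always ends with a newline.
#'
#' @param tab A genotype `data.frame` as returned by [read_genotype_table()].
#' @param path Output path.
#' @param provenance Optional character vector of header comment lines
#'   (without the leading `#`).
#' @export
write_genotype_table <- function(tab, path, provenance = NULL) {
  out <- as.data.frame(tab)
  for (j in seq_along(out))
    out[[j]][is.na(out[[j]])] <- MISSING_CALL
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
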