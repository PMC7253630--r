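#' Triplicate Ct quality control
#'
#' qPCR runs are performed in triplicate; a sample whose three Ct values
#' spread by more than the threshold (default 0.3 cycles) must be retested
#' and is withheld from quantification.
#'
#' @param cts Numeric vector of exactly 3 Ct values (cycles).
#' @param threshold Maximum admissible Ct range, default 0.3.
#' @return `"pass"` or `"retest"`.
#' @export
triplicate_qc <- function(cts, threshold = 0.3) {
  if (length(cts) != 3L) stop("triplicate QC needs exactly 3 Ct values")
  if (!all(is.finite(cts)) || any(cts <= 0)) stop("Ct values must be positive and finite")
  if (max(cts) - min(cts) > threshold + 1e-9) "retest" else "pass"
}

#' Relative copy number from Ct triplicates
#'
#' Efficiency-corrected delta-Ct quantification against a two-copy autosomal
#' reference (GAPDH-style):
#' \deqn{CN = 2 \cdot E_t^{-\bar{Ct}_t} / E_r^{-\bar{Ct}_r}}
#' so that equal mean Cts with equal efficiencies give exactly 2, and with
#' perfect efficiencies (E = 2) this reduces to
#' \eqn{CN = 2 \cdot 2^{\bar{Ct}_r - \bar{Ct}_t}} — one cycle of advantage
#' doubles the estimate.
#'
#' @param ct_target,ct_reference Numeric vectors of 3 Ct values each.
#' @param efficiency_target,efficiency_reference Amplification efficiencies
#'   in (1, 2], default 2 (perfect doubling per cycle).
#' @param qc_threshold Passed to [triplicate_qc()]; a retest on either
#'   channel aborts quantification.
#' @return Positive continuous copy-number estimate.
#' @export
relative_copy_number <- function(ct_target, ct_reference,
                                 efficiency_target = 2,
                                 efficiency_reference = 2,
                                 qc_threshold = 0.3) {
  if (efficiency_target <= 1 || efficiency_target > 2 ||
      efficiency_reference <= 1 || efficiency_reference > 2)
    stop("amplification efficiencies must lie in (1, 2]")
  if (triplicate_qc(ct_target, qc_threshold) == "retest" ||
      triplicate_qc(ct_reference, qc_threshold) == "retest")
    stop("triplicate QC failed (retest); refusing to quantify")
  2 * efficiency_target^(-mean(ct_target)) /
    efficiency_reference^(-mean(ct_reference))
}

#' Fit amplification efficiency from a dilution-series standard curve
#'
#' Regresses Ct on log10 template amount; a slope of -3.32 corresponds to
#' perfect doubling. Efficiency is \eqn{10^{-1/slope}}.
#'
#' @param dilution Relative template amounts (e.g. 1, 0.1, 0.01).
#' @param ct Observed Ct values, same length.
#' @return Efficiency (capped into (1, 2]).
#' @export
fit_efficiency <- function(dilution, ct) {
  stopifnot(length(dilution) == length(ct), length(ct) >= 3L)
  slope <- stats::coef(stats::lm(ct ~ log10(dilution)))[[2L]]
  if (slope >= 0) stop("standard curve slope must be negative")
  min(max(10^(-1 / slope), 1 + 1e-9), 2)
}

#' Snap a continuous copy-number estimate to an integer ladder
#'
#' Snapping is on the log2 scale, because Ct error is multiplicative in
#' copies: the chosen ladder value minimises
#' \eqn{|\log_2(\mathrm{ladder}) - \log_2(CN)|}. An exact tie returns the
#' smaller value and is flagged ambiguous.
#'
#' @param cn_continuous Positive continuous estimate.
#' @param ladder Strictly increasing integer ladder.
#' @return List with `cn_integer` and `ambiguous`.
#' @export
snap_to_ladder <- function(cn_continuous, ladder) {
  if (!length(ladder)) stop("empty copy-number ladder")
  if (!is.finite(cn_continuous) || cn_continuous <= 0)
    stop("cn_continuous must be positive")
  ladder <- sort(as.integer(ladder))
  d <- abs(log2(ladder) - log2(cn_continuous))
  best <- which(d <= min(d) + 1e-12)
  list(cn_integer = ladder[best[1L]], ambiguous = length(best) > 1L)
}

#' Read a qPCR plate table
#'
#' TSV with columns `sample_id`, `locus_id`, `rep` (1-3), `ct_target`,
#' `ct_reference`; `#` lines are skipped.
#'
#' @param path TSV path.
#' @return `data.frame` with those columns, Cts numeric.
#' @export
read_qpcr_table <- function(path) {
  if (!file.exists(path)) stop("qPCR table not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           check.names = FALSE, quote = "",
                           colClasses = c(sample_id = "character",
                                          locus_id = "character"))
  need <- c("sample_id", "locus_id", "rep", "ct_target", "ct_reference")
  if (!all(need %in% names(tab)))
    stop("qPCR table must have columns ", paste(need, collapse = ", "))
  tab
}

#' Call integer copy numbers from qPCR triplicates
#'
#' Groups the plate table by sample and locus, applies triplicate QC on both
#' channels (retest wells are excluded, never imputed), computes the
#' efficiency-corrected continuous estimate, optionally rescales by a
#' calibrator of known copy number, and snaps to the locus ladder.
#'
#' @param qpcr qPCR plate `data.frame` (see [read_qpcr_table()]).
#' @param panel A `"ypanel"` supplying per-locus ladders.
#' @param efficiency_target,efficiency_reference Efficiencies, default 2.
#' @param qc_threshold Ct-range threshold, default 0.3 cycles.
#' @param calibrator Optional `list(sample_id =, cn =)` naming a control
#'   sample of known copy number; all estimates at each locus are rescaled
#'   so the calibrator is exact.
#' @return `data.frame` of class `"cn_calls"`: `sample_id`, `locus_id`,
#'   `cn_continuous`, `cn_integer`, `ambiguous`, `qc_flag`. For retest rows
#'   the numeric fields are `NA` — the call is withheld from downstream
#'   layers.
#' @export
call_copy_number <- function(qpcr, panel = horse_y_panel(),
                             efficiency_target = 2,
                             efficiency_reference = 2,
                             qc_threshold = 0.3, calibrator = NULL) {
  key <- interaction(qpcr$sample_id, qpcr$locus_id, drop = TRUE, sep = "\x1f")
  parts <- split(qpcr, key)
  rows <- lapply(parts, function(d) {
    sid <- d$sample_id[1L]; lid <- d$locus_id[1L]
    if (nrow(d) != 3L)
      stop("sample ", sid, " locus ", lid, ": expected 3 replicates, got ",
           nrow(d))
    if (!lid %in% names(panel)) stop("locus ", lid, " not in panel")
    flag <- if (triplicate_qc(d$ct_target, qc_threshold) == "retest" ||
                triplicate_qc(d$ct_reference, qc_threshold) == "retest")
      "retest" else "pass"
    cn <- if (flag == "pass")
      relative_copy_number(d$ct_target, d$ct_reference, efficiency_target,
                           efficiency_reference, qc_threshold) else NA_real_
    data.frame(sample_id = sid, locus_id = lid, cn_continuous = cn,
               qc_flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(calibrator)) {
    for (lid in unique(out$locus_id)) {
      i <- out$locus_id == lid & out$sample_id == calibrator$sample_id &
        out$qc_flag == "pass"
      if (any(i)) {
        scale <- calibrator$cn / out$cn_continuous[which(i)[1L]]
        j <- out$locus_id == lid
        out$cn_continuous[j] <- out$cn_continuous[j] * scale
      }
    }
  }
  snap <- mapply(function(cn, lid) {
    if (is.na(cn)) return(c(NA_integer_, NA))
    s <- snap_to_ladder(cn, panel[[lid]]$cn_ladder)
    c(s$cn_integer, s$ambiguous)
  }, out$cn_continuous, out$locus_id)
  out$cn_integer <- as.integer(snap[1L, ])
  out$ambiguous <- as.logical(snap[2L, ])
  out <- out[order(out$sample_id, out$locus_id),
             c("sample_id", "locus_id", "cn_continuous", "cn_integer",
               "ambiguous", "qc_flag")]
  rownames(out) <- NULL
  class(out) <- c("cn_calls", "data.frame")
  out
}

# integer-preserving median: lower middle value for even counts
integer_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

#' Per-group per-locus copy-number summary
#'
#' Median (lower middle value for even counts, keeping the summary on the
#' integer ladder) and range of pass-flag integer calls, per group and
#' locus. Empty cells are reported as `NA`, never zero.
#'
#' @param calls `"cn_calls"` data frame.
#' @param groups Named character vector mapping sample_id to group label.
#' @return `data.frame`: `group`, `locus_id`, `n`, `median`, `min`, `max`.
#' @export
cn_summary <- function(calls, groups) {
  ok <- calls$qc_flag == "pass" & !is.na(calls$cn_integer)
  d <- calls[ok, , drop = FALSE]
  d$group <- unname(groups[d$sample_id])
  grid <- expand.grid(group = sort(unique(unname(groups))),
                      locus_id = sort(unique(calls$locus_id)),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- d$cn_integer[d$group == grid$group[i] &
                        d$locus_id == grid$locus_id[i]]
    if (!length(x))
      return(data.frame(grid[i, ], n = 0L, median = NA_integer_,
                        min = NA_integer_, max = NA_integer_))
    data.frame(grid[i, ], n = length(x), median = integer_median(x),
               min = min(x), max = max(x))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Copy-number polymorphism (unbiased gene diversity over CN states)
#'
#' \eqn{(n/(n-1)) (1 - \sum_k p_k^2)} where \eqn{p_k} is the frequency of
#' copy-number state k; 0 iff the group is monomorphic, at most 1, and
#' undefined (NA) for fewer than two samples.
#'
#' @param cn Integer copy numbers of one group at one locus.
#' @return Gene diversity in [0, 1], or `NA` if `length(cn) < 2`.
#' @export
cnv_polymorphism <- function(cn) {
  cn <- cn[!is.na(cn)]
  n <- length(cn)
  if (n < 2L) return(NA_real_)
  p <- as.vector(table(cn)) / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Per-group per-locus CNV polymorphism table
#'
#' @param calls `"cn_calls"` data frame.
#' @param groups Named character vector mapping sample_id to group.
#' @return `data.frame`: `group`, `locus_id`, `n`, `diversity`.
#' @export
cnv_polymorphism_table <- function(calls, groups) {
  ok <- calls$qc_flag == "pass" & !is.na(calls$cn_integer)
  d <- calls[ok, , drop = FALSE]
  d$group <- unname(groups[d$sample_id])
  grid <- expand.grid(group = sort(unique(unname(groups))),
                      locus_id = sort(unique(calls$locus_id)),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    x <- d$cn_integer[d$group == grid$group[i] &
                        d$locus_id == grid$locus_id[i]]
    data.frame(grid[i, ], n = length(x), diversity = cnv_polymorphism(x))
  }))
  rownames(out) <- NULL
  out
}
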