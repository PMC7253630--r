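#' Haplotype (gene) diversity with standard error
#'
#' Nei's unbiased haplotype diversity
#' \deqn{h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)}
#' — the bias-corrected probability that two randomly drawn chromosomes
#' carry different haplotypes — with its sampling variance
#' \deqn{V(h) = \frac{2}{n(n-1)}\left\{2(n-2)\left[\sum p_i^3 -
#'   \left(\sum p_i^2\right)^2\right] + \sum p_i^2 -
#'   \left(\sum p_i^2\right)^2\right\}}
#' (Nei 1987, eqs. 8.4 and 8.12). `h = 0` iff a single haplotype is present.
#'
#' @param counts Positive integer carrier counts, one per haplotype.
#' @return List with `h`, `se`, `n`, `k`.
#' @examples
#' haplotype_diversity(c(6, 1))  # h = 0.286, se = 0.196
#' @export
haplotype_diversity <- function(counts) {
  counts <- as.integer(counts)
  if (any(counts < 1L)) stop("haplotype counts must be positive")
  n <- sum(counts)
  if (n < 2L) stop("haplotype diversity is undefined for n < 2")
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  h <- n / (n - 1) * (1 - s2)
  V <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(h = h, se = sqrt(max(V, 0)), n = n, k = length(counts))
}

# site distance between two call strings: 1 if the atomic states differ.
# A double call counts distance 1 from either single state and from a
# different double call, consistent with call-string equality.
call_distance <- function(x, y) as.numeric(x != y)

#' Pairwise Hamming distance between haplotype call vectors
#'
#' Number of panel sites whose call strings differ; double base calls are
#' atomic states, at unit distance from either single-base state.
#'
#' @param calls Character matrix, rows = haplotypes (rownames are labels),
#'   columns = sites.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
hamming_matrix <- function(calls) {
  k <- nrow(calls)
  d <- matrix(0, k, k, dimnames = list(rownames(calls), rownames(calls)))
  if (k < 2L) return(d)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    d[i, j] <- d[j, i] <- sum(calls[i, ] != calls[j, ])
  }
  d
}

#' Nucleotide diversity with standard error
#'
#' Mean pairwise difference per site,
#' \deqn{\pi = \frac{n}{n-1} \sum_{u<v} 2 p_u p_v d_{uv} / L,}
#' the unbiased weighting consistent with [haplotype_diversity()]; equals
#' the average Hamming distance over all \eqn{\binom{n}{2}} sample pairs
#' divided by L. The standard error uses Nei's (1987, eq. 10.7) stochastic
#' variance
#' \deqn{V(\pi) = \frac{n+1}{3(n-1)L}\pi +
#'   \frac{2(n^2+n+3)}{9n(n-1)}\pi^2.}
#'
#' @param counts Carrier counts, one per haplotype.
#' @param d Pairwise site-difference matrix between haplotypes (same order
#'   as `counts`), e.g. from [hamming_matrix()].
#' @param L Number of sites analysed (alignment length); the screened
#'   length, not just the segregating sites.
#' @return List with `pi`, `se`, `n`.
#' @export
nucleotide_diversity <- function(counts, d, L) {
  counts <- as.integer(counts)
  n <- sum(counts)
  if (n < 2L) stop("nucleotide diversity is undefined for n < 2")
  if (L < 1) stop("L (sites analysed) must be >= 1")
  d <- as.matrix(d)
  stopifnot(nrow(d) == length(counts), ncol(d) == length(counts))
  p <- counts / n
  pi_hat <- n / (n - 1) * sum((p %o% p) * d) / L  # full matrix = 2 * sum_{u<v}
  V <- (n + 1) / (3 * (n - 1) * L) * pi_hat +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi_hat^2
  list(pi = pi_hat, se = sqrt(max(V, 0)), n = n)
}

#' Count segregating sites
#'
#' Number of panel sites showing at least two distinct call strings among
#' the haplotypes (double calls count as their own state).
#'
#' @param calls Character matrix, rows = haplotypes, columns = sites.
#' @return Integer count.
#' @export
count_segregating_sites <- function(calls) {
  if (nrow(calls) < 2L) return(0L)
  sum(apply(calls, 2L, function(col) length(unique(col)) > 1L))
}

#' Per-population diversity table
#'
#' Computes, for each population, the number of haplotypes and samples, the
#' haplotype list, haplotype diversity with SE and nucleotide diversity
#' with SE — the per-population summary table of a patriline survey.
#'
#' @param hs A `"haploset"` (see [collapse_haplotypes()]).
#' @param L Sites analysed for the per-site scaling of `pi`.
#' @param by Grouping column of `hs$samples`, `"population"` (default) or
#'   `"group"`.
#' @return `data.frame`: `population`, `n`, `k`, `haplotypes`, `h`, `h_se`,
#'   `pi`, `pi_se`. Populations with a single sample get `NA` statistics.
#' @export
diversity_table <- function(hs, L, by = "population") {
  stopifnot(inherits(hs, "haploset"))
  dmat <- hamming_matrix(hs$calls)
  parts <- split(hs$samples, hs$samples[[by]])
  out <- lapply(names(parts), function(popname) {
    s <- parts[[popname]]
    cnt <- table(s$haplotype)
    haps <- names(cnt)
    row <- data.frame(population = popname, n = nrow(s), k = length(cnt),
                      haplotypes = paste(sort(haps), collapse = ","),
                      stringsAsFactors = FALSE)
    if (nrow(s) < 2L)
      return(cbind(row, h = NA_real_, h_se = NA_real_, pi = NA_real_,
                   pi_se = NA_real_))
    hd <- haplotype_diversity(as.integer(cnt))
    nd <- nucleotide_diversity(as.integer(cnt),
                               dmat[haps, haps, drop = FALSE], L)
    cbind(row, h = hd$h, h_se = hd$se, pi = nd$pi, pi_se = nd$se)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
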