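---
title: "Three-layer Y-chromosome patriline analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-layer Y-chromosome patriline analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patrilineR)
```

## The problem

The male-specific region of the Y chromosome is inherited patrilineally and
does not recombine, so every stallion carries a single haplotype that traces
his paternal line. Sequence diversity on the horse Y is notoriously low,
which limits the phylogenetic resolution available from SNPs alone. This
package implements a three-layer marker system that recovers finer patriline
structure from the same assays:

1. **Layer 1 — SNP haplotypes.** A panel of male-specific sites (14 by
   default) is genotyped per stallion; the distinct multi-locus call vectors
   are the haplotypes. Because most of these sites sit in *repeated*
   fragments, a haploid chromosome can show an apparent heterozygote (a
   "double base call") when divergent repeat copies carry different bases.
   We treat a double call as an atomic third state of the site: `"G"`,
   `"A"` and `"G/A"` are three distinct haplotype states.
2. **Layer 2 — copy number.** The repeated fragments vary in copy number
   between lines. Integer copy numbers per locus are quantified by qPCR
   against a two-copy autosomal reference gene, so two stallions with the
   same SNP haplotype can belong to different lines with, say, 5 and 10
   copies of the same fragment.
3. **Layer 3 — allele-specific copy number.** At a double-call locus the
   two alleles need not occupy equally many repeat copies. The
   pyrosequencing ratio of base variants (RBV) — the fractional signal of
   one allele — determines the integer split: `G3A2` (3 G-copies + 2
   A-copies) and `G2A3` are different paternal lines even though they share
   the genotype and the total copy number.

The refinement is strictly nested: layer 2 subdivides layer-1 haplotypes and
layer 3 subdivides layer-2 lines; a later layer can never merge groups that
an earlier layer separates.

## Copy-number quantification

Each sample×locus cell is measured as Ct triplicates on a target and a
reference channel. Quality control follows the bench rule that triplicates
spreading by more than 0.3 cycles must be retested: such wells are excluded,
never imputed (`triplicate_qc()`). Quantification uses the
efficiency-corrected ΔCt model

$$CN = 2 \cdot \frac{E_t^{-\bar{Ct}_t}}{E_r^{-\bar{Ct}_r}},$$

anchored so that equal mean Cts with equal efficiencies give exactly the
reference's 2 copies; with perfect efficiencies ($E=2$) one cycle of
advantage doubles the estimate. Per-assay efficiencies can be fitted from a
dilution-series standard curve (slope $s$ gives $E = 10^{-1/s}$,
`fit_efficiency()`), and an optional calibrator sample of known copy number
rescales a plate exactly.

Continuous estimates are snapped to the locus's admissible integer ladder
**on the log2 scale**, because Ct error is multiplicative in copies: the
call is $\arg\min_k |\log_2 k - \log_2 CN|$. An exact tie returns the
smaller ladder value and is flagged ambiguous; ambiguous and retest calls
are withheld from the layered refinement. The default ladder for the horse
panel is the geometric set $\{1, 2, 5, 10, 20\}$, which matches the
copy-number values observed across populations; with that spacing
(≥ 1 log2 unit) and triplicate Ct noise of 0.1 cycles, miscalls are
vanishingly rare — the recovery tests demand ≥ 99% and observe ~100%.

Copy-number polymorphism per population is summarised as unbiased gene
diversity over CN states, $\frac{n}{n-1}(1 - \sum_k p_k^2)$ — zero iff
monomorphic, as for populations represented by a single outgroup animal.
The published polymorphism table does not state its statistic; gene
diversity is this package's choice, and only its structural properties
(zero iff monomorphic, ≤ 1) are asserted.

## Allele-specific splits

A heterozygous multi-copy site with total copy number $N$ admits the splits
$(a, b)$, $a + b = N$, $a, b \ge 1$. Given an RBV $r$ the resolved split
minimises $|a/N - r|$. If the runner-up candidate is within a tolerance
(default 0.02) of the best in this objective, the call is flagged ambiguous
and both candidates are reported: pyrosequencing allele quantification is
typically accurate to a few percent, and adjacent candidates are $1/N$
apart, so the default tolerance only bites for exact or near ties (e.g.
$N = 5$, $r = 0.5$). Split patterns are keyed by allele order (`3:2` ≠
`2:3`): the two orientations are distinct paternal lines. The per-sample
total $N$ is taken from the sample's own integer qPCR call — a withheld
copy number blocks split resolution for that sample.

## Diversity statistics

The package uses Nei's (1987) unbiased estimators: haplotype diversity
$h = \frac{n}{n-1}(1 - \sum p_i^2)$ with variance

$$V(h) = \frac{2}{n(n-1)}\left\{2(n-2)\!\left[\sum p_i^3 -
\left(\sum p_i^2\right)^2\right] + \sum p_i^2 -
\left(\sum p_i^2\right)^2\right\},$$

and nucleotide diversity as the unbiased mean pairwise difference per site,
with the standard stochastic variance
$V(\pi) = \frac{n+1}{3(n-1)L}\pi + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2$.
These formulas were chosen because they reproduce, to printed precision,
the published per-population $h$ *and* its standard error for every row
whose frequency spectrum is uniquely determined by an integer-partition
search (YQ, IMG, KZK, YN, GZ-JC); `table_fixture("table1_spectra")` carries
those derived spectra. A few published rows (e.g. TB, NQ, ELC) are not
reproducible from any partition of their printed sample size — most
plausibly genotyping failures reduced the effective $n$ — and are asserted
nowhere. The per-site scaling $L$ of $\pi$ is an explicit parameter
(default 53,000, the approximate screened length) because per-population
alignment lengths are not recoverable; published $\pi$ values are therefore
not used as checks.

## Layered distance and trees

The joint distance between two refined profiles is

$$d = w_{snp}\, d_{Ham} + w_{cnv} \sum_\ell \big|\log_2 CN_x^{(\ell)} -
\log_2 CN_y^{(\ell)}\big| + w_{ascnv}\, \#\{\ell : \text{split labels
differ}\},$$

with default weights (1, 1, 1). The CN term is logarithmic because
copy-number evolution on these fragments is multiplicative (the observed
ladder is geometric). Loci with an unknown layer in either profile
contribute zero — agnostic, never infinite — since the study design only
resolves AS-CNVs for a subset of carriers. Setting
$w_{cnv} = w_{ascnv} = 0$ provably reduces the joint matrix to the SNP
Hamming matrix, so the joint UPGMA tree degenerates to the SNP-only tree.
The distance is a semimetric and empirically satisfies the triangle
inequality for these components (property-tested on random profiles).

UPGMA itself is delegated to average-linkage `hclust` with node heights
halved (leaves equidistant from the root); labels are sorted before
clustering so ties merge the lexicographically smallest pair, making the
Newick output a deterministic function of the distances. Branch lengths
are in absolute site differences; whether the original analysis divided by
sites affects lengths only, not topology.

## Median-joining networks

No installed R package provides the Bandelt–Forster–Röhl median-joining
algorithm, so `mjn()` implements it directly:

1. the ε-relaxed minimum spanning network over the current node set
   (ε = 0, the default used here, keeps exactly the links lying on some
   minimum spanning tree);
2. for every triplet connected by at least two links, the quasi-median:
   site-wise majority where one exists, otherwise all combinations of the
   tied states (multi-state sites, including double calls, are handled by
   expansion);
3. the candidate median that most reduces the minimum-spanning-tree length
   is added; steps 1–3 iterate to fixation (ties between candidates break
   lexicographically on the call vector);
4. median vectors ending with degree ≤ 1 are discarded.

Maximum-parsimony pruning (`mp_prune()`) then retains exactly the links and
median vectors lying on at least one minimum-length tree spanning the
observed haplotypes — a Steiner tree through the admissible medians under
full Hamming distances. Up to 12 network nodes this is computed exactly by
enumerating median subsets (discarding subsets that contain a removable
median, so retained medians have degree ≥ 3); larger networks fall back to
greedy deletion of medians whose removal leaves the spanning length
unchanged. The exact path is cross-checked in the test suite against an
independent brute-force Steiner oracle built on igraph MSTs with a
force-the-edge membership criterion. On infinite-sites data the pruned
network is provably a tree whose total length equals the number of
segregating sites, and the tests verify this on simulated genealogies.

## What the synthetic generator emulates

`simulate_patrilines()` produces complete datasets plus truth files so every
stage is testable without any external download. It emulates:

- a random bifurcating patrilineal genealogy (`ape::rtree`);
- infinite-sites SNP mutations: each of the (default 14) sites is placed on
  one edge drawn with probability proportional to branch length — the
  Poisson-per-branch mutation model conditioned on the observed number of
  segregating sites — so a perfect phylogeny always holds;
- stepwise copy-number evolution on the geometric ladder along branches
  (Poisson number of ±1-step moves per edge, rate 0.05 — rare, as CNV
  lineage differences in the data are few but deep);
- partial mutations at multi-copy loci (probability 0.5): the affected
  clade becomes double-call and each carrier receives a true split drawn
  from a clade-level derived fraction;
- qPCR noise: per-replicate reference Cts ~ Normal(20, 0.1 cycles) and
  target Cts offset by −log2(CN/2) with the same noise;
- RBV noise: uniform within ±1/(4·CN) — a quarter of the spacing between
  adjacent splits, the regime in which resolution is provably exact;
- genotype dropout at rate 0.01, applied last, mirroring the small fraction
  of samples that fail genotyping.

Defaults (96 samples, 5 populations in 3 groups) are sized to the study's
discovery panel; the acceptance script runs this default configuration.
What passing tests on this generator do **not** show: robustness to
homoplasy (recurrent mutation violating infinite sites), to non-Gaussian
qPCR failure modes (inhibition, plate effects beyond a constant calibrator
shift), or to pyrosequencing biases that are systematic rather than
bounded-uniform. Real-data workflows should treat the retest and ambiguity
flags as first-class QC outputs, not rarities.

## Numerical and design choices

- **Haplotype naming** is by descending carrier frequency, ties broken
  lexicographically by call vector — publication numbering is data-entry
  order and unrecoverable, and determinism matters more.
- **Missing data**: samples with any missing panel call are excluded from
  haplotype collapsing and reported; downstream layers only ever see
  included samples.
- **Unknown-layer grouping**: a sample with an unknown CN or split merges
  into the unique compatible fully-known line; with zero or several
  compatible lines it keeps its own `?`-marked name. "Not applicable"
  (a single-base call has no split) is distinct from "unknown".
- **Tie-breaks** are lexicographic everywhere (ladder snapping prefers the
  smaller value and flags the tie; split resolution reports the larger
  first-allele count first and flags the tie).
- **Problem sizes in tests**: simulations use 20–96 samples and the exact
  Steiner oracle runs on ≤ 12-node networks; these sizes make the full
  suite run in well under a minute while still exercising every code path,
  and match the scale of the original survey (≤ 39 haplotypes per
  network).

## Known limitations

- The MJN median-acceptance rule ("most reduces MST length") is a faithful
  but not bit-identical reconstruction of the vendor software's internal
  bookkeeping; published networks also depend on unprinted per-sample
  genotypes, so exact figure reproduction is out of scope by design.
- The unbiased-$h$ variance is the large-sample form; for $n < 4$ its
  square root is a rough guide only.
- CN calling assumes the reference gene is exactly two copies in every
  sample; a reference CNV would bias all targets of that sample.
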