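# build a small refined-lines scenario by hand
make_layer_scenario <- function(cn_s2 = 5L, split_s2 = "G3A2",
                                cn_s2_na = FALSE) {
  p <- toy_panel()
  calls <- rbind(s1 = c("G/A", "T"), s2 = c("G/A", "T"), s3 = c("G", "T"))
  colnames(calls) <- names(p)
  hs <- collapse_haplotypes(make_genotypes(calls), p)
  cn <- data.frame(sample_id = c("s1", "s2", "s3"), locus_id = "9",
                   cn_continuous = 5, cn_integer = c(5L, cn_s2, 1L),
                   ambiguous = FALSE, qc_flag = "pass",
                   stringsAsFactors = FALSE)
  if (cn_s2_na) cn$qc_flag[2] <- "retest"
  splits <- data.frame(sample_id = c("s1", "s2"), locus_id = "9",
                       total_cn = c(5L, cn_s2), rbv = 0.6,
                       a_copies = c(3L, as.integer(sub(".*G(\\d)A.*", "\\1",
                                                       split_s2))),
                       b_copies = c(2L, cn_s2 - as.integer(
                         sub(".*G(\\d)A.*", "\\1", split_s2))),
                       label = c("G3A2", split_s2),
                       pattern = "x", ambiguous = FALSE,
                       stringsAsFactors = FALSE)
  list(hs = hs, cn = cn, splits = splits, panel = p)
}

test_that("CNV differences split SNP haplotypes into distinct lines", {
  sc <- make_layer_scenario(cn_s2 = 10L, split_s2 = "G6A4")
  lines <- refine(sc$hs, sc$cn, sc$splits, sc$panel)
  expect_equal(lines$base_name[lines$sample_id == "s1"],
               lines$base_name[lines$sample_id == "s2"])
  expect_false(lines$full_name[lines$sample_id == "s1"] ==
                 lines$full_name[lines$sample_id == "s2"])
})

test_that("AS-CNV orientation splits lines with identical SNPs and total CN", {
  sc <- make_layer_scenario(cn_s2 = 5L, split_s2 = "G2A3")
  lines <- refine(sc$hs, sc$cn, sc$splits, sc$panel)
  expect_false(lines$full_name[lines$sample_id == "s1"] ==
                 lines$full_name[lines$sample_id == "s2"])

  sc_same <- make_layer_scenario(cn_s2 = 5L, split_s2 = "G3A2")
  lines <- refine(sc_same$hs, sc_same$cn, sc_same$splits, sc_same$panel)
  expect_equal(lines$full_name[lines$sample_id == "s1"],
               lines$full_name[lines$sample_id == "s2"])
})

test_that("unknown layer entries never split an otherwise identical group", {
  sc <- make_layer_scenario(cn_s2 = 5L, split_s2 = "G3A2", cn_s2_na = TRUE)
  sc$splits <- sc$splits[sc$splits$sample_id == "s1", ]
  lines <- refine(sc$hs, sc$cn, sc$splits, sc$panel)
  expect_equal(lines$full_name[lines$sample_id == "s2"],
               lines$full_name[lines$sample_id == "s1"])
})

test_that("splits inconsistent with the copy-number layer are rejected", {
  sc <- make_layer_scenario()
  sc$splits$a_copies[1] <- 4L  # 4 + 2 != 5
  expect_error(refine(sc$hs, sc$cn, sc$splits, sc$panel),
               "inconsistent with copy number")
})

test_that("refinement is a nested partition over the three layers", {
  cfg <- sim_config(seed = 17, n_samples = 50, dropout_rate = 0)
  sim <- simulate_patrilines(cfg)
  hs <- collapse_haplotypes(sim$genotypes)
  cn <- call_copy_number(sim$qpcr)
  splits <- resolve_splits(sim$pyro, cn)
  lines <- refine(hs, cn, splits)
  # layer-3 partition refines layer-1: equal full_name implies equal base
  agg <- tapply(lines$base_name, lines$full_name,
                function(x) length(unique(x)))
  expect_true(all(agg == 1))
  # and layer-2 keys never merge distinct base names
  agg2 <- tapply(lines$base_name, paste(lines$base_name, lines$cn_string),
                 function(x) length(unique(x)))
  expect_true(all(agg2 == 1))
})

test_that("layered distance is a semimetric with log2 CN and split terms", {
  snp <- c("G", "T"); cn <- c(5L); sp <- c("G3A2")
  expect_equal(layered_distance(snp, snp, cn, cn, sp, sp), 0)
  expect_equal(layered_distance(snp, snp, c(5L), c(10L), sp, sp), 1)
  expect_equal(layered_distance(snp, snp, cn, cn, c("G3A2"), c("G2A3")), 1)
  expect_equal(layered_distance(snp, snp, cn, NA_integer_,
                                sp, NA_character_), 0)
  set.seed(12)
  rand_prof <- function() list(
    snp = sample(c("G", "A", "G/A"), 4, replace = TRUE),
    cn = sample(c(1L, 2L, 5L, 10L, 20L), 2, replace = TRUE),
    sp = sample(c("G3A2", "G2A3", "G4A1"), 2, replace = TRUE))
  for (k in 1:30) {
    x <- rand_prof(); y <- rand_prof(); z <- rand_prof()
    dxy <- layered_distance(x$snp, y$snp, x$cn, y$cn, x$sp, y$sp)
    dyx <- layered_distance(y$snp, x$snp, y$cn, x$cn, y$sp, x$sp)
    dxz <- layered_distance(x$snp, z$snp, x$cn, z$cn, x$sp, z$sp)
    dzy <- layered_distance(z$snp, y$snp, z$cn, y$cn, z$sp, y$sp)
    expect_equal(dxy, dyx)
    expect_lte(dxy, dxz + dzy + 1e-9)
  }
})

test_that("zero CNV/AS-CNV weights reduce the joint tree to the SNP tree", {
  cfg <- sim_config(seed = 23, n_samples = 24, dropout_rate = 0)
  sim <- simulate_patrilines(cfg)
  hs <- collapse_haplotypes(sim$genotypes)
  cn <- call_copy_number(sim$qpcr)
  splits <- resolve_splits(sim$pyro, cn)
  lines <- refine(hs, cn, splits)
  d_joint0 <- layered_distance_matrix(hs, lines, c(1, 0, 0))
  samples <- lines$sample_id
  snp <- hs$calls[hs$assignment[samples], , drop = FALSE]
  rownames(snp) <- samples
  d_snp <- hamming_matrix(snp)
  expect_equal(d_joint0, d_snp[samples, samples])
})
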