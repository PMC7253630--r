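test_that("triplicate QC applies the 0.3-cycle retest rule", {
  expect_equal(triplicate_qc(c(20.0, 20.1, 20.2)), "pass")
  expect_equal(triplicate_qc(c(20.0, 20.2, 20.4)), "retest")
  expect_equal(triplicate_qc(c(20.0, 20.0, 20.0)), "pass")
  expect_equal(triplicate_qc(c(20.0, 20.1, 20.3)), "pass")  # range == 0.3
  expect_error(triplicate_qc(c(20, 20)), "exactly 3")
})

test_that("relative copy number follows the efficiency-corrected delta-Ct model", {
  ct <- c(20, 20, 20)
  expect_equal(relative_copy_number(ct, ct), 2)
  expect_equal(relative_copy_number(ct - 1, ct), 4)  # one-cycle doubling
  expect_equal(relative_copy_number(ct, ct - 1), 1)
  expect_equal(relative_copy_number(ct, ct + 1.3219), 5, tolerance = 0.01)

  # scale invariance: adding a constant to all six Cts leaves CN unchanged
  set.seed(3)
  for (k in 1:5) {
    t0 <- runif(3, 18, 22); r0 <- runif(3, 18, 22)
    t0 <- t0 - (max(t0) - min(t0)) * 0.6  # keep within QC range
    t0 <- rep(mean(t0), 3); r0 <- rep(mean(r0), 3)
    shift <- runif(1, -5, 5)
    expect_equal(relative_copy_number(t0, r0),
                 relative_copy_number(t0 + shift, r0 + shift))
  }
  # monotone: lowering the target Ct strictly raises CN
  expect_gt(relative_copy_number(ct - 0.5, ct), relative_copy_number(ct, ct))
  expect_error(relative_copy_number(c(20, 20.2, 20.4), ct), "retest")
})

test_that("standard-curve efficiency fit recovers known efficiencies", {
  dil <- c(1, 0.1, 0.01, 0.001)
  ct_perfect <- 20 - log2(dil)          # slope -1/log10(2) per log10
  expect_equal(fit_efficiency(dil, ct_perfect), 2, tolerance = 1e-6)
  ct_e15 <- 20 - log(dil) / log(1.5)
  expect_equal(fit_efficiency(dil, ct_e15), 1.5, tolerance = 1e-6)
})

test_that("ladder snapping works on the log2 scale with tie flagging", {
  expect_equal(snap_to_ladder(2.1, 1:20)$cn_integer, 2L)
  expect_equal(snap_to_ladder(6.9, 1:20)$cn_integer, 7L)
  s <- snap_to_ladder(6, c(4, 9))  # log-scale tie: |log2 6/4| == |log2 6/9|
  expect_equal(s$cn_integer, 4L)
  expect_true(s$ambiguous)
  expect_false(snap_to_ladder(2.1, 1:20)$ambiguous)
  expect_error(snap_to_ladder(2, integer(0)), "empty")
  expect_error(snap_to_ladder(-1, 1:20), "positive")
})

test_that("copy-number calling excludes retest wells and summarises correctly", {
  p <- toy_panel()
  q <- rbind(make_triplicate("s1", "9", 5), make_triplicate("s2", "9", 5),
             make_triplicate("s3", "9", 5), make_triplicate("s4", "9", 10))
  bad <- make_triplicate("s5", "9", 5)
  bad$ct_target <- c(20, 20.5, 21)
  calls <- call_copy_number(rbind(q, bad), p)
  expect_equal(calls$qc_flag[calls$sample_id == "s5"], "retest")
  expect_true(is.na(calls$cn_integer[calls$sample_id == "s5"]))
  expect_equal(calls$cn_integer[calls$sample_id == "s4"], 10L)

  groups <- c(s1 = "SC", s2 = "SC", s3 = "SC", s4 = "SC", s5 = "SC")
  cs <- cn_summary(calls, groups)
  expect_equal(cs$median, 5L)  # {5,5,5,10} -> lower-middle median 5
  expect_equal(c(cs$min, cs$max), c(5L, 10L))

  # degenerate one-sample cell
  cs1 <- cn_summary(calls[calls$sample_id == "s4", ], c(s4 = "EP"))
  expect_equal(unlist(cs1[, c("median", "min", "max")], use.names = FALSE),
               c(10L, 10L, 10L))

  # even count takes the lower middle value
  calls56 <- call_copy_number(rbind(make_triplicate("a", "9", 5),
                                    make_triplicate("b", "9", 10)), p)
  expect_equal(cn_summary(calls56, c(a = "G", b = "G"))$median, 5L)
})

test_that("CNV polymorphism is unbiased gene diversity over CN states", {
  expect_equal(cnv_polymorphism(c(5, 5, 5)), 0)
  expect_equal(cnv_polymorphism(c(5, 10)), 1)
  expect_equal(cnv_polymorphism(rep(c(5L, 10L), c(9, 1))), 0.2)
  expect_true(is.na(cnv_polymorphism(5)))
  set.seed(8)
  for (k in 1:20) {
    x <- sample(c(1, 2, 5, 10, 20), sample(2:30, 1), replace = TRUE)
    d <- cnv_polymorphism(x)
    expect_lte(d, 1)
    expect_equal(d == 0, length(unique(x)) == 1)
  }
})

test_that("true copy numbers are recovered from noisy synthetic plates", {
  set.seed(21)
  p <- toy_panel()
  truth <- sample(c(1, 2, 5, 10, 20), 150, replace = TRUE)
  q <- do.call(rbind, lapply(seq_along(truth), function(i)
    make_triplicate(sprintf("s%03d", i), "9", truth[i], sd = 0.1)))
  calls <- call_copy_number(q, p)
  ok <- calls$qc_flag == "pass"
  expect_gte(mean(calls$cn_integer[ok] ==
                    truth[match(calls$sample_id, sprintf("s%03d",
                                                         seq_along(truth)))][ok]),
             0.99)
})

test_that("a calibrator of known copy number rescales a biased plate", {
  p <- toy_panel()
  q <- rbind(make_triplicate("cal", "9", 5), make_triplicate("s1", "9", 10))
  q$ct_target <- q$ct_target + 0.7  # constant plate bias
  calls <- call_copy_number(q, p, calibrator = list(sample_id = "cal", cn = 5))
  expect_equal(calls$cn_continuous[calls$sample_id == "cal"], 5)
  expect_equal(calls$cn_integer[calls$sample_id == "s1"], 10L)
})
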