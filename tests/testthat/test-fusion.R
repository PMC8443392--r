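mk_gate <- function(per_axis, flag = "PASS", idx = 0L) {
  structure(list(window_flag = flag, per_axis = per_axis,
                 peaks = rep(0.03, 6), window_index = idx),
            class = "gate_outcome")
}
mk_dec <- function(label) {
  structure(list(axis_index = 0L, label = label, err_fm = 0, err_nonfm = 1,
                 method = "OMP"), class = "axis_decision")
}

test_that("fuse_masks is the OR of candidate-axis FM labels", {
  g <- mk_gate(rep("CANDIDATE", 6))
  all0 <- fuse_masks(rep(list(mk_dec("NON_FM")), 6), g)
  expect_equal(all0$mask, rep(0L, 6))
  expect_equal(all0$fused_label, "NON_FM")

  one <- fuse_masks(c(rep(list(mk_dec("NON_FM")), 3), list(mk_dec("FM")),
                      rep(list(mk_dec("NON_FM")), 2)), g)
  expect_equal(one$mask, c(0L, 0L, 0L, 1L, 0L, 0L))
  expect_equal(one$fused_label, "FM")
})

test_that("fuse_masks equals popcount >= 1 over all 64 label patterns", {
  g <- mk_gate(rep("CANDIDATE", 6))
  for (bits in 0:63) {
    lab <- ifelse(bitwAnd(bits, 2^(0:5)) > 0, "FM", "NON_FM")
    out <- fuse_masks(lapply(lab, mk_dec), g)
    expect_equal(out$mask, as.integer(lab == "FM"))
    expect_equal(out$fused_label, if (bits > 0) "FM" else "NON_FM")
  }
})

test_that("suppressed axes and artifact windows force zero mask bits", {
  g <- mk_gate(c("CANDIDATE", rep("SUPPRESSED", 5)))
  out <- fuse_masks(c(list(mk_dec("FM")), rep(list(NULL), 5)), g)
  expect_equal(out$mask, c(1L, rep(0L, 5)))
  # a suppressed axis contributes 0 even if a decision object is present
  g2 <- mk_gate(rep("SUPPRESSED", 6), flag = "ARTIFACT")
  out2 <- fuse_masks(rep(list(mk_dec("FM")), 6), g2)
  expect_equal(out2$mask, rep(0L, 6))
  expect_equal(out2$fused_label, "NON_FM")
  expect_equal(out2$gate_flag, "ARTIFACT")
  expect_error(fuse_masks(rep(list(NULL), 5), g), "exactly 6")
})

test_that("decisions_to_events merges runs of consecutive FM windows", {
  lab <- rep("NON_FM", 10); lab[c(4, 5, 6)] <- "FM"  # indices 3,4,5 0-based
  dec <- data.frame(window_index = 0:9, start_s = (0:9) * 2.56,
                    fused_label = lab)
  ev <- decisions_to_events(dec, 2.56)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_s, 3 * 2.56)   # 7.68
  expect_equal(ev$end_s, 6 * 2.56)     # 15.36

  none <- decisions_to_events(transform(dec, fused_label = "NON_FM"), 2.56)
  expect_equal(nrow(none), 0L)

  lab2 <- rep("NON_FM", 10); lab2[c(3, 8)] <- "FM"
  two <- decisions_to_events(transform(dec, fused_label = lab2), 2.56)
  expect_equal(nrow(two), 2L)
})

test_that("metrics arithmetic follows the published definition and rounding", {
  m1 <- metrics_from_counts(TMF = 39, DME = 35, FD = 4)
  expect_equal(m1$TDR, 89.74)
  expect_equal(m1$PPV, 89.74)
  m2 <- metrics_from_counts(TMF = 39, DME = 36, FD = 8)
  expect_equal(m2$TDR, 92.31)
  expect_equal(m2$PPV, 81.82)
  m3 <- metrics_from_counts(TMF = 10, DME = 10, FD = 0)
  expect_equal(m3$TDR, 100)
  expect_equal(m3$PPV, 100)
  expect_error(metrics_from_counts(0, 0, 0), "TMF == 0")
  expect_error(metrics_from_counts(5, 6, 0), "DME <= TMF")
})

test_that("compute_metrics counts overlaps once per truth event", {
  truth <- data.frame(start_s = c(10, 50, 100), end_s = c(12.56, 52.56, 102.56))
  det <- data.frame(start_s = c(9, 11, 200), end_s = c(11, 13, 202))
  # two detected events overlap truth 1 -> one DME, no extra FD;
  # the event at 200 s matches nothing -> FD
  m <- compute_metrics(det, truth)
  expect_equal(m$TMF, 3L)
  expect_equal(m$DME, 1L)
  expect_equal(m$FD, 1L)
  expect_equal(m$TDR, 33.33)
  expect_equal(m$PPV, 50)
  # order invariance
  m2 <- compute_metrics(det[c(3, 1, 2), ], truth)
  expect_equal(m2$DME, m$DME)
  expect_equal(m2$FD, m$FD)
  # empty detection: PPV defined as 0
  m0 <- compute_metrics(det[0, ], truth)
  expect_equal(m0$DME, 0L)
  expect_equal(m0$PPV, 0)
  expect_error(compute_metrics(det, truth[0, ]), "metrics undefined")
})

test_that("metrics monotonicity: helpful events raise TDR, junk lowers PPV", {
  truth <- data.frame(start_s = c(10, 50), end_s = c(12.56, 52.56))
  det <- data.frame(start_s = 9, end_s = 11)
  base <- compute_metrics(det, truth)
  plus_hit <- compute_metrics(rbind(det, c(49, 51)), truth)
  expect_gte(plus_hit$TDR, base$TDR)
  plus_junk <- compute_metrics(rbind(det, c(200, 202)), truth)
  expect_lte(plus_junk$PPV, base$PPV)
  expect_equal(plus_junk$TDR, base$TDR)
  # DME can never exceed min(TMF, detected count)
  expect_lte(plus_junk$DME, min(plus_junk$TMF, 2))
})

test_that("metrics tables serialize with the standard columns", {
  path <- tempfile(fileext = ".tsv")
  write_metrics(list(metrics_from_counts(12, 11, 1, subject = 1),
                     metrics_from_counts(39, 35, 4, subject = "All")), path)
  tab <- read.delim(path)
  expect_equal(names(tab), c("subject", "TMF", "DME", "FD", "TDR", "PPV"))
  expect_equal(tab$TDR, c(91.67, 89.74))
})
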