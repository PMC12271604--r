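test_that("metric formulas handle degenerate counts", {
  expect_equal(unname(svMetrics(0, 5, 5)), c(0, 0, 0))
  expect_equal(unname(svMetrics(10, 0, 0)), c(1, 1, 1))
  m <- svMetrics(30, 10, 20)
  expect_equal(unname(m["recall"]), 0.6)
  expect_equal(unname(m["precision"]), 0.75)
  expect_equal(unname(m["f1"]), 2 * 0.6 * 0.75 / 1.35)
})

test_that("percent formatting rounds half-up to one decimal", {
  expect_equal(fmtPct(0.7295), "73.0")
  expect_equal(fmtPct(0.51551), "51.6")
  expect_equal(fmtPct(0.99995), "100.0")
  expect_equal(fmtPct(NA), "NA")
})

make_classified <- function(seed, n_sv = 15, split = 0.3, drop = 0.1,
                            fp = 0.2) {
  simref <- simulateReference(120000, seed = seed)
  truth <- simulateTruth(simref$ref, n_sv, seed = seed)
  pert <- perturbCallset(truth, simref$ref,
                         perturbationSpec(split_fraction = split,
                                          dropout_rate = drop, fp_rate = fp,
                                          seed = seed + 1))
  cl <- reclassify(matchCallset(pert$callset, truth$callset, simref$ref),
                   simref$ref)
  list(cl = cl, truth = truth, pert = pert, ref = simref$ref)
}

test_that("size bins partition the counts", {
  x <- make_classified(81)
  s <- summarizeClassification(x$cl)
  pb <- s@perBin
  expect_equal(sum(pb$TP), unname(s@counts["TP"]))
  expect_equal(sum(pb$FN), unname(s@counts["FN"]))
  expect_equal(sum(pb$FP), unname(s@counts["FP"]))
  expect_equal(sum(pb$LP), unname(s@counts["LP"]))
  bins <- defaultSizeBins()
  expect_equal(svcompare:::binOf(50, bins), 1)       # [20,100)
  expect_equal(svcompare:::binOf(12000, bins), 8)    # [10000,50000]
  expect_equal(svcompare:::binOf(50000, bins), 8)    # closed last edge
  expect_equal(svcompare:::binLabels(bins)[1], "[20,100)")
  expect_equal(svcompare:::binLabels(bins)[8], "[10000,50000]")
})

test_that("deviation statistics follow the d and r definitions", {
  mt <- data.frame(d = c(0, 100, 10, 10, 10), r = c(1, 101 / 201, 1, 1.05, 3),
                   via_merge = FALSE)
  dev <- deviationStats(mt)
  expect_equal(dev$frac_d50, 4 / 5)
  expect_equal(dev$frac_r_band, 3 / 5)
  expect_equal(dev$r[2], 101 / 201)
  # a systematic +10 bp shift dominates the d histogram
  expect_equal(as.integer(names(which.max(table(dev$d)))), 10)
})

test_that("matched pairs record d and r consistently with their coordinates", {
  x <- make_classified(82)
  mt <- matchResults(x$cl)
  direct <- mt[!mt$via_merge, ]
  qt <- svcompare:::svTable(x$pert$callset)
  bt <- svcompare:::svTable(x$truth$callset)
  for (j in seq_len(nrow(direct))) {
    q <- qt[qt$recordID == direct$query_id[j], ]
    b <- bt[bt$recordID == direct$bench_id[j], ]
    expect_equal(direct$d[j], q$pos - b$pos)
    expect_equal(direct$r[j], (q$end - q$pos + 1) / (b$end - b$pos + 1))
  }
})

test_that("TP overlap tables obey set algebra and reject foreign benchmarks", {
  x <- make_classified(83)
  y_pert <- perturbCallset(x$truth, x$ref,
                           perturbationSpec(split_fraction = 0,
                                            dropout_rate = 0.4, fp_rate = 0,
                                            seed = 991), source = "c2")
  cl2 <- reclassify(matchCallset(y_pert$callset, x$truth$callset, x$ref),
                    x$ref)
  ov <- tpOverlap(list(A = x$cl, B = cl2))
  tpA <- names(benchLabels(x$cl))[benchLabels(x$cl) == "TP"]
  tpB <- names(benchLabels(cl2))[benchLabels(cl2) == "TP"]
  expect_equal(sum(ov$count), length(union(tpA, tpB)))
  both <- ov$count[ov$combination == "A&B"]
  expect_equal(if (length(both)) both else 0L, length(intersect(tpA, tpB)))
  # identical classifications: everything lands in the shared combination
  ov2 <- tpOverlap(list(A = x$cl, B = x$cl))
  expect_equal(ov2$combination, "A&B")
  expect_equal(ov2$count, length(tpA))
  ov3 <- tpOverlap(list(only = x$cl))
  expect_equal(ov3$count, length(tpA))
  z <- make_classified(84, n_sv = 10)
  expect_error(tpOverlap(list(A = x$cl, B = z$cl)), "benchmark")
})

test_that("reports render deterministically and survive empty callsets", {
  x <- make_classified(85)
  s <- summarizeClassification(x$cl)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  ov <- tpOverlap(list(caller1 = x$cl))
  p1 <- renderReport(list(s), ov, x$cl@config, d1)
  p2 <- renderReport(list(s), ov, x$cl@config, d2)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  html <- paste(readLines(p1[["html"]]), collapse = "\n")
  expect_match(html, "caller1")
  expect_match(html, "SeqSim")
  # empty callset: all zero counts, no crash
  empty <- svcompare:::callSetFromRecords(data.frame(), "none")
  cl0 <- matchCallset(empty, x$truth$callset, x$ref)
  s0 <- summarizeClassification(cl0)
  expect_equal(unname(s0@counts["TP"]), 0)
  expect_equal(unname(s0@counts["FN"]), length(x$truth$callset))
  expect_silent(renderReport(list(s0), NULL, cl0@config,
                             file.path(tempdir(), "rep0")))
})

test_that("per-class VCF output tags classes and merge links", {
  x <- make_classified(86, split = 0.5, drop = 0.2, fp = 0.3)
  out <- file.path(tempdir(), "classvcf")
  paths <- writeClassVcfs(x$cl, out)
  expect_true(all(file.exists(paths)))
  lp_lines <- readLines(paths[["lp"]])
  lp_body <- lp_lines[!startsWith(lp_lines, "#")]
  expect_equal(length(lp_body), lpCount(x$cl))
  if (length(lp_body)) {
    expect_true(all(grepl("ASVBM_CLASS=LP", lp_body)))
    expect_true(all(grepl("ASVBM_MERGE_ID=", lp_body)))
  }
  fn_lines <- readLines(paths[["fn"]])
  expect_equal(sum(!startsWith(fn_lines, "#")), fnCount(x$cl))
  tp_back <- readSVVcf(paths[["tp"]], matchConfig(), "tp")
  expect_equal(length(tp_back), sum(callLabels(x$cl) == "TP"))
})
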