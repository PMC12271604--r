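make_callset <- function(recs, source = "t") {
  df <- do.call(rbind, lapply(recs, function(r) {
    data.frame(chrom = r$chrom, pos = r$pos, end = r$end, svtype = r$svtype,
               svlen = r$svlen, seq = r$seq,
               refCol = ifelse(is.na(r$seq), "N",
                               ifelse(r$svtype == "DEL",
                                      paste0("N", r$seq), "N")),
               altCol = ifelse(is.na(r$seq), paste0("<", r$svtype, ">"),
                               ifelse(r$svtype == "DEL", "N",
                                      paste0("N", r$seq))),
               symbolic = r$symbolic, recordID = r$recordID,
               genotype = NA_character_, stringsAsFactors = FALSE)
  }))
  svcompare:::callSetFromRecords(df, source)
}

test_that("candidate search honours the two-stage window rules", {
  cfg <- matchConfig()
  set.seed(31)
  bench <- make_callset(list(
    rec(pos = 1000, svtype = "INS", svlen = 50, seq = rand_seq(50), symbolic = FALSE, id = "b1"),
    rec(pos = 5000, svtype = "INS", svlen = 50, seq = rand_seq(50), symbolic = FALSE, id = "b2"),
    rec(pos = 9000, svtype = "INS", svlen = 50, seq = rand_seq(50), symbolic = FALSE, id = "b3")))
  ref <- ref_from_seq(rand_seq(10000))
  idx <- buildBenchmarkIndex(bench, NULL)
  idx$chromLens["chr1"] <- 1e6                    # 1 Mbp contig -> w0 = 200
  q <- rec(pos = 5050, svtype = "INS", svlen = 50, seq = rand_seq(50), symbolic = FALSE)
  expect_equal(candidateSearch(q, idx, cfg)$recordID, "b2")
  # stage 2: empty 200 bp window, 150 bp query widens to 1 kbp + size band
  bench2 <- make_callset(list(
    rec(pos = 5000, svtype = "INS", svlen = 150, seq = rand_seq(150), symbolic = FALSE, id = "b1")))
  idx2 <- buildBenchmarkIndex(bench2, NULL)
  idx2$chromLens["chr1"] <- 1e6
  q2 <- rec(pos = 5900, svtype = "INS", svlen = 150, seq = rand_seq(150), symbolic = FALSE)
  expect_equal(candidateSearch(q2, idx2, cfg)$recordID, "b1")
  # same distance but a size ratio outside the band is filtered in stage 2;
  # the >100 bp benchmark record is still retrieved for completeness
  q3 <- rec(pos = 5900, svtype = "INS", svlen = 110, seq = rand_seq(110), symbolic = FALSE)
  cand3 <- candidateSearch(q3, idx2, cfg)
  expect_true(nrow(cand3) >= 1)                   # gated later by criteria
  q4 <- rec(chrom = "chr9", pos = 100, svtype = "INS", svlen = 50,
            seq = rand_seq(50), symbolic = FALSE)
  expect_equal(nrow(candidateSearch(q4, idx, cfg)), 0)
})

test_that("the best match is allele-aware by sequence similarity", {
  set.seed(32)
  cfg <- matchConfig()
  s60 <- rand_seq(60); s80 <- rand_seq(80)
  bench <- make_callset(list(
    rec(pos = 2000, svtype = "INS", svlen = 60, seq = s60, symbolic = FALSE, id = "a60"),
    rec(pos = 2000, svtype = "INS", svlen = 80, seq = s80, symbolic = FALSE, id = "a80")))
  idx <- buildBenchmarkIndex(bench, NULL)
  q <- rec(pos = 2001, svtype = "INS", svlen = 79,
           seq = substr(s80, 1, 79), symbolic = FALSE)
  cand <- candidateSearch(q, idx, cfg)
  m <- matchOne(q, cand, NULL, cfg)
  expect_equal(m$bench_id, "a80")
  # identical single candidate: d = 0, r = 1, similarity 1
  qi <- rec(pos = 2000, svtype = "INS", svlen = 60, seq = s60, symbolic = FALSE)
  m2 <- matchOne(qi, cand, NULL, cfg)
  expect_equal(m2$d, 0)
  expect_equal(m2$r, 1)
  expect_equal(m2$seq_sim, 1)
  # all candidates below the size-similarity threshold: no match
  qs <- rec(pos = 2000, svtype = "INS", svlen = 25, seq = rand_seq(25), symbolic = FALSE)
  expect_null(matchOne(qs, cand, NULL, cfg))
})

test_that("identical and disjoint callsets classify trivially", {
  set.seed(33)
  simref <- simulateReference(100000, seed = 33)
  truth <- simulateTruth(simref$ref, 12, seed = 33)
  cl <- matchCallset(truth$callset, truth$callset, simref$ref)
  expect_equal(tpCount(cl), 12)
  expect_equal(fpCount(cl), 0)
  expect_equal(fnCount(cl), 0)
  # shifted far away: everything disjoint
  far <- svcompare:::svTable(truth$callset)
  m <- S4Vectors::mcols(svRanges(truth$callset))
  df <- data.frame(chrom = far$chrom, pos = far$pos + 40000,
                   end = far$end + 40000, svtype = far$svtype,
                   svlen = far$svlen, seq = m$seq, refCol = m$refCol,
                   altCol = m$altCol, symbolic = m$symbolic,
                   recordID = paste0("x_", far$recordID),
                   genotype = NA_character_, stringsAsFactors = FALSE)
  df <- df[df$end < 100000, ]
  calls <- svcompare:::callSetFromRecords(df, "far")
  cl2 <- matchCallset(calls, truth$callset, simref$ref)
  expect_equal(tpCount(cl2), 0)
  expect_equal(fpCount(cl2), length(calls))
  expect_equal(fnCount(cl2), length(truth$callset))
})

test_that("TP + FN always equals the benchmark size and thresholds are monotone", {
  for (sd in c(41, 42)) {
    simref <- simulateReference(120000, seed = sd)
    truth <- simulateTruth(simref$ref, 15, seed = sd)
    pert <- perturbCallset(truth, simref$ref,
                           perturbationSpec(split_fraction = 0.2,
                                            dropout_rate = 0.2, fp_rate = 0.3,
                                            seed = sd))
    for (thr in c(0.7, 0.8, 0.95)) {
      cfg <- matchConfig(seq_sim_threshold = thr, size_sim_threshold = thr)
      cl <- matchCallset(pert$callset, truth$callset, simref$ref, cfg)
      expect_equal(tpCount(cl) + fnCount(cl), length(truth$callset))
    }
    tp_by_thr <- vapply(c(0.7, 0.9, 0.99), function(thr)
      tpCount(matchCallset(pert$callset, truth$callset, simref$ref,
                           matchConfig(seq_sim_threshold = thr,
                                       size_sim_threshold = thr))),
      numeric(1))
    expect_true(all(diff(tp_by_thr) <= 0))
  }
})

test_that("classification is identical across repeated runs and thread settings", {
  simref <- simulateReference(100000, seed = 51)
  truth <- simulateTruth(simref$ref, 12, seed = 51)
  pert <- perturbCallset(truth, simref$ref,
                         perturbationSpec(split_fraction = 0.3,
                                          dropout_rate = 0.1, fp_rate = 0.2,
                                          seed = 52))
  run <- function(threads) {
    cfg <- matchConfig(threads = threads)
    cl <- reclassify(matchCallset(pert$callset, truth$callset, simref$ref,
                                  cfg), simref$ref, cfg)
    list(callLabels(cl), benchLabels(cl), matchResults(cl))
  }
  expect_identical(run(1), run(1))
  expect_identical(run(1), run(8))
})
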