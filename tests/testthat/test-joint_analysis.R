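fp_frame <- function(recs) {
  do.call(rbind, lapply(recs, function(r)
    data.frame(idx = NA_integer_, chrom = r$chrom, pos = r$pos, end = r$end,
               svtype = r$svtype, svlen = r$svlen, seq = r$seq,
               symbolic = r$symbolic, recordID = r$recordID,
               best_seq_sim = r$best %||% NA_real_,
               stringsAsFactors = FALSE)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("superclusters group by type within the gap and drop singletons", {
  set.seed(61)
  cfg <- matchConfig()
  fp <- fp_frame(list(
    rec(pos = 1000, svtype = "INS", svlen = 49, seq = rand_seq(49), symbolic = FALSE, id = "i1"),
    rec(pos = 1049, svtype = "INS", svlen = 98, seq = rand_seq(98), symbolic = FALSE, id = "i2"),
    rec(pos = 5000, svtype = "DEL", svlen = 60, seq = rand_seq(60), symbolic = FALSE, id = "d1")))
  cls <- buildSuperclusters(fp, cfg)
  expect_length(cls, 1)
  expect_equal(cls[[1]]$svtype, "INS")
  expect_equal(cls[[1]]$members$recordID, c("i1", "i2"))
  expect_equal(cls[[1]]$combined_len, 147)
  # gap beyond the threshold: no cluster
  far <- fp_frame(list(
    rec(pos = 1000, svtype = "INS", svlen = 49, seq = rand_seq(49), symbolic = FALSE, id = "i1"),
    rec(pos = 6000, svtype = "INS", svlen = 98, seq = rand_seq(98), symbolic = FALSE, id = "i2")))
  expect_length(buildSuperclusters(far, cfg), 0)
})

test_that("coordinate-overlapping members are reduced to the best-scoring allele", {
  set.seed(62)
  cfg <- matchConfig()
  fp <- fp_frame(list(
    c(rec(pos = 1000, svtype = "INS", svlen = 40, seq = rand_seq(40), symbolic = FALSE, id = "keep"), best = 0.9),
    c(rec(pos = 1000, svtype = "INS", svlen = 45, seq = rand_seq(45), symbolic = FALSE, id = "eject"), best = 0.4),
    c(rec(pos = 1100, svtype = "INS", svlen = 50, seq = rand_seq(50), symbolic = FALSE, id = "other"), best = NA_real_)))
  cls <- buildSuperclusters(fp, cfg)
  expect_length(cls, 1)
  expect_setequal(cls[[1]]$members$recordID, c("keep", "other"))
})

test_that("a split insertion validates as a merge with the combined length", {
  set.seed(63)
  cfg <- matchConfig()
  simref <- simulateReference(20000, seed = 63)
  ref <- simref$ref
  ins <- rand_seq(147)
  target <- rec(pos = 10000, svtype = "INS", svlen = 147, seq = ins,
                symbolic = FALSE, id = "bench1")
  fp <- fp_frame(list(
    rec(pos = 10000, svtype = "INS", svlen = 49, seq = substr(ins, 1, 49),
        symbolic = FALSE, id = "p1"),
    rec(pos = 10002, svtype = "INS", svlen = 98, seq = substr(ins, 50, 147),
        symbolic = FALSE, id = "p2")))
  cls <- buildSuperclusters(fp, cfg)
  v <- validateCluster(cls[[1]], target, ref, cfg)
  expect_false(is.null(v))
  expect_equal(v$combined_len, 147)
  expect_setequal(v$member_ids, c("p1", "p2"))
  expect_gte(v$seq_sim, cfg@seqSimThreshold)
  # same sizes but unrelated random sequences fail the sequence gate
  fp_bad <- fp_frame(list(
    rec(pos = 10000, svtype = "INS", svlen = 49, seq = rand_seq(49),
        symbolic = FALSE, id = "r1"),
    rec(pos = 10002, svtype = "INS", svlen = 98, seq = rand_seq(98),
        symbolic = FALSE, id = "r2")))
  cls_bad <- buildSuperclusters(fp_bad, cfg)
  expect_null(validateCluster(cls_bad[[1]], target, ref, cfg))
})

test_that("six adjacent deletions validate against one 300 bp benchmark deletion", {
  set.seed(64)
  cfg <- matchConfig()
  simref <- simulateReference(20000, seed = 64)
  ref <- simref$ref
  p <- 8000
  target <- rec(pos = p, svtype = "DEL", svlen = 300,
                seq = refWindow(ref, "chr1", p + 1, p + 300),
                symbolic = FALSE, id = "benchdel")
  parts <- lapply(0:5, function(j) {
    pp <- p + j * 50
    rec(pos = pp, svtype = "DEL", svlen = 50,
        seq = refWindow(ref, "chr1", pp + 1, pp + 50),
        symbolic = FALSE, id = sprintf("d%d", j + 1))
  })
  cls <- buildSuperclusters(fp_frame(parts), cfg)
  v <- validateCluster(cls[[1]], target, ref, cfg)
  expect_false(is.null(v))
  expect_length(v$member_ids, 6)
  expect_equal(v$combined_len, 300)
})

test_that("reclassification leaves runs without FNs untouched", {
  simref <- simulateReference(80000, seed = 65)
  truth <- simulateTruth(simref$ref, 8, seed = 65)
  cl <- matchCallset(truth$callset, truth$callset, simref$ref)
  expect_equal(fnCount(cl), 0)
  cl2 <- reclassify(cl, simref$ref)
  expect_identical(callLabels(cl), callLabels(cl2))
  expect_identical(benchLabels(cl), benchLabels(cl2))
})

test_that("splitting every truth variant yields all-LP calls and full recall", {
  simref <- simulateReference(150000, seed = 66)
  truth <- simulateTruth(simref$ref, 12, seed = 66,
                         size_distribution = function(n) sample(120:400, n, TRUE))
  pert <- perturbCallset(truth, simref$ref,
                         perturbationSpec(split_fraction = 1, dropout_rate = 0,
                                          fp_rate = 0, seed = 67))
  first <- matchCallset(pert$callset, truth$callset, simref$ref)
  expect_equal(tpCount(first), 0)
  post <- reclassify(first, simref$ref)
  expect_equal(lpCount(post), length(pert$callset))
  expect_equal(fnCount(post), 0)
  expect_equal(tpCount(post), length(truth$callset))
  mt <- matchResults(post)
  expect_true(all(mt$via_merge))
  expect_equal(sort(mt$merge_len), sort(svcompare:::svTable(truth$callset)$svlen))
})

test_that("joint analysis never decreases TP nor increases FP or FN", {
  for (sd in 71:73) {
    simref <- simulateReference(120000, seed = sd)
    truth <- simulateTruth(simref$ref, 15, seed = sd)
    pert <- perturbCallset(truth, simref$ref,
                           perturbationSpec(split_fraction = 0.4,
                                            dropout_rate = 0.15,
                                            fp_rate = 0.3, seed = sd + 100))
    first <- matchCallset(pert$callset, truth$callset, simref$ref)
    post <- reclassify(first, simref$ref)
    expect_gte(tpCount(post), tpCount(first))
    expect_lte(fpCount(post), fpCount(first))
    expect_lte(fnCount(post), fnCount(first))
    expect_equal(tpCount(post) + fnCount(post), length(truth$callset))
    expect_equal(fpCount(post) + lpCount(post) +
                   sum(callLabels(post) == "TP"), length(pert$callset))
  }
})
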