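test_that("extension length is 200 bp up to 100 bp and 1 kbp above", {
  expect_equal(extendLength(50), 200)
  expect_equal(extendLength(100), 200)
  expect_equal(extendLength(101), 1000)
  expect_equal(extendLength(5000), 1000)
  expect_error(extendLength(0))
})

test_that("type compatibility is exact in strict mode, INS~DUP in loose", {
  expect_true(typeCompatible("DEL", "DEL", "strict"))
  expect_false(typeCompatible("INS", "DUP", "strict"))
  expect_true(typeCompatible("INS", "DUP", "loose"))
  expect_true(typeCompatible("DUP", "INS", "loose"))
  expect_false(typeCompatible("DEL", "INV", "loose"))
})

test_that("overlap uses per-type extended spans", {
  cfg <- matchConfig()
  a <- rec(pos = 1000, svtype = "DEL", svlen = 100, seq = "x", symbolic = FALSE)
  b <- rec(pos = 1350, svtype = "DEL", svlen = 100, seq = "x", symbolic = FALSE)
  expect_equal(overlapStatus(a, b, cfg), "overlap")     # [800,1299] vs [1150,1649]
  i1 <- rec(pos = 5000, svtype = "INS", svlen = 30, seq = "x", symbolic = FALSE)
  i2 <- rec(pos = 5150, svtype = "INS", svlen = 30, seq = "x", symbolic = FALSE)
  i3 <- rec(pos = 5300, svtype = "INS", svlen = 30, seq = "x", symbolic = FALSE)
  expect_equal(overlapStatus(i1, i2, cfg), "overlap")   # fixed +/-100 rule
  expect_equal(overlapStatus(i1, i3, cfg), "disjoint")
  i4 <- rec(chrom = "chr2", pos = 5000, svtype = "INS", svlen = 30, seq = "x",
            symbolic = FALSE)
  expect_equal(overlapStatus(i1, i4, cfg), "disjoint")
})

test_that("size similarity is min over max of the lengths", {
  expect_equal(sizeSimilarity(147, 147), 1)
  expect_equal(sizeSimilarity(146, 147), 146 / 147)
  expect_equal(sizeSimilarity(49, 147), 1 / 3)
  expect_equal(sizeSimilarity(49, 147), sizeSimilarity(147, 49))
})

test_that("the relief-factor score credits long gap runs", {
  cfg <- matchConfig()
  aln <- nwAlign("AAAATTTTCCCC", "AAAACCCC", cfg)
  expect_equal(aln$aln1, "AAAATTTTCCCC")
  expect_equal(aln$aln2, "AAAA----CCCC")
  st <- alignmentStats(aln$aln1, aln$aln2)
  expect_equal(st$M, 8)
  expect_equal(st$G, 4)
  expect_equal(st$aln_len, 12)
  a <- rec(pos = 100, svtype = "INS", svlen = 12, seq = "AAAATTTTCCCC",
           symbolic = FALSE)
  b <- rec(pos = 100, svtype = "INS", svlen = 8, seq = "AAAACCCC",
           symbolic = FALSE)
  expect_equal(sequenceSimilarity(a, b, NULL, cfg), (8 + 4 * 0.5) / 12)
  cfg0 <- matchConfig(relief_factor = 0)
  expect_equal(sequenceSimilarity(a, b, NULL, cfg0), 8 / 12)
})

test_that("sequence similarity of a record with itself is 1", {
  set.seed(11)
  for (L in c(1, 5, 30, 200)) {
    s <- rand_seq(L)
    a <- rec(pos = 1000, svtype = "INS", svlen = L, seq = s, symbolic = FALSE)
    expect_equal(sequenceSimilarity(a, a, NULL, matchConfig()), 1)
  }
})

test_that("pairwise criteria are symmetric in their arguments", {
  set.seed(12)
  cfg <- matchConfig()
  for (k in 1:20) {
    L1 <- sample(20:200, 1); L2 <- sample(20:200, 1)
    a <- rec(pos = sample(1000:2000, 1), svtype = sample(c("INS", "DEL"), 1),
             svlen = L1, seq = rand_seq(L1), symbolic = FALSE)
    b <- rec(pos = sample(1000:2000, 1), svtype = a$svtype,
             svlen = L2, seq = rand_seq(L2), symbolic = FALSE)
    expect_equal(sizeSimilarity(a, b), sizeSimilarity(b, a))
    expect_equal(overlapStatus(a, b, cfg), overlapStatus(b, a, cfg))
    expect_equal(sequenceSimilarity(a, b, NULL, cfg),
                 sequenceSimilarity(b, a, NULL, cfg))
  }
})

test_that("raising the relief factor never lowers a similarity score", {
  set.seed(13)
  rfs <- c(0, 0.25, 0.5, 0.75, 1)
  for (k in 1:10) {
    L1 <- sample(20:120, 1); L2 <- sample(20:120, 1)
    a <- rec(pos = 1000, svtype = "INS", svlen = L1, seq = rand_seq(L1),
             symbolic = FALSE)
    b <- rec(pos = 1000, svtype = "INS", svlen = L2, seq = rand_seq(L2),
             symbolic = FALSE)
    sc <- vapply(rfs, function(rf)
      sequenceSimilarity(a, b, NULL, matchConfig(relief_factor = rf)),
      numeric(1))
    expect_true(all(diff(sc) >= -1e-12))
  }
})

test_that("the shared-context score can rescue placement differences", {
  set.seed(14)
  # a 20 bp tandem unit repeated through 2001..2120: inserting four extra
  # copies at 2000, or a rotated representation at 2030, spells the same
  # haplotype -- only the shared-context alignment can see that
  unit <- rand_seq(20)
  refseq <- paste0(rand_seq(2000), strrep(unit, 6), rand_seq(2000))
  ref <- ref_from_seq(refseq)
  ins_a <- strrep(unit, 4)
  ins_b <- substr(strrep(unit, 5), 11, 90)      # rotation by 10 bp
  a <- rec(pos = 2000, svtype = "INS", svlen = 80, seq = ins_a, symbolic = FALSE)
  b <- rec(pos = 2030, svtype = "INS", svlen = 80, seq = ins_b, symbolic = FALSE)
  raw <- sequenceSimilarity(a, b, NULL, matchConfig())
  with_ctx <- sequenceSimilarity(a, b, ref, matchConfig())
  expect_equal(with_ctx, 1)
  expect_gte(with_ctx, raw)
})

test_that("symbolic pairs have no sequence score and the criterion is vacuous", {
  cfg <- matchConfig(match_mode = "loose")
  dup <- rec(pos = 1010, svtype = "DUP", svlen = 80)
  ins <- rec(pos = 1000, svtype = "INS", svlen = 80, seq = rand_seq(80),
             symbolic = FALSE)
  expect_true(is.na(sequenceSimilarity(ins, dup, NULL, cfg)))
  ev <- evaluatePair(ins, dup, NULL, cfg)
  expect_true(ev$type_ok)
  expect_true(ev$all_pass)
  expect_true(is.na(ev$seq_sim))
  ev_strict <- evaluatePair(ins, dup, NULL, matchConfig())
  expect_false(ev_strict$type_ok)
  expect_false(ev_strict$all_pass)
})

test_that("the reference-distance criterion uses the larger variant's extension", {
  cfg <- matchConfig()
  a <- rec(pos = 1000, svtype = "DEL", svlen = 300, seq = rand_seq(300),
           symbolic = FALSE)
  b <- rec(pos = 2500, svtype = "DEL", svlen = 300, seq = rand_seq(300),
           symbolic = FALSE)
  ev <- evaluatePair(a, b, NULL, cfg)
  expect_false(ev$distance_ok)       # 1500 > 1000
  expect_false(ev$all_pass)
  ident <- rec(pos = 1000, svtype = "INS", svlen = 50, seq = rand_seq(50),
               symbolic = FALSE)
  ev2 <- evaluatePair(ident, ident, NULL, cfg)
  expect_true(ev2$all_pass)
  expect_equal(ev2$seq_sim, 1)
  expect_equal(ev2$size_sim, 1)
})
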