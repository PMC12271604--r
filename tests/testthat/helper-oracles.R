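# Shared helpers: independent oracles and small record constructors.

rand_seq <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, sub_rate = 0.02, n_indel = 0, indel_max = 5) {
  v <- strsplit(s, "")[[1]]
  i <- which(runif(length(v)) < sub_rate)
  if (length(i)) v[i] <- sample(c("A", "C", "G", "T"), length(i), TRUE)
  s <- paste(v, collapse = "")
  for (k in seq_len(n_indel)) {
    at <- sample.int(nchar(s) - indel_max - 1, 1)
    l <- sample.int(indel_max, 1)
    s <- if (runif(1) < 0.5)
      paste0(substr(s, 1, at), rand_seq(l), substr(s, at + 1, nchar(s)))
    else
      paste0(substr(s, 1, at), substr(s, at + l + 1, nchar(s)))
  }
  s
}

# Minimal record constructor matching the internal record shape.
rec <- function(chrom = "chr1", pos, svtype, svlen, seq = NA_character_,
                symbolic = is.na(seq), id = sprintf("%s_%d", svtype, pos)) {
  end <- if (svtype == "INS") pos else pos + svlen - 1
  list(idx = NA_integer_, chrom = chrom, pos = pos, end = end,
       svtype = svtype, svlen = svlen, seq = seq, symbolic = symbolic,
       recordID = id)
}

ref_from_seq <- function(seq, chrom = "chr1") {
  svcompare:::svReference(setNames(list(seq), chrom))
}

# Independent plain-R Needleman-Wunsch with the same scoring and the same
# traceback preference (diagonal, then gap-in-second, then gap-in-first).
nw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  S <- matrix(0, n + 1, m + 1)
  D <- matrix(0L, n + 1, m + 1)         # 0 diag, 1 up, 2 left
  S[1, ] <- (0:m) * gap; D[1, ] <- 2L
  S[, 1] <- (0:n) * gap; D[, 1] <- 1L
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sc <- c(S[i, j] + ifelse(av[i] == bv[j], match, mismatch),
            S[i, j + 1] + gap, S[i + 1, j] + gap)
    k <- which.max(sc)                  # which.max takes the first maximum
    S[i + 1, j + 1] <- sc[k]; D[i + 1, j + 1] <- k - 1L
  }
  r1 <- character(); r2 <- character()
  i <- n; j <- m
  while (i > 0 || j > 0) {
    d <- D[i + 1, j + 1]
    if (i > 0 && j > 0 && d == 0L) {
      r1 <- c(av[i], r1); r2 <- c(bv[j], r2); i <- i - 1; j <- j - 1
    } else if (i > 0 && (d == 1L || j == 0)) {
      r1 <- c(av[i], r1); r2 <- c("-", r2); i <- i - 1
    } else {
      r1 <- c("-", r1); r2 <- c(bv[j], r2); j <- j - 1
    }
  }
  list(aln1 = paste(r1, collapse = ""), aln2 = paste(r2, collapse = ""),
       score = S[n + 1, m + 1])
}

# Independent M/G counter over a gapped alignment.
aln_stats_oracle <- function(aln1, aln2, run_min = 3) {
  v1 <- strsplit(aln1, "")[[1]]; v2 <- strsplit(aln2, "")[[1]]
  M <- sum(v1 == v2 & v1 != "-")
  G <- 0
  for (v in list(v1, v2)) {
    r <- rle(v == "-")
    G <- G + sum(r$lengths[r$values & r$lengths >= run_min])
  }
  list(M = M, G = G, aln_len = length(v1))
}

# Exhaustive all-pairs matcher oracle: replicates search eligibility,
# five-criteria evaluation (via the package), best-match selection and
# benchmark-record consumption with naive scans instead of the index.
brute_force_match <- function(callset, benchmark, ref, config) {
  qt <- svcompare:::svTable(callset)
  bt <- svcompare:::svTable(benchmark)
  chrom_len <- vapply(split(bt$end, bt$chrom), max, numeric(1))
  if (!is.null(ref)) {
    cl <- chromLengths(ref)
    hit <- intersect(names(chrom_len), names(cl))
    chrom_len[hit] <- cl[hit]
  }
  consumed <- rep(FALSE, nrow(bt))
  call_lab <- rep("FP", nrow(qt))
  bench_lab <- rep("FN", nrow(bt))
  pairs <- list()
  for (i in seq_len(nrow(qt))) {
    q <- as.list(qt[i, , drop = FALSE])
    same <- which(bt$chrom == q$chrom)
    if (!length(same)) next
    w0 <- min(max(config@smallWindow, chrom_len[[q$chrom]] * 1e-5),
              config@expandedWindow)
    dist <- abs(bt$pos[same] - q$pos)
    stage1 <- same[dist <= w0 |
                     (bt$svlen[same] > 100 & dist <= config@expandedWindow)]
    cand <- stage1
    if (!length(stage1) && q$svlen >= 100) {
      wide <- same[dist <= config@expandedWindow]
      cand <- wide[vapply(wide, function(j) {
        typeCompatible(q$svtype, bt$svtype[j], config@matchMode) &&
          {
            r <- q$svlen / bt$svlen[j]
            r >= config@sizeRatioBand[1] && r <= config@sizeRatioBand[2]
          }
      }, logical(1))]
    }
    cand <- cand[!consumed[cand]]
    best <- NULL
    for (j in cand) {
      b <- as.list(bt[j, , drop = FALSE])
      ev <- evaluatePair(q, b, ref, config)
      if (!ev$all_pass) next
      score <- if (is.na(ev$seq_sim)) ev$size_sim else ev$seq_sim
      key <- c(-score, abs(q$pos - b$pos), b$pos)
      if (is.null(best) || lexicoLess(key, best$key))
        best <- list(j = j, key = key)
    }
    if (!is.null(best)) {
      consumed[best$j] <- TRUE
      call_lab[i] <- "TP"
      bench_lab[best$j] <- "TP"
      pairs[[length(pairs) + 1]] <-
        c(query = q$recordID, bench = bt$recordID[best$j])
    }
  }
  list(call = setNames(call_lab, qt$recordID),
       bench = setNames(bench_lab, bt$recordID),
       pairs = pairs)
}

lexicoLess <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

# Build the split-insertion fixture of the worked example: one benchmark
# insertion of `total` bp called as adjacent insertions of `parts` bp
# carrying the exact subsequences.
split_ins_fixture <- function(dir, seed = 1, total = 147, parts = c(49, 98),
                              ref_len = 50000, pos = 25000) {
  set.seed(seed)
  simref <- simulateReference(ref_len, seed = seed)
  ref <- simref$ref
  ins <- rand_seq(total)
  pad <- refWindow(ref, "chr1", pos, pos)
  bench_df <- data.frame(
    chrom = "chr1", pos = pos, end = pos, svtype = "INS", svlen = total,
    seq = ins, refCol = pad, altCol = paste0(pad, ins), symbolic = FALSE,
    recordID = "bench_ins", genotype = "0/1", stringsAsFactors = FALSE)
  off <- c(0, cumsum(parts))
  call_df <- do.call(rbind, lapply(seq_along(parts), function(j) {
    p <- pos + 2 * (j - 1)
    padj <- refWindow(ref, "chr1", p, p)
    core <- substr(ins, off[j] + 1, off[j + 1])
    data.frame(chrom = "chr1", pos = p, end = p, svtype = "INS",
               svlen = parts[j], seq = core, refCol = padj,
               altCol = paste0(padj, core), symbolic = FALSE,
               recordID = sprintf("call_part%d", j), genotype = "0/1",
               stringsAsFactors = FALSE)
  }))
  bench_vcf <- file.path(dir, "bench.vcf")
  calls_vcf <- file.path(dir, "calls.vcf")
  fasta <- file.path(dir, "ref.fa")
  writeSVVcf(svcompare:::callSetFromRecords(bench_df, "benchmark"), bench_vcf)
  writeSVVcf(svcompare:::callSetFromRecords(call_df, "caller"), calls_vcf)
  Biostrings::writeXStringSet(ref@sequences, fasta)
  list(ref = ref, bench_vcf = bench_vcf, calls_vcf = calls_vcf,
       fasta = fasta, ins = ins)
}
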