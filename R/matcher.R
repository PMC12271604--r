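#' Build a per-chromosome benchmark index
#'
#' Splits the filtered benchmark records into position-sorted
#' per-chromosome tables and records chromosome lengths (from the
#' reference when available, otherwise the rightmost record coordinate).
#'
#' @param benchmark an [SVCallSet-class].
#' @param ref optional [SVReference-class] supplying chromosome lengths.
#' @return A list with `byChrom` (named list of data.frames) and
#'   `chromLens` (named numeric).
#' @export
buildBenchmarkIndex <- function(benchmark, ref = NULL) {
  bt <- svTable(benchmark)
  by_chrom <- split(bt, bt$chrom)
  by_chrom <- lapply(by_chrom, function(d) d[order(d$pos, d$recordID), ])
  lens <- vapply(by_chrom, function(d) max(d$end), numeric(1))
  if (!is.null(ref)) {
    cl <- chromLengths(ref)
    hit <- intersect(names(lens), names(cl))
    lens[hit] <- cl[hit]
  }
  list(byChrom = by_chrom, chromLens = lens)
}

#' Two-stage candidate search in the benchmark index
#'
#' Stage 1 returns benchmark records whose start lies within
#' `w0 = min(max(small_window, chrom_len * 1e-5), expanded_window)` of the
#' query start; benchmark records longer than 100 bp are additionally
#' retrieved within the expanded window, since the reference-distance
#' criterion (governed by the larger variant of a pair) can accept them at
#' up to 1 kbp. When stage 1 is empty and the query is at least 100 bp
#' long, stage 2 widens the window to 1 kbp on each side and filters
#' candidates by type compatibility and a query/candidate size ratio
#' within the configured band.
#'
#' @param query an SV record (named list or one-row data.frame).
#' @param index a [buildBenchmarkIndex()] result.
#' @param config a [MatchConfig-class].
#' @return data.frame of candidate benchmark records (possibly empty).
#' @export
candidateSearch <- function(query, index, config = matchConfig()) {
  q <- asRec(query)
  tb <- index$byChrom[[q$chrom]]
  if (is.null(tb) || !nrow(tb)) return(tb %||% emptyCandidates())
  clen <- index$chromLens[[q$chrom]]
  w0 <- min(max(config@smallWindow, clen * 1e-5), config@expandedWindow)
  dist <- abs(tb$pos - q$pos)
  stage1 <- dist <= w0 | (tb$svlen > 100 & dist <= config@expandedWindow)
  if (any(stage1)) return(tb[stage1, , drop = FALSE])
  if (q$svlen >= 100) {
    stage2 <- dist <= config@expandedWindow
    if (any(stage2)) {
      cand <- tb[stage2, , drop = FALSE]
      ok <- vapply(seq_len(nrow(cand)), function(i) {
        typeCompatible(q$svtype, cand$svtype[i], config@matchMode) &&
          {
            r <- q$svlen / cand$svlen[i]
            r >= config@sizeRatioBand[1] && r <= config@sizeRatioBand[2]
          }
      }, logical(1))
      return(cand[ok, , drop = FALSE])
    }
  }
  emptyCandidates()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

emptyCandidates <- function() {
  data.frame(idx = integer(), chrom = character(), pos = numeric(),
             end = numeric(), svtype = character(), svlen = numeric(),
             seq = character(), symbolic = logical(),
             recordID = character(), stringsAsFactors = FALSE)
}

#' Allele-aware best match for one query
#'
#' Evaluates the five criteria against every candidate; among fully
#' passing candidates the one with the highest sequence similarity wins
#' (symbolic pairs, which have no sequence score, rank by size
#' similarity), with ties broken by smaller |d| and then by lower
#' benchmark position. `d` is the signed start difference (query minus
#' benchmark) and `r` the query/benchmark span-length ratio.
#'
#' @param query an SV record.
#' @param candidates data.frame from [candidateSearch()].
#' @param ref optional [SVReference-class].
#' @param config a [MatchConfig-class].
#' @return A list (`bench_idx`, `bench_id`, `seq_sim`, `size_sim`, `d`,
#'   `r`) or NULL when no candidate passes.
#' @export
matchOne <- function(query, candidates, ref = NULL, config = matchConfig()) {
  .matchOneImpl(query, candidates, ref, config)$result
}

# Internal: best match plus the best sequence similarity seen across all
# evaluated candidates (needed by the supercluster allele filter even for
# queries that end up unmatched).
.matchOneImpl <- function(query, candidates, ref, config) {
  q <- asRec(query)
  best_seen <- NA_real_
  if (is.null(candidates) || !nrow(candidates))
    return(list(result = NULL, best_seq_sim = best_seen))
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    b <- as.list(candidates[i, , drop = FALSE])
    ev <- evaluatePair(q, b, ref, config)
    if (!is.na(ev$seq_sim))
      best_seen <- max(best_seen, ev$seq_sim, na.rm = TRUE)
    if (ev$all_pass) {
      rows[[length(rows) + 1]] <- list(
        bench_idx = b$idx, bench_id = b$recordID,
        seq_sim = ev$seq_sim, size_sim = ev$size_sim,
        score = if (is.na(ev$seq_sim)) ev$size_sim else ev$seq_sim,
        d = q$pos - b$pos,
        r = (q$end - q$pos + 1) / (b$end - b$pos + 1),
        bpos = b$pos)
    }
  }
  if (!length(rows)) return(list(result = NULL, best_seq_sim = best_seen))
  sc <- vapply(rows, `[[`, numeric(1), "score")
  ad <- abs(vapply(rows, `[[`, numeric(1), "d"))
  bp <- vapply(rows, `[[`, numeric(1), "bpos")
  pick <- order(-sc, ad, bp)[1]
  list(result = rows[[pick]], best_seq_sim = best_seen)
}

#' First-pass classification of one callset against the benchmark
#'
#' Processes queries in genomic order; each matched query consumes its
#' benchmark record (one query per benchmark record and one benchmark
#' record per query, so the two records of a multi-allelic benchmark site
#' can be matched by two distinct queries). Matched queries become TP,
#' unmatched queries FP, unmatched benchmark records FN. Deterministic:
#' consumption conflicts resolve by query order.
#'
#' @param callset,benchmark [SVCallSet-class] objects (filtered, sorted).
#' @param ref optional [SVReference-class].
#' @param config a [MatchConfig-class].
#' @return An [SVClassification-class] (no LP labels yet; see
#'   [reclassify()]).
#' @export
matchCallset <- function(callset, benchmark, ref = NULL,
                         config = matchConfig()) {
  qt <- svTable(callset)
  index <- buildBenchmarkIndex(benchmark, ref)
  n_bench <- length(benchmark)
  consumed <- logical(n_bench)
  call_lab <- rep("FP", nrow(qt))
  bench_lab <- rep("FN", n_bench)
  best_seq <- rep(NA_real_, nrow(qt))
  mrows <- list()
  for (i in seq_len(nrow(qt))) {
    q <- as.list(qt[i, , drop = FALSE])
    cand <- candidateSearch(q, index, config)
    if (nrow(cand)) cand <- cand[!consumed[cand$idx], , drop = FALSE]
    mi <- .matchOneImpl(q, cand, ref, config)
    best_seq[i] <- mi$best_seq_sim
    m <- mi$result
    if (is.null(m)) next
    consumed[m$bench_idx] <- TRUE
    call_lab[i] <- "TP"
    bench_lab[m$bench_idx] <- "TP"
    mrows[[length(mrows) + 1]] <- data.frame(
      query_id = q$recordID, bench_id = m$bench_id,
      seq_sim = m$seq_sim, size_sim = m$size_sim,
      d = m$d, r = m$r, via_merge = FALSE,
      merge_id = NA_character_, merge_members = NA_character_,
      merge_len = NA_real_, stringsAsFactors = FALSE)
  }
  matches <- if (length(mrows)) do.call(rbind, mrows) else emptyMatches()
  new("SVClassification", callset = callset, benchmark = benchmark,
      callLabels = call_lab, benchLabels = bench_lab,
      matches = matches, bestSeqSim = best_seq, config = config)
}

emptyMatches <- function() {
  data.frame(query_id = character(), bench_id = character(),
             seq_sim = numeric(), size_sim = numeric(),
             d = numeric(), r = numeric(), via_merge = logical(),
             merge_id = character(), merge_members = character(),
             merge_len = numeric(), stringsAsFactors = FALSE)
}
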