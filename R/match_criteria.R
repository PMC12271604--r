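#' Length-dependent search/extension window
#'
#' Variants are extended by 200 bp when no longer than 100 bp and by 1 kbp
#' otherwise, both for the reference-distance criterion and for span
#' extension in overlap determination.
#'
#' @param L variant length(s) in bp (positive).
#' @return Extension length(s) in bp (200 or 1000), vectorized.
#' @export
extendLength <- function(L) {
  stopifnot(all(L > 0))
  ifelse(L <= 100, 200, 1000)
}

#' SV type compatibility
#'
#' Strict mode requires identical types; loose mode additionally allows
#' insertion/duplication matches (a tandem duplication is an insertion of
#' the duplicated unit).
#'
#' @param t1,t2 SV types (INS, DEL, DUP, INV).
#' @param mode "strict" or "loose".
#' @return Logical flag.
#' @export
typeCompatible <- function(t1, t2, mode = c("strict", "loose")) {
  mode <- match.arg(mode)
  if (t1 == t2) return(TRUE)
  mode == "loose" && all(c(t1, t2) %in% c("INS", "DUP"))
}

#' Overlap criterion on extended spans
#'
#' Each record's span is extended on both sides: spanned types (DEL, DUP,
#' INV) by [extendLength()] of their own length, span-less insertions by
#' the fixed 100 bp extension. Two records overlap iff the maximum of the
#' extended starts does not exceed the minimum of the extended ends;
#' records on different chromosomes are disjoint by definition.
#'
#' @param a,b SV records (named lists or one-row data.frames with `chrom`,
#'   `pos`, `end`, `svtype`, `svlen`).
#' @param config a [MatchConfig-class].
#' @return `"overlap"` or `"disjoint"`.
#' @export
overlapStatus <- function(a, b, config = matchConfig()) {
  a <- asRec(a); b <- asRec(b)
  if (a$chrom != b$chrom) return("disjoint")
  extSpan <- function(r) {
    e <- if (r$svtype == "INS") config@fixedInsOverlapExt
         else extendLength(r$svlen)
    c(r$pos - e, r$end + e)
  }
  sa <- extSpan(a); sb <- extSpan(b)
  if (max(sa[1], sb[1]) <= min(sa[2], sb[2])) "overlap" else "disjoint"
}

#' Size similarity
#'
#' Ratio of the smaller to the larger variant length (deletion lengths are
#' the deleted spans, i.e. the REF-carried sequence; other types use the
#' ALT-carried variant sequence -- both equal the normalized record length
#' after ingestion).
#'
#' @param a,b SV records (or bare numeric lengths).
#' @return Value in (0, 1]; 1 iff the lengths are equal. Symmetric.
#' @export
sizeSimilarity <- function(a, b) {
  la <- if (is.numeric(a)) a else asRec(a)$svlen
  lb <- if (is.numeric(b)) b else asRec(b)$svlen
  stopifnot(la > 0, lb > 0)
  min(la, lb) / max(la, lb)
}

#' Global alignment with deterministic traceback
#'
#' Needleman-Wunsch with linear gap cost and fixed tie-breaking (diagonal,
#' then gap-in-second, then gap-in-first), so co-optimal alignments resolve
#' identically across runs.
#'
#' @param s1,s2 sequences (character strings).
#' @param config a [MatchConfig-class] supplying the scores.
#' @return List with `aln1`, `aln2` (gapped strings) and `score`.
#' @export
nwAlign <- function(s1, s2, config = matchConfig()) {
  cells <- (nchar(s1) + 1) * (nchar(s2) + 1)
  if (cells > 1.5e9)
    stop("sequences too long for full-matrix alignment (",
         nchar(s1), " x ", nchar(s2), ")")
  nw_align_cpp(s1, s2, as.integer(config@nwMatch),
               as.integer(config@nwMismatch), as.integer(config@nwGap))
}

#' Alignment statistics for the relief-factor score
#'
#' Counts `M`, the matching columns, and `G`, the gap characters lying in
#' maximal gap runs of length at least `gap_run_min` (runs counted per
#' sequence and summed), over a gapped alignment.
#'
#' @param aln1,aln2 gapped aligned strings of equal length.
#' @param gap_run_min minimal relieved run length.
#' @return List with `M`, `G` and `aln_len`.
#' @export
alignmentStats <- function(aln1, aln2, gap_run_min = 3) {
  stopifnot(nchar(aln1) == nchar(aln2))
  aln_stats_cpp(aln1, aln2, as.integer(gap_run_min))
}

# (M + G * RF) / aln_len, clipped to [0, 1].
reliefScore <- function(st, rf) {
  if (st$aln_len == 0) return(0)
  min(1, max(0, (st$M + st$G * rf) / st$aln_len))
}

# Align two sequences and return the relief score, routing pairs that both
# exceed the large-SV threshold (or that would need an oversized DP matrix)
# through the minimizer-anchored path. Arguments are put in canonical
# (lexicographic) order first: co-optimal alignments depend on the traceback
# direction, and canonical order makes the score invariant under swapping.
alignScore <- function(s1, s2, config) {
  if (s2 < s1) { tmp <- s1; s1 <- s2; s2 <- tmp }
  n1 <- nchar(s1); n2 <- nchar(s2)
  if (n1 == 0 || n2 == 0) return(0)
  big <- n1 > config@largeSvThreshold && n2 > config@largeSvThreshold
  if (big || (n1 + 1) * (n2 + 1) > 6e8)
    return(anchoredSimilarity(s1, s2, config))
  aln <- nwAlign(s1, s2, config)
  reliefScore(alignmentStats(aln$aln1, aln$aln2, config@gapRunMin),
              config@reliefFactor)
}

# End of the REF-carried span of a record (used for shared-context bounds).
refSpanEnd <- function(r) {
  switch(r$svtype,
         DEL = r$pos + r$svlen,
         INS = r$pos,
         r$end)
}

#' Sequence similarity with shared-context construction
#'
#' Scores two sequence-resolved records as the maximum of two relief-factor
#' weighted alignment scores: (X) the raw variant sequences (inserted bases
#' for ALT-carried types, deleted bases for deletions) aligned globally;
#' and (A) the two variant sequences embedded in a shared reference
#' context spanning from the upstream-most start to the downstream-most
#' reference-span end of the pair, which compensates for placement
#' differences between callers. Each alignment is scored
#' `(M + G * RF) / aln_len` where `G` counts gap characters in runs of
#' length >= `gap_run_min` and RF is the relief factor. Pairs whose
#' sequences both exceed the large-SV threshold are aligned with the
#' minimizer-anchored path ([anchoredSimilarity()]).
#'
#' Symbolic-allele pairs have no computable sequence similarity and return
#' NA; the criterion is then vacuously satisfied if the other four hold.
#' When the reference (or the records' chromosome) is unavailable the
#' context-free score X is returned alone.
#'
#' @param a,b SV records.
#' @param ref an [SVReference-class] or NULL.
#' @param config a [MatchConfig-class].
#' @return Similarity in \[0, 1\], or NA for symbolic pairs.
#' @export
sequenceSimilarity <- function(a, b, ref = NULL, config = matchConfig()) {
  a <- asRec(a); b <- asRec(b)
  if (isTRUE(a$symbolic) || isTRUE(b$symbolic)) return(NA_real_)
  if (is.na(a$seq) || is.na(b$seq) || !nzchar(a$seq) || !nzchar(b$seq))
    return(NA_real_)
  score_x <- alignScore(a$seq, b$seq, config)
  score_a <- NA_real_
  if (a$chrom == b$chrom && hasChrom(ref, a$chrom)) {
    S <- min(a$pos, b$pos)
    E <- max(refSpanEnd(a), refSpanEnd(b))
    ctxSeq <- function(r) {
      right_from <- if (r$svtype == "DEL") r$pos + r$svlen + 1 else r$pos + 1
      paste0(refWindow(ref, r$chrom, S, r$pos), r$seq,
             refWindow(ref, r$chrom, right_from, E))
    }
    score_a <- alignScore(ctxSeq(a), ctxSeq(b), config)
  }
  min(1, max(0, max(score_x, score_a, na.rm = TRUE)))
}

#' Evaluate the five matching criteria for one pair
#'
#' Applies, in order: SV type compatibility, reference distance (start
#' positions within [extendLength()] of the larger variant's length), span
#' overlap, size similarity against its threshold, and sequence similarity
#' against its threshold (vacuously satisfied for symbolic pairs; only
#' computed when the four cheaper criteria pass, in which case a skipped
#' evaluation is reported as NA).
#'
#' @param a,b SV records (query and benchmark).
#' @param ref an [SVReference-class] or NULL.
#' @param config a [MatchConfig-class].
#' @return A list: `type_ok`, `distance_ok`, `overlap_ok`, `size_sim`,
#'   `size_sim_ok`, `seq_sim`, `seq_sim_ok`, `all_pass`.
#' @export
evaluatePair <- function(a, b, ref = NULL, config = matchConfig()) {
  a <- asRec(a); b <- asRec(b)
  type_ok <- typeCompatible(a$svtype, b$svtype, config@matchMode)
  distance_ok <- a$chrom == b$chrom &&
    abs(a$pos - b$pos) <= extendLength(max(a$svlen, b$svlen))
  overlap_ok <- overlapStatus(a, b, config) == "overlap"
  size_sim <- sizeSimilarity(a, b)
  size_sim_ok <- size_sim >= config@sizeSimThreshold
  seq_sim <- NA_real_
  seq_sim_ok <- NA
  if (type_ok && distance_ok && overlap_ok && size_sim_ok) {
    seq_sim <- sequenceSimilarity(a, b, ref, config)
    seq_sim_ok <- if (is.na(seq_sim)) TRUE else seq_sim >= config@seqSimThreshold
  }
  all_pass <- type_ok && distance_ok && overlap_ok && size_sim_ok &&
    isTRUE(seq_sim_ok)
  list(type_ok = type_ok, distance_ok = distance_ok,
       overlap_ok = overlap_ok, size_sim = size_sim,
       size_sim_ok = size_sim_ok, seq_sim = seq_sim,
       seq_sim_ok = seq_sim_ok, all_pass = all_pass)
}
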