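#' Minimizer sketch of a sequence
#'
#' Slides a window of `w` consecutive k-mers over the sequence and keeps,
#' per window, the k-mer of minimal hash (leftmost on ties), deduplicated
#' by position. The hash is a fixed invertible integer mix (splitmix64
#' finalizer, seed 0) of the 2-bit encoded k-mer, truncated to 53 bits so
#' sketches are reproducible across platforms.
#'
#' @param seq character sequence.
#' @param k k-mer length (default 15).
#' @param w window size in k-mers (default 10); `w = 1` keeps every k-mer.
#' @return data.frame with columns `hash` and `offset` (1-based k-mer
#'   starts, strictly increasing). Sequences shorter than `k` give an
#'   empty sketch.
#' @export
minimizerSketch <- function(seq, k = 15, w = 10) {
  stopifnot(k >= 1, w >= 1)
  minimizer_sketch_cpp(seq, as.integer(k), as.integer(w))
}

# Longest strictly-increasing subsequence (indices) of y; ties among equal
# chain lengths resolve to the lexicographically earliest chain by
# construction (patience sorting with leftmost placement).
lisIndices <- function(y) {
  n <- length(y)
  if (!n) return(integer())
  tails <- integer(0)   # indices of smallest tail per length
  prev <- integer(n)
  for (i in seq_len(n)) {
    lo <- 1L; hi <- length(tails) + 1L
    while (lo < hi) {             # first tail with y >= y[i]
      mid <- (lo + hi) %/% 2L
      if (y[tails[mid]] < y[i]) lo <- mid + 1L else hi <- mid
    }
    prev[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
  }
  out <- integer(length(tails))
  k <- tails[length(tails)]
  for (j in rev(seq_along(tails))) { out[j] <- k; k <- prev[k] }
  out
}

#' Minimizer-anchored similarity for large sequence pairs
#'
#' Divide-and-align similarity for pairs above the large-SV threshold:
#' both sequences are sketched ([minimizerSketch()]), hash-matched
#' minimizers that occur uniquely in both sketches become anchor
#' candidates, a colinear chain is selected (longest strictly increasing
#' chain of second-sequence offsets in first-sequence order), overlapping
#' anchors are trimmed to disjoint k-length spans, inter-anchor segments
#' are aligned with [nwAlign()], and the merged alignment (anchors counted
#' as exact matches) is scored with the same relief-factor formula as
#' [sequenceSimilarity()].
#'
#' When no colinear anchor survives, the pair falls back to direct
#' alignment if the dynamic-programming matrix is affordable; otherwise 0
#' is returned with attribute `no_anchor = TRUE`.
#'
#' @param s1,s2 character sequences.
#' @param config a [MatchConfig-class] (k, w, scores, relief factor).
#' @return Similarity in \[0, 1\]; attribute `no_anchor` set when the
#'   anchorless fallback could not align.
#' @export
anchoredSimilarity <- function(s1, s2, config = matchConfig()) {
  k <- as.integer(config@kmerK)
  sk1 <- minimizerSketch(s1, k, config@minimizerW)
  sk2 <- minimizerSketch(s2, k, config@minimizerW)
  anchors <- NULL
  if (nrow(sk1) && nrow(sk2)) {
    # unique-in-both hashes only: repeated minimizers are ambiguous anchors
    u1 <- sk1[!(duplicated(sk1$hash) | duplicated(sk1$hash, fromLast = TRUE)), ]
    u2 <- sk2[!(duplicated(sk2$hash) | duplicated(sk2$hash, fromLast = TRUE)), ]
    mm <- merge(u1, u2, by = "hash", suffixes = c("1", "2"))
    if (nrow(mm)) {
      mm <- mm[order(mm$offset1, mm$offset2), ]
      keep <- lisIndices(mm$offset2)
      mm <- mm[keep, , drop = FALSE]
      # trim to disjoint k-length spans in both sequences
      sel <- logical(nrow(mm)); last1 <- -Inf; last2 <- -Inf
      for (i in seq_len(nrow(mm))) {
        if (mm$offset1[i] >= last1 + k && mm$offset2[i] >= last2 + k) {
          sel[i] <- TRUE; last1 <- mm$offset1[i]; last2 <- mm$offset2[i]
        }
      }
      anchors <- mm[sel, , drop = FALSE]
    }
  }
  if (is.null(anchors) || !nrow(anchors)) {
    if ((nchar(s1) + 1) * (nchar(s2) + 1) <= 5e7) {
      aln <- nwAlign(s1, s2, config)
      return(reliefScore(alignmentStats(aln$aln1, aln$aln2, config@gapRunMin),
                         config@reliefFactor))
    }
    return(structure(0, no_anchor = TRUE))
  }
  # segment boundaries: [prev anchor end + 1, next anchor start - 1]
  starts1 <- c(1, anchors$offset1 + k); ends1 <- c(anchors$offset1 - 1, nchar(s1))
  starts2 <- c(1, anchors$offset2 + k); ends2 <- c(anchors$offset2 - 1, nchar(s2))
  M <- nrow(anchors) * k
  G <- 0; len <- nrow(anchors) * k
  for (i in seq_along(starts1)) {
    seg1 <- if (ends1[i] >= starts1[i]) substr(s1, starts1[i], ends1[i]) else ""
    seg2 <- if (ends2[i] >= starts2[i]) substr(s2, starts2[i], ends2[i]) else ""
    n1 <- nchar(seg1); n2 <- nchar(seg2)
    if (n1 == 0 && n2 == 0) next
    if (n1 == 0 || n2 == 0) {
      g <- max(n1, n2)
      if (g >= config@gapRunMin) G <- G + g
      len <- len + g
      next
    }
    if ((n1 + 1) * (n2 + 1) > 4e7) {
      # degenerate safeguard: score an oversized divergent segment as an
      # unaligned block (no matches, length difference as one gap run)
      g <- abs(n1 - n2)
      if (g >= config@gapRunMin) G <- G + g
      len <- len + max(n1, n2)
      next
    }
    aln <- nwAlign(seg1, seg2, config)
    st <- alignmentStats(aln$aln1, aln$aln2, config@gapRunMin)
    M <- M + st$M; G <- G + st$G; len <- len + st$aln_len
  }
  if (len == 0) return(0)
  min(1, max(0, (M + G * config@reliefFactor) / len))
}
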