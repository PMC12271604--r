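# Apply non-overlapping variants to the reference window [S, E] (1-based
# inclusive) and return the resulting haplotype string. Insertions (and
# sequence-resolved duplications) add their sequence after their start
# base; deletions remove [pos + 1, pos + length].
applyVariantsToWindow <- function(ref, chrom, S, E, recs) {
  hap <- refWindow(ref, chrom, S, E)
  recs <- recs[order(vapply(recs, `[[`, numeric(1), "pos"), decreasing = TRUE)]
  for (r in recs) {
    off <- r$pos - S + 1           # 1-based offset of the start base
    if (r$svtype == "DEL") {
      from <- off + 1
      to <- min(off + r$svlen, nchar(hap))
      if (from <= to)
        hap <- paste0(substr(hap, 1, from - 1),
                      substr(hap, to + 1, nchar(hap)))
    } else {
      hap <- paste0(substr(hap, 1, off), r$seq,
                    substr(hap, off + 1, nchar(hap)))
    }
  }
  hap
}

#' Group residual false-positive calls into superclusters
#'
#' Single-linkage grouping of calls per (chromosome, SV type): consecutive
#' calls whose gap does not exceed `cluster_gap` join one cluster. Within
#' a cluster, calls whose original coordinates overlap are reduced to the
#' one with the highest first-pass sequence similarity (multi-allelic
#' protection); singletons are discarded since there is nothing to merge.
#'
#' @param fp_calls data.frame of first-pass FP records (as produced by the
#'   matching engine; must carry `chrom`, `pos`, `end`, `svtype`, `svlen`,
#'   `seq`, `recordID` and optionally `best_seq_sim`).
#' @param config a [MatchConfig-class].
#' @return List of clusters; each is a list with `chrom`, `svtype`,
#'   `members` (data.frame sorted by position), `span` and `combined_len`
#'   (sum of member lengths).
#' @export
buildSuperclusters <- function(fp_calls, config = matchConfig()) {
  if (is.null(fp_calls) || !nrow(fp_calls)) return(list())
  if (is.null(fp_calls$best_seq_sim))
    fp_calls$best_seq_sim <- NA_real_
  out <- list()
  for (key in split(seq_len(nrow(fp_calls)),
                    paste(fp_calls$chrom, fp_calls$svtype))) {
    d <- fp_calls[key, , drop = FALSE]
    d <- d[order(d$pos, d$recordID), , drop = FALSE]
    gap_new <- c(TRUE, d$pos[-1] - d$end[-nrow(d)] > config@clusterGap)
    for (grp in split(seq_len(nrow(d)), cumsum(gap_new))) {
      m <- d[grp, , drop = FALSE]
      if (nrow(m) > 1) {
        # eject coordinate-overlapping members, keeping the best-scoring one
        keep <- rep(TRUE, nrow(m))
        for (i in seq_len(nrow(m))) {
          if (!keep[i]) next
          for (j in seq_len(nrow(m))) {
            if (i == j || !keep[j]) next
            if (m$pos[i] <= m$end[j] && m$pos[j] <= m$end[i]) {
              si <- ifelse(is.na(m$best_seq_sim[i]), -Inf, m$best_seq_sim[i])
              sj <- ifelse(is.na(m$best_seq_sim[j]), -Inf, m$best_seq_sim[j])
              if (si >= sj) keep[j] <- FALSE else keep[i] <- FALSE
            }
          }
        }
        m <- m[keep, , drop = FALSE]
      }
      if (nrow(m) < 2) next
      out[[length(out) + 1]] <- list(
        chrom = m$chrom[1], svtype = m$svtype[1], members = m,
        span = c(min(m$pos), max(m$end)),
        combined_len = sum(m$svlen))
    }
  }
  out
}

#' Validate a supercluster merge against one missed benchmark variant
#'
#' Enumerates contiguous member subsets (2 up to `max_merge_cardinality`
#' calls) in breakpoint order. A subset is a candidate when the size
#' similarity of its combined length to the target's length reaches the
#' size-similarity threshold. For candidates, the merged haplotype (the
#' reference over the shared region with the subset's variants applied)
#' is aligned against the target's haplotype over the same region; the
#' best-scoring subset at or above the sequence-similarity threshold is
#' accepted, its members become latent positives (LP) and the benchmark
#' target a TP. Ties resolve to the smaller span, then the leftmost
#' subset. Returns NULL when no subset validates (the target stays FN and
#' the members stay FP).
#'
#' @param cluster one element of [buildSuperclusters()].
#' @param target a benchmark record (named list / one-row data.frame),
#'   first-pass FN, same chromosome.
#' @param ref an [SVReference-class] (required: haplotypes are built from
#'   reference context).
#' @param config a [MatchConfig-class].
#' @return NULL, or a list with `member_ids`, `member_rows`, `seq_sim`,
#'   `size_sim`, `combined_len`, `span`.
#' @export
validateCluster <- function(cluster, target, ref, config = matchConfig()) {
  t <- asRec(target)
  m <- cluster$members
  if (!hasChrom(ref, t$chrom)) return(NULL)
  if (any(is.na(m$seq)) || is.na(t$seq)) return(NULL)   # symbolic: no haplotype
  n <- nrow(m)
  best <- NULL
  for (sz in 2:min(config@maxMergeCardinality, n)) {
    for (s in seq_len(n - sz + 1)) {
      sub <- m[s:(s + sz - 1), , drop = FALSE]
      if (any(sub$pos[-1] <= sub$end[-sz]))   # overlapping applied variants
        next
      comb <- sum(sub$svlen)
      ssim <- sizeSimilarity(comb, t$svlen)
      if (ssim < config@sizeSimThreshold) next
      recs <- lapply(seq_len(sz), function(i) as.list(sub[i, , drop = FALSE]))
      S <- min(sub$pos, t$pos)
      E <- max(vapply(recs, refSpanEnd, numeric(1)), refSpanEnd(t))
      merged_hap <- applyVariantsToWindow(ref, t$chrom, S, E, recs)
      target_hap <- applyVariantsToWindow(ref, t$chrom, S, E, list(t))
      score <- alignScore(merged_hap, target_hap, config)
      if (score < config@seqSimThreshold) next
      span <- max(sub$end) - min(sub$pos)
      cand <- list(member_ids = sub$recordID, member_rows = sub,
                   seq_sim = score, size_sim = ssim, combined_len = comb,
                   span = c(min(sub$pos), max(sub$end)))
      if (is.null(best) || score > best$seq_sim ||
          (score == best$seq_sim &&
           (span < best$span[2] - best$span[1] ||
            (span == best$span[2] - best$span[1] &&
             min(sub$pos) < best$span[1]))))
        best <- cand
    }
  }
  best
}

#' Second-pass local joint analysis
#'
#' For each first-pass FN benchmark variant in genomic order, nearby
#' superclusters of residual FP calls (same SV type, span within the
#' expanded window) are tested with [validateCluster()]. On acceptance
#' the members move FP to LP, the target FN to TP, and a merge match is
#' recorded (`via_merge`, with `d` and `r` computed from the cluster span
#' against the target span). Each call participates in at most one
#' accepted merge. Joint analysis never decreases TP and never increases
#' FP or FN.
#'
#' @param first_pass an [SVClassification-class] from [matchCallset()].
#' @param ref an [SVReference-class]; when NULL the input is returned
#'   unchanged (merge validation needs reference context).
#' @param config a [MatchConfig-class]; defaults to the one stored in
#'   `first_pass`.
#' @return The updated [SVClassification-class].
#' @export
reclassify <- function(first_pass, ref = NULL, config = first_pass@config) {
  if (is.null(ref)) return(first_pass)
  cl <- first_pass
  qt <- svTable(cl@callset)
  qt$best_seq_sim <- cl@bestSeqSim
  bt <- svTable(cl@benchmark)
  call_lab <- cl@callLabels
  bench_lab <- cl@benchLabels
  matches <- cl@matches
  fn_idx <- which(bench_lab == "FN")
  for (bi in fn_idx) {
    t <- as.list(bt[bi, , drop = FALSE])
    fp_pool <- qt[call_lab[qt$idx] == "FP", , drop = FALSE]
    clusters <- buildSuperclusters(fp_pool, config)
    best <- NULL
    for (cluster in clusters) {
      if (cluster$chrom != t$chrom) next
      if (!typeCompatible(cluster$svtype, t$svtype, config@matchMode)) next
      if (cluster$span[1] > t$end + config@expandedWindow ||
          t$pos > cluster$span[2] + config@expandedWindow) next
      v <- validateCluster(cluster, t, ref, config)
      if (is.null(v)) next
      v$dist <- abs(v$span[1] - t$pos)
      if (is.null(best) || v$seq_sim > best$seq_sim ||
          (v$seq_sim == best$seq_sim && v$dist < best$dist))
        best <- v
    }
    if (is.null(best)) next
    members <- match(best$member_ids, qt$recordID)
    call_lab[qt$idx[members]] <- "LP"
    bench_lab[bi] <- "TP"
    matches <- rbind(matches, data.frame(
      query_id = best$member_ids[1], bench_id = t$recordID,
      seq_sim = best$seq_sim, size_sim = best$size_sim,
      d = best$span[1] - t$pos,
      r = (best$span[2] - best$span[1] + 1) / (t$end - t$pos + 1),
      via_merge = TRUE,
      merge_id = paste0("merge_", t$recordID),
      merge_members = paste(best$member_ids, collapse = ","),
      merge_len = best$combined_len, stringsAsFactors = FALSE))
  }
  new("SVClassification", callset = cl@callset, benchmark = cl@benchmark,
      callLabels = call_lab, benchLabels = bench_lab, matches = matches,
      bestSeqSim = cl@bestSeqSim, config = config)
}
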