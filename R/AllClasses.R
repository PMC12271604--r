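SV_TYPES <- c("INS", "DEL", "DUP", "INV")

DEFAULT_CHROMS <- c(as.character(1:22), "X", "Y",
                    paste0("chr", c(as.character(1:22), "X", "Y")))

#' Default size-bin edges
#'
#' Eight size bins used for stratified reporting, spanning the configured
#' minimum to maximum variant size: small variants (< 100 bp) first, very
#' large variants (>= 10 kbp) last.
#'
#' @param min_size,max_size outer edges in bp.
#' @return Numeric vector of 9 bin edges; bin i covers
#'   \[edge_i, edge_{i+1}) with the last bin closed.
#' @export
defaultSizeBins <- function(min_size = 20, max_size = 50000) {
  c(min_size, 100, 250, 500, 1000, 2500, 5000, 10000, max_size)
}

#' MatchConfig: parameters of the benchmarking method
#'
#' Holds every threshold and tuning parameter: ingestion size limits,
#' similarity thresholds, the relief factor applied to long gap runs,
#' Needleman-Wunsch scores, search-window sizes, minimizer sketch parameters
#' for large variants, size bins, and the joint-analysis merge limits.
#'
#' @slot minSize,maxSize ingestion size filter (bp).
#' @slot sizeSimThreshold,seqSimThreshold matching thresholds in \[0,1\].
#' @slot sizeRatioBand size-ratio band applied in the expanded search stage.
#' @slot matchMode "strict" (exact type match) or "loose" (INS~DUP allowed).
#' @slot reliefFactor weight in \[0,1\] crediting gap characters in long runs.
#' @slot gapRunMin minimal gap-run length that receives relief.
#' @slot nwMatch,nwMismatch,nwGap alignment scores (linear gap).
#' @slot fixedInsOverlapExt fixed span extension for span-less types (bp).
#' @slot smallWindow,expandedWindow search windows (bp).
#' @slot largeSvThreshold length above which minimizer anchoring is used (bp).
#' @slot kmerK,minimizerW minimizer sketch parameters.
#' @slot sizeBins bin edges for stratified reporting.
#' @slot clusterGap supercluster single-linkage gap (bp).
#' @slot maxMergeCardinality maximal number of calls merged into one variant.
#' @slot chroms chromosome inclusion set.
#' @slot threads worker count recorded in the run manifest (the
#'   implementation is deterministic and independent of this value).
#' @export
setClass("MatchConfig", representation(
  minSize = "numeric", maxSize = "numeric",
  sizeSimThreshold = "numeric", seqSimThreshold = "numeric",
  sizeRatioBand = "numeric", matchMode = "character",
  reliefFactor = "numeric", gapRunMin = "numeric",
  nwMatch = "numeric", nwMismatch = "numeric", nwGap = "numeric",
  fixedInsOverlapExt = "numeric",
  smallWindow = "numeric", expandedWindow = "numeric",
  largeSvThreshold = "numeric", kmerK = "numeric", minimizerW = "numeric",
  sizeBins = "numeric", clusterGap = "numeric",
  maxMergeCardinality = "numeric", chroms = "character",
  threads = "numeric"))

setValidity("MatchConfig", function(object) {
  msg <- character()
  pos1 <- c(minSize = object@minSize, maxSize = object@maxSize,
            gapRunMin = object@gapRunMin,
            fixedInsOverlapExt = object@fixedInsOverlapExt,
            smallWindow = object@smallWindow,
            expandedWindow = object@expandedWindow,
            largeSvThreshold = object@largeSvThreshold,
            kmerK = object@kmerK, minimizerW = object@minimizerW,
            clusterGap = object@clusterGap,
            maxMergeCardinality = object@maxMergeCardinality,
            threads = object@threads)
  if (any(pos1 <= 0)) msg <- c(msg, "all length/count parameters must be positive")
  if (object@minSize >= object@maxSize) msg <- c(msg, "minSize must be < maxSize")
  if (object@reliefFactor < 0 || object@reliefFactor > 1)
    msg <- c(msg, "reliefFactor must lie in [0,1]")
  thr <- c(object@sizeSimThreshold, object@seqSimThreshold)
  if (any(thr < 0 | thr > 1)) msg <- c(msg, "thresholds must lie in [0,1]")
  if (length(object@sizeRatioBand) != 2 ||
      object@sizeRatioBand[1] >= object@sizeRatioBand[2])
    msg <- c(msg, "sizeRatioBand must be (low, high) with low < high")
  if (!object@matchMode %in% c("strict", "loose"))
    msg <- c(msg, "matchMode must be 'strict' or 'loose'")
  if (length(object@sizeBins) < 2 || is.unsorted(object@sizeBins, strictly = TRUE))
    msg <- c(msg, "sizeBins must be strictly increasing edges")
  if (length(msg)) msg else TRUE
})

#' Build a MatchConfig
#'
#' All arguments default to the method's standard settings: 20 bp--50 kbp
#' ingestion window, 0.7 size- and sequence-similarity thresholds,
#' \[0.7, 1.2\] expanded-stage size-ratio band, relief factor 0.5 on gap runs
#' of length >= 3, NW scores +1/-1/-2, 100 bp fixed extension for insertions,
#' 200 bp / 1 kbp search windows, minimizer k = 15 and w = 10 above 10 kbp,
#' eight size bins, 1 kbp supercluster gap and at most 6 merged calls.
#'
#' @param min_size,max_size ingestion size filter (bp).
#' @param size_sim_threshold,seq_sim_threshold matching thresholds.
#' @param size_ratio_band numeric(2) expanded-stage band.
#' @param match_mode "strict" or "loose".
#' @param relief_factor gap-run relief weight in \[0,1\].
#' @param gap_run_min minimal relieved gap-run length.
#' @param nw_match,nw_mismatch,nw_gap alignment scores.
#' @param fixed_ins_overlap_ext fixed extension for span-less types (bp).
#' @param small_window,expanded_window search windows (bp).
#' @param large_sv_threshold minimizer-path length threshold (bp).
#' @param kmer_k,minimizer_w sketch parameters.
#' @param size_bins bin edges for reporting.
#' @param cluster_gap supercluster linkage gap (bp).
#' @param max_merge_cardinality maximal merge size.
#' @param chroms chromosome inclusion set (default autosomes + X + Y, with
#'   and without the "chr" prefix).
#' @param threads recorded worker count.
#' @return A validated [MatchConfig-class] object.
#' @examples
#' cfg <- matchConfig(match_mode = "loose")
#' @export
matchConfig <- function(min_size = 20, max_size = 50000,
                        size_sim_threshold = 0.7, seq_sim_threshold = 0.7,
                        size_ratio_band = c(0.7, 1.2),
                        match_mode = c("strict", "loose"),
                        relief_factor = 0.5, gap_run_min = 3,
                        nw_match = 1, nw_mismatch = -1, nw_gap = -2,
                        fixed_ins_overlap_ext = 100,
                        small_window = 200, expanded_window = 1000,
                        large_sv_threshold = 10000,
                        kmer_k = 15, minimizer_w = 10,
                        size_bins = defaultSizeBins(min_size, max_size),
                        cluster_gap = 1000, max_merge_cardinality = 6,
                        chroms = DEFAULT_CHROMS, threads = 1) {
  match_mode <- match.arg(match_mode)
  new("MatchConfig", minSize = min_size, maxSize = max_size,
      sizeSimThreshold = size_sim_threshold,
      seqSimThreshold = seq_sim_threshold,
      sizeRatioBand = size_ratio_band, matchMode = match_mode,
      reliefFactor = relief_factor, gapRunMin = gap_run_min,
      nwMatch = nw_match, nwMismatch = nw_mismatch, nwGap = nw_gap,
      fixedInsOverlapExt = fixed_ins_overlap_ext,
      smallWindow = small_window, expandedWindow = expanded_window,
      largeSvThreshold = large_sv_threshold,
      kmerK = kmer_k, minimizerW = minimizer_w, sizeBins = size_bins,
      clusterGap = cluster_gap, maxMergeCardinality = max_merge_cardinality,
      chroms = chroms, threads = threads)
}

setMethod("show", "MatchConfig", function(object) {
  cat("MatchConfig\n")
  cat(sprintf("  size filter: [%g, %g] bp | mode: %s\n",
              object@minSize, object@maxSize, object@matchMode))
  cat(sprintf("  thresholds: sizeSim %.2f, seqSim %.2f | ratio band [%.2f, %.2f]\n",
              object@sizeSimThreshold, object@seqSimThreshold,
              object@sizeRatioBand[1], object@sizeRatioBand[2]))
  cat(sprintf("  relief factor %.2f (gap runs >= %d) | NW %+d/%+d/%+d\n",
              object@reliefFactor, as.integer(object@gapRunMin),
              object@nwMatch, object@nwMismatch, object@nwGap))
  cat(sprintf("  windows: %g/%g bp | large-SV: > %g bp (k=%d, w=%d)\n",
              object@smallWindow, object@expandedWindow,
              object@largeSvThreshold, as.integer(object@kmerK),
              as.integer(object@minimizerW)))
  cat(sprintf("  joint analysis: gap %g bp, <= %d merged calls\n",
              object@clusterGap, as.integer(object@maxMergeCardinality)))
})

#' SVReference: in-memory reference genome
#'
#' Wraps a [Biostrings::DNAStringSet] of chromosome sequences and provides
#' clamped 1-based inclusive window extraction.
#'
#' @slot sequences DNAStringSet, one element per chromosome.
#' @export
setClass("SVReference", representation(sequences = "DNAStringSet"))

setValidity("SVReference", function(object) {
  nm <- names(object@sequences)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    return("chromosome sequences must carry unique non-empty names")
  TRUE
})

setMethod("show", "SVReference", function(object) {
  cat(sprintf("SVReference with %d sequence(s), total %.0f bp\n",
              length(object@sequences), sum(width(object@sequences))))
})

#' SVCallSet: a normalized set of structural variant records
#'
#' One callset (or the benchmark set) after VCF ingestion: a position-sorted
#' [GenomicRanges::GRanges] whose metadata columns carry the SV type, the
#' normalized (positive) length, the variant core sequence (inserted bases
#' for INS/DUP/INV, deleted bases for DEL; NA for symbolic alleles), the raw
#' REF/ALT columns, a symbolic-allele flag, the record ID and the raw
#' genotype. Records excluded at ingestion are tallied per reason.
#'
#' @slot ranges GRanges of the retained records (start = POS; for INS
#'   end == start).
#' @slot source label of the originating callset.
#' @slot exclusions named integer tally of records excluded per reason.
#' @export
setClass("SVCallSet", representation(
  ranges = "GRanges", source = "character", exclusions = "integer"))

setValidity("SVCallSet", function(object) {
  m <- mcols(object@ranges)
  need <- c("svtype", "svlen", "seq", "refCol", "altCol", "symbolic",
            "recordID", "genotype")
  if (!all(need %in% colnames(m)))
    return(paste("missing metadata columns:",
                 paste(setdiff(need, colnames(m)), collapse = ", ")))
  if (length(object@ranges)) {
    if (!all(m$svtype %in% SV_TYPES))
      return("svtype must be one of INS, DEL, DUP, INV")
    if (any(m$svlen <= 0)) return("all lengths must be positive")
    if (any(start(object@ranges) < 1)) return("pos must be >= 1")
    ins <- m$svtype == "INS"
    if (any(end(object@ranges)[ins] != start(object@ranges)[ins]))
      return("INS records must have end == pos")
    sp <- m$svtype %in% c("DEL", "DUP", "INV")
    if (any(end(object@ranges)[sp] - start(object@ranges)[sp] + 1 != m$svlen[sp]))
      return("spanned records must satisfy end - pos + 1 == length")
  }
  if (length(object@source) != 1 || !nzchar(object@source))
    return("source must be a single non-empty label")
  TRUE
})

setMethod("show", "SVCallSet", function(object) {
  tab <- table(factor(mcols(object@ranges)$svtype, levels = SV_TYPES))
  cat(sprintf("SVCallSet '%s': %d records (%s)\n", object@source,
              length(object@ranges),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  if (sum(object@exclusions))
    cat("  excluded:",
        paste(sprintf("%s %d", names(object@exclusions), object@exclusions),
              collapse = ", "), "\n")
})

setMethod("length", "SVCallSet", function(x) length(x@ranges))

#' SVClassification: one callset-vs-benchmark classification
#'
#' The complete TP/FP/FN/LP assignment for one run: every call carries
#' exactly one label in TP/FP/LP, every benchmark record exactly one label
#' in TP/FN, and accepted matches (direct or via joint-analysis merges) are
#' listed with their similarity scores, signed breakpoint distance d and
#' size ratio r.
#'
#' @slot callset,benchmark the classified [SVCallSet-class] objects.
#' @slot callLabels character, one of TP/FP/LP per call.
#' @slot benchLabels character, one of TP/FN per benchmark record.
#' @slot matches data.frame of accepted matches (query_id, bench_id,
#'   seq_sim, size_sim, d, r, via_merge, merge_id, merge_members).
#' @slot bestSeqSim best sequence similarity observed per call during the
#'   first pass (NA when never evaluated); used by the supercluster allele
#'   filter.
#' @slot config the [MatchConfig-class] used.
#' @export
setClass("SVClassification", representation(
  callset = "SVCallSet", benchmark = "SVCallSet",
  callLabels = "character", benchLabels = "character",
  matches = "data.frame", bestSeqSim = "numeric", config = "MatchConfig"))

setValidity("SVClassification", function(object) {
  if (length(object@callLabels) != length(object@callset))
    return("one label per call required")
  if (length(object@benchLabels) != length(object@benchmark))
    return("one label per benchmark record required")
  if (!all(object@callLabels %in% c("TP", "FP", "LP")))
    return("call labels must be TP, FP or LP")
  if (!all(object@benchLabels %in% c("TP", "FN")))
    return("benchmark labels must be TP or FN")
  TRUE
})

setMethod("show", "SVClassification", function(object) {
  cat(sprintf("SVClassification '%s' vs '%s'\n",
              object@callset@source, object@benchmark@source))
  cat(sprintf("  TP %d | FP %d | FN %d | LP %d\n",
              tpCount(object), fpCount(object), fnCount(object),
              lpCount(object)))
})

#' BenchmarkSummary: headline and stratified benchmarking metrics
#'
#' Counts and derived statistics for one classification: TP/FP/FN/LP,
#' recall, precision, F1, mean sequence similarity of scored matches,
#' per-size-bin sub-summaries and breakpoint-deviation fractions.
#'
#' @slot source callset label.
#' @slot counts named numeric: TP, FP, FN, LP.
#' @slot metrics named numeric: recall, precision, f1, mean_seq_sim
#'   (proportions in \[0,1\]; NA mean when no match carries a score).
#' @slot perBin data.frame of per-size-bin counts and metrics.
#' @slot deviation list: d, r vectors plus frac_d50 (|d| <= 50 bp) and
#'   frac_r_band (r in \[0.7, 1.2\]).
#' @slot nBenchmark size of the filtered benchmark set.
#' @slot emptyBenchmark flag set when the benchmark set was empty (recall
#'   reported as 0).
#' @export
setClass("BenchmarkSummary", representation(
  source = "character", counts = "numeric", metrics = "numeric",
  perBin = "data.frame", deviation = "list", nBenchmark = "numeric",
  emptyBenchmark = "logical"))

setValidity("BenchmarkSummary", function(object) {
  if (!all(c("TP", "FP", "FN", "LP") %in% names(object@counts)))
    return("counts must carry TP, FP, FN, LP")
  if (!all(c("recall", "precision", "f1", "mean_seq_sim") %in%
           names(object@metrics)))
    return("metrics must carry recall, precision, f1, mean_seq_sim")
  TRUE
})

setMethod("show", "BenchmarkSummary", function(object) {
  cat(sprintf("BenchmarkSummary '%s' (benchmark n = %d)\n",
              object@source, as.integer(object@nBenchmark)))
  cat(sprintf("  TP %d  FP %d  FN %d  LP %d\n",
              object@counts["TP"], object@counts["FP"],
              object@counts["FN"], object@counts["LP"]))
  cat(sprintf("  Rc %s  Pr %s  F1 %s  SeqSim %s\n",
              fmtPct(object@metrics["recall"]),
              fmtPct(object@metrics["precision"]),
              fmtPct(object@metrics["f1"]),
              fmtPct(object@metrics["mean_seq_sim"])))
})
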