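#' Recall, precision and F1 from classification counts
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`,
#' `f1 = 2 * precision * recall / (precision + recall)`; each is 0 when
#' its denominator is 0. TP is the benchmark-side true-positive count;
#' latent positives are excluded from both the precision numerator and
#' denominator.
#'
#' @param tp,fp,fn counts.
#' @return Named numeric: recall, precision, f1 (proportions in \[0,1\]).
#' @examples
#' svMetrics(38154, 14142, 35858)
#' @export
svMetrics <- function(tp, fp, fn) {
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(recall = recall, precision = precision, f1 = f1)
}

#' Format a proportion as a percentage, one decimal, half-up
#'
#' @param x proportion in \[0,1\] (NA allowed).
#' @return Character like "51.6" ("NA" when undefined).
#' @export
fmtPct <- function(x) {
  unname(ifelse(is.na(x), "NA", sprintf("%.1f", floor(x * 1000 + 0.5) / 10)))
}

binLabels <- function(edges) {
  n <- length(edges) - 1
  lab <- sprintf("[%g,%g)", edges[-length(edges)], edges[-1])
  lab[n] <- sprintf("[%g,%g]", edges[n], edges[n + 1])
  lab
}

binOf <- function(len, edges) {
  i <- findInterval(len, edges, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), length(edges) - 1L)
}

#' Size-stratified counts and metrics
#'
#' Benchmark records (TP and FN) are binned by their own length, residual
#' calls (FP and LP) by theirs; per-bin counts sum to the global counts.
#'
#' @param classification an [SVClassification-class].
#' @param bins bin edges (default: the configuration's).
#' @return data.frame with one row per bin: counts and
#'   recall/precision/f1.
#' @export
sizeStratify <- function(classification,
                         bins = classification@config@sizeBins) {
  labs <- binLabels(bins)
  nb <- length(labs)
  bt <- svTable(classification@benchmark)
  qt <- svTable(classification@callset)
  tab <- data.frame(bin = labs,
                    TP = integer(nb), FP = integer(nb), FN = integer(nb),
                    LP = integer(nb), stringsAsFactors = FALSE)
  addCounts <- function(col, lens) {
    if (length(lens)) {
      t <- table(factor(binOf(lens, bins), levels = seq_len(nb)))
      tab[[col]] <<- tab[[col]] + as.integer(t)
    }
  }
  addCounts("TP", bt$svlen[classification@benchLabels == "TP"])
  addCounts("FN", bt$svlen[classification@benchLabels == "FN"])
  addCounts("FP", qt$svlen[classification@callLabels == "FP"])
  addCounts("LP", qt$svlen[classification@callLabels == "LP"])
  met <- t(vapply(seq_len(nb), function(i)
    svMetrics(tab$TP[i], tab$FP[i], tab$FN[i]), numeric(3)))
  cbind(tab, as.data.frame(met))
}

#' Breakpoint-deviation statistics of accepted matches
#'
#' Summarizes the signed breakpoint distance `d` (query start minus
#' benchmark start) and the span-length ratio `r` over the accepted
#' matches: full vectors, fixed-break histograms, and the two headline
#' fractions (|d| <= 50 bp; r in \[0.7, 1.2\]).
#'
#' @param matches data.frame of matches ([matchResults()]).
#' @return List: `d`, `r`, `frac_d50`, `frac_r_band`, `d_hist`, `r_hist`.
#' @export
deviationStats <- function(matches) {
  d <- matches$d[!is.na(matches$d)]
  r <- matches$r[!is.na(matches$r)]
  d_breaks <- c(-Inf, -500, -100, -50, -10, 0, 10, 50, 100, 500, Inf)
  r_breaks <- c(0, 0.5, 0.7, 0.9, 1, 1.1, 1.2, 1.5, 2, Inf)
  list(d = d, r = r,
       frac_d50 = if (length(d)) mean(abs(d) <= 50) else NA_real_,
       frac_r_band = if (length(r)) mean(r >= 0.7 & r <= 1.2) else NA_real_,
       d_hist = table(cut(d, d_breaks, right = TRUE)),
       r_hist = table(cut(r, r_breaks, right = TRUE)))
}

#' Summarize a classification
#'
#' Computes the headline counts and metrics (TP/FP/FN/LP, recall,
#' precision, F1 and the mean sequence similarity over scored matches,
#' accepted merges contributing their single score once), the size-bin
#' stratification and the deviation statistics. An empty benchmark set
#' yields recall 0 with the `emptyBenchmark` flag raised (and a warning).
#'
#' @param classification an [SVClassification-class] (final, i.e. after
#'   [reclassify()]).
#' @param bins size-bin edges.
#' @return A [BenchmarkSummary-class].
#' @export
summarizeClassification <- function(classification,
                                    bins = classification@config@sizeBins) {
  tp <- tpCount(classification); fp <- fpCount(classification)
  fn <- fnCount(classification); lp <- lpCount(classification)
  empty <- length(classification@benchmark) == 0
  if (empty) warning("empty benchmark set: recall reported as 0")
  met <- svMetrics(tp, fp, fn)
  ss <- classification@matches$seq_sim
  mss <- if (any(!is.na(ss))) mean(ss, na.rm = TRUE) else NA_real_
  new("BenchmarkSummary", source = classification@callset@source,
      counts = c(TP = tp, FP = fp, FN = fn, LP = lp),
      metrics = c(met, mean_seq_sim = mss),
      perBin = sizeStratify(classification, bins),
      deviation = deviationStats(classification@matches),
      nBenchmark = length(classification@benchmark),
      emptyBenchmark = empty)
}

#' Benchmark-TP overlap across callsets
#'
#' For classifications of several callsets against one benchmark set,
#' counts for every callset combination the benchmark records that are TP
#' in exactly that combination (the data behind an upset plot). Counts
#' over all combinations sum to the number of benchmark records that are
#' TP in at least one callset.
#'
#' @param classifications named list of [SVClassification-class] objects
#'   sharing one benchmark set.
#' @return data.frame with `combination` (callset names joined by "&"),
#'   `degree` and `count`, ordered by degree then combination.
#' @export
tpOverlap <- function(classifications) {
  stopifnot(length(classifications) >= 1)
  nm <- names(classifications)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- vapply(classifications, function(x) x@callset@source, character(1))
  fp0 <- vapply(classifications, function(x)
    paste(mcols(x@benchmark@ranges)$recordID, collapse = "\r"), character(1))
  if (length(unique(fp0)) != 1)
    stop("classifications do not share one benchmark set")
  tpm <- vapply(classifications, function(x) x@benchLabels == "TP",
                logical(length(classifications[[1]]@benchmark)))
  if (is.null(dim(tpm))) tpm <- matrix(tpm, nrow = 1)
  any_tp <- rowSums(tpm) > 0
  combo <- apply(tpm, 1, function(z) paste(nm[z], collapse = "&"))
  tab <- table(combo[any_tp])
  out <- data.frame(combination = names(tab),
                    degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out[order(out$degree, out$combination), , drop = FALSE]
}
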