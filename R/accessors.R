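#' @name svcompare-accessors
#' @title Accessors for svcompare classes
#' @description Small read-only accessors so user code never touches slots.
#' @param x an svcompare object.
NULL

#' @rdname svcompare-accessors
#' @export
setGeneric("svSource", function(x) standardGeneric("svSource"))
#' @rdname svcompare-accessors
#' @export
setMethod("svSource", "SVCallSet", function(x) x@source)

#' @rdname svcompare-accessors
#' @export
setGeneric("svRanges", function(x) standardGeneric("svRanges"))
#' @rdname svcompare-accessors
#' @export
setMethod("svRanges", "SVCallSet", function(x) x@ranges)

#' @rdname svcompare-accessors
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))
#' @rdname svcompare-accessors
#' @export
setMethod("exclusions", "SVCallSet", function(x) x@exclusions)

#' @rdname svcompare-accessors
#' @export
setGeneric("tpCount", function(x) standardGeneric("tpCount"))
#' @rdname svcompare-accessors
#' @export
setMethod("tpCount", "SVClassification",
          function(x) sum(x@benchLabels == "TP"))

#' @rdname svcompare-accessors
#' @export
setGeneric("fpCount", function(x) standardGeneric("fpCount"))
#' @rdname svcompare-accessors
#' @export
setMethod("fpCount", "SVClassification",
          function(x) sum(x@callLabels == "FP"))

#' @rdname svcompare-accessors
#' @export
setGeneric("fnCount", function(x) standardGeneric("fnCount"))
#' @rdname svcompare-accessors
#' @export
setMethod("fnCount", "SVClassification",
          function(x) sum(x@benchLabels == "FN"))

#' @rdname svcompare-accessors
#' @export
setGeneric("lpCount", function(x) standardGeneric("lpCount"))
#' @rdname svcompare-accessors
#' @export
setMethod("lpCount", "SVClassification",
          function(x) sum(x@callLabels == "LP"))

#' @rdname svcompare-accessors
#' @export
setGeneric("callLabels", function(x) standardGeneric("callLabels"))
#' @rdname svcompare-accessors
#' @export
setMethod("callLabels", "SVClassification", function(x) {
  setNames(x@callLabels, mcols(x@callset@ranges)$recordID)
})

#' @rdname svcompare-accessors
#' @export
setGeneric("benchLabels", function(x) standardGeneric("benchLabels"))
#' @rdname svcompare-accessors
#' @export
setMethod("benchLabels", "SVClassification", function(x) {
  setNames(x@benchLabels, mcols(x@benchmark@ranges)$recordID)
})

#' @rdname svcompare-accessors
#' @export
setGeneric("matchResults", function(x) standardGeneric("matchResults"))
#' @rdname svcompare-accessors
#' @export
setMethod("matchResults", "SVClassification", function(x) x@matches)

#' @rdname svcompare-accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname svcompare-accessors
#' @export
setMethod("chromLengths", "SVReference",
          function(x) setNames(width(x@sequences), names(x@sequences)))

# Internal: flat data.frame view of a callset used by the matching engine.
svTable <- function(x) {
  gr <- x@ranges
  m <- mcols(gr)
  data.frame(idx = seq_along(gr),
             chrom = as.character(seqnames(gr)),
             pos = start(gr), end = end(gr),
             svtype = m$svtype, svlen = m$svlen,
             seq = m$seq, symbolic = m$symbolic,
             recordID = m$recordID,
             stringsAsFactors = FALSE)
}

# Internal: one record as a plain list (the pairwise operations accept
# these or one-row data.frames interchangeably).
svRecord <- function(x, i) {
  df <- svTable(x)
  as.list(df[i, , drop = FALSE])
}

# Internal: coerce a one-row data.frame / list record to list form.
asRec <- function(r) {
  if (is.data.frame(r)) as.list(r[1, , drop = FALSE]) else r
}
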