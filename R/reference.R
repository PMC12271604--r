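#' Load a reference genome from FASTA
#'
#' @param fasta_path path to a (optionally gzipped) FASTA file.
#' @return An [SVReference-class] object.
#' @export
readReference <- function(fasta_path) {
  if (!file.exists(fasta_path))
    stop("reference FASTA not found: ", fasta_path)
  seqs <- readDNAStringSet(fasta_path)
  # FASTA headers may carry descriptions after the first token
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1)
  new("SVReference", sequences = seqs)
}

# Construct an SVReference from named character sequences (fixtures, tests).
svReference <- function(seqs) {
  new("SVReference", sequences = DNAStringSet(unlist(seqs)))
}

#' Extract a clamped reference window
#'
#' Returns the 1-based inclusive subsequence `[start, end]` of a chromosome;
#' coordinates outside the chromosome are clamped to its ends, and an empty
#' string is returned when the clamped window is empty (e.g. `end < start`).
#'
#' @param ref an [SVReference-class].
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @return A character string of `min(end, len) - max(start, 1) + 1` bases
#'   (possibly empty).
#' @export
refWindow <- function(ref, chrom, start, end) {
  seqs <- ref@sequences
  if (!chrom %in% names(seqs))
    stop("chromosome not in reference: ", chrom)
  len <- length(seqs[[chrom]])
  s <- max(1L, as.integer(start))
  e <- min(len, as.integer(end))
  if (e < s) return("")
  as.character(subseq(seqs[[chrom]], s, e))
}

# Does the reference know this chromosome?
hasChrom <- function(ref, chrom) {
  !is.null(ref) && chrom %in% names(ref@sequences)
}
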