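EXCLUSION_REASONS <- c("malformed", "unsupported_type", "excluded_chrom",
                       "no_length", "below_min_size", "above_max_size")

#' Infer the length of a structural variant
#'
#' Precedence: `|info_svlen|` when present; otherwise the reference span
#' `end - pos` for spanned types (DEL, DUP, INV); otherwise the resolved
#' sequences (inserted length `len(alt) - len(ref)` for INS and other
#' ALT-carried types, deleted length `len(ref) - len(alt)` for DEL).
#'
#' @param pos,end 1-based coordinates (`end` may be NA).
#' @param ref_seq,alt_seq raw REF/ALT column strings (NA when symbolic).
#' @param svtype one of INS, DEL, DUP, INV.
#' @param info_svlen INFO SVLEN value (sign ignored; NA when absent).
#' @return Positive integer length, or NA when no source is usable (the
#'   record is then rejected with reason "no_length").
#' @export
inferSVLength <- function(pos, end, ref_seq, alt_seq, svtype,
                          info_svlen = NA) {
  if (!is.na(info_svlen) && is.finite(info_svlen) && info_svlen != 0)
    return(abs(as.numeric(info_svlen)))
  if (svtype != "INS" && !is.na(end) && end > pos)
    return(as.numeric(end) - as.numeric(pos))
  if (!is.na(ref_seq) && !is.na(alt_seq) && nzchar(ref_seq) && nzchar(alt_seq)) {
    d <- if (svtype == "DEL") nchar(ref_seq) - nchar(alt_seq)
         else nchar(alt_seq) - nchar(ref_seq)
    if (d > 0) return(as.numeric(d))
  }
  NA_real_
}

#' Recompute the end coordinate of a record from its length
#'
#' The INFO END of a VCF record can be inaccurate (notably for insertions in
#' simulated benchmark sets), so the end is always rederived: spanned types
#' get `end = pos + length - 1`; insertions have no reference span and get
#' `end = pos`.
#'
#' @param record a record as a named list or one-row data.frame with at
#'   least `pos`, `svlen` and `svtype`.
#' @return The record with its `end` field replaced.
#' @export
recomputeEnd <- function(record) {
  r <- asRec(record)
  r$end <- if (r$svtype == "INS") r$pos else r$pos + r$svlen - 1
  r
}

# Strip the shared VCF padding to obtain the variant core sequence:
# inserted bases for ALT-carried types, deleted bases for DEL.
coreSequence <- function(ref_seq, alt_seq, svtype) {
  if (is.na(ref_seq) || is.na(alt_seq)) return(NA_character_)
  if (svtype == "DEL") {
    if (startsWith(ref_seq, alt_seq)) substring(ref_seq, nchar(alt_seq) + 1)
    else ref_seq
  } else {
    if (startsWith(alt_seq, ref_seq)) substring(alt_seq, nchar(ref_seq) + 1)
    else alt_seq
  }
}

# Order used everywhere: configured chromosome order, then position, then ID.
chromFactor <- function(chrom, config) {
  lev <- unique(c(config@chroms, sort(unique(chrom))))
  factor(chrom, levels = lev)
}

#' Read and normalize a structural variant callset from VCF
#'
#' Parses a VCF v4.2 file (plain or bgzipped), splits multi-allelic lines
#' into one record per ALT, normalizes SVLEN signs to positive lengths,
#' rederives end coordinates, and applies the ingestion filters: supported
#' SV types only (INS/DEL/DUP/INV; BND and other types are rejected),
#' configured chromosome inclusion set, and the `[min_size, max_size]`
#' length window. Excluded records are tallied per reason, never aborting
#' the parse; malformed records are skipped with a warning.
#'
#' @param vcf_path path to the VCF.
#' @param config a [MatchConfig-class]; defaults govern the filters.
#' @param source_label label recorded on every record (defaults to the
#'   file name).
#' @return An [SVCallSet-class] sorted by (chromosome, position, ID).
#' @examples
#' \dontrun{cs <- readSVVcf("calls.vcf", matchConfig(), "caller1")}
#' @export
readSVVcf <- function(vcf_path, config = matchConfig(),
                      source_label = basename(vcf_path)) {
  if (!file.exists(vcf_path)) stop("cannot read VCF: ", vcf_path)
  vcf0 <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(vcf_path, genome = "unknown")),
    error = function(e) stop("failed to parse VCF ", vcf_path, ": ",
                             conditionMessage(e)))
  ids0 <- names(SummarizedExperiment::rowRanges(vcf0))
  nalt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf0))
  vcf <- VariantAnnotation::expand(vcf0)
  n <- nrow(vcf)
  tally <- setNames(integer(length(EXCLUSION_REASONS)), EXCLUSION_REASONS)
  if (n == 0) return(newSVCallSet(emptyRecords(), source_label, tally))

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(seqnames(rr))
  pos <- start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- as.character(VariantAnnotation::alt(vcf))
  ids <- names(rr)
  if (is.null(ids) && !is.null(ids0) && sum(nalt) == n)
    ids <- rep(ids0, nalt)    # expand() drops row names; restore per ALT
  if (is.null(ids)) ids <- rep(NA_character_, n)
  inf <- VariantAnnotation::info(vcf)
  getInfo <- function(key) {
    if (!key %in% colnames(inf)) return(rep(NA, n))
    v <- inf[[key]]
    if (is(v, "List") || is.list(v))
      v <- vapply(v, function(x) if (length(x)) as.numeric(x[[1]]) else NA_real_,
                  numeric(1))
    v
  }
  getInfoChr <- function(key) {
    if (!key %in% colnames(inf)) return(rep(NA_character_, n))
    v <- inf[[key]]
    if (is(v, "List") || is.list(v))
      v <- vapply(v, function(x) if (length(x)) as.character(x[[1]]) else NA_character_,
                  character(1))
    as.character(v)
  }
  info_svlen <- suppressWarnings(as.numeric(getInfo("SVLEN")))
  info_end <- suppressWarnings(as.numeric(getInfo("END")))
  info_svtype <- getInfoChr("SVTYPE")
  gt <- tryCatch({
    g <- VariantAnnotation::geno(vcf)
    if ("GT" %in% names(g) && ncol(g$GT) >= 1) as.character(g$GT[, 1])
    else rep(NA_character_, n)
  }, error = function(e) rep(NA_character_, n))

  keep <- logical(n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- tryCatch({
      a <- alts[i]
      symbolic <- !is.na(a) && grepl("^<", a)
      svtype <- info_svtype[i]
      if (is.na(svtype) || !nzchar(svtype)) {
        if (symbolic) svtype <- gsub("[<>]", "", a)
        else if (!is.na(a) && !is.na(refs[i])) {
          svtype <- if (nchar(a) > nchar(refs[i])) "INS"
                    else if (nchar(a) < nchar(refs[i])) "DEL"
                    else NA_character_
        }
      }
      if (is.na(svtype) || !svtype %in% SV_TYPES) {
        tally["unsupported_type"] <- tally["unsupported_type"] + 1L
        return_rec <- NULL
      } else if (!chrom[i] %in% config@chroms) {
        tally["excluded_chrom"] <- tally["excluded_chrom"] + 1L
        return_rec <- NULL
      } else {
        end_i <- info_end[i]
        if (is.na(end_i)) end_i <- end(rr)[i]
        len <- inferSVLength(pos[i], end_i,
                             if (symbolic) NA_character_ else refs[i],
                             if (symbolic) NA_character_ else a,
                             svtype, info_svlen[i])
        if (is.na(len)) {
          tally["no_length"] <- tally["no_length"] + 1L
          return_rec <- NULL
        } else if (len < config@minSize) {
          tally["below_min_size"] <- tally["below_min_size"] + 1L
          return_rec <- NULL
        } else if (len > config@maxSize) {
          tally["above_max_size"] <- tally["above_max_size"] + 1L
          return_rec <- NULL
        } else {
          rid <- ids[i]
          if (is.na(rid) || rid %in% c("", "."))
            rid <- sprintf("%s_%s_%d_%d", source_label, chrom[i], pos[i], i)
          core <- if (symbolic) NA_character_
                  else coreSequence(refs[i], a, svtype)
          r <- recomputeEnd(list(pos = pos[i], svlen = len, svtype = svtype))
          return_rec <- list(chrom = chrom[i], pos = pos[i], end = r$end,
                             svtype = svtype, svlen = len, seq = core,
                             refCol = if (symbolic) refs[i] else refs[i],
                             altCol = a, symbolic = symbolic,
                             recordID = rid, genotype = gt[i])
        }
      }
      return_rec
    }, error = function(e) {
      warning("skipping malformed record ", i, " in ", vcf_path, ": ",
              conditionMessage(e))
      tally["malformed"] <<- tally["malformed"] + 1L
      NULL
    })
    if (!is.null(rec)) { keep[i] <- TRUE; out[[i]] <- rec }
  }
  recs <- out[keep]
  if (!length(recs)) return(newSVCallSet(emptyRecords(), source_label, tally))
  df <- do.call(rbind, lapply(recs, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  df$recordID <- make.unique(df$recordID, sep = "_allele")
  o <- order(chromFactor(df$chrom, config), df$pos, df$recordID,
             method = "radix")
  df <- df[o, , drop = FALSE]
  newSVCallSet(recordsToGRanges(df), source_label, tally)
}

recordsToGRanges <- function(df) {
  gr <- GRanges(df$chrom, IRanges(df$pos, df$end))
  mcols(gr) <- DataFrame(svtype = df$svtype, svlen = as.numeric(df$svlen),
                         seq = df$seq, refCol = df$refCol, altCol = df$altCol,
                         symbolic = df$symbolic, recordID = df$recordID,
                         genotype = df$genotype)
  gr
}

emptyRecords <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(svtype = character(), svlen = numeric(),
                         seq = character(), refCol = character(),
                         altCol = character(), symbolic = logical(),
                         recordID = character(), genotype = character())
  gr
}

newSVCallSet <- function(gr, source, exclusions) {
  new("SVCallSet", ranges = gr, source = source,
      exclusions = as.integer(exclusions) |> setNames(names(exclusions)))
}

# Build an SVCallSet directly from a records data.frame (fixtures, tests).
callSetFromRecords <- function(df, source, config = matchConfig()) {
  tally <- setNames(integer(length(EXCLUSION_REASONS)), EXCLUSION_REASONS)
  if (!nrow(df)) return(newSVCallSet(emptyRecords(), source, tally))
  if (is.null(df$genotype)) df$genotype <- NA_character_
  o <- order(chromFactor(df$chrom, config), df$pos, df$recordID,
             method = "radix")
  newSVCallSet(recordsToGRanges(df[o, , drop = FALSE]), source, tally)
}

#' Write an SVCallSet to a VCF v4.2 file
#'
#' Emits one record per line with SVTYPE, SVLEN and END INFO keys plus any
#' extra INFO columns supplied in `extra_info` (a data.frame aligned with
#' the records; NA entries are omitted). Output is deterministic, so
#' identical inputs give byte-identical files.
#'
#' @param callset an [SVCallSet-class].
#' @param path output path.
#' @param extra_info optional data.frame of additional INFO fields.
#' @param contig_lengths optional named vector adding contig header lines.
#' @return `path`, invisibly.
#' @export
writeSVVcf <- function(callset, path, extra_info = NULL,
                       contig_lengths = NULL) {
  gr <- callset@ranges
  m <- mcols(gr)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=svcompare_%s", utils::packageVersion("svcompare")),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of structural variant\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of structural variant\">")
  if (!is.null(extra_info))
    for (k in colnames(extra_info)) {
      type <- if (is.numeric(extra_info[[k]])) "Float" else "String"
      hdr <- c(hdr, sprintf(
        "##INFO=<ID=%s,Number=1,Type=%s,Description=\"svcompare annotation\">",
        k, type))
    }
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  has_gt <- length(gr) > 0 && any(!is.na(m$genotype))
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (has_gt) {
    hdr <- c(hdr, "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
    cols <- c(cols, "FORMAT", "SAMPLE")
  }
  hdr <- c(hdr, paste(cols, collapse = "\t"))
  lines <- hdr
  if (length(gr)) {
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", m$svtype,
                    as.integer(m$svlen), as.integer(end(gr)))
    if (!is.null(extra_info))
      for (k in colnames(extra_info)) {
        v <- extra_info[[k]]
        add <- !is.na(v)
        vchr <- if (is.numeric(v)) sprintf("%.6g", v) else as.character(v)
        info[add] <- paste0(info[add], ";", k, "=", vchr[add])
      }
    body <- paste(as.character(seqnames(gr)), start(gr), m$recordID,
                  m$refCol, m$altCol, ".", "PASS", info, sep = "\t")
    if (has_gt) {
      gtv <- ifelse(is.na(m$genotype), "./.", m$genotype)
      body <- paste(body, "GT", gtv, sep = "\t")
    }
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write per-class VCFs for a classification
#'
#' Writes `tp.vcf`, `fp.vcf` and `lp.vcf` (calls labelled TP/FP/LP) and
#' `fn.vcf` (benchmark records labelled FN) into `out_dir`. Matched calls
#' carry `ASVBM_CLASS`, `ASVBM_SEQSIM`, `ASVBM_D` and `ASVBM_R` INFO tags;
#' LP records additionally carry `ASVBM_MERGE_ID` linking the members of
#' one accepted merge to their validated benchmark target.
#'
#' @param classification an [SVClassification-class].
#' @param out_dir output directory (created if missing).
#' @return Named character vector of the four paths, invisibly.
#' @export
writeClassVcfs <- function(classification, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cs <- classification@callset
  bs <- classification@benchmark
  lab <- classification@callLabels
  mt <- classification@matches
  n <- length(cs)
  ann <- data.frame(ASVBM_CLASS = lab,
                    ASVBM_SEQSIM = rep(NA_real_, n),
                    ASVBM_D = rep(NA_real_, n),
                    ASVBM_R = rep(NA_real_, n),
                    ASVBM_MERGE_ID = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  ids <- mcols(cs@ranges)$recordID
  if (nrow(mt)) for (j in seq_len(nrow(mt))) {
    members <- if (isTRUE(mt$via_merge[j]))
      strsplit(mt$merge_members[j], ",", fixed = TRUE)[[1]] else mt$query_id[j]
    k <- match(members, ids)
    ann$ASVBM_SEQSIM[k] <- mt$seq_sim[j]
    ann$ASVBM_D[k] <- mt$d[j]
    ann$ASVBM_R[k] <- mt$r[j]
    if (isTRUE(mt$via_merge[j])) ann$ASVBM_MERGE_ID[k] <- mt$merge_id[j]
  }
  subsetCS <- function(x, i, src) newSVCallSet(x@ranges[i], src, x@exclusions)
  paths <- c(tp = file.path(out_dir, "tp.vcf"),
             fp = file.path(out_dir, "fp.vcf"),
             lp = file.path(out_dir, "lp.vcf"),
             fn = file.path(out_dir, "fn.vcf"))
  for (cl in c("TP", "FP", "LP")) {
    i <- which(lab == cl)
    writeSVVcf(subsetCS(cs, i, cs@source), paths[tolower(cl)],
               extra_info = ann[i, , drop = FALSE])
  }
  i <- which(classification@benchLabels == "FN")
  fn_ann <- data.frame(ASVBM_CLASS = rep("FN", length(i)))
  writeSVVcf(subsetCS(bs, i, bs@source), paths["fn"], extra_info = fn_ann)
  invisible(paths)
}
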