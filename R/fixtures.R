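randomSeq <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Perturbation settings for synthetic callsets
#'
#' Rates of the independent per-variant actions applied by
#' [perturbCallset()]: dropout (expected FN), split into k adjacent parts
#' carrying exact subsequences (expected LP members validating the truth
#' record), or in-place jitter of breakpoint and size (expected TP);
#' plus decoy and allele-injection rates that append expected FPs.
#' Defaults keep jitter within half the matching tolerances (shifts
#' clamped to +/- 50 bp, sizes within 5 %), so jittered calls are TPs by
#' construction.
#'
#' @param breakpoint_shift_sd SD (bp) of the breakpoint shift; realized
#'   shifts are clamped to +/- 50 bp.
#' @param size_jitter_frac maximal relative size change.
#' @param split_fraction probability that an eligible variant is split.
#' @param split_k candidate part counts (subset of 2:6).
#' @param dropout_rate probability a truth variant is dropped.
#' @param fp_rate decoy count as a fraction of the truth count.
#' @param allele_injection_rate probability a kept call gains a divergent
#'   second allele at the same site (expected FP).
#' @param seed mandatory RNG seed.
#' @return A validated list of settings.
#' @export
perturbationSpec <- function(breakpoint_shift_sd = 10,
                             size_jitter_frac = 0.05,
                             split_fraction = 0.2, split_k = 2:6,
                             dropout_rate = 0.1, fp_rate = 0.15,
                             allele_injection_rate = 0, seed) {
  if (missing(seed)) stop("perturbationSpec: seed is mandatory")
  rates <- c(split_fraction, dropout_rate, fp_rate, allele_injection_rate)
  if (any(rates < 0 | rates > 1))
    stop("perturbationSpec: rates must lie in [0,1]")
  if (dropout_rate + split_fraction > 1)
    stop("perturbationSpec: dropout_rate + split_fraction must not exceed 1")
  if (!all(split_k %in% 2:6)) stop("perturbationSpec: split_k must be in 2..6")
  list(breakpoint_shift_sd = breakpoint_shift_sd,
       size_jitter_frac = size_jitter_frac,
       split_fraction = split_fraction, split_k = split_k,
       dropout_rate = dropout_rate, fp_rate = fp_rate,
       allele_injection_rate = allele_injection_rate, seed = seed)
}

#' Simulate a reference chromosome
#'
#' Random uniform sequence with optionally planted tandem-repeat tracts
#' (to stress ambiguous variant placement). Deterministic per seed:
#' repeated runs give byte-identical FASTA output.
#'
#' @param length chromosome length in bp (>= 10 kbp).
#' @param seed RNG seed.
#' @param repeat_fraction target fraction of the sequence covered by
#'   tandem-repeat tracts.
#' @param chrom chromosome name.
#' @param fasta_path optional output FASTA path; a sidecar
#'   `<fasta_path>.repeats.bed` is written when tracts were planted.
#' @return List: `ref` ([SVReference-class]), `repeats` (data.frame of
#'   tracts, 0-based BED coordinates), `fasta` (path or NA).
#' @export
simulateReference <- function(length, seed, repeat_fraction = 0,
                              chrom = "chr1", fasta_path = NULL) {
  stopifnot(length >= 10000)
  set.seed(seed)
  s <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  repeats <- data.frame(chrom = character(), start = integer(),
                        end = integer(), unit = character())
  if (repeat_fraction > 0) {
    covered <- 0
    while (covered < repeat_fraction * length) {
      unit <- randomSeq(sample(5:30, 1))
      copies <- sample(5:40, 1)
      tract <- strsplit(strrep(unit, copies), "")[[1]]
      tl <- base::length(tract)
      if (tl > length - 2000) next
      at <- sample.int(length - tl - 1000, 1) + 500
      s[at:(at + tl - 1)] <- tract
      repeats <- rbind(repeats, data.frame(
        chrom = chrom, start = at - 1L, end = at + tl - 1L, unit = unit))
      covered <- covered + tl
    }
  }
  ref <- svReference(setNames(list(paste(s, collapse = "")), chrom))
  if (!is.null(fasta_path)) {
    writeXStringSet(ref@sequences, fasta_path)
    if (nrow(repeats))
      utils::write.table(repeats, paste0(fasta_path, ".repeats.bed"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
  }
  list(ref = ref, repeats = repeats,
       fasta = if (is.null(fasta_path)) NA_character_ else fasta_path)
}

# Build the full record row for one simulated variant.
truthRecord <- function(ref, chrom, pos, svtype, len, id) {
  pad <- refWindow(ref, chrom, pos, pos)
  if (svtype == "INS") {
    core <- randomSeq(len)
    list(chrom = chrom, pos = pos, end = pos, svtype = "INS", svlen = len,
         seq = core, refCol = pad, altCol = paste0(pad, core),
         symbolic = FALSE, recordID = id, genotype = "0/1")
  } else if (svtype == "DEL") {
    core <- refWindow(ref, chrom, pos + 1, pos + len)
    list(chrom = chrom, pos = pos, end = pos + len - 1, svtype = "DEL",
         svlen = len, seq = core, refCol = paste0(pad, core), altCol = pad,
         symbolic = FALSE, recordID = id, genotype = "0/1")
  } else {
    list(chrom = chrom, pos = pos, end = pos + len - 1, svtype = svtype,
         svlen = len, seq = NA_character_, refCol = pad,
         altCol = paste0("<", svtype, ">"), symbolic = TRUE,
         recordID = id, genotype = "0/1")
  }
}

recListToDf <- function(recs) {
  do.call(rbind, lapply(recs, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
}

#' Simulate a truth (benchmark) variant set
#'
#' Places `n_sv` non-overlapping variants with at least `min_sep` bp
#' between start positions. Insertions and deletions are fully sequence
#' resolved; duplications and inversions are emitted as symbolic alleles.
#' The implied alternative haplotype (insertions and deletions applied to
#' the reference) is returned for reconstruction checks.
#'
#' @param ref an [SVReference-class] (single chromosome used).
#' @param n_sv number of variants.
#' @param type_mix named probabilities over INS/DEL/DUP/INV.
#' @param size_distribution a single size (bp) or a `function(n)`
#'   returning `n` sizes; the default draws log-uniform sizes in
#'   \[30, 500\].
#' @param seed RNG seed.
#' @param min_sep minimal start-position separation (default 2 kbp, twice
#'   the expanded search window).
#' @param vcf_path optional truth VCF output path.
#' @param config filters/ordering configuration.
#' @return List: `callset` ([SVCallSet-class], source "truth"), `labels`
#'   (data.frame), `haplotype` (character), `vcf` (path or NA).
#' @export
simulateTruth <- function(ref, n_sv,
                          type_mix = c(INS = 0.5, DEL = 0.5),
                          size_distribution = NULL, seed = 1,
                          min_sep = 2000, vcf_path = NULL,
                          config = matchConfig()) {
  set.seed(seed)
  chrom <- names(ref@sequences)[1]
  clen <- chromLengths(ref)[[1]]
  sizes <- if (is.null(size_distribution))
    round(exp(runif(n_sv, log(30), log(500))))
  else if (is.function(size_distribution)) size_distribution(n_sv)
  else rep(size_distribution, n_sv)
  sizes <- pmax(sizes, config@minSize)
  slot_w <- min_sep + max(sizes)
  starts <- seq(1000, clen - max(sizes) - 1000, by = slot_w)
  if (length(starts) < n_sv)
    stop(sprintf("cannot place %d variants: only %d slots of %d bp on a %d bp reference",
                 n_sv, length(starts), slot_w, clen))
  pos <- sort(sample(starts, n_sv)) + sample.int(500, n_sv, replace = TRUE)
  types <- sample(names(type_mix), n_sv, replace = TRUE, prob = type_mix)
  recs <- lapply(seq_len(n_sv), function(i)
    truthRecord(ref, chrom, pos[i], types[i], sizes[i],
                sprintf("truth_%03d", i)))
  df <- recListToDf(recs)
  cs <- callSetFromRecords(df, "truth", config)
  resolved <- lapply(recs, asRec)
  resolved <- Filter(function(r) r$svtype %in% c("INS", "DEL"), resolved)
  hap <- applyVariantsToWindow(ref, chrom, 1, clen, resolved)
  vcf <- NA_character_
  if (!is.null(vcf_path)) {
    writeSVVcf(cs, vcf_path, contig_lengths = setNames(clen, chrom))
    vcf <- vcf_path
  }
  list(callset = cs,
       labels = df[, c("recordID", "svtype", "svlen", "pos")],
       haplotype = hap, vcf = vcf, seed = seed)
}

# Partition len into k parts, each >= min_part, roughly equal with jitter.
splitLengths <- function(len, k, min_part) {
  base <- len %/% k
  parts <- rep(base, k)
  parts[k] <- parts[k] + len - sum(parts)
  jit_max <- max(0, base - min_part)
  if (jit_max > 0 && k >= 2) {
    j <- sample.int(min(jit_max, max(1, base %/% 5)), k - 1, replace = TRUE) *
      sample(c(-1L, 1L), k - 1, replace = TRUE)
    parts[1:(k - 1)] <- parts[1:(k - 1)] + j
    parts[k] <- len - sum(parts[1:(k - 1)])
  }
  if (any(parts < min_part)) return(rep(len %/% k, k) +
                                      c(rep(0, k - 1), len - k * (len %/% k)))
  parts
}

#' Perturb a truth set into a synthetic callset with known labels
#'
#' Each truth variant is independently dropped (expected FN), split into
#' k adjacent calls carrying the exact subsequences of the original
#' variant (expected LP members + TP target via joint analysis), or kept
#' with bounded breakpoint/size jitter (expected TP). Decoy calls at
#' unrelated positions (expected FP) and divergent same-site alleles
#' (expected FP) are appended per the spec rates. The expected
#' classification is returned alongside the callset.
#'
#' @param truth result of [simulateTruth()] (or an [SVCallSet-class]).
#' @param ref the [SVReference-class] used to simulate the truth set.
#' @param spec a [perturbationSpec()].
#' @param source label for the generated callset.
#' @param vcf_path optional callset VCF output path.
#' @param config filters/ordering configuration.
#' @return List: `callset`, `expected` (list `call`, `bench`: named label
#'   vectors), `actions` (data.frame per truth record), `vcf`.
#' @export
perturbCallset <- function(truth, ref, spec, source = "calls",
                           vcf_path = NULL, config = matchConfig()) {
  cs <- if (is(truth, "SVCallSet")) truth else truth$callset
  gr <- cs@ranges
  m <- mcols(gr)
  n <- length(gr)
  set.seed(spec$seed)
  chrom_all <- as.character(seqnames(gr))
  calls <- list()
  exp_call <- character(); exp_bench <- setNames(character(n), m$recordID)
  actions <- character(n)
  for (i in seq_len(n)) {
    id <- m$recordID[i]
    pos <- start(gr)[i]; L <- m$svlen[i]; ty <- m$svtype[i]
    chrom <- chrom_all[i]
    u <- runif(1)
    splittable <- ty %in% c("INS", "DEL") && !m$symbolic[i]
    kopts <- spec$split_k[L %/% spec$split_k >= config@minSize + 5]
    if (u < spec$dropout_rate) {
      actions[i] <- "dropout"
      exp_bench[id] <- "FN"
      next
    }
    if (u < spec$dropout_rate + spec$split_fraction && splittable &&
        length(kopts)) {
      k <- if (length(kopts) == 1) kopts else sample(kopts, 1)
      parts <- splitLengths(L, k, config@minSize)
      # keep every part below the direct-match size-similarity threshold
      if (max(parts) / L < config@sizeSimThreshold) {
        actions[i] <- sprintf("split_k%d", k)
        exp_bench[id] <- "TP"
        off <- c(0, cumsum(parts))
        ins_gaps <- c(0, cumsum(sample(1:3, k - 1, replace = TRUE)))
        for (j in seq_len(k)) {
          pid <- sprintf("%s_%s_part%d", source, id, j)
          if (ty == "INS") {
            ppos <- pos + ins_gaps[j]
            pad <- refWindow(ref, chrom, ppos, ppos)
            core <- substr(m$seq[i], off[j] + 1, off[j + 1])
            calls[[length(calls) + 1]] <- list(
              chrom = chrom, pos = ppos, end = ppos, svtype = "INS",
              svlen = parts[j], seq = core, refCol = pad,
              altCol = paste0(pad, core), symbolic = FALSE,
              recordID = pid, genotype = "0/1")
          } else {
            ppos <- pos + off[j]
            pad <- refWindow(ref, chrom, ppos, ppos)
            core <- substr(m$seq[i], off[j] + 1, off[j + 1])
            calls[[length(calls) + 1]] <- list(
              chrom = chrom, pos = ppos, end = ppos + parts[j] - 1,
              svtype = "DEL", svlen = parts[j], seq = core,
              refCol = paste0(pad, core), altCol = pad, symbolic = FALSE,
              recordID = pid, genotype = "0/1")
          }
          exp_call[pid] <- "LP"
        }
        next
      }
    }
    # in-place jitter -> expected TP
    actions[i] <- "jitter"
    exp_bench[id] <- "TP"
    shift <- max(-50, min(50, round(rnorm(1, 0, spec$breakpoint_shift_sd))))
    delta <- round(L * runif(1, -spec$size_jitter_frac, spec$size_jitter_frac))
    newL <- max(config@minSize, L + delta)
    npos <- max(2, pos + shift)
    cid <- sprintf("%s_%s", source, id)
    pad <- refWindow(ref, chrom, npos, npos)
    if (ty == "INS") {
      core <- m$seq[i]
      core <- if (newL <= nchar(core)) substr(core, 1, newL)
              else paste0(core, randomSeq(newL - nchar(core)))
      calls[[length(calls) + 1]] <- list(
        chrom = chrom, pos = npos, end = npos, svtype = "INS",
        svlen = newL, seq = core, refCol = pad,
        altCol = paste0(pad, core), symbolic = FALSE, recordID = cid,
        genotype = "0/1")
    } else if (ty == "DEL") {
      core <- refWindow(ref, chrom, npos + 1, npos + newL)
      calls[[length(calls) + 1]] <- list(
        chrom = chrom, pos = npos, end = npos + newL - 1, svtype = "DEL",
        svlen = newL, seq = core, refCol = paste0(pad, core), altCol = pad,
        symbolic = FALSE, recordID = cid, genotype = "0/1")
    } else {
      calls[[length(calls) + 1]] <- list(
        chrom = chrom, pos = npos, end = npos + newL - 1, svtype = ty,
        svlen = newL, seq = NA_character_, refCol = pad,
        altCol = paste0("<", ty, ">"), symbolic = TRUE, recordID = cid,
        genotype = "0/1")
    }
    exp_call[cid] <- "TP"
    if (runif(1) < spec$allele_injection_rate && ty == "INS") {
      aid <- sprintf("%s_%s_allele2", source, id)
      aL <- max(config@minSize, round(L * 1.6) + 25)
      core2 <- randomSeq(aL)
      calls[[length(calls) + 1]] <- list(
        chrom = chrom, pos = npos, end = npos, svtype = "INS", svlen = aL,
        seq = core2, refCol = pad, altCol = paste0(pad, core2),
        symbolic = FALSE, recordID = aid, genotype = "0/1")
      exp_call[aid] <- "FP"
    }
  }
  # decoys: novel calls far from every truth record -> expected FP
  n_decoy <- round(spec$fp_rate * n)
  if (n_decoy > 0) {
    chrom <- names(ref@sequences)[1]
    clen <- chromLengths(ref)[[1]]
    taken <- start(gr)
    placed <- 0; tries <- 0
    while (placed < n_decoy && tries < 50 * n_decoy) {
      tries <- tries + 1
      dpos <- sample.int(clen - 2000, 1) + 500
      if (any(abs(taken - dpos) < 3000)) next
      taken <- c(taken, dpos)
      placed <- placed + 1
      dL <- sample(30:300, 1)
      did <- sprintf("%s_decoy_%03d", source, placed)
      pad <- refWindow(ref, chrom, dpos, dpos)
      if (runif(1) < 0.5) {
        core <- randomSeq(dL)
        calls[[length(calls) + 1]] <- list(
          chrom = chrom, pos = dpos, end = dpos, svtype = "INS",
          svlen = dL, seq = core, refCol = pad,
          altCol = paste0(pad, core), symbolic = FALSE, recordID = did,
          genotype = "0/1")
      } else {
        core <- refWindow(ref, chrom, dpos + 1, dpos + dL)
        calls[[length(calls) + 1]] <- list(
          chrom = chrom, pos = dpos, end = dpos + dL - 1, svtype = "DEL",
          svlen = dL, seq = core, refCol = paste0(pad, core), altCol = pad,
          symbolic = FALSE, recordID = did, genotype = "0/1")
      }
      exp_call[did] <- "FP"
    }
  }
  df <- if (length(calls)) recListToDf(calls) else data.frame()
  out_cs <- callSetFromRecords(df, source, config)
  vcf <- NA_character_
  if (!is.null(vcf_path)) {
    writeSVVcf(out_cs, vcf_path)
    vcf <- vcf_path
  }
  list(callset = out_cs,
       expected = list(call = exp_call, bench = exp_bench),
       actions = data.frame(recordID = m$recordID, action = actions,
                            stringsAsFactors = FALSE),
       vcf = vcf)
}
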