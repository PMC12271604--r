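#' Benchmark one or more callsets against a benchmark VCF
#'
#' End-to-end run: parse the reference and VCFs, first-pass matching,
#' joint-analysis reclassification, summary metrics, per-class VCFs,
#' multi-callset TP overlap, report rendering and a run manifest. The
#' whole pipeline is deterministic: identical inputs and configuration
#' give identical outputs regardless of the configured thread count.
#'
#' @param benchmark_vcf path to the benchmark VCF.
#' @param callset_vcfs character vector (optionally named; names become
#'   callset labels) of one or more callset VCF paths.
#' @param reference_fasta path to the reference FASTA.
#' @param out_dir output directory.
#' @param config a [MatchConfig-class].
#' @return Invisibly, a list with `classifications`, `summaries`,
#'   `overlap` and `manifest`.
#' @export
runBench <- function(benchmark_vcf, callset_vcfs, reference_fasta, out_dir,
                     config = matchConfig()) {
  t0 <- Sys.time()
  stopifnot(length(callset_vcfs) >= 1)
  for (p in c(benchmark_vcf, callset_vcfs, reference_fasta))
    if (!file.exists(p)) stop("input not found: ", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  labels <- names(callset_vcfs)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- make.unique(basename(callset_vcfs))
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(
    tool = "svcompare",
    version = as.character(utils::packageVersion("svcompare")),
    config = configEcho(config),
    inputs = list(
      benchmark = list(path = benchmark_vcf,
                       md5 = unname(tools::md5sum(benchmark_vcf))),
      reference = list(path = reference_fasta,
                       md5 = unname(tools::md5sum(reference_fasta))),
      callsets = lapply(seq_along(callset_vcfs), function(i)
        list(label = labels[i], path = callset_vcfs[i],
             md5 = unname(tools::md5sum(callset_vcfs[i]))))),
    status = "failed", wall_time_sec = NA)
  on.exit(write_json(manifest, manifest_path, auto_unbox = TRUE,
                     digits = NA, pretty = TRUE, na = "null"))

  ref <- readReference(reference_fasta)
  benchmark <- readSVVcf(benchmark_vcf, config, "benchmark")
  classifications <- list()
  summaries <- list()
  outputs <- list()
  for (i in seq_along(callset_vcfs)) {
    lab <- labels[i]
    message("benchmarking callset '", lab, "' (", callset_vcfs[i], ")")
    cs <- readSVVcf(callset_vcfs[i], config, lab)
    cl <- reclassify(matchCallset(cs, benchmark, ref, config), ref, config)
    classifications[[lab]] <- cl
    summaries[[lab]] <- summarizeClassification(cl)
    cdir <- file.path(out_dir, lab)
    vcfs <- writeClassVcfs(cl, cdir)
    outputs[[lab]] <- as.list(vcfs)
  }
  overlap <- tpOverlap(classifications)
  rep_paths <- renderReport(summaries, overlap, config, out_dir)
  manifest$outputs <- c(outputs, as.list(rep_paths))
  manifest$status <- "ok"
  manifest$wall_time_sec <-
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  invisible(list(classifications = classifications, summaries = summaries,
                 overlap = overlap, manifest = manifest))
}
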