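summaryRow <- function(s) {
  data.frame(source = s@source,
             TP = s@counts["TP"], FP = s@counts["FP"],
             FN = s@counts["FN"], LP = s@counts["LP"],
             Rc = fmtPct(s@metrics["recall"]),
             Pr = fmtPct(s@metrics["precision"]),
             F1 = fmtPct(s@metrics["f1"]),
             SeqSim = fmtPct(s@metrics["mean_seq_sim"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

summaryJSON <- function(s) {
  list(source = s@source,
       counts = as.list(s@counts),
       metrics = as.list(s@metrics),
       n_benchmark = s@nBenchmark,
       frac_d_within_50bp = s@deviation$frac_d50,
       frac_r_within_band = s@deviation$frac_r_band,
       per_bin = s@perBin)
}

configEcho <- function(config) {
  sn <- slotNames(config)
  setNames(lapply(sn, function(s) slot(config, s)), sn)
}

htmlBar <- function(frac, color) {
  sprintf(paste0("<div style='background:%s;width:%.1f%%;height:12px;",
                 "display:inline-block'></div>"),
          color, 100 * max(0, min(1, frac)))
}

htmlTable <- function(df) {
  hd <- paste0("<tr>", paste0("<th>", colnames(df), "</th>", collapse = ""),
               "</tr>")
  rows <- apply(df, 1, function(r)
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>"))
  paste0("<table border='1' cellspacing='0' cellpadding='3'>", hd,
         paste(rows, collapse = "\n"), "</table>")
}

#' Render the benchmarking report
#'
#' Writes, into `out_dir`: `report.txt` (fixed-width table, one row per
#' callset with TP/FP/FN/LP and Rc/Pr/F1/SeqSim percentages), `report.html`
#' (the same table plus recall/precision bars and the TP-overlap table),
#' `summary.json` (full-precision machine-readable counts, metrics,
#' per-bin tables and a configuration echo) and `upset_data.tsv` (the
#' TP-overlap combination counts). Output is deterministic: identical
#' inputs and configuration give byte-identical files.
#'
#' @param summaries list of [BenchmarkSummary-class] objects.
#' @param overlap data.frame from [tpOverlap()] (or NULL).
#' @param config the [MatchConfig-class] used.
#' @param out_dir output directory (created if missing).
#' @return Named character vector of the file paths, invisibly.
#' @export
renderReport <- function(summaries, overlap, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output dir not writable: ", out_dir)
  tab <- do.call(rbind, lapply(summaries, summaryRow))
  txt <- utils::capture.output(print(format(tab), row.names = FALSE))
  paths <- c(txt = file.path(out_dir, "report.txt"),
             html = file.path(out_dir, "report.html"),
             json = file.path(out_dir, "summary.json"),
             upset = file.path(out_dir, "upset_data.tsv"))
  writeLines(c("svcompare benchmarking report", "", txt), paths["txt"])

  bars <- vapply(summaries, function(s) sprintf(
    "<tr><td>%s</td><td>%s %s</td><td>%s %s</td></tr>", s@source,
    htmlBar(s@metrics["recall"], "#4878a8"), fmtPct(s@metrics["recall"]),
    htmlBar(s@metrics["precision"], "#58a868"), fmtPct(s@metrics["precision"])),
    character(1))
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            "<title>svcompare report</title></head><body>",
            "<h1>svcompare benchmarking report</h1>",
            "<h2>Per-callset metrics</h2>", htmlTable(tab),
            "<h2>Recall / precision</h2>",
            "<table><tr><th>callset</th><th>recall</th><th>precision</th></tr>",
            bars, "</table>")
  if (!is.null(overlap) && nrow(overlap)) {
    ob <- vapply(seq_len(nrow(overlap)), function(i) sprintf(
      "<tr><td>%s</td><td>%s %d</td></tr>", overlap$combination[i],
      htmlBar(overlap$count[i] / max(overlap$count), "#a85858"),
      overlap$count[i]), character(1))
    html <- c(html, "<h2>Benchmark TP overlap (upset data)</h2>",
              "<table><tr><th>combination</th><th>count</th></tr>", ob,
              "</table>")
  }
  html <- c(html, "</body></html>")
  writeLines(html, paths["html"])

  write_json(list(callsets = lapply(summaries, summaryJSON),
                  tp_overlap = overlap, config = configEcho(config)),
             paths["json"], auto_unbox = TRUE, digits = NA, pretty = TRUE,
             na = "null")
  if (is.null(overlap))
    overlap <- data.frame(combination = character(), degree = integer(),
                          count = integer())
  utils::write.table(overlap, paths["upset"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
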