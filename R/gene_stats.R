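## gene_stats module: map unit-level association p-values onto per-gene
## scores on the -log10 p scale. Five statistics: gene-wise collapsing p,
## min / mean-log p over 5-kb windows overlapping the gene (rare variants),
## and min / mean-log p over the SNPs in the gene (common variants).

GENE_STATISTICS <- c("genewise", "min_window", "mlp_window", "min_snp", "mlp_snp")

#' Assign sliding windows to genes by overlap
#'
#' A window is assigned to every gene whose span it overlaps by at least one
#' base pair (`mode = "overlap"`), or only to genes that fully contain it
#' (`mode = "containment"`). Both inputs use 0-based half-open coordinates.
#'
#' @param windows Data frame with `unit_id`, `chrom`, `start`, `end` (e.g.
#'   the window rows of a [collapsing_scan()] result).
#' @param genes Gene annotation: `gene`, `chrom`, `start`, `end`.
#' @param mode Overlap rule.
#' @return Data frame with columns `gene`, `unit_id` (one row per pair).
#' @export
assign_windows_to_genes <- function(windows, genes,
                                    mode = c("overlap", "containment")) {
  mode <- match.arg(mode)
  pairs <- lapply(seq_len(nrow(genes)), function(i) {
    hit <- windows$chrom == genes$chrom[i] &
      (if (mode == "overlap")
        windows$start < genes$end[i] & windows$end > genes$start[i]
       else
         windows$start >= genes$start[i] & windows$end <= genes$end[i])
    if (!any(hit)) return(NULL)
    data.frame(gene = genes$gene[i], unit_id = windows$unit_id[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pairs)
  if (is.null(out)) out <- data.frame(gene = character(), unit_id = character())
  out
}

#' Per-gene scores from unit-level association p-values
#'
#' Aggregates testable unit p-values into one score per gene on the -log10
#' scale: `genewise` transforms the gene-based collapsing p; `min_window` /
#' `min_snp` transform the minimum p over the gene's windows / SNPs;
#' `mlp_window` / `mlp_snp` average -log10 p over them. Untestable units are
#' excluded; genes with no testable unit are absent from the output (not
#' scored zero), so the downstream gene universe contains only covered genes.
#'
#' @param results [collapsing_scan()] rows of the kind the statistic expects:
#'   gene units for `genewise`, window units of one size for `*_window`,
#'   SNP units for `*_snp`.
#' @param statistic One of `"genewise"`, `"min_window"`, `"mlp_window"`,
#'   `"min_snp"`, `"mlp_snp"`.
#' @param window_map Gene-to-window mapping from
#'   [assign_windows_to_genes()]; required for the window statistics.
#' @return Data frame: `gene`, `statistic_id`, `score` (>= 0), `n_units`.
#' @export
score_genes <- function(results, statistic = GENE_STATISTICS, window_map = NULL) {
  statistic <- match.arg(statistic)
  expected_kind <- switch(statistic,
    genewise = "gene", min_window = "window", mlp_window = "window",
    min_snp = "snp", mlp_snp = "snp")
  if (!all(results$unit_kind == expected_kind))
    stopf("statistic '%s' expects results of unit kind '%s' only",
          statistic, expected_kind)
  r <- results[!is.na(results$p_value), , drop = FALSE]
  if (nrow(r) == 0)
    return(data.frame(gene = character(), statistic_id = character(),
                      score = numeric(), n_units = integer()))

  if (statistic == "genewise") {
    agg <- data.frame(gene = r$gene, score = -log10(r$p_value), n_units = 1L)
  } else if (statistic %in% c("min_window", "mlp_window")) {
    if (is.null(window_map))
      stopf("window statistics require a window_map")
    mm <- merge(window_map, r[, c("unit_id", "p_value")], by = "unit_id")
    agg <- aggregate_scores(mm$gene, mm$p_value, statistic)
  } else {
    agg <- aggregate_scores(r$gene, r$p_value, statistic)
  }
  agg <- agg[order(agg$gene), , drop = FALSE]
  data.frame(gene = agg$gene, statistic_id = statistic,
             score = agg$score, n_units = agg$n_units,
             stringsAsFactors = FALSE, row.names = NULL)
}

aggregate_scores <- function(gene, p, statistic) {
  sp <- split(p, gene)
  score <- if (startsWith(statistic, "min"))
    vapply(sp, function(x) -log10(min(x)), numeric(1))
  else
    vapply(sp, function(x) mean(-log10(x)), numeric(1))
  data.frame(gene = names(sp), score = unname(score),
             n_units = unname(lengths(sp)), stringsAsFactors = FALSE)
}

#' Run all requested gene statistics on a scan
#'
#' Convenience wrapper selecting the right unit kind (and the 5-kb windows
#' for the window statistics, the size carried forward in the analysis) for
#' each statistic.
#'
#' @param results Full [collapsing_scan()] output.
#' @param genes Gene annotation.
#' @param statistics Statistics to compute.
#' @param window_size Window size feeding the window statistics (default
#'   5000 bp).
#' @return Named list of [score_genes()] data frames.
#' @export
score_genes_all <- function(results, genes, statistics = GENE_STATISTICS,
                            window_size = 5000) {
  win <- results[results$unit_kind == "window" & results$size == window_size, ,
                 drop = FALSE]
  wmap <- if (any(c("min_window", "mlp_window") %in% statistics))
    assign_windows_to_genes(win, genes) else NULL
  out <- lapply(statistics, function(s) {
    r <- switch(s,
      genewise = results[results$unit_kind == "gene", , drop = FALSE],
      min_window = win, mlp_window = win,
      results[results$unit_kind == "snp", , drop = FALSE])
    score_genes(r, s, window_map = wmap)
  })
  setNames(out, statistics)
}
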