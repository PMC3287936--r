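## mlp_enrichment module: pathway analysis with the mean log p-value (MLP)
## statistic and a gene-resampling permutation null.

#' Gene-set collection constructor
#'
#' @param sets Named list of character vectors (member genes; duplicates are
#'   collapsed).
#' @param descriptions Optional named character vector of set descriptions.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, function(x) unique(as.character(x)))
  if (any(lengths(sets) == 0)) stopf("empty gene sets are not allowed")
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, descriptions = descriptions[names(sets)]),
            class = "gene_set_collection")
}

#' Read gene sets from a GMT file
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(structure(list(sets = setNames(list(), character()),
                          descriptions = setNames(character(), character())),
                     class = "gene_set_collection"))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stopf("GMT parse error at line %d: fewer than 3 tab-separated fields", bad[1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  desc <- setNames(vapply(fields, `[[`, character(1), 2L), names(sets))
  gene_set_collection(sets, desc)
}

#' Write gene sets to a GMT file
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Mean log p-value statistic of a gene set
#'
#' Arithmetic mean of the member genes' scores on the -log10 p scale,
#' restricted to genes present in the scored universe.
#'
#' @param scores Named numeric vector of gene scores (-log10 p scale).
#' @param set_members Character vector of member gene names.
#' @param min_set_size Minimum number of scored members (default 3); sets
#'   below it are skipped (returns `NULL`).
#' @return List with `observed_mlp` and `n_genes_used`, or `NULL` when fewer
#'   than `min_set_size` members are scored.
#' @export
gene_set_mlp <- function(scores, set_members, min_set_size = 3) {
  used <- intersect(unique(set_members), names(scores))
  if (length(used) < min_set_size) return(NULL)
  list(observed_mlp = mean(scores[used]), n_genes_used = length(used))
}

#' Permutation p-value for an observed MLP statistic
#'
#' The null is built by drawing `set_size` genes from the scored universe
#' without replacement `n_perm` times and averaging their scores; the
#' p-value uses the plus-one correction
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param observed_mlp Observed mean score of the set.
#' @param universe_scores Numeric vector of all gene scores in the universe.
#' @param set_size Number of genes drawn per permutation.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional seed; omit to draw from the current RNG stream.
#' @param return_null Also return the null sample.
#' @return List with `perm_p`, `n_perm`, and (optionally) `null_sample`.
#' @export
permutation_p <- function(observed_mlp, universe_scores, set_size, n_perm = 1000,
                          seed = NULL, return_null = FALSE) {
  if (set_size > length(universe_scores))
    stopf("set_size exceeds the universe size")
  if (n_perm < 100) stopf("n_perm must be at least 100")
  draw <- function() {
    vapply(seq_len(n_perm), function(i) {
      mean(universe_scores[sample.int(length(universe_scores), set_size)])
    }, numeric(1))
  }
  null <- if (is.null(seed)) draw() else with_seed(seed, draw())
  out <- list(perm_p = (1 + sum(null >= observed_mlp)) / (n_perm + 1),
              n_perm = n_perm)
  if (return_null) out$null_sample <- null
  out
}

#' Rank gene sets by MLP permutation p-value
#'
#' Scores every analyzable set, computes its permutation p-value from a
#' common seeded stream, and ranks ascending by p-value with ties broken by
#' larger observed MLP, then by set name.
#'
#' @param collection A `gene_set_collection`.
#' @param scores Named numeric vector of gene scores, or a [score_genes()]
#'   data frame.
#' @param n_perm Permutations per set (default 10000).
#' @param seed Master seed for the permutation stream.
#' @param min_set_size Minimum scored members per set (default 3).
#' @param top_k Number of top rows kept in the `top` attribute (default 20).
#' @param report_k Number of rows in the printed report (default 6).
#' @return Data frame of class `gene_set_results`: `set_name`,
#'   `n_genes_used`, `observed_mlp`, `perm_p`, `fdr`, `rank`, `n_perm`,
#'   ordered by rank; skipped sets (too few scored members) are recorded in
#'   the `skipped` attribute.
#' @export
rank_gene_sets <- function(collection, scores, n_perm = 10000, seed = 1,
                           min_set_size = 3, top_k = 20, report_k = 6) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.data.frame(scores)) scores <- setNames(scores$score, scores$gene)
  nm <- sort(names(collection$sets))
  rows <- vector("list", length(nm))
  skipped <- character(0)
  with_seed(seed, {
    for (i in seq_along(nm)) {
      mlp <- gene_set_mlp(scores, collection$sets[[nm[i]]], min_set_size)
      if (is.null(mlp)) {
        skipped <- c(skipped, nm[i])
        next
      }
      pp <- permutation_p(mlp$observed_mlp, unname(scores), mlp$n_genes_used,
                          n_perm = n_perm)
      rows[[i]] <- data.frame(set_name = nm[i], n_genes_used = mlp$n_genes_used,
                              observed_mlp = mlp$observed_mlp,
                              perm_p = pp$perm_p, n_perm = n_perm,
                              stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no analyzable gene set (all below min_set_size)")
  ord <- order(out$perm_p, -out$observed_mlp, out$set_name)
  out <- out[ord, , drop = FALSE]
  out$fdr <- p.adjust(out$perm_p, method = "BH")
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("set_name", "n_genes_used", "observed_mlp", "perm_p", "fdr",
                 "rank", "n_perm")]
  attr(out, "skipped") <- skipped
  attr(out, "top_k") <- min(top_k, nrow(out))
  attr(out, "report_k") <- min(report_k, nrow(out))
  class(out) <- c("gene_set_results", class(out))
  out
}

#' Markdown top-pathway report
#'
#' Formats the leading rows of one or more ranked gene-set tables as a
#' markdown report (statistic, top pathways, permutation p-value at 4
#' significant digits).
#'
#' @param results Named list of `gene_set_results` tables (names = statistic
#'   labels) or a single table.
#' @param report_k Rows per statistic (default 6).
#' @return Character vector of markdown lines.
#' @export
top_pathway_report <- function(results, report_k = 6) {
  if (inherits(results, "gene_set_results")) results <- list(results = results)
  lines <- c("# Top pathways by MLP permutation p-value", "")
  for (nm in names(results)) {
    r <- head(results[[nm]], report_k)
    lines <- c(lines, sprintf("## %s", nm), "",
               "| rank | pathway | genes used | observed MLP | p-value |",
               "|-----:|---------|-----------:|-------------:|--------:|",
               sprintf("| %d | %s | %d | %s | %s |", r$rank, r$set_name,
                       r$n_genes_used, signif(r$observed_mlp, 4),
                       signif(r$perm_p, 4)),
               "")
  }
  lines
}
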