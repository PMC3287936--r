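## pipeline module: simulate/load -> QC -> collapsing scan -> gene scores ->
## MLP enrichment -> boosting, from one config, with a file manifest.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] for synthetic mode, or `NULL` with
#'   `input_dir` set to a directory of cohort files ([write_cohort()] layout).
#' @param input_dir Directory of cohort files (file mode).
#' @param out_dir Output directory.
#' @param window_sizes Sliding-window sizes in bp.
#' @param carry_window_size Window size carried into the gene statistics
#'   (default 5000 bp).
#' @param maf_max Rare-variant threshold.
#' @param statistics Gene statistics to run (see [score_genes()]).
#' @param n_perm Permutations per gene set.
#' @param hwe_alpha HWE removal threshold in controls.
#' @param prune_r2,prune_window,prune_step Correlated-marker pruning
#'   parameters.
#' @param mds_k Number of stratification components.
#' @param sgb An [sgb_params()].
#' @param sgb_top_snps Common SNPs (smallest single-SNP p) fed to boosting.
#' @param sgb_top_genes Genes (smallest gene-wise collapsing p) whose rare
#'   variants are fed to boosting.
#' @param seed Master seed; every stochastic stage derives its own seed from
#'   it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            out_dir = tempfile("rarepath_run_"),
                            window_sizes = c(1000, 5000, 25000, 50000, 100000),
                            carry_window_size = 5000,
                            maf_max = 0.05,
                            statistics = GENE_STATISTICS,
                            n_perm = 10000,
                            hwe_alpha = 1e-4,
                            prune_r2 = 0.2, prune_window = 50, prune_step = 5,
                            mds_k = 2,
                            sgb = sgb_params(),
                            sgb_top_snps = 100, sgb_top_genes = 20,
                            seed = 1) {
  if (is.null(sim) && is.null(input_dir))
    stopf("either sim (synthetic mode) or input_dir (file mode) is required")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stopf("input_dir does not exist: %s", input_dir)
  if (!carry_window_size %in% window_sizes)
    stopf("carry_window_size must be one of window_sizes")
  structure(list(sim = sim, input_dir = input_dir, out_dir = out_dir,
                 window_sizes = window_sizes,
                 carry_window_size = carry_window_size,
                 maf_max = maf_max, statistics = statistics, n_perm = n_perm,
                 hwe_alpha = hwe_alpha, prune_r2 = prune_r2,
                 prune_window = prune_window, prune_step = prune_step,
                 mds_k = mds_k, sgb = sgb, sgb_top_snps = sgb_top_snps,
                 sgb_top_genes = sgb_top_genes, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, QC (HWE filter in controls, correlated-marker
#' pruning, MDS), the collapsing/association scan, gene scoring, MLP pathway
#' enrichment per statistic, and boosting on preselected SNPs; writes all
#' stage outputs under `config$out_dir` and a manifest listing every file
#' with its MD5 hash, stage, seed and wall time. Given the same config and
#' master seed, all outputs are byte-identical across runs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest data frame.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  manifest <- list()
  log_path <- file.path(out, "run.log")
  cat(sprintf("rarepath pipeline, master seed %d\n", config$seed), file = log_path)
  note <- function(msg) {
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  record <- function(stage, files, seed, elapsed) {
    files <- unname(files)
    rel <- sub("^/", "", substring(files, nchar(out) + 1))
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, file = rel, md5 = unname(tools::md5sum(files)),
      seed = seed, wall_time_s = round(unname(elapsed), 3),
      stringsAsFactors = FALSE)
  }

  ## stage 1: cohort
  t0 <- proc.time()[3]
  if (!is.null(config$input_dir)) {
    cohort <- read_cohort(config$input_dir)
    sim_seed <- NA_integer_
    note(sprintf("load: cohort from %s", config$input_dir))
  } else {
    sim_cfg <- config$sim
    sim_seed <- derive_seed(config$seed, 1)
    sim_cfg$seed <- sim_seed
    cohort <- simulate_cohort(sim_cfg)
    note(sprintf("simulate: %d subjects, %d variants, %d genes, %d sets",
                 nrow(cohort$genotypes), ncol(cohort$genotypes),
                 nrow(cohort$genes), length(cohort$gene_sets$sets)))
  }
  cdir <- file.path(out, "cohort")
  cohort_files <- write_cohort(cohort, cdir)
  summ <- cohort_summary(cohort)
  write_tsv(summ, file.path(out, "cohort_summary.tsv"))
  record("cohort", c(cohort_files, file.path(out, "cohort_summary.tsv")),
         sim_seed, proc.time()[3] - t0)

  ## stage 2: QC
  t0 <- proc.time()[3]
  hw <- hwe_filter(cohort$genotypes, cohort$phenotypes, alpha = config$hwe_alpha)
  write_tsv(hw$removed, file.path(out, "hwe_removed.tsv"))
  kept <- prune_correlated(hw$genotypes, r2_max = config$prune_r2,
                           window = config$prune_window, step = config$prune_step)
  mds <- mds_components(hw$genotypes[, kept, drop = FALSE], k = config$mds_k)
  mds_df <- data.frame(subject_id = rownames(mds$coordinates),
                       mds$coordinates, stringsAsFactors = FALSE)
  write_tsv(mds_df, file.path(out, "mds_components.tsv"))
  note(sprintf("qc: removed %d/%d variants by HWE; %d pruned markers for MDS",
               nrow(hw$removed), ncol(cohort$genotypes), length(kept)))
  record("qc", file.path(out, c("hwe_removed.tsv", "mds_components.tsv")),
         NA_integer_, proc.time()[3] - t0)
  cohort$genotypes <- hw$genotypes

  ## stage 3: collapsing scan
  t0 <- proc.time()[3]
  scan <- collapsing_scan(cohort, window_sizes = config$window_sizes,
                          maf_max = config$maf_max)
  scan_files <- character(0)
  flat_cols <- setdiff(names(scan), c("member_variants", "gene_overlaps"))
  for (size in config$window_sizes) {
    fp <- file.path(out, sprintf("collapsing_%dkb.tsv", size / 1000))
    write_tsv(scan[scan$unit_kind == "window" & scan$size == size, flat_cols], fp)
    scan_files <- c(scan_files, fp)
  }
  fp <- file.path(out, "collapsing_genewise.tsv")
  write_tsv(scan[scan$unit_kind == "gene", flat_cols], fp)
  scan_files <- c(scan_files, fp)
  fp <- file.path(out, "snp_assoc.tsv")
  write_tsv(scan[scan$unit_kind == "snp", flat_cols], fp)
  scan_files <- c(scan_files, fp)
  mh <- manhattan_data(scan[scan$unit_kind == "window" &
                              scan$size == config$carry_window_size, ])
  fp <- file.path(out, "manhattan_windows.tsv")
  write_tsv(mh, fp)
  scan_files <- c(scan_files, fp)
  note(sprintf("collapse: %d units tested (%d untestable)",
               sum(!is.na(scan$p_value)), sum(is.na(scan$p_value))))
  record("collapsing", scan_files, NA_integer_, proc.time()[3] - t0)

  ## stage 4: gene scores
  t0 <- proc.time()[3]
  scores <- score_genes_all(scan, cohort$genes, statistics = config$statistics,
                            window_size = config$carry_window_size)
  score_files <- vapply(names(scores), function(s) {
    fp <- file.path(out, sprintf("gene_scores_%s.tsv", s))
    write_tsv(scores[[s]], fp)
    fp
  }, character(1))
  record("gene_stats", score_files, NA_integer_, proc.time()[3] - t0)

  ## stage 5: MLP enrichment
  t0 <- proc.time()[3]
  enr_seed <- derive_seed(config$seed, 5)
  enrich <- list()
  enr_files <- character(0)
  for (s in names(scores)) {
    if (nrow(scores[[s]]) == 0) next
    res <- rank_gene_sets(cohort$gene_sets, scores[[s]], n_perm = config$n_perm,
                          seed = enr_seed)
    enrich[[s]] <- res
    fp <- file.path(out, sprintf("gene_set_results_%s.tsv", s))
    write_tsv(as.data.frame(res), fp)
    enr_files <- c(enr_files, fp)
  }
  fp <- file.path(out, "top_pathways.md")
  writeLines(top_pathway_report(enrich), fp)
  enr_files <- c(enr_files, fp)
  record("mlp_enrichment", enr_files, enr_seed, proc.time()[3] - t0)

  ## stage 6: boosting on preselected SNPs + MDS components + covariates
  t0 <- proc.time()[3]
  sgb_seed <- derive_seed(config$seed, 6)
  snp_res <- scan[scan$unit_kind == "snp" & !is.na(scan$p_value), ]
  top_snps <- head(snp_res$unit_id[order(snp_res$p_value)], config$sgb_top_snps)
  gene_res <- scan[scan$unit_kind == "gene" & !is.na(scan$p_value), ]
  top_genes <- head(gene_res$gene[order(gene_res$p_value)], config$sgb_top_genes)
  rare_maf <- sample_maf(cohort$genotypes)
  rare_in_top <- cohort$variants$variant_id[
    cohort$variants$gene %in% top_genes &
      cohort$variants$variant_id %in% colnames(cohort$genotypes)[rare_maf < config$maf_max]]
  feat_ids <- unique(c(top_snps, rare_in_top))
  ph <- cohort$phenotypes[match(rownames(cohort$genotypes),
                                cohort$phenotypes$subject_id), ]
  geno_feat <- cohort$genotypes[, feat_ids, drop = FALSE]
  geno_feat[is.na(geno_feat)] <- 0L  # boosting requires complete features
  features <- cbind(geno_feat,
                    mds$coordinates[rownames(cohort$genotypes), , drop = FALSE],
                    age = ph$age, sex = ph$sex, smoke = ph$smoke)
  sgb_cfg <- config$sgb
  sgb_cfg$seed <- sgb_seed
  model <- fit_sgb(features, ph$affected, sgb_cfg)
  imp <- variable_importance(model)
  imp$gene <- cohort$variants$gene[match(imp$variable, cohort$variants$variant_id)]
  if (!is.null(cohort$truth))
    imp$is_causal <- imp$variable %in% cohort$truth$causal_variants |
      (!is.na(imp$gene) & imp$gene %in% cohort$truth$causal_genes)
  write_tsv(imp, file.path(out, "sgb_importance.tsv"))
  preds <- data.frame(subject_id = rownames(features),
                      p_case = predict_sgb(model, features),
                      stringsAsFactors = FALSE)
  write_tsv(preds, file.path(out, "sgb_predictions.tsv"))
  write_sgb_model(model, file.path(out, "sgb_model.json"))
  note(sprintf("boost: %d features, %d trees, %d selected at cutoff %.2f",
               ncol(features), sgb_cfg$n_trees, sum(imp$selected),
               sgb_cfg$importance_cutoff))
  record("boosting", file.path(out, c("sgb_importance.tsv",
                                      "sgb_predictions.tsv", "sgb_model.json")),
         sgb_seed, proc.time()[3] - t0)

  manifest <- do.call(rbind, manifest)
  write_tsv(manifest, file.path(out, "manifest.tsv"))
  invisible(manifest)
}
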