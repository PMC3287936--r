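## synthetic_data module: seeded generator for a mini-exome-like case-control
## cohort with known ground truth (causal pathways, genes and variants).

#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set of [simulate_cohort()]. Defaults
#' describe a 697-subject case-control cohort with ~30% affected subjects,
#' three subpopulations, and an allele-frequency spectrum dominated by rare
#' (MAF 1-5%) and very rare (MAF < 1%) variants, with causal rare alleles
#' concentrated in the genes of designated pathways and a smoking covariate
#' associated with case status.
#'
#' @param n_subjects Number of subjects.
#' @param case_fraction Target marginal fraction of affected subjects.
#' @param n_populations Number of subpopulations.
#' @param divergence Fst-like drift parameter in `[0, 1)` of the
#'   Balding-Nichols model; population allele frequencies are drawn from
#'   `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral frequency `p`.
#' @param n_genes Number of genes laid head-to-tail on one synthetic chromosome.
#' @param variants_per_gene Variants placed uniformly within each gene.
#' @param gene_length,gene_gap Gene span and inter-gene gap in base pairs.
#' @param n_sets,genes_per_set Pathway collection layout: `n_sets` disjoint
#'   sets of `genes_per_set` consecutive genes (requires
#'   `n_sets * genes_per_set <= n_genes`).
#' @param causal_set_ids Names of the pathways holding the causal genes
#'   (default: the first set).
#' @param n_causal_genes Number of causal genes, sampled from the causal sets.
#' @param rare_fraction,very_rare_fraction Expected fractions of variants with
#'   ancestral MAF < 0.05 and < 0.01 (`very_rare_fraction <= rare_fraction`).
#' @param carrier_effect Log-odds increment on affection per causal gene in
#'   which a subject carries at least one rare minor allele.
#' @param smoke_effect Log-odds increment for smoking.
#' @param pop_effect Half-range of the (centered) per-population intercepts.
#' @param base_rate Intercept on the probability scale; covariate terms are
#'   mean-centered so the marginal case fraction stays near `base_rate`.
#' @param smoke_prevalence Marginal smoking prevalence.
#' @param maf_min Floor on ancestral MAF.
#' @param missing_rate Fraction of dosages set missing at random.
#' @param seed Integer seed; identical configurations give bit-identical
#'   cohorts.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 697,
                       case_fraction = 0.30,
                       n_populations = 3,
                       divergence = 0.10,
                       n_genes = 300,
                       variants_per_gene = 12,
                       gene_length = 20000,
                       gene_gap = 5000,
                       n_sets = 30,
                       genes_per_set = 10,
                       causal_set_ids = NULL,
                       n_causal_genes = 6,
                       rare_fraction = 0.87,
                       very_rare_fraction = 0.74,
                       carrier_effect = 1.4,
                       smoke_effect = 0.7,
                       pop_effect = 0.1,
                       base_rate = case_fraction,
                       smoke_prevalence = 0.25,
                       maf_min = 5e-4,
                       missing_rate = 0,
                       seed = 1) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), case_fraction = case_fraction,
    n_populations = as.integer(n_populations), divergence = divergence,
    n_genes = as.integer(n_genes), variants_per_gene = as.integer(variants_per_gene),
    gene_length = as.integer(gene_length), gene_gap = as.integer(gene_gap),
    n_sets = as.integer(n_sets), genes_per_set = as.integer(genes_per_set),
    causal_set_ids = causal_set_ids, n_causal_genes = as.integer(n_causal_genes),
    rare_fraction = rare_fraction, very_rare_fraction = very_rare_fraction,
    carrier_effect = carrier_effect, smoke_effect = smoke_effect,
    pop_effect = pop_effect, base_rate = base_rate,
    smoke_prevalence = smoke_prevalence, maf_min = maf_min,
    missing_rate = missing_rate, seed = as.integer(seed)
  )
  if (is.null(cfg$causal_set_ids)) cfg$causal_set_ids <- set_names_for(1L)
  props <- c(cfg$case_fraction, cfg$rare_fraction, cfg$very_rare_fraction,
             cfg$base_rate, cfg$smoke_prevalence, cfg$missing_rate)
  if (any(props < 0 | props > 1)) stopf("all proportions must lie in [0, 1]")
  if (cfg$very_rare_fraction > cfg$rare_fraction)
    stopf("very_rare_fraction must not exceed rare_fraction")
  if (cfg$divergence < 0 || cfg$divergence >= 1)
    stopf("divergence must lie in [0, 1)")
  if (cfg$n_sets * cfg$genes_per_set > cfg$n_genes)
    stopf("n_sets * genes_per_set exceeds n_genes")
  if (cfg$n_causal_genes > cfg$genes_per_set * length(cfg$causal_set_ids))
    stopf("n_causal_genes exceeds the genes available in the causal sets")
  structure(cfg, class = "sim_config")
}

set_names_for <- function(i) sprintf("SET_%03d", i)

# Ancestral MAF spectrum: three strata (very rare < 0.01, rare 0.01-0.05,
# common 0.05-0.5); within the rare strata a Beta(1,2) shape concentrates mass
# toward the lower bound, the common stratum is uniform.
draw_ancestral_maf <- function(m, cfg) {
  w <- c(cfg$very_rare_fraction,
         cfg$rare_fraction - cfg$very_rare_fraction,
         1 - cfg$rare_fraction)
  stratum <- sample.int(3L, m, replace = TRUE, prob = w)
  lo <- c(cfg$maf_min, 0.01, 0.05)[stratum]
  hi <- c(0.01, 0.05, 0.50)[stratum]
  shape <- ifelse(stratum == 3L, 1, 2)
  lo + (hi - lo) * rbeta(m, 1, shape)
}

#' Simulate a mini-exome-like case-control cohort
#'
#' Generates genotypes, phenotypes, gene annotation, pathway collection and a
#' ground-truth record from a [sim_config()]. Ancestral minor-allele
#' frequencies follow a rare-skewed mixture spectrum; population-specific
#' frequencies drift from them under a Balding-Nichols model; genotypes are
#' Hardy-Weinberg within each population; affection status follows a logistic
#' model on the number of causal genes in which the subject carries a rare
#' allele, smoking, and a small population intercept, with all terms
#' mean-centered around `qlogis(base_rate)`.
#'
#' @param config A [sim_config()].
#' @return An object of class `cohort`: a list with elements `genotypes`
#'   (subjects x variants dosage matrix, values 0/1/2/NA), `phenotypes`
#'   (data frame: subject_id, affected, age, sex, smoke, population),
#'   `variants` (variant_id, chrom, pos, gene; positions 0-based),
#'   `genes` (gene, chrom, start, end; 0-based half-open), `gene_sets`
#'   (a `gene_set_collection`), and `truth` (causal sets/genes/variants and
#'   the per-subject causal-carrier count).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_subjects
    m <- cfg$n_genes * cfg$variants_per_gene

    ## gene layout on one synthetic chromosome, 0-based half-open spans
    gene_names <- sprintf("GENE_%04d", seq_len(cfg$n_genes))
    pitch <- cfg$gene_length + cfg$gene_gap
    genes <- data.frame(
      gene = gene_names, chrom = "1",
      start = (seq_len(cfg$n_genes) - 1L) * pitch,
      end = (seq_len(cfg$n_genes) - 1L) * pitch + cfg$gene_length,
      stringsAsFactors = FALSE
    )

    ## variant positions uniform within genes
    pos <- unlist(lapply(seq_len(cfg$n_genes), function(i) {
      genes$start[i] + sort(sample.int(cfg$gene_length, cfg$variants_per_gene))
    })) - 1L
    variants <- data.frame(
      variant_id = sprintf("V%06d", seq_len(m)), chrom = "1", pos = pos,
      gene = rep(gene_names, each = cfg$variants_per_gene),
      stringsAsFactors = FALSE
    )

    ## pathway collection: disjoint blocks of consecutive genes
    sets <- lapply(seq_len(cfg$n_sets), function(i) {
      gene_names[((i - 1L) * cfg$genes_per_set + 1L):(i * cfg$genes_per_set)]
    })
    names(sets) <- set_names_for(seq_len(cfg$n_sets))
    gene_sets <- gene_set_collection(
      sets, descriptions = setNames(sprintf("synthetic pathway %d", seq_len(cfg$n_sets)),
                                    names(sets))
    )
    if (!all(cfg$causal_set_ids %in% names(sets)))
      stopf("causal_set_ids not present in the generated collection")

    ## causal genes and their rare variants (rarity by ancestral MAF)
    maf0 <- draw_ancestral_maf(m, cfg)
    causal_pool <- unlist(sets[cfg$causal_set_ids], use.names = FALSE)
    causal_genes <- sort(sample(causal_pool, cfg$n_causal_genes))
    causal_variants <- variants$variant_id[variants$gene %in% causal_genes & maf0 < 0.05]

    ## Balding-Nichols population frequencies
    pop <- sort(rep_len(seq_len(cfg$n_populations), n))
    if (cfg$divergence > 0 && cfg$n_populations > 1) {
      f <- cfg$divergence
      freqs <- matrix(rbeta(cfg$n_populations * m,
                            rep(maf0, each = cfg$n_populations) * (1 - f) / f,
                            rep(1 - maf0, each = cfg$n_populations) * (1 - f) / f),
                      nrow = cfg$n_populations)
    } else {
      freqs <- matrix(rep(maf0, each = cfg$n_populations), nrow = cfg$n_populations)
    }

    ## genotypes: HWE binomial within population
    geno <- matrix(0L, n, m)
    for (k in seq_len(cfg$n_populations)) {
      rows <- which(pop == k)
      geno[rows, ] <- rbinom(length(rows) * m, 2L,
                             rep(freqs[k, ], each = length(rows)))
    }
    dimnames(geno) <- list(sprintf("SUBJ_%04d", seq_len(n)), variants$variant_id)
    if (cfg$missing_rate > 0) {
      miss <- runif(length(geno)) < cfg$missing_rate
      geno[miss] <- NA_integer_
    }

    ## per-subject count of causal genes carrying >= 1 rare allele
    carrier_count <- integer(n)
    for (g in causal_genes) {
      vg <- intersect(causal_variants, variants$variant_id[variants$gene == g])
      if (length(vg))
        carrier_count <- carrier_count +
          as.integer(rowSums(geno[, vg, drop = FALSE] >= 1L, na.rm = TRUE) > 0L)
    }

    ## phenotypes: centered logistic model keeps the marginal near base_rate
    smoke <- rbinom(n, 1L, cfg$smoke_prevalence)
    sex <- rbinom(n, 1L, 0.5)
    age <- round(runif(n, 20, 70))
    pop_int <- if (cfg$n_populations > 1) {
      v <- seq_len(cfg$n_populations) - (cfg$n_populations + 1) / 2
      cfg$pop_effect * v / max(abs(v))
    } else 0
    lp <- qlogis(cfg$base_rate) +
      cfg$carrier_effect * (carrier_count - mean(carrier_count)) +
      cfg$smoke_effect * (smoke - mean(smoke)) +
      (if (cfg$n_populations > 1) pop_int[pop] - mean(pop_int[pop]) else 0)
    affected <- rbinom(n, 1L, plogis(lp))

    phenotypes <- data.frame(
      subject_id = rownames(geno), affected = affected, age = age,
      sex = sex, smoke = smoke, population = pop, stringsAsFactors = FALSE
    )

    structure(list(
      genotypes = geno, phenotypes = phenotypes, variants = variants,
      genes = genes, gene_sets = gene_sets,
      truth = list(causal_sets = cfg$causal_set_ids, causal_genes = causal_genes,
                   causal_variants = causal_variants,
                   carrier_count = setNames(carrier_count, rownames(geno))),
      config = cfg
    ), class = "cohort")
  })
}

#' Case-control composition summary
#'
#' Counts and percentages of affected and unaffected subjects, plus smoking
#' prevalence by case status (percentages rounded to one decimal, matching
#' report conventions).
#'
#' @param x A `cohort` or a phenotype data frame with an `affected` column.
#' @return A one-row data frame: n, n_affected, n_unaffected, pct_affected,
#'   pct_unaffected, pct_smoke_affected, pct_smoke_unaffected.
#' @export
cohort_summary <- function(x) {
  ph <- if (inherits(x, "cohort")) x$phenotypes else x
  stopifnot(is.data.frame(ph), "affected" %in% names(ph))
  n <- nrow(ph)
  na <- sum(ph$affected == 1)
  out <- data.frame(
    n = n, n_affected = na, n_unaffected = n - na,
    pct_affected = round(100 * na / n, 1),
    pct_unaffected = round(100 * (n - na) / n, 1)
  )
  if ("smoke" %in% names(ph)) {
    out$pct_smoke_affected <- round(100 * mean(ph$smoke[ph$affected == 1]), 1)
    out$pct_smoke_unaffected <- round(100 * mean(ph$smoke[ph$affected == 0]), 1)
  }
  out
}

#' Simulate a flat SNP panel with a few strong causal SNPs
#'
#' Companion generator for predictor-screening experiments: independent SNP
#' dosages (no gene structure), a handful of causal SNPs with additive
#' log-odds effects, and a centered logistic affection model. Used to study
#' variable-importance recovery amid many null predictors.
#'
#' @param n_subjects Number of subjects.
#' @param n_null Number of null SNPs.
#' @param n_causal Number of causal SNPs.
#' @param effect Per-allele log-odds increment of each causal SNP.
#' @param causal_maf Range of causal-SNP MAFs.
#' @param null_maf Range of null-SNP MAFs.
#' @param case_fraction Target marginal case fraction.
#' @param seed Integer seed.
#' @return List with `genotypes` (n x (n_null + n_causal) dosage matrix),
#'   `affected`, and `causal` (causal SNP column names).
#' @export
simulate_snp_panel <- function(n_subjects = 697, n_null = 500, n_causal = 5,
                               effect = 0.9, causal_maf = c(0.10, 0.30),
                               null_maf = c(0.05, 0.50),
                               case_fraction = 0.30, seed = 1) {
  with_seed(seed, {
    m <- n_null + n_causal
    maf <- c(runif(n_causal, causal_maf[1], causal_maf[2]),
             runif(n_null, null_maf[1], null_maf[2]))
    geno <- matrix(rbinom(n_subjects * m, 2L, rep(maf, each = n_subjects)),
                   n_subjects, m)
    colnames(geno) <- c(sprintf("CAUSAL_%02d", seq_len(n_causal)),
                        sprintf("NULL_%04d", seq_len(n_null)))
    score <- geno[, seq_len(n_causal), drop = FALSE] %*% rep(effect, n_causal)
    lp <- qlogis(case_fraction) + score - mean(score)
    affected <- rbinom(n_subjects, 1L, plogis(lp))
    list(genotypes = geno, affected = affected,
         causal = colnames(geno)[seq_len(n_causal)])
  })
}
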