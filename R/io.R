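## Cohort serialization: VCF (genotypes), TSVs (phenotypes, genes, variant->gene
## map, truth), GMT (pathways). Internal coordinates are 0-based half-open;
## VCF POS and the gene table on disk are 1-based inclusive.

#' Write a cohort to a directory
#'
#' Emits `genotypes.vcf` (VCF v4.2, GT only, unphased), `phenotypes.tsv`,
#' `genes.tsv` (1-based inclusive spans), `variants.tsv` (variant-to-gene
#' map), `gene_sets.gmt` and `truth.tsv`. [read_cohort()] round-trips the
#' result.
#'
#' @param cohort A `cohort` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stopf("directory not writable: %s", dir)
  paths <- c(
    genotypes = file.path(dir, "genotypes.vcf"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    genes = file.path(dir, "genes.tsv"),
    variants = file.path(dir, "variants.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.tsv")
  )

  write_vcf(cohort$genotypes, cohort$variants, paths[["genotypes"]])
  write_tsv(cohort$phenotypes[, c("subject_id", "affected", "age", "sex", "smoke")],
            paths[["phenotypes"]])
  genes_out <- cohort$genes
  genes_out$start <- genes_out$start + 1L  # to 1-based inclusive
  write_tsv(genes_out[, c("chrom", "start", "end", "gene")], paths[["genes"]])
  write_tsv(cohort$variants, paths[["variants"]])
  write_gmt(cohort$gene_sets, paths[["gene_sets"]])

  truth <- rbind(
    data.frame(kind = "causal_set", id = cohort$truth$causal_sets),
    data.frame(kind = "causal_gene", id = cohort$truth$causal_genes),
    data.frame(kind = "causal_variant", id = cohort$truth$causal_variants),
    data.frame(kind = "population",
               id = paste(cohort$phenotypes$subject_id,
                          cohort$phenotypes$population, sep = ":"))
  )
  write_tsv(truth, paths[["truth"]])
  invisible(paths)
}

write_vcf <- function(genotypes, variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=rarepath",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  ), con)
  m <- nrow(variants)
  if (m == 0L) return(invisible(path))
  gt <- matrix(c("0/0", "0/1", "1/1")[genotypes + 1L],
               nrow = nrow(genotypes), ncol = ncol(genotypes))
  gt[is.na(genotypes)] <- "./."
  lines <- vapply(seq_len(m), function(j) {
    paste(c(variants$chrom[j], variants$pos[j] + 1L, variants$variant_id[j],
            "A", "T", ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding the files emitted by [write_cohort()].
#' @return A `cohort` object (without the generator `config`).
#' @export
read_cohort <- function(dir) {
  vcf <- vcfR::read.vcfR(file.path(dir, "genotypes.vcf"), verbose = FALSE)
  variants <- read_tsv(file.path(dir, "variants.tsv"))
  variants$chrom <- as.character(variants$chrom)
  phen <- read_tsv(file.path(dir, "phenotypes.tsv"))
  genes <- read_tsv(file.path(dir, "genes.tsv"))
  genes <- data.frame(gene = genes$gene, chrom = as.character(genes$chrom),
                      start = genes$start - 1L,  # back to 0-based half-open
                      end = genes$end, stringsAsFactors = FALSE)
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))

  if (nrow(vcf@gt) > 0L) {
    gtm <- vcfR::extract.gt(vcf, element = "GT")
    dos <- matrix(NA_integer_, nrow = ncol(gtm), ncol = nrow(gtm),
                  dimnames = list(colnames(gtm), rownames(gtm)))
    map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
    dos[] <- map[t(gtm)]
  } else {
    dos <- matrix(integer(0), nrow = nrow(phen), ncol = 0L,
                  dimnames = list(phen$subject_id, NULL))
  }

  truth_df <- read_tsv(file.path(dir, "truth.tsv"))
  pops <- truth_df[truth_df$kind == "population", "id"]
  pop_map <- do.call(rbind, strsplit(pops, ":", fixed = TRUE))
  phen$population <- as.integer(pop_map[match(phen$subject_id, pop_map[, 1]), 2])
  truth <- list(
    causal_sets = truth_df$id[truth_df$kind == "causal_set"],
    causal_genes = truth_df$id[truth_df$kind == "causal_gene"],
    causal_variants = truth_df$id[truth_df$kind == "causal_variant"]
  )

  structure(list(genotypes = dos, phenotypes = phen, variants = variants,
                 genes = genes, gene_sets = sets, truth = truth),
            class = "cohort")
}
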