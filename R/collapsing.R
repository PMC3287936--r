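## collapsing module: rare-variant burden (carrier) tests over genes and
## overlapping sliding windows, plus single-SNP allelic tests for common
## variants. Coordinates are 0-based half-open throughout.

#' Tile sliding windows over the variant-bearing span
#'
#' Windows of `size` bp start at multiples of `step`, from the largest
#' multiple at or below the first variant position through the last variant
#' position; the final window is truncated at the span end. Each window is
#' annotated with its member variants and (optionally) every gene it overlaps
#' by at least one base pair.
#'
#' @param variants Data frame with `variant_id`, `chrom`, `pos` (0-based).
#' @param size Window size in base pairs.
#' @param step Window advance in base pairs; must satisfy `0 < step <= size`
#'   so no variant falls between windows.
#' @param genes Optional gene annotation (`gene`, `chrom`, `start`, `end`,
#'   0-based half-open) used to fill `gene_overlaps`.
#' @return Data frame with columns `unit_id`, `chrom`, `start`, `end`, and
#'   list columns `member_variants` and `gene_overlaps`.
#' @export
make_windows <- function(variants, size, step = size / 2, genes = NULL) {
  if (size <= 0) stopf("size must be positive")
  if (step <= 0 || step > size)
    stopf("step must satisfy 0 < step <= size (gaps would drop variants)")
  out <- lapply(split(variants, variants$chrom), function(v) {
    v <- v[order(v$pos), , drop = FALSE]
    span_lo <- min(v$pos)
    span_hi <- max(v$pos) + 1  # half-open span end
    starts <- seq(floor(span_lo / step) * step, max(v$pos), by = step)
    ends <- pmin(starts + size, span_hi)
    members <- lapply(seq_along(starts), function(i) {
      v$variant_id[v$pos >= starts[i] & v$pos < starts[i] + size]
    })
    df <- data.frame(
      unit_id = sprintf("win%d_%s_%d", as.integer(size), v$chrom[1],
                        as.integer(starts)),
      chrom = v$chrom[1], start = starts, end = ends,
      stringsAsFactors = FALSE
    )
    df$member_variants <- members
    df
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!is.null(genes)) {
    out$gene_overlaps <- lapply(seq_len(nrow(out)), function(i) {
      g <- genes[genes$chrom == out$chrom[i] &
                   genes$start < out$end[i] & genes$end > out$start[i], "gene"]
      as.character(g)
    })
  } else {
    out$gene_overlaps <- vector("list", nrow(out))
  }
  out
}

#' Rare-variant carrier indicator
#'
#' The rare set is the subset of `variant_ids` with sample MAF strictly below
#' `maf_max` (minor allele defined by the full-sample frequency). The
#' indicator is 1 iff the subject carries at least one minor allele at any
#' rare-set variant; missing dosages count as non-carrying.
#'
#' @param genotypes Subjects x variants dosage matrix.
#' @param variant_ids Variants forming the unit (non-empty).
#' @param maf_max Rare-variant MAF threshold (strict inequality).
#' @return Integer 0/1 vector per subject with attribute `rare_variants`, or
#'   `NULL` when the rare set is empty (unit untestable).
#' @export
carrier_status <- function(genotypes, variant_ids, maf_max = 0.05) {
  if (length(variant_ids) == 0) stopf("variant subset must be non-empty")
  sub <- genotypes[, variant_ids, drop = FALSE]
  f <- colMeans(sub, na.rm = TRUE) / 2
  f[is.nan(f)] <- 0
  maf <- pmin(f, 1 - f)
  rare <- variant_ids[maf < maf_max]
  if (length(rare) == 0) return(NULL)
  flipped <- f[maf < maf_max] > 0.5
  g <- sub[, maf < maf_max, drop = FALSE]
  carr <- matrix(FALSE, nrow(g), ncol(g))
  carr[, !flipped] <- !is.na(g[, !flipped, drop = FALSE]) & g[, !flipped, drop = FALSE] >= 1L
  carr[, flipped] <- !is.na(g[, flipped, drop = FALSE]) & g[, flipped, drop = FALSE] <= 1L
  out <- as.integer(rowSums(carr) > 0L)
  names(out) <- rownames(genotypes)
  attr(out, "rare_variants") <- rare
  out
}

# Two-sided Fisher exact p for one 2x2 table (a,b = case carriers/non,
# c,d = control carriers/non): sums hypergeometric tables with probability
# not exceeding the observed one.
fisher_p_2x2 <- function(a, b, c, d) {
  fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value
}

# Vectorized 2x2 testing core shared by carrier and allelic tests.
# a = case carriers, b = case non-carriers, c = control carriers,
# d = control non-carriers. Pearson chi-square (1 df, no continuity
# correction) when all four expected counts are >= 5, else two-sided Fisher
# exact. Degenerate margins are untestable (test "none", p NA).
test_tables_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  untest <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  min_exp <- pmin(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n
  stat <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  test_used <- ifelse(untest, "none", ifelse(min_exp >= 5, "chisq", "fisher"))
  fi <- which(test_used == "fisher")
  for (i in fi) p[i] <- fisher_p_2x2(a[i], b[i], c[i], d[i])
  p[untest] <- NA_real_
  data.frame(case_carriers = a, case_noncarriers = b,
             control_carriers = c, control_noncarriers = d,
             test_used = test_used, p_value = p, stringsAsFactors = FALSE)
}

#' Carrier-proportion association test
#'
#' Builds the 2x2 case/control x carrier/non-carrier table and tests the
#' difference in carrier proportions: Pearson chi-square (1 df, no continuity
#' correction) when all expected cell counts are at least 5, otherwise a
#' two-sided Fisher exact test. A degenerate margin (all or no subjects
#' carriers) makes the unit untestable.
#'
#' @param carriers Binary carrier indicator per subject.
#' @param affected Binary affection status, aligned with `carriers`.
#' @return List of class `assoc_result`: `table` (named counts), `test_used`
#'   (`"chisq"`, `"fisher"` or `"none"`), `p_value` (NA when untestable).
#' @export
carrier_test <- function(carriers, affected) {
  stopifnot(length(carriers) == length(affected))
  if (length(unique(affected)) < 2) stopf("both affection classes must be present")
  a <- sum(carriers == 1 & affected == 1)
  b <- sum(carriers == 0 & affected == 1)
  c <- sum(carriers == 1 & affected == 0)
  d <- sum(carriers == 0 & affected == 0)
  res <- test_tables_2x2(a, b, c, d)
  structure(list(
    table = c(case_carriers = a, case_noncarriers = b,
              control_carriers = c, control_noncarriers = d),
    test_used = res$test_used, p_value = res$p_value
  ), class = "assoc_result")
}

#' Single-SNP allelic association test
#'
#' Allelic 2x2 test (minor vs major allele counts, cases vs controls) with
#' the same chi-square/Fisher expected-count rule as [carrier_test()].
#' Monomorphic SNPs are untestable.
#'
#' @param dosages Per-subject minor-allele dosage (0/1/2, NA allowed).
#' @param affected Binary affection status.
#' @return An `assoc_result` list (allele-count table).
#' @export
single_snp_test <- function(dosages, affected) {
  stopifnot(length(dosages) == length(affected))
  ok <- !is.na(dosages)
  a1_case <- sum(dosages[ok & affected == 1])
  n_case <- 2 * sum(ok & affected == 1)
  a1_ctrl <- sum(dosages[ok & affected == 0])
  n_ctrl <- 2 * sum(ok & affected == 0)
  res <- test_tables_2x2(a1_case, n_case - a1_case, a1_ctrl, n_ctrl - a1_ctrl)
  structure(list(
    table = c(case_minor = a1_case, case_major = n_case - a1_case,
              control_minor = a1_ctrl, control_major = n_ctrl - a1_ctrl),
    test_used = res$test_used, p_value = res$p_value
  ), class = "assoc_result")
}

# Carrier counts for a list of variant-id sets, computed from a precomputed
# per-variant carrier matrix (subjects x rare variants, logical).
unit_counts <- function(carr_mat, member_list, affected) {
  n_case <- sum(affected == 1)
  n_ctrl <- sum(affected == 0)
  res <- matrix(0L, length(member_list), 3L)
  for (i in seq_along(member_list)) {
    cols <- member_list[[i]]
    if (length(cols) == 0L) {
      res[i, ] <- c(0L, 0L, 0L)
      next
    }
    carr <- if (length(cols) == 1L) carr_mat[, cols] else
      rowSums(carr_mat[, cols, drop = FALSE]) > 0L
    res[i, ] <- c(sum(carr & affected == 1), sum(carr & affected == 0), length(cols))
  }
  data.frame(case_carriers = res[, 1], control_carriers = res[, 2],
             n_rare_variants = res[, 3],
             case_total = n_case, control_total = n_ctrl)
}

#' Genome-wide collapsing and single-SNP association scan
#'
#' Runs gene-wise collapsing, sliding-window collapsing at each requested
#' size (overlapping windows, step = `step_fraction` x size), and single-SNP
#' allelic tests on common variants, returning one row per tested unit with
#' its 2x2 counts, the test used and the p-value. Units with no rare variant
#' (or degenerate tables) are flagged untestable (`test_used = "none"`).
#'
#' @param cohort A `cohort`, or a list with `genotypes`, `phenotypes`,
#'   `variants`, `genes` of the same shapes.
#' @param window_sizes Window sizes in bp (default 1, 5, 25, 50, 100 kb).
#' @param include_genewise Run gene-based collapsing.
#' @param include_snp Run single-SNP tests on common variants
#'   (MAF >= `maf_max`).
#' @param maf_max Rare-variant threshold (strict) for the carrier indicator.
#' @param step_fraction Window step as a fraction of window size (default
#'   0.5: overlapping windows).
#' @return Data frame: `unit_id`, `unit_kind` ("gene", "window", "snp"),
#'   `size`, `chrom`, `start`, `end`, `position` (midpoint), `gene`,
#'   `n_rare_variants`, carrier/allele counts, `test_used`, `p_value`.
#' @export
collapsing_scan <- function(cohort,
                            window_sizes = c(1000, 5000, 25000, 50000, 100000),
                            include_genewise = TRUE, include_snp = TRUE,
                            maf_max = 0.05, step_fraction = 0.5) {
  geno <- cohort$genotypes
  variants <- cohort$variants
  genes <- cohort$genes
  affected <- cohort$phenotypes$affected[
    match(rownames(geno), cohort$phenotypes$subject_id)]

  variants <- variants[variants$variant_id %in% colnames(geno), , drop = FALSE]
  f <- colMeans(geno, na.rm = TRUE) / 2
  f[is.nan(f)] <- 0
  maf <- pmin(f, 1 - f)
  rare_ids <- colnames(geno)[maf < maf_max]

  # per-variant minor-allele carrier matrix for all rare variants
  if (length(rare_ids)) {
    g <- geno[, rare_ids, drop = FALSE]
    flip <- f[rare_ids] > 0.5
    carr_mat <- !is.na(g) & g >= 1L
    if (any(flip))
      carr_mat[, flip] <- !is.na(g[, flip, drop = FALSE]) &
        g[, flip, drop = FALSE] <= 1L
  } else {
    carr_mat <- matrix(FALSE, nrow(geno), 0L,
                       dimnames = list(rownames(geno), NULL))
  }

  blocks <- list()

  if (include_genewise) {
    members <- split(intersect(variants$variant_id, rare_ids),
                     variants$gene[match(intersect(variants$variant_id, rare_ids),
                                         variants$variant_id)])
    gsub <- genes[genes$gene %in% names(members), , drop = FALSE]
    members <- members[gsub$gene]
    cnt <- unit_counts(carr_mat, members, affected)
    tst <- test_tables_2x2(cnt$case_carriers, cnt$case_total - cnt$case_carriers,
                           cnt$control_carriers, cnt$control_total - cnt$control_carriers)
    blocks$gene <- data.frame(
      unit_id = paste0("gene_", gsub$gene), unit_kind = "gene", size = NA_real_,
      chrom = gsub$chrom, start = gsub$start, end = gsub$end,
      position = (gsub$start + gsub$end) / 2, gene = gsub$gene,
      n_rare_variants = cnt$n_rare_variants,
      case_carriers = cnt$case_carriers, control_carriers = cnt$control_carriers,
      case_total = cnt$case_total, control_total = cnt$control_total,
      test_used = tst$test_used, p_value = tst$p_value,
      stringsAsFactors = FALSE
    )
  }

  for (size in window_sizes) {
    w <- make_windows(variants, size = size, step = size * step_fraction,
                      genes = genes)
    members <- lapply(w$member_variants, function(v) intersect(v, rare_ids))
    cnt <- unit_counts(carr_mat, members, affected)
    tst <- test_tables_2x2(cnt$case_carriers, cnt$case_total - cnt$case_carriers,
                           cnt$control_carriers, cnt$control_total - cnt$control_carriers)
    tst$test_used[cnt$n_rare_variants == 0L] <- "none"
    tst$p_value[cnt$n_rare_variants == 0L] <- NA_real_
    blocks[[paste0("win", size)]] <- data.frame(
      unit_id = w$unit_id, unit_kind = "window", size = size,
      chrom = w$chrom, start = w$start, end = w$end,
      position = (w$start + w$end) / 2, gene = NA_character_,
      n_rare_variants = cnt$n_rare_variants,
      case_carriers = cnt$case_carriers, control_carriers = cnt$control_carriers,
      case_total = cnt$case_total, control_total = cnt$control_total,
      test_used = tst$test_used, p_value = tst$p_value,
      stringsAsFactors = FALSE
    )
  }

  if (include_snp) {
    common_ids <- colnames(geno)[maf >= maf_max & maf > 0]
    if (length(common_ids)) {
      g <- geno[, common_ids, drop = FALSE]
      ok <- !is.na(g)
      minor <- g  # orient to the sample minor allele
      flip <- f[common_ids] > 0.5
      if (any(flip)) minor[, flip] <- 2L - g[, flip, drop = FALSE]
      a <- colSums(minor[affected == 1, , drop = FALSE], na.rm = TRUE)
      n_case_al <- 2 * colSums(ok[affected == 1, , drop = FALSE])
      c_ <- colSums(minor[affected == 0, , drop = FALSE], na.rm = TRUE)
      n_ctrl_al <- 2 * colSums(ok[affected == 0, , drop = FALSE])
      tst <- test_tables_2x2(a, n_case_al - a, c_, n_ctrl_al - c_)
      vs <- variants[match(common_ids, variants$variant_id), , drop = FALSE]
      blocks$snp <- data.frame(
        unit_id = common_ids, unit_kind = "snp", size = NA_real_,
        chrom = vs$chrom, start = vs$pos, end = vs$pos + 1,
        position = vs$pos, gene = vs$gene,
        n_rare_variants = NA_integer_,
        case_carriers = a, control_carriers = c_,
        case_total = n_case_al, control_total = n_ctrl_al,
        test_used = tst$test_used, p_value = tst$p_value,
        stringsAsFactors = FALSE
      )
    }
  }

  out <- do.call(rbind, blocks)
  out <- out[order(out$unit_kind, out$size, out$chrom, out$position), ]
  rownames(out) <- NULL
  out
}

#' Manhattan plot coordinates from a scan
#'
#' @param results A [collapsing_scan()] result (typically filtered to one
#'   unit kind/size).
#' @return Data frame: `unit_id`, `chrom`, `position`, `neg_log10_p`
#'   (untestable units dropped).
#' @export
manhattan_data <- function(results) {
  r <- results[!is.na(results$p_value), , drop = FALSE]
  data.frame(unit_id = r$unit_id, chrom = r$chrom, position = r$position,
             neg_log10_p = -log10(r$p_value), stringsAsFactors = FALSE)
}
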