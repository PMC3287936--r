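## qc module: Hardy-Weinberg filtering in controls, correlated-marker pruning,
## and population-stratification components by classical MDS of 1 - IBS.

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against Hardy-Weinberg expectations computed from the sample allele
#' frequency. Monomorphic input returns p = 1 by convention. All three
#' arguments may be vectors of equal length.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (reference homozygote, heterozygote,
#'   alternate homozygote).
#' @return Vector of p-values.
#' @export
#' @examples
#' hwe_test(25, 50, 25)  # exactly HWE: p = 1
#' hwe_test(10, 10, 10)
hwe_test <- function(n_AA, n_Aa, n_aa) {
  counts <- cbind(n_AA, n_Aa, n_aa)
  if (any(counts < 0, na.rm = TRUE)) stopf("genotype counts must be non-negative")
  n <- rowSums(counts)
  if (any(n == 0)) stopf("total genotype count must be positive")
  q <- (counts[, 2] + 2 * counts[, 3]) / (2 * n)  # alt allele frequency
  p <- 1 - q
  exp_counts <- cbind(n * p^2, n * 2 * p * q, n * q^2)
  stat <- rowSums((counts - exp_counts)^2 / exp_counts, na.rm = TRUE)
  pv <- pchisq(stat, df = 1, lower.tail = FALSE)
  pv[q == 0 | q == 1] <- 1  # monomorphic convention
  unname(pv)
}

genotype_counts <- function(genotypes) {
  cbind(n_AA = colSums(genotypes == 0L, na.rm = TRUE),
        n_Aa = colSums(genotypes == 1L, na.rm = TRUE),
        n_aa = colSums(genotypes == 2L, na.rm = TRUE))
}

#' Filter variants by Hardy-Weinberg deviation in controls
#'
#' Computes the HWE test on control subjects only and removes variants with
#' p below `alpha` (strict), the standard genotyping-quality screen.
#'
#' @param genotypes Subjects x variants dosage matrix (0/1/2/NA) with
#'   subject row names and variant column names.
#' @param phenotypes Data frame with `subject_id` and `affected` covering all
#'   subjects.
#' @param alpha Removal threshold (default 1e-4).
#' @return List with `genotypes` (kept columns), `removed` (data frame:
#'   variant_id, p_hwe) and `p_hwe` (all variants).
#' @export
hwe_filter <- function(genotypes, phenotypes, alpha = 1e-4) {
  if (!all(rownames(genotypes) %in% phenotypes$subject_id))
    stopf("phenotype table does not cover all subjects")
  ctrl <- phenotypes$subject_id[phenotypes$affected == 0]
  if (length(ctrl) == 0) stopf("no control subjects")
  cc <- genotype_counts(genotypes[rownames(genotypes) %in% ctrl, , drop = FALSE])
  p <- hwe_test(cc[, 1], cc[, 2], cc[, 3])
  drop <- p < alpha
  list(
    genotypes = genotypes[, !drop, drop = FALSE],
    removed = data.frame(variant_id = colnames(genotypes)[drop],
                         p_hwe = p[drop], stringsAsFactors = FALSE),
    p_hwe = setNames(p, colnames(genotypes))
  )
}

#' Greedy windowed pruning of correlated markers
#'
#' Within each sliding window of `window` variants (advanced by `step`),
#' repeatedly finds the pair of retained variants with the highest squared
#' Pearson correlation of dosages above `r2_max` and drops the member with
#' the lower sample MAF (ties: the later position). The surviving set has no
#' within-window pair above the threshold. Deterministic given input order.
#'
#' @param genotypes Subjects x variants dosage matrix.
#' @param r2_max Squared-correlation threshold (default 0.2).
#' @param window Window width in variants (default 50).
#' @param step Window advance in variants (default 5).
#' @return Character vector of kept variant ids.
#' @export
prune_correlated <- function(genotypes, r2_max = 0.2, window = 50, step = 5) {
  m <- ncol(genotypes)
  if (m < 2) return(colnames(genotypes))
  maf <- sample_maf(genotypes)
  keep <- rep(TRUE, m)
  has_na <- anyNA(genotypes)
  starts <- seq(1L, max(1L, m - 1L), by = step)
  for (s in starts) {
    idx <- s:min(s + window - 1L, m)
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    cm <- suppressWarnings(cor(genotypes[, idx, drop = FALSE],
                               use = if (has_na) "pairwise.complete.obs" else "everything"))
    r2 <- cm^2
    r2[!is.finite(r2)] <- 0
    diag(r2) <- 0
    while (TRUE) {
      mx <- max(r2)
      if (mx <= r2_max) break
      w <- which(r2 == mx, arr.ind = TRUE)[1, ]
      i <- idx[w[1]]; j <- idx[w[2]]
      # drop lower MAF; tie -> later position
      victim <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j else max(i, j)
      keep[victim] <- FALSE
      vloc <- match(victim, idx)
      r2[vloc, ] <- 0
      r2[, vloc] <- 0
    }
  }
  colnames(genotypes)[keep]
}

#' Pairwise 1 - IBS distance between subjects
#'
#' Identity-by-state similarity between two subjects is the mean over
#' non-missing variants of `(2 - |d_i - d_j|) / 2`; the distance is one minus
#' that. Missing dosages are excluded pairwise.
#'
#' @param genotypes Subjects x variants dosage matrix.
#' @return A `dist` object over subjects.
#' @export
ibs_distance <- function(genotypes) {
  m <- ncol(genotypes)
  if (m == 0) stopf("need at least one variant")
  # dist(manhattan) rescales NA-skipped pairs to the full column count,
  # which is exactly the pairwise-complete mean needed here
  dist(genotypes, method = "manhattan") / (2 * m)
}

#' Population-stratification components by classical MDS
#'
#' Torgerson (classical) multidimensional scaling of the 1 - IBS distance
#' matrix; the input should be the pruned marker set. Component signs are
#' arbitrary, as inherent to the eigendecomposition.
#'
#' @param genotypes Subjects x variants dosage matrix.
#' @param k Number of components (must be < number of subjects).
#' @return List of class `mds_result`: `coordinates` (subjects x k, rows named
#'   by subject), `k`, `distance_metric`, `eig` (eigenvalues).
#' @export
mds_components <- function(genotypes, k = 2) {
  n <- nrow(genotypes)
  if (k >= n) stopf("k must be smaller than the number of subjects")
  d <- ibs_distance(genotypes)
  fit <- cmdscale(d, k = k, eig = TRUE)
  coords <- fit$points
  # cmdscale may return fewer columns for degenerate inputs; pad with zeros
  if (ncol(coords) < k)
    coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
  rownames(coords) <- rownames(genotypes)
  colnames(coords) <- paste0("C", seq_len(k))
  structure(list(coordinates = coords, k = k, distance_metric = "1-IBS",
                 eig = fit$eig), class = "mds_result")
}
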