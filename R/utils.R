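## Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stage seed from a master seed; stays below 2^31 - 1.
derive_seed <- function(seed, offset) {
  ((as.numeric(seed) %% 1000003) * 1009 + offset) %% 2147483647
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

# Sample minor-allele frequency of dosage columns (0/1/2, NA allowed).
sample_maf <- function(genotypes) {
  f <- colMeans(genotypes, na.rm = TRUE) / 2
  f[is.nan(f)] <- 0
  pmin(f, 1 - f)
}
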