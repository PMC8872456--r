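# Internal helpers shared across modules.

# Columns every long-format genotype table must carry.
GENO_COLS <- c("individual", "population", "locus", "allele_1", "allele_2")

assert_genotypes <- function(geno, call = rlang::caller_env()) {
  if (!is.data.frame(geno)) {
    abort("`geno` must be a data frame of diploid genotypes.", call = call)
  }
  missing_cols <- setdiff(GENO_COLS, names(geno))
  if (length(missing_cols) > 0) {
    abort(
      paste0(
        "`geno` is missing column(s): ",
        paste(missing_cols, collapse = ", "), "."
      ),
      call = call
    )
  }
  bad <- c(geno$allele_1, geno$allele_2)
  bad <- bad[!is.na(bad)]
  if (length(bad) > 0 && any(bad <= 0 | bad != round(bad))) {
    abort(
      "Allele labels must be positive integers (fragment length, bp) or NA.",
      call = call
    )
  }
  invisible(geno)
}

assert_frequencies <- function(freqs, call = rlang::caller_env()) {
  if (!is.data.frame(freqs)) {
    abort("`freqs` must be a data frame of allele frequencies.", call = call)
  }
  needed <- c("population", "locus", "allele", "freq", "n_copies")
  missing_cols <- setdiff(needed, names(freqs))
  if (length(missing_cols) > 0) {
    abort(
      paste0(
        "`freqs` is missing column(s): ",
        paste(missing_cols, collapse = ", "), "."
      ),
      call = call
    )
  }
  invisible(freqs)
}

# Named frequency vector for one (population, locus); zero-length if unscored.
freq_vector <- function(freqs, pop, loc) {
  rows <- freqs[freqs$population == pop & freqs$locus == loc &
                  !is.na(freqs$allele), , drop = FALSE]
  setNames(rows$freq, rows$allele)
}

copies_at <- function(freqs, pop, loc) {
  rows <- freqs[freqs$population == pop & freqs$locus == loc, , drop = FALSE]
  if (nrow(rows) == 0) return(0L)
  as.integer(rows$n_copies[1])
}

# Align two named vectors on the union of their names, filling zeros.
align_freqs <- function(x, y) {
  alleles <- union(names(x), names(y))
  list(
    x = setNames(ifelse(alleles %in% names(x), x[alleles], 0), alleles),
    y = setNames(ifelse(alleles %in% names(y), y[alleles], 0), alleles),
    alleles = alleles
  )
}

# Multivariate hypergeometric draw: sample k gene copies without replacement
# from a pool with `counts` copies per allele label.
rmvhyper <- function(counts, k) {
  stopifnot(k <= sum(counts))
  out <- integer(length(counts))
  remaining <- sum(counts)
  left <- k
  for (i in seq_along(counts)) {
    if (left == 0L) break
    if (i == length(counts)) {
      out[i] <- left
      break
    }
    x <- stats::rhyper(1, counts[i], remaining - counts[i], left)
    out[i] <- x
    left <- left - x
    remaining <- remaining - counts[i]
  }
  setNames(out, names(counts))
}

# Derive a reproducible child seed (< 2^31) from a base seed and a stage tag.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}
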