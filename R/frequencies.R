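#' Allele frequencies by population or taxon
#'
#' Counts non-missing gene copies at every (group, locus) and converts them to
#' frequencies. Grouping by taxon pools all populations of a taxon weighted by
#' gene copies, i.e. pooled counts, not a mean of population frequencies.
#'
#' A (group, locus) with no scored individuals is kept as a single row with
#' `allele = NA`, `freq = NA`, `n_copies = 0` — frequencies there are
#' undefined, not zero.
#'
#' @param geno Long-format genotype tibble (see [read_genepop()]).
#' @param by `"population"` (default) or `"taxon"`.
#' @param meta Population metadata with `population` and `taxon`; required for
#'   `by = "taxon"`.
#' @return A tibble with columns `population` (the group id, even when the
#'   grouping unit is a taxon), `locus`, `allele`, `freq`, `n_copies`;
#'   frequencies at each (group, locus) with `n_copies > 0` sum to 1.
#' @export
allele_frequencies <- function(geno, by = c("population", "taxon"),
                               meta = NULL) {
  assert_genotypes(geno)
  by <- match.arg(by)
  if (nrow(geno) == 0) abort("`geno` is empty.")
  g <- geno
  if (by == "taxon") {
    if (is.null(meta)) abort("`meta` is required when grouping by taxon.")
    g <- dplyr::left_join(g, meta[, c("population", "taxon")],
                          by = "population")
    if (anyNA(g$taxon)) {
      abort("Some populations have no taxon in `meta`.")
    }
    g$population <- g$taxon
  }

  long <- tidyr::pivot_longer(
    g[, c("population", "locus", "allele_1", "allele_2")],
    cols = c("allele_1", "allele_2"), values_to = "allele"
  )
  counts <- long |>
    dplyr::filter(!is.na(.data$allele)) |>
    dplyr::count(.data$population, .data$locus, .data$allele,
                 name = "copies") |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::mutate(
      n_copies = sum(.data$copies),
      freq = .data$copies / .data$n_copies
    ) |>
    dplyr::ungroup() |>
    dplyr::select("population", "locus", "allele", "freq", "n_copies")

  # Restore (group, locus) combinations that exist but are wholly missing.
  all_combos <- dplyr::distinct(g, .data$population, .data$locus)
  empty <- dplyr::anti_join(all_combos, counts,
                            by = c("population", "locus"))
  if (nrow(empty) > 0) {
    empty$allele <- NA_integer_
    empty$freq <- NA_real_
    empty$n_copies <- 0L
    counts <- dplyr::bind_rows(counts, empty)
  }
  dplyr::arrange(counts, .data$population, .data$locus, .data$allele)
}

#' Inbreeding coefficient F_IS with a bootstrap CI across loci
#'
#' Per-locus F_IS is `1 - H_obs / H_exp`, with `H_exp` the unbiased
#' small-sample-corrected expected heterozygosity
#' `2n/(2n - 1) * (1 - sum(p^2))`. The across-loci estimate is a ratio of
#' sums (`1 - sum(H_obs) / sum(H_exp)`), and its 95% CI comes from a
#' percentile bootstrap resampling loci with replacement. Monomorphic loci
#' have undefined F_IS and are excluded (with a message).
#'
#' @param geno Long-format genotype tibble.
#' @param population Population id to analyse (required if `geno` holds more
#'   than one population).
#' @param nboot Bootstrap replicates over loci (default 10000).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level for the percentile interval.
#' @return An object of class `fis_est` with `tidy()` (per-locus table) and
#'   `glance()` (across-loci estimate and CI) methods.
#' @export
f_is <- function(geno, population = NULL, nboot = 10000, seed = 1L,
                 conf = 0.95) {
  assert_genotypes(geno)
  pops <- unique(geno$population)
  if (is.null(population)) {
    if (length(pops) > 1) {
      abort("`geno` holds several populations; pick one with `population`.")
    }
    population <- pops
  }
  g <- geno[geno$population == population, , drop = FALSE]
  if (nrow(g) == 0) abort(paste0("Unknown population: ", population))

  per_locus <- g |>
    dplyr::filter(!is.na(.data$allele_1)) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      n = dplyr::n(),
      h_obs = mean(.data$allele_1 != .data$allele_2),
      h_exp = {
        p <- table(c(.data$allele_1, .data$allele_2))
        p <- as.numeric(p) / sum(p)
        (2 * dplyr::n()) / (2 * dplyr::n() - 1) * (1 - sum(p^2))
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(f_is = 1 - .data$h_obs / .data$h_exp)

  mono <- per_locus$h_exp <= 0
  if (any(mono)) {
    inform(paste0(
      "Excluding monomorphic locus(es) from F_IS: ",
      paste(per_locus$locus[mono], collapse = ", ")
    ))
    per_locus$f_is[mono] <- NA_real_
  }
  poly <- per_locus[!mono, , drop = FALSE]
  if (nrow(poly) < 2) {
    abort("At least 2 polymorphic loci are needed for the across-loci F_IS.")
  }
  overall <- 1 - sum(poly$h_obs) / sum(poly$h_exp)

  set.seed(seed)
  L <- nrow(poly)
  idx <- matrix(sample.int(L, L * nboot, replace = TRUE), nrow = nboot)
  ho <- matrix(poly$h_obs[idx], nrow = nboot)
  he <- matrix(poly$h_exp[idx], nrow = nboot)
  boot <- 1 - rowSums(ho) / rowSums(he)
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE))

  structure(
    list(
      population = population, per_locus = per_locus, f_is = overall,
      ci = ci, conf = conf, nboot = nboot, seed = seed
    ),
    class = "fis_est"
  )
}

#' @export
print.fis_est <- function(x, ...) {
  cat(sprintf(
    "F_IS for population %s: %.4f (%.0f%% CI %.4f to %.4f; %d loci, %d bootstrap reps)\n",
    x$population, x$f_is, 100 * x$conf, x$ci[1], x$ci[2],
    sum(!is.na(x$per_locus$f_is)), x$nboot
  ))
  invisible(x)
}

#' @export
tidy.fis_est <- function(x, ...) {
  dplyr::mutate(x$per_locus, population = x$population, .before = 1)
}

#' @export
glance.fis_est <- function(x, ...) {
  tibble::tibble(
    population = x$population, f_is = x$f_is,
    ci_low = x$ci[1], ci_high = x$ci[2], conf = x$conf,
    n_loci = sum(!is.na(x$per_locus$f_is)), nboot = x$nboot, seed = x$seed
  )
}

#' Write an allele-frequency table to CSV
#'
#' @param freqs Output of [allele_frequencies()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_frequencies <- function(freqs, path) {
  assert_frequencies(freqs)
  readr::write_csv(freqs, path)
  invisible(path)
}
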