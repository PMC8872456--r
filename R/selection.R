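# Allele-class pooling and the two-island migration-selection solver: the
# selection coefficient required, in each direction, to hold an observed
# class-frequency difference against symmetric gross migration at
# equilibrium.

#' Pool microsatellite alleles into two classes for one locus
#'
#' Collapses a multi-allelic locus at one sympatric pair into a biallelic
#' contrast: every allele strictly more common in the ancestral population
#' joins the ancestral-favored class; the rest form the derived-favored
#' class. Ties (equal frequency, including shared absence) go to the
#' ancestral class — they contribute equally to both populations' class
#' frequency, so the difference `a1 - a2` is unaffected. By construction
#' `a1 >= a2`.
#'
#' @param freq_anc,freq_der Named numeric vectors (allele label ->
#'   frequency) for the ancestral and derived population; each must sum
#'   to 1.
#' @return A list `a1` (ancestral-class frequency in the ancestral
#'   population), `a2` (same class in the derived population), and
#'   `ancestral_class` (the pooled allele labels).
#' @export
pool_alleles <- function(freq_anc, freq_der) {
  for (v in list(freq_anc, freq_der)) {
    if (length(v) > 0 && abs(sum(v) - 1) > 1e-6) {
      abort("Frequency vectors must each sum to 1.")
    }
  }
  al <- align_freqs(freq_anc, freq_der)
  anc_class <- al$alleles[al$x >= al$y]
  a1 <- sum(al$x[al$x >= al$y])
  a2 <- sum(al$y[al$x >= al$y])
  list(a1 = a1, a2 = a2, ancestral_class = anc_class)
}

#' Pool a sympatric pair across loci
#'
#' Applies [pool_alleles()] at every locus scored in both populations of a
#' sympatric ancestral/derived pair; loci missing in either population are
#' skipped with a message.
#'
#' @param freqs Allele-frequency table ([allele_frequencies()]).
#' @param pop_ancestral,pop_derived Population ids.
#' @param m Assumed symmetric gross migration rate in \[0, 0.5\].
#' @param h Dominance coefficient (default 0.5).
#' @param loci Optional locus subset.
#' @param pair_id Label for reports.
#' @return A list of class `pooled_pair`: `per_locus` tibble
#'   (`locus, a1, a2`), `m`, `h`, `pair_id`, populations.
#' @export
pool_pair <- function(freqs, pop_ancestral, pop_derived, m, h = 0.5,
                      loci = NULL, pair_id = NULL) {
  assert_frequencies(freqs)
  if (m < 0 || m > 0.5) abort("`m` must lie in [0, 0.5].")
  scored <- function(p) unique(
    freqs$locus[freqs$population == p & freqs$n_copies > 0]
  )
  shared <- intersect(scored(pop_ancestral), scored(pop_derived))
  wanted <- loci %||% shared
  skipped <- setdiff(wanted, shared)
  if (length(skipped) > 0) {
    inform(paste0(
      "Skipping locus(es) missing in one population: ",
      paste(skipped, collapse = ", ")
    ))
  }
  use <- intersect(wanted, shared)
  if (length(use) == 0) abort("No pooled loci for this pair.")
  per_locus <- purrr::map(use, function(loc) {
    pooled <- pool_alleles(
      freq_vector(freqs, pop_ancestral, loc),
      freq_vector(freqs, pop_derived, loc)
    )
    tibble::tibble(locus = loc, a1 = pooled$a1, a2 = pooled$a2)
  }) |> dplyr::bind_rows()
  structure(
    list(
      per_locus = per_locus, m = m, h = h,
      pop_ancestral = pop_ancestral, pop_derived = pop_derived,
      pair_id = pair_id %||% paste(pop_ancestral, pop_derived, sep = "-")
    ),
    class = "pooled_pair"
  )
}

# One-generation selection change in the favored-class frequency p under
# fitnesses (1, 1-h*s, 1-s).
delta_p_selection <- function(p, s, h) select_favored(p, s, h) - p

#' Selection coefficient required to hold a frequency difference at
#' equilibrium
#'
#' Migration removes `delta = m * (p_favored - p_immigrant)` from the
#' resident favored-class frequency each generation; this solves for the
#' selection coefficient whose one-generation gain exactly compensates.
#' Two conventions for where the selection response is evaluated are
#' provided:
#'
#' * `"compensatory"` (default): selection acts at the observed resident
#'   frequency, `delta_p_sel(p_favored, s) = delta`. With `h = 0.5` the
#'   selection response is `p q s / (2 (1 - q s))`, giving the closed form
#'   `s = delta / (q (p/2 + delta))` at `(p, q) = (p_favored, 1 -
#'   p_favored)`.
#' * `"sequential"`: migration acts first, `p* = (1 - m) p_favored +
#'   m p_immigrant`, and selection must carry `p*` back up to `p_favored`;
#'   same closed form evaluated at `p*`. This is the exact inversion of the
#'   migration-then-selection equilibrium recursion.
#'
#' For general `h` the full diploid update is solved by bisection. A
#' required `s` above 1 means the observed difference cannot be maintained
#' at equilibrium under the assumed migration rate: the value is capped at
#' 1 and flagged. A resident frequency of exactly 0 or 1 with a nonzero
#' difference is degenerate (no segregating variation for selection to act
#' on); it is reported as capped and flagged degenerate.
#'
#' @param p_favored Resident frequency of the locally favored class
#'   (>= `p_immigrant`).
#' @param p_immigrant Frequency of the same class in the immigrant source.
#' @param m Symmetric gross migration rate in \[0, 0.5\].
#' @param h Dominance coefficient.
#' @param convention `"compensatory"` or `"sequential"`.
#' @return A list `s` (in \[0, 1\]), `capped`, `degenerate`.
#' @export
required_s <- function(p_favored, p_immigrant, m, h = 0.5,
                       convention = c("compensatory", "sequential")) {
  convention <- match.arg(convention)
  if (m < 0 || m > 0.5) abort("`m` must lie in [0, 0.5].")
  if (p_favored < p_immigrant - 1e-12) {
    abort("`p_favored` must be >= `p_immigrant` (pooling guarantees this).")
  }
  delta <- m * (p_favored - p_immigrant)
  if (delta <= 0) return(list(s = 0, capped = FALSE, degenerate = FALSE))

  p_eval <- switch(convention,
    compensatory = p_favored,
    sequential = (1 - m) * p_favored + m * p_immigrant
  )
  q_eval <- 1 - p_eval
  if (p_eval <= 0 || p_eval >= 1 || p_favored >= 1) {
    # no heterozygote/segregating variation: unattainable at equilibrium
    return(list(s = 1, capped = TRUE, degenerate = TRUE))
  }

  if (abs(h - 0.5) < 1e-12) {
    s <- delta / (q_eval * (p_eval / 2 + delta))
  } else {
    f <- function(s) delta_p_selection(p_eval, s, h) - delta
    if (f(1) < 0) {
      return(list(s = 1, capped = TRUE, degenerate = FALSE))
    }
    s <- stats::uniroot(f, c(0, 1), tol = 1e-12)$root
  }
  if (s > 1) {
    list(s = 1, capped = TRUE, degenerate = FALSE)
  } else {
    list(s = s, capped = FALSE, degenerate = FALSE)
  }
}

#' Per-locus selection profile for a pooled sympatric pair
#'
#' Applies [required_s()] at every pooled locus in both directions: in the
#' ancestral population the locally favored class is the ancestral class
#' (resident `a1`, immigrant `a2`); in the derived population it is the
#' derived class (resident `1 - a2`, immigrant `1 - a1`). Summaries
#' (mean/min/max per direction) are computed on capped values, matching how
#' such coefficients are conventionally reported.
#'
#' @param pair A [pool_pair()] result.
#' @param convention Solver convention, see [required_s()].
#' @return An object of class `selection_profile` with `per_locus` tibble
#'   (`locus, a1, a2, s_in_ancestral, capped_ancestral, s_in_derived,
#'   capped_derived, degenerate`), `summary` tibble per direction, the pair
#'   metadata, and `tidy()`/`glance()`/`autoplot()` methods.
#' @export
pair_selection_profile <- function(pair,
                                   convention = c("compensatory",
                                                  "sequential")) {
  stopifnot(inherits(pair, "pooled_pair"))
  convention <- match.arg(convention)
  if (nrow(pair$per_locus) < 1) abort("No pooled loci.")
  rows <- purrr::pmap(pair$per_locus, function(locus, a1, a2) {
    anc <- required_s(a1, a2, pair$m, pair$h, convention)
    der <- required_s(1 - a2, 1 - a1, pair$m, pair$h, convention)
    tibble::tibble(
      locus = locus, a1 = a1, a2 = a2,
      s_in_ancestral = anc$s, capped_ancestral = anc$capped,
      s_in_derived = der$s, capped_derived = der$capped,
      degenerate = anc$degenerate | der$degenerate
    )
  }) |> dplyr::bind_rows()
  summarise_dir <- function(s, capped) {
    tibble::tibble(
      mean = mean(s), min = min(s), max = max(s), n_capped = sum(capped),
      n_loci = length(s)
    )
  }
  smry <- dplyr::bind_rows(
    dplyr::mutate(
      summarise_dir(rows$s_in_ancestral, rows$capped_ancestral),
      direction = "against_derived_in_ancestral", .before = 1
    ),
    dplyr::mutate(
      summarise_dir(rows$s_in_derived, rows$capped_derived),
      direction = "against_ancestral_in_derived", .before = 1
    )
  )
  structure(
    list(
      per_locus = rows, summary = smry, pair_id = pair$pair_id,
      pop_ancestral = pair$pop_ancestral, pop_derived = pair$pop_derived,
      m = pair$m, h = pair$h, convention = convention
    ),
    class = "selection_profile"
  )
}

#' @export
print.selection_profile <- function(x, ...) {
  cat(sprintf(
    "Selection profile %s (m = %.3f, h = %.2f, %s convention)\n",
    x$pair_id, x$m, x$h, x$convention
  ))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.selection_profile <- function(x, ...) {
  dplyr::mutate(x$per_locus, pair = x$pair_id, .before = 1)
}

#' @export
glance.selection_profile <- function(x, ...) {
  dplyr::mutate(x$summary, pair = x$pair_id, m = x$m,
                convention = x$convention, .before = 1)
}

#' Tests for asymmetry between the two selection directions
#'
#' Paired t-test across loci on the per-locus difference between the
#' derived-direction and ancestral-direction coefficients, and an F test on
#' the variance ratio with the derived-direction variance in the numerator
#' (two-sided p).
#'
#' @param profile A [pair_selection_profile()] result with >= 3 loci.
#' @return A tibble with rows `paired_t` and `variance_f`: `statistic, df1,
#'   df2, p_value`, plus the direction means/variances.
#' @export
asymmetry_tests <- function(profile) {
  stopifnot(inherits(profile, "selection_profile"))
  s_a <- profile$per_locus$s_in_ancestral
  s_d <- profile$per_locus$s_in_derived
  if (length(s_a) < 3) abort("Need >= 3 loci for asymmetry tests.")
  diffs <- s_d - s_a
  if (sd(diffs) == 0) {
    t_row <- tibble::tibble(
      test = "paired_t", statistic = 0, df1 = length(s_a) - 1,
      df2 = NA_real_, p_value = 1
    )
  } else {
    tt <- t.test(s_d, s_a, paired = TRUE)
    t_row <- tibble::tibble(
      test = "paired_t", statistic = unname(tt$statistic),
      df1 = unname(tt$parameter), df2 = NA_real_, p_value = tt$p.value
    )
  }
  if (var(s_a) == 0 || var(s_d) == 0) {
    warn("Zero variance in one direction; F test undefined.")
    f_row <- tibble::tibble(
      test = "variance_f", statistic = NA_real_, df1 = length(s_d) - 1,
      df2 = length(s_a) - 1, p_value = NA_real_
    )
  } else {
    f_stat <- var(s_d) / var(s_a)
    df1 <- length(s_d) - 1
    df2 <- length(s_a) - 1
    p_one <- pf(f_stat, df1, df2, lower.tail = FALSE)
    f_row <- tibble::tibble(
      test = "variance_f", statistic = f_stat, df1 = df1, df2 = df2,
      p_value = min(1, 2 * min(p_one, 1 - p_one))
    )
  }
  out <- dplyr::bind_rows(t_row, f_row)
  out$mean_in_derived <- mean(s_d)
  out$mean_in_ancestral <- mean(s_a)
  out$var_in_derived <- var(s_d)
  out$var_in_ancestral <- var(s_a)
  out
}
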