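#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a standardized subsample of `g`
#' gene copies, computed from the hypergeometric expectation of allele
#' presence: `alpha_g = sum_i (1 - C(N - N_i, g) / C(N, g))` over alleles
#' with copy counts `N_i` at a (population, locus) with `N` total copies.
#'
#' @param freqs Allele-frequency table from [allele_frequencies()].
#' @param g Gene-copy subsample sizes. `NULL` (default) uses `2..g_max`
#'   where `g_max` is the smallest non-zero gene-copy count across the
#'   populations in `freqs` (the standardization needed to compare
#'   populations with unequal sampling). Any requested `g` above a
#'   (population, locus)'s `N` is an error.
#' @return A tibble `population, locus, g, alpha` (curve rows); wholly
#'   missing (population, locus) combinations are dropped with a warning.
#' @export
rarefied_richness <- function(freqs, g = NULL) {
  assert_frequencies(freqs)
  empty <- freqs$n_copies == 0
  if (any(empty)) {
    warn("Dropping (population, locus) combinations with no scored copies.")
    freqs <- freqs[!empty, , drop = FALSE]
  }
  if (is.null(g)) {
    g_max <- min(freqs$n_copies)
    if (g_max < 2) abort("g_max < 2: too little data to rarefy.")
    g <- 2:g_max
  }
  freqs |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::reframe({
      N <- .data$n_copies[1]
      if (any(g > N)) {
        abort(sprintf(
          "g = %d exceeds N = %d at (%s, %s).", max(g), N,
          .data$population[1], .data$locus[1]
        ))
      }
      counts <- round(.data$freq * N)
      tibble::tibble(
        g = g,
        alpha = vapply(g, function(gg) {
          sum(1 - exp(lchoose(N - counts, gg) - lchoose(N, gg)))
        }, numeric(1))
      )
    })
}

#' Fit an asymptotic model to rarefaction curves
#'
#' Least-squares fit of the saturating two-parameter negative-exponential
#' form `alpha(g) = A * (1 - exp(-g/B))` per (population, locus), with the
#' asymptote constrained to be at least the observed curve maximum. `B` is
#' the gene-copy scale at which the curve reaches `1 - 1/e` of its
#' asymptote. This form tracks the fast saturation of hypergeometric
#' rarefaction curves; hyperbolic (Michaelis-Menten) fits systematically
#' overshoot the asymptote on such curves. Degenerate flat curves (e.g.
#' monomorphic loci) get `A = alpha(g_max)` with `B` at its lower bound and
#' a warning flag.
#'
#' @param curve Output of [rarefied_richness()].
#' @return A tibble `population, locus, a_inf, b, rss, degenerate`.
#' @export
fit_asymptote <- function(curve) {
  stopifnot(all(c("population", "locus", "g", "alpha") %in% names(curve)))
  curve |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::reframe({
      g <- .data$g
      alpha <- .data$alpha
      if (length(unique(g)) < 4) {
        abort("Need >= 4 distinct g values to fit the asymptotic model.")
      }
      a_floor <- max(alpha)
      flat <- diff(range(alpha)) < 1e-10
      if (flat) {
        tibble::tibble(a_inf = a_floor, b = 1e-6, rss = 0, degenerate = TRUE)
      } else {
        b0 <- g[which.min(abs(alpha - (1 - exp(-1)) * a_floor))]
        fit <- tryCatch(
          minpack.lm::nlsLM(
            alpha ~ A * (1 - exp(-g / B)),
            start = list(A = a_floor * 1.1, B = max(b0, 0.5)),
            lower = c(A = a_floor, B = 1e-6),
            control = minpack.lm::nls.lm.control(maxiter = 200)
          ),
          error = function(e) NULL
        )
        if (is.null(fit)) {
          tibble::tibble(a_inf = a_floor, b = 1e-6, rss = NA_real_,
                         degenerate = TRUE)
        } else {
          cf <- coef(fit)
          tibble::tibble(
            a_inf = unname(cf["A"]), b = unname(cf["B"]),
            rss = sum(resid(fit)^2), degenerate = FALSE
          )
        }
      }
    })
}

#' Per-population allelic richness via rarefaction + asymptote
#'
#' Convenience wrapper: builds rarefaction curves standardized to the
#' smallest gene-copy count across populations, fits the asymptotic model
#' per locus, and averages the estimated asymptotes across loci within each
#' population.
#'
#' @param freqs Allele-frequency table.
#' @param g_max Optional rarefaction ceiling (default: smallest gene-copy
#'   count in `freqs`).
#' @return A tibble `population, richness, se, n_loci`, with the per-locus
#'   fits in attribute `"fits"`.
#' @export
allelic_richness <- function(freqs, g_max = NULL) {
  g <- if (is.null(g_max)) NULL else 2:g_max
  curves <- rarefied_richness(freqs, g = g)
  fits <- fit_asymptote(curves)
  out <- fits |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      richness = mean(.data$a_inf),
      se = sd(.data$a_inf) / sqrt(dplyr::n()),
      n_loci = dplyr::n(),
      .groups = "drop"
    )
  attr(out, "fits") <- fits
  out
}

#' Private alleles of a focal taxon relative to a reference taxon
#'
#' An allele is private iff it is entirely absent from every reference
#' population and present in at least `min_pops` populations of the focal
#' taxon (screening out singleton or site-local variants; lower `min_pops`
#' to 1 for taxa represented by a single population). The reported
#' taxon-wide frequency is gene-copy weighted across all focal individuals.
#'
#' @param freqs Allele-frequency table (by population).
#' @param meta Population metadata with `population`, `taxon`.
#' @param focal_taxon Focal taxon label.
#' @param reference_taxa Character vector of reference taxon labels.
#' @param min_pops Minimum focal populations an allele must occur in.
#' @return A tibble `locus, allele, n_pops, freq` (one row per private
#'   allele) of class `private_allele_report`; `summary()`/[tidy()] give the
#'   per-locus summed frequencies.
#' @export
private_alleles <- function(freqs, meta, focal_taxon, reference_taxa,
                            min_pops = 2) {
  assert_frequencies(freqs)
  known <- unique(meta$taxon)
  bad <- setdiff(c(focal_taxon, reference_taxa), known)
  if (length(bad) > 0) {
    abort(paste0("Unknown taxon label(s): ", paste(bad, collapse = ", ")))
  }
  focal_pops <- meta$population[meta$taxon == focal_taxon]
  ref_pops <- meta$population[meta$taxon %in% reference_taxa]
  if (length(focal_pops) < min_pops) {
    abort(sprintf(
      "Focal taxon %s has %d population(s) but min_pops = %d; lower min_pops.",
      focal_taxon, length(focal_pops), min_pops
    ))
  }
  f <- freqs[!is.na(freqs$allele) & freqs$freq > 0, , drop = FALSE]
  ref_present <- dplyr::distinct(
    f[f$population %in% ref_pops, c("locus", "allele")]
  )
  focal <- f[f$population %in% focal_pops, , drop = FALSE]
  candidates <- dplyr::anti_join(focal, ref_present,
                                 by = c("locus", "allele"))
  copy_totals <- freqs[freqs$population %in% focal_pops, ] |>
    dplyr::distinct(.data$population, .data$locus, .data$n_copies) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(total_copies = sum(.data$n_copies), .groups = "drop")

  report <- candidates |>
    dplyr::group_by(.data$locus, .data$allele) |>
    dplyr::summarise(
      n_pops = dplyr::n_distinct(.data$population),
      copies = sum(.data$freq * .data$n_copies),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_pops >= min_pops) |>
    dplyr::left_join(copy_totals, by = "locus") |>
    dplyr::mutate(freq = .data$copies / .data$total_copies) |>
    dplyr::select("locus", "allele", "n_pops", "freq")

  structure(
    report,
    focal_taxon = focal_taxon, reference_taxa = reference_taxa,
    min_pops = min_pops,
    class = c("private_allele_report", class(report))
  )
}

#' Per-locus private-allele frequency summary
#'
#' @param object A `private_allele_report`.
#' @param ... Unused.
#' @return A tibble `locus, n_alleles, freq` (summed private-allele
#'   frequency per locus).
#' @export
summary.private_allele_report <- function(object, ...) {
  tibble::as_tibble(object) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      n_alleles = dplyr::n(), freq = sum(.data$freq), .groups = "drop"
    )
}

#' Compare allelic richness across groups by one-way ANOVA + Tukey HSD
#'
#' Operates on population-level mean richness (one value per population).
#' Groups with a single population cannot contribute to the error variance
#' and are excluded with a message.
#'
#' @param richness Tibble `population, richness` (see [allelic_richness()]).
#' @param groups Tibble `population, group` assigning each population to a
#'   taxon/region group.
#' @param alpha Significance level for the Tukey letter display.
#' @return Object of class `richness_anova` with `tidy()` (the ANOVA row)
#'   and a `letters` element mapping groups to Tukey HSD letter groups.
#' @export
compare_richness <- function(richness, groups, alpha = 0.05) {
  d <- dplyr::inner_join(richness, groups, by = "population")
  sizes <- table(d$group)
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons) > 0) {
    inform(paste0(
      "Excluding single-population group(s) from the test: ",
      paste(singletons, collapse = ", ")
    ))
    d <- d[!d$group %in% singletons, , drop = FALSE]
  }
  if (dplyr::n_distinct(d$group) < 2) {
    abort("Need >= 2 groups with >= 2 populations each.")
  }
  d$group <- factor(d$group)
  fit <- aov(richness ~ group, data = d)
  an <- summary(fit)[[1]]
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Tukey"))
  cld <- multcomp::cld(glht, level = alpha)
  letters_tbl <- tibble::tibble(
    group = names(cld$mcletters$Letters),
    letter = unname(cld$mcletters$Letters)
  )
  structure(
    list(
      f = an[["F value"]][1], df1 = an[["Df"]][1], df2 = an[["Df"]][2],
      p_value = an[["Pr(>F)"]][1], letters = letters_tbl, fit = fit,
      excluded = singletons
    ),
    class = "richness_anova"
  )
}

#' @export
print.richness_anova <- function(x, ...) {
  cat(sprintf(
    "Allelic richness ANOVA: F_%d,%d = %.2f, p = %.3g\n",
    x$df1, x$df2, x$f, x$p_value
  ))
  print(x$letters)
  invisible(x)
}

#' @export
tidy.richness_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$f, df1 = x$df1, df2 = x$df2, p_value = x$p_value
  )
}

#' @export
glance.richness_anova <- function(x, ...) tidy(x)
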