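# ggplot2 displays for the main result types. Each returns a ggplot that
# the caller can theme further.

#' Plot mean allelic richness per group
#'
#' Mean of per-population richness within each group with +/- 1 SE bars,
#' the usual display for comparing rarefied richness across taxa.
#'
#' @param richness Output of [allelic_richness()].
#' @param groups Tibble `population, group`.
#' @return A ggplot.
#' @export
plot_richness <- function(richness, groups) {
  d <- dplyr::inner_join(richness, groups, by = "population") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mean_richness = mean(.data$richness),
      se = sd(.data$richness) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group,
                                  y = .data$mean_richness)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_richness - .data$se,
                   ymax = .data$mean_richness + .data$se),
      width = 0.2, na.rm = TRUE
    ) +
    ggplot2::labs(x = NULL, y = "Mean estimated allelic richness") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dest_tbl <- function(object, ...) {
  pair <- paste(attr(object, "pair"), collapse = " vs ")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dest)) +
    ggplot2::geom_dotplot(binwidth = 0.05, method = "histodot") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(
      x = expression(D[EST]), y = NULL,
      title = paste("Locus-specific differentiation:", pair)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.selection_profile <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$per_locus[, c("locus", "s_in_ancestral", "s_in_derived")],
    cols = c("s_in_ancestral", "s_in_derived"),
    names_to = "direction", values_to = "s"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$direction, y = .data$s)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$locus), alpha = 0.3) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = NULL, y = "Required selection coefficient s",
      title = sprintf("%s (m = %.3f)", object$pair_id, object$m)
    ) +
    ggplot2::theme_minimal()
}

#' Plot clinal PC1 scores against latitude
#'
#' @param scan A [detect_clinal_loci()] result.
#' @param loci Optional locus subset (default: flagged clinal loci).
#' @return A ggplot, one facet per locus.
#' @export
plot_cline_scores <- function(scan, loci = NULL) {
  stopifnot(inherits(scan, "clinal_scan"))
  pcas <- attr(scan, "pcas")
  loci <- loci %||% scan$locus[scan$clinal]
  d <- purrr::map(loci, function(loc) {
    p <- pcas[[loc]]
    tibble::tibble(
      locus = loc, population = names(p$scores),
      score = unname(p$scores), latitude = unname(p$latitudes)
    )
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$latitude, y = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~locus, scales = "free_y") +
    ggplot2::labs(x = "Latitude (°N)", y = "PC1 score") +
    ggplot2::theme_minimal()
}
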