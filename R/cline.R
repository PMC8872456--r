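# Per-locus PCA of ancestral-race allele frequencies along latitude, and
# projection of derived taxa onto the ancestral axes.

#' Principal component of allele frequencies at one locus
#'
#' Collapses the allelic variation at one locus across a set of (ancestral)
#' populations into orthogonal axes by PCA on the centered population x
#' allele frequency matrix (no scaling; populations are the observational
#' unit). The PC1 sign is fixed so that its correlation with latitude is
#' non-negative: higher score = more northern.
#'
#' @param freqs Allele-frequency table.
#' @param populations Population ids spanning the ancestral range (>= 4).
#' @param locus Locus name.
#' @param latitudes Numeric latitudes aligned with `populations`.
#' @return An object of class `locus_pca`: `locus`, `alleles`, `center`,
#'   `loadings` (unit norm), `scores` (per population), `var_explained`,
#'   `latitudes`, `degenerate` flag.
#' @export
locus_pca <- function(freqs, populations, locus, latitudes) {
  assert_frequencies(freqs)
  if (length(populations) < 4) abort("Need >= 4 ancestral populations.")
  stopifnot(length(latitudes) == length(populations))
  vecs <- lapply(populations, function(p) freq_vector(freqs, p, locus))
  alleles <- sort(unique(unlist(lapply(vecs, names))))
  if (length(alleles) < 2) abort("Need >= 2 alleles for a PCA axis.")
  mat <- t(vapply(vecs, function(v) {
    setNames(ifelse(alleles %in% names(v), v[alleles], 0), alleles)
  }, numeric(length(alleles))))
  rownames(mat) <- populations
  center <- colMeans(mat)
  centered <- sweep(mat, 2, center)
  degenerate <- sum(centered^2) < 1e-14
  if (degenerate) {
    warn(sprintf("Locus %s has no frequency variance across populations.",
                 locus))
    loadings <- c(1, rep(0, length(alleles) - 1))
    scores <- rep(0, length(populations))
    ve <- NA_real_
  } else {
    sv <- svd(centered)
    loadings <- sv$v[, 1]
    scores <- drop(centered %*% loadings)
    ve <- sv$d[1]^2 / sum(sv$d^2)
    if (!is.na(cor(scores, latitudes)) && cor(scores, latitudes) < 0) {
      loadings <- -loadings
      scores <- -scores
    }
  }
  structure(
    list(
      locus = locus, alleles = alleles, center = center,
      loadings = setNames(loadings, alleles),
      scores = setNames(scores, populations),
      var_explained = ve, latitudes = setNames(latitudes, populations),
      degenerate = degenerate
    ),
    class = "locus_pca"
  )
}

# Project arbitrary population frequency vectors onto an ancestral axis.
# Alleles unseen in the ancestral populations carry no positional
# information and get zero loading (count returned for logging).
project_onto_axis <- function(pca, freq_vec) {
  shared <- intersect(names(freq_vec), pca$alleles)
  if (length(shared) == 0) {
    return(list(score = NA_real_, n_unseen = length(freq_vec)))
  }
  v <- setNames(numeric(length(pca$alleles)), pca$alleles)
  v[shared] <- freq_vec[shared]
  list(
    score = sum((v - pca$center) * pca$loadings),
    n_unseen = sum(!names(freq_vec) %in% pca$alleles)
  )
}

#' Detect major clinal loci by PC1-latitude correlation
#'
#' Runs [locus_pca()] per locus over the ancestral populations and flags a
#' locus as major-clinal iff `|Pearson r(PC1, latitude)| >= r_threshold`
#' and the correlation test p-value is at most `alpha`.
#'
#' @param freqs Allele-frequency table.
#' @param meta Metadata with `population`, `latitude` (and the ancestral
#'   populations selected via `populations`).
#' @param populations Ancestral population ids (>= 4).
#' @param loci Loci to scan (default: all loci in `freqs`).
#' @param r_threshold Correlation magnitude threshold (default 0.8).
#' @param alpha Significance threshold (default 0.05).
#' @return A tibble of class `clinal_scan`: `locus, r, p_value, clinal`,
#'   with the fitted `locus_pca` objects in attribute `"pcas"`.
#' @export
detect_clinal_loci <- function(freqs, meta, populations, loci = NULL,
                               r_threshold = 0.8, alpha = 0.05) {
  if (length(populations) < 4) abort("Need >= 4 ancestral populations.")
  lat <- meta$latitude[match(populations, meta$population)]
  if (anyNA(lat)) abort("Missing latitude for some ancestral populations.")
  loci <- loci %||% sort(unique(freqs$locus))
  pcas <- lapply(loci, function(loc) {
    locus_pca(freqs, populations, loc, lat)
  })
  names(pcas) <- loci
  rows <- purrr::map(pcas, function(p) {
    if (p$degenerate || sd(p$scores) == 0) {
      tibble::tibble(locus = p$locus, r = NA_real_, p_value = NA_real_,
                     clinal = FALSE)
    } else {
      ct <- cor.test(p$scores, p$latitudes)
      tibble::tibble(
        locus = p$locus, r = unname(ct$estimate), p_value = ct$p.value,
        clinal = abs(ct$estimate) >= r_threshold & ct$p.value <= alpha
      )
    }
  }) |> dplyr::bind_rows()
  structure(rows, pcas = pcas, r_threshold = r_threshold, alpha = alpha,
            populations = populations,
            class = c("clinal_scan", class(rows)))
}

#' Project derived taxa onto ancestral clinal axes and classify them
#'
#' For every flagged clinal locus and derived taxon, population frequency
#' vectors are projected onto the ancestral PC1 axis. The taxon mean score
#' gets a 95% CI: a percentile bootstrap over populations when the taxon
#' has >= 3 populations, otherwise a parametric bootstrap over gene copies
#' (multinomial resampling of each population's allele counts). The
#' ancestral mid-latitude band is the pointwise 95% confidence band of the
#' linear regression of ancestral score on latitude, evaluated across the
#' derived taxon's latitude range. Classification: `northern_like` if the
#' taxon CI lies entirely above the band, `southern_like` if entirely
#' below, else `mid_latitude`.
#'
#' @param scan A [detect_clinal_loci()] result.
#' @param freqs Allele-frequency table covering the derived populations.
#' @param meta Metadata (`population`, `taxon`, `latitude`).
#' @param taxa Derived taxon labels to classify.
#' @param ci_reps Bootstrap replicates for the taxon CI.
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return A tibble `taxon, locus, n_pops, mean_score, ci_low, ci_high,
#'   band_low, band_high, classification, n_unseen_alleles`.
#' @export
project_and_classify <- function(scan, freqs, meta, taxa, ci_reps = 1000,
                                 seed = 1L, conf = 0.95) {
  stopifnot(inherits(scan, "clinal_scan"))
  pcas <- attr(scan, "pcas")
  anc_pops <- attr(scan, "populations")
  clinal <- scan$locus[scan$clinal]
  if (length(clinal) == 0) abort("No clinal loci flagged in `scan`.")
  alpha <- (1 - conf) / 2
  set.seed(seed)
  rows <- list()
  for (loc in clinal) {
    pca <- pcas[[loc]]
    band_fit <- lm(score ~ lat,
                   data = data.frame(score = pca$scores,
                                     lat = pca$latitudes))
    for (tx in taxa) {
      pops <- meta$population[meta$taxon == tx]
      pops <- pops[vapply(pops, function(p) {
        copies_at(freqs, p, loc) > 0
      }, logical(1))]
      if (length(pops) == 0) {
        warn(sprintf("Taxon %s unscored at locus %s.", tx, loc))
        next
      }
      proj <- lapply(pops, function(p) {
        project_onto_axis(pca, freq_vector(freqs, p, loc))
      })
      sc <- vapply(proj, `[[`, numeric(1), "score")
      n_unseen <- sum(vapply(proj, `[[`, numeric(1), "n_unseen"))
      mean_score <- mean(sc)

      if (length(pops) >= 3) {
        boot <- replicate(ci_reps, {
          mean(sc[sample.int(length(sc), replace = TRUE)])
        })
      } else {
        boot <- replicate(ci_reps, {
          mean(vapply(pops, function(p) {
            v <- freq_vector(freqs, p, loc)
            n <- copies_at(freqs, p, loc)
            counts <- rmultinom(1, n, v)[, 1]
            project_onto_axis(pca, setNames(counts / n, names(v)))$score
          }, numeric(1)))
        })
      }
      ci <- unname(quantile(boot, c(alpha, 1 - alpha)))

      lat_rng <- range(meta$latitude[meta$population %in% pops])
      grid <- data.frame(lat = seq(lat_rng[1], lat_rng[2], length.out = 25))
      band <- predict(band_fit, newdata = grid, interval = "confidence",
                      level = conf)
      band_low <- min(band[, "lwr"])
      band_high <- max(band[, "upr"])
      classification <- if (ci[1] > band_high) {
        "northern_like"
      } else if (ci[2] < band_low) {
        "southern_like"
      } else {
        "mid_latitude"
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        taxon = tx, locus = loc, n_pops = length(pops),
        mean_score = mean_score, ci_low = ci[1], ci_high = ci[2],
        band_low = band_low, band_high = band_high,
        classification = classification, n_unseen_alleles = n_unseen
      )
    }
  }
  dplyr::bind_rows(rows)
}
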