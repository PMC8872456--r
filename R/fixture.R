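# A deterministic-for-seed synthetic survey emulating the shape of a
# multi-taxon host-race radiation: 33 populations, 6 taxa, 19 loci,
# latitudinal clines in the ancestral taxon, sympatric ancestral/derived
# pairs, and private alleles injected into the more diverged taxa.

RPSG_LOCI <- c(
  "P71", "P37", "P4", "P3", "P46", "P73", "P70", "P80", "P7", "P16",
  "P23", "P66", "P11", "P29", "P50", "P60", "P18", "P9", "P27"
)
RPSG_CLINAL <- c("P71", "P37", "P70", "P80", "P16", "P7", "P23")

rpsg_meta <- function() {
  n_raw <- c(
    48, 96, 49, 46, 41, 48, 56, 98, 94, 40, 47, 49, 39, 47,    # hawthorn
    47, 96, 47, 48, 48, 105,                                   # apple
    36, 40, 39,                                                # dogwood fly
    32, 32, 26, 32,                                            # mendax
    48, 72, 59, 29, 29,                                        # zephyria
    34                                                         # cornivora
  )
  # Scale survey-design sample sizes to a ~1568-fly total, keeping each
  # population inside the design range.
  n <- pmin(105L, pmax(26L, as.integer(round(n_raw * 1568 / sum(n_raw)))))
  tibble::tibble(
    population = c(
      sprintf("H%02d", 1:14), sprintf("A%02d", 15:20),
      sprintf("D%02d", 21:23), sprintf("M%02d", 24:27),
      sprintf("Z%02d", 28:32), "C33"
    ),
    taxon = c(
      rep("pomonella_hawthorn", 14), rep("pomonella_apple", 6),
      rep("dogwood_fly", 3), rep("mendax", 4), rep("zephyria", 5),
      "cornivora"
    ),
    host = c(
      rep("downy_hawthorn", 5), rep("green_hawthorn", 3),
      rep("mayhaw", 2), rep("blueberry_hawthorn", 2),
      rep("black_hawthorn", 2), rep("apple", 6),
      rep("flowering_dogwood", 3), rep("blueberry", 4),
      rep("snowberry", 5), "silky_dogwood"
    ),
    latitude = c(
      43.35, 42.60, 41.88, 40.08, 36.53, 32.04, 31.27, 29.22, 31.31,
      31.27, 31.31, 31.21, 45.70, 45.60,
      43.35, 42.60, 41.88, 40.08, 45.70, 45.60,
      42.00, 36.45, 31.31,
      42.60, 39.82, 33.54, 34.08,
      45.73, 45.60, 43.58, 46.57, 47.52,
      40.08
    ),
    n = n
  )
}

rpsg_pairs <- function() {
  tibble::tibble(
    pair = letters[1:7],
    ancestral = c("H01", "H02", "H04", "H03", "H07", "H09", "H14"),
    derived = c("A15", "M24", "C33", "D21", "H10", "H12", "Z29"),
    ancestral_taxon = c(
      "pomonella_hawthorn", "pomonella_hawthorn", "pomonella_hawthorn",
      "pomonella_hawthorn", "pomonella_hawthorn", "pomonella_hawthorn",
      "pomonella_hawthorn"
    ),
    derived_taxon = c(
      "pomonella_apple", "mendax", "cornivora", "dogwood_fly",
      "pomonella_hawthorn", "pomonella_hawthorn", "zephyria"
    ),
    # Assumed per-pair symmetric gross migration rates; the cornivora pair
    # has no defensible rate and is excluded from selection profiles.
    m = c(0.045, 0.02, NA, 0.03, 0.05, 0.04, 0.01)
  )
}

# Per-taxon injected private-allele loci and taxon-wide target frequencies.
rpsg_private_plan <- function() {
  list(
    mendax = c(
      P71 = 0.076, P4 = 0.104, P70 = 0.05, P7 = 0.187, P11 = 0.05
    ),
    zephyria = c(
      P37 = 0.084, P3 = 0.236, P46 = 0.091, P73 = 0.05, P80 = 0.051,
      P7 = 0.70, P18 = 0.124, P27 = 0.137, P23 = 0.402
    ),
    cornivora = c(
      P71 = 0.219, P4 = 0.656, P3 = 1.0, P46 = 0.75, P73 = 0.241,
      P70 = 0.339, P7 = 0.167, P16 = 0.353, P23 = 0.303, P29 = 0.912,
      P18 = 0.594, P9 = 1.0, P27 = 0.375
    )
  )
}

clamp01 <- function(x, lo = 0.02, hi = 0.98) pmin(hi, pmax(lo, x))

#' Generate a synthetic multi-taxon microsatellite survey
#'
#' Builds a deterministic-for-seed genotype dataset with the structure the
#' package's analyses assume: 33 populations from 6 taxa at 19 loci, an
#' ancestral hawthorn-race taxon carrying latitudinal clines at 7 loci, a
#' recently derived apple race, three species-level derived taxa with
#' injected private alleles (5, 9 and 13 loci; two fixed private alleles in
#' the most divergent taxon), reduced allelic richness in one taxon, and
#' seven sympatric ancestral/derived population pairs with assumed gross
#' migration rates. Genotypes are drawn under Hardy-Weinberg within
#' populations.
#'
#' @param seed Integer seed; the full dataset is a deterministic function
#'   of it.
#' @return A list of class `rpsg_fixture`: `genotypes` (long tibble),
#'   `meta` (population metadata), `pairs` (sympatric pair definitions with
#'   migration rates), and `truth` (construction bookkeeping: clinal loci,
#'   injected private alleles per taxon, expected class frequencies).
#' @export
make_rpsg_fixture <- function(seed = 1L) {
  set.seed(seed)
  meta <- rpsg_meta()
  pairs <- rpsg_pairs()
  loci <- RPSG_LOCI
  base <- setNames(100L + 30L * seq_along(loci), loci)
  private_plan <- rpsg_private_plan()

  haw <- meta[meta$taxon == "pomonella_hawthorn", ]
  lat_rng <- range(haw$latitude)
  rel <- function(lat) (lat - lat_rng[1]) / (lat_rng[2] - lat_rng[1])

  # Locus-level constants (seeded once): non-clinal northern-class
  # frequency, within-class allele splits, per-taxon shift magnitudes.
  p_flat <- setNames(runif(length(loci), 0.35, 0.65), loci)
  w_n <- c(0.6, 0.4)   # split of the "northern" class over its two labels
  w_s <- c(0.55, 0.45)
  shift_sign <- setNames(sample(c(-1, 1), length(loci), replace = TRUE), loci)
  shift_apple <- setNames(runif(length(loci), 0.03, 0.2), loci)
  shift_dogwood <- setNames(runif(length(loci), 0.08, 0.4), loci)
  shift_mendax <- setNames(runif(length(loci), 0.08, 0.45), loci)
  shift_corn <- setNames(runif(length(loci), 0.3, 0.6), loci)

  # Northern-class frequency expected for a hawthorn population at `lat`.
  p_haw <- function(locus, lat) {
    if (locus %in% RPSG_CLINAL) 0.15 + 0.7 * rel(lat) else p_flat[[locus]]
  }

  # Mosaic endpoints for the derived species-level taxa (northern-like,
  # southern-like or mid-latitude class frequencies per clinal locus).
  mosaic <- list(
    dogwood_fly = c(
      P71 = 0.15, P37 = 0.15, P70 = 0.35, P80 = 0.15, P16 = 0.15,
      P7 = 0.15, P23 = 0.85
    ),
    mendax = c(
      P71 = 0.5, P37 = 0.5, P70 = 0.85, P80 = 0.5, P16 = 0.15,
      P7 = 0.85, P23 = 0.85
    ),
    zephyria = c(
      P71 = 0.5, P37 = 0.9, P70 = 0.9, P80 = 0.1, P16 = 0.9,
      P7 = 0.9, P23 = 0.7
    ),
    cornivora = c(
      P71 = 0.85, P37 = 0.85, P70 = 0.85, P80 = 0.5, P16 = 0.85,
      P7 = 0.85, P23 = 0.5
    )
  )

  class_freq_for <- function(pop_row, locus) {
    taxon <- pop_row$taxon
    lat <- pop_row$latitude
    if (taxon %in% c("pomonella_hawthorn")) {
      p <- p_haw(locus, lat)
    } else if (taxon == "pomonella_apple") {
      p <- p_haw(locus, lat) + shift_sign[[locus]] * shift_apple[[locus]] / 2
    } else {
      endpoints <- mosaic[[taxon]]
      p <- if (locus %in% RPSG_CLINAL) endpoints[[locus]] else
        p_flat[[locus]]
      shift <- switch(taxon,
        dogwood_fly = shift_dogwood[[locus]],
        mendax = shift_mendax[[locus]],
        zephyria = 0,          # mosaic endpoints already far from sympatric
        cornivora = shift_corn[[locus]] * (!locus %in% RPSG_CLINAL)
      )
      p <- p + shift_sign[[locus]] * shift
    }
    clamp01(p)
  }

  # Full allele-frequency vector for one population at one locus.
  freq_vector_for <- function(pop_row, locus) {
    b <- base[[locus]]
    p <- class_freq_for(pop_row, locus)
    # per-population jitter keeps frequency vectors from being identical
    p <- clamp01(p + runif(1, -0.04, 0.04))
    taxon <- pop_row$taxon
    if (taxon == "zephyria") {
      # reduced richness: one label per class
      v <- setNames(c(p, 1 - p), c(b, b + 4L))
    } else {
      v <- setNames(
        c(p * w_n, (1 - p) * w_s),
        c(b, b + 2L, b + 4L, b + 6L)
      )
    }
    priv <- private_plan[[taxon]]
    if (!is.null(priv) && locus %in% names(priv)) {
      fp <- priv[[locus]]
      lbl <- switch(taxon, mendax = b + 8L, zephyria = b + 10L,
                    cornivora = b + 12L)
      v <- c(v * (1 - fp), setNames(fp, lbl))
      v <- v[v > 0]
    }
    v
  }

  rows <- vector("list", nrow(meta) * length(loci))
  k <- 0L
  for (i in seq_len(nrow(meta))) {
    pop_row <- meta[i, ]
    n <- pop_row$n
    for (locus in loci) {
      v <- freq_vector_for(pop_row, locus)
      counts <- rmultinom(1, 2 * n, v)[, 1]
      copies <- sample(rep(as.integer(names(v)), counts))
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        individual = paste0(pop_row$population, "_",
                            sprintf("%03d", seq_len(n))),
        population = pop_row$population,
        locus = locus,
        allele_1 = copies[seq(1, 2 * n, 2)],
        allele_2 = copies[seq(2, 2 * n, 2)]
      )
    }
  }

  structure(
    list(
      genotypes = dplyr::bind_rows(rows),
      meta = meta,
      pairs = pairs,
      truth = list(
        seed = seed,
        loci = loci,
        clinal_loci = RPSG_CLINAL,
        private = private_plan,
        allele_base = base,
        mosaic = mosaic
      )
    ),
    class = "rpsg_fixture"
  )
}

#' @export
print.rpsg_fixture <- function(x, ...) {
  cat(sprintf(
    "Synthetic host-race survey: %d populations, %d taxa, %d loci, %d flies (seed %d)\n",
    dplyr::n_distinct(x$meta$population), dplyr::n_distinct(x$meta$taxon),
    dplyr::n_distinct(x$genotypes$locus), sum(x$meta$n), x$truth$seed
  ))
  invisible(x)
}
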