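# Two-island migration-selection machinery and genotype simulators.

#' Configure a two-island migration-selection model
#'
#' Two demes of equal size exchange a symmetric gross migration fraction `m`
#' each generation. At every locus one allele class ("A", the class favored in
#' deme 1) segregates against its complement ("a", favored in deme 2), with
#' diploid viability fitnesses (favored hom, het, disfavored hom) =
#' `(1, 1 - h*s, 1 - s)` in each deme for that deme's own selection
#' coefficient. Drift and stepwise mutation apply only in the finite-size
#' Wright-Fisher simulator; the deterministic recursion requires `mu = 0`.
#'
#' @param m Symmetric gross migration rate per generation, in \[0, 0.5\].
#' @param s_deme1,s_deme2 Per-locus selection coefficients (length `n_loci`,
#'   recycled) acting in deme 1 (favoring class A) and deme 2 (favoring
#'   class a). Set a deme's value to 0 for no selection there.
#' @param n_loci Number of loci.
#' @param h Dominance coefficient in \[0, 1\] (default 0.5).
#' @param Ne Diploid deme size; `Inf` selects deterministic mode.
#' @param mu Stepwise mutation rate per gene copy per generation.
#' @param mu_step Mutation step in bp (default 2, dinucleotide repeats).
#' @param generations Generations to iterate (cap, for the recursion).
#' @param p_init Initial frequency of class A; scalar, length-2 (per deme) or
#'   a 2 x `n_loci` matrix.
#' @param n_sample Diploid individuals sampled per deme at the end.
#' @param order Life-cycle order: migration before selection (default) or the
#'   reverse; drift/mutation always follow both.
#' @param seed Integer seed (stochastic mode).
#' @return A `two_island_config` list.
#' @export
two_island_config <- function(m, s_deme1 = 0, s_deme2 = s_deme1, n_loci = 1L,
                              h = 0.5, Ne = Inf, mu = 0, mu_step = 2L,
                              generations = 1e5, p_init = 0.5,
                              n_sample = 50L,
                              order = c("migration_first", "selection_first"),
                              seed = 1L) {
  order <- match.arg(order)
  if (m < 0 || m > 0.5) abort("`m` must lie in [0, 0.5].")
  if (h < 0 || h > 1) abort("`h` must lie in [0, 1].")
  if (any(s_deme1 < 0) || any(s_deme2 < 0)) abort("`s` must be >= 0.")
  if (mu < 0) abort("`mu` must be >= 0.")
  if (is.infinite(Ne) && mu > 0) {
    abort("Deterministic mode (Ne = Inf) requires mu = 0.")
  }
  s1 <- rep_len(s_deme1, n_loci)
  s2 <- rep_len(s_deme2, n_loci)
  if (is.matrix(p_init)) {
    stopifnot(nrow(p_init) == 2, ncol(p_init) == n_loci)
    p0 <- p_init
  } else if (length(p_init) == 2) {
    p0 <- matrix(rep(p_init, n_loci), nrow = 2)
  } else {
    p0 <- matrix(rep_len(p_init, n_loci), nrow = 2, ncol = n_loci,
                 byrow = TRUE)
  }
  if (any(p0 < 0 | p0 > 1)) abort("Initial frequencies must lie in [0, 1].")
  structure(
    list(
      m = m, s_deme1 = s1, s_deme2 = s2, n_loci = as.integer(n_loci), h = h,
      Ne = Ne, mu = mu, mu_step = as.integer(mu_step),
      generations = generations, p_init = p0,
      n_sample = as.integer(n_sample), order = order, seed = as.integer(seed)
    ),
    class = "two_island_config"
  )
}

# One generation of viability selection on the frequency of the favored
# allele class (fitnesses 1, 1-h*s, 1-s). Vectorized over loci.
select_favored <- function(p, s, h) {
  q <- 1 - p
  w_bar <- p^2 + 2 * p * q * (1 - h * s) + q^2 * (1 - s)
  p_new <- (p^2 + p * q * (1 - h * s)) / w_bar
  ifelse(s == 0 | w_bar == 0, p, p_new)
}

# Selection step in both demes for class-A frequency p (vector over loci).
# Deme 1 favors A at s1; deme 2 favors the complement at s2.
two_island_selection <- function(p1, p2, cfg) {
  list(
    p1 = select_favored(p1, cfg$s_deme1, cfg$h),
    p2 = 1 - select_favored(1 - p2, cfg$s_deme2, cfg$h)
  )
}

two_island_migration <- function(p1, p2, m) {
  list(p1 = (1 - m) * p1 + m * p2, p2 = (1 - m) * p2 + m * p1)
}

#' Iterate the deterministic two-island recursion to a fixed point
#'
#' Applies migration and viability selection (in the configured order) each
#' generation until the largest per-locus frequency change falls below `tol`.
#' Used as the exact oracle for the selection-coefficient solver.
#'
#' @param cfg A [two_island_config()] with `Ne = Inf` (or any config; drift
#'   and mutation are ignored here).
#' @param p1,p2 Optional starting class-A frequencies per locus; default from
#'   `cfg$p_init`.
#' @param order Override of the life-cycle order in `cfg`.
#' @param tol Convergence threshold on max |delta p| per generation.
#' @param max_gen Generation cap; non-convergence raises an error that
#'   carries the last state in its `data` field.
#' @return A list with `p1`, `p2` (equilibrium frequencies per locus) and
#'   `generations` used.
#' @export
iterate_two_island_deterministic <- function(cfg, p1 = NULL, p2 = NULL,
                                             order = NULL, tol = 1e-12,
                                             max_gen = cfg$generations) {
  stopifnot(inherits(cfg, "two_island_config"))
  order <- order %||% cfg$order
  p1 <- p1 %||% cfg$p_init[1, ]
  p2 <- p2 %||% cfg$p_init[2, ]
  for (gen in seq_len(max_gen)) {
    old1 <- p1; old2 <- p2
    if (order == "migration_first") {
      mig <- two_island_migration(p1, p2, cfg$m)
      sel <- two_island_selection(mig$p1, mig$p2, cfg)
    } else {
      sel0 <- two_island_selection(p1, p2, cfg)
      sel <- two_island_migration(sel0$p1, sel0$p2, cfg$m)
    }
    p1 <- sel$p1; p2 <- sel$p2
    if (max(abs(p1 - old1), abs(p2 - old2)) < tol) {
      return(list(p1 = p1, p2 = p2, generations = gen))
    }
  }
  cnd <- rlang::error_cnd(
    class = "divflow_no_convergence",
    message = sprintf(
      "Two-island recursion did not converge within %d generations.", max_gen
    ),
    data = list(p1 = p1, p2 = p2, generations = max_gen)
  )
  rlang::cnd_signal(cnd)
}

# Build initial per-label gamete pools for the stochastic simulator: each
# class realized as a set of microsatellite fragment-length labels.
init_label_pool <- function(p_class_a, labels_a, labels_b) {
  x <- c(
    setNames(rep(p_class_a / length(labels_a), length(labels_a)),
             labels_a),
    setNames(rep((1 - p_class_a) / length(labels_b), length(labels_b)),
             labels_b)
  )
  x
}

# Stepwise mutation on a named frequency vector; class membership is
# inherited from the parental allele. Returns updated freq + class vectors.
stepwise_mutate <- function(x, classes, mu, step) {
  if (mu == 0) return(list(x = x, classes = classes))
  labels <- as.integer(names(x))
  parent_class <- classes[names(x)]
  all_labels <- c(labels, labels + step, labels - step)
  all_mass <- c(x * (1 - mu), x * mu / 2, x * mu / 2)
  all_class <- c(parent_class, parent_class, parent_class)
  key <- as.character(all_labels)
  out <- tapply(all_mass, key, sum)
  out <- setNames(as.numeric(out), names(out))
  # a label reachable from both classes keeps its first donor's class;
  # in practice class ranges do not overlap at the mutation scales used
  new_classes <- classes
  fresh <- setdiff(names(out), names(new_classes))
  if (length(fresh) > 0) {
    donor <- match(fresh, key)
    new_classes[fresh] <- all_class[donor]
  }
  list(x = out[x_order(names(out))], classes = new_classes)
}

# stable numeric ordering of label names
x_order <- function(nms) nms[order(as.integer(nms))]

#' Simulate a two-island Wright-Fisher population pair
#'
#' Each generation applies the deterministic migration + selection
#' expectation at the allele-class level, stepwise mutation (labels move
#' +/- `mu_step` bp, class inherited), and multinomial drift over `2 Ne`
#' gene copies per deme. Selection acts on the two allele classes; the
#' microsatellite labels inside a class are selectively equivalent. At the
#' end, `n_sample` diploid individuals per deme are drawn without
#' replacement from the final gene-copy pool.
#'
#' @param cfg A [two_island_config()] with finite `Ne`.
#' @param labels_a,labels_b Fragment-length labels (bp) initially making up
#'   class A and class a at each locus. Lists of integer vectors (recycled
#'   across loci) or single vectors.
#' @return A list with `genotypes` (long tibble), `meta` (deme metadata),
#'   `freqs_true` (final per-deme class-A frequencies per locus), and
#'   `truth` (the generating parameters, including per-label classes).
#' @export
simulate_two_island <- function(cfg, labels_a = c(100L, 102L),
                                labels_b = c(120L, 122L)) {
  stopifnot(inherits(cfg, "two_island_config"))
  if (is.infinite(cfg$Ne)) abort("Stochastic simulation needs finite `Ne`.")
  set.seed(cfg$seed)
  if (!is.list(labels_a)) labels_a <- rep(list(labels_a), cfg$n_loci)
  if (!is.list(labels_b)) labels_b <- rep(list(labels_b), cfg$n_loci)
  n2 <- 2 * cfg$Ne

  pools <- vector("list", cfg$n_loci)
  class_of <- vector("list", cfg$n_loci)
  for (l in seq_len(cfg$n_loci)) {
    cls <- c(
      setNames(rep("A", length(labels_a[[l]])), labels_a[[l]]),
      setNames(rep("a", length(labels_b[[l]])), labels_b[[l]])
    )
    class_of[[l]] <- cls
    pools[[l]] <- list(
      init_label_pool(cfg$p_init[1, l], labels_a[[l]], labels_b[[l]]),
      init_label_pool(cfg$p_init[2, l], labels_a[[l]], labels_b[[l]])
    )
  }

  class_freq <- function(x, cls) sum(x[cls[names(x)] == "A"])

  for (gen in seq_len(cfg$generations)) {
    for (l in seq_len(cfg$n_loci)) {
      x <- pools[[l]][[1]]; y <- pools[[l]][[2]]
      al <- align_freqs(x, y)
      x <- al$x; y <- al$y
      cls <- class_of[[l]]

      apply_sel <- function(v, s, favored) {
        pA <- class_freq(v, cls)
        p_fav <- if (favored == "A") pA else 1 - pA
        w_fav <- p_fav + (1 - p_fav) * (1 - cfg$h * s)
        w_dis <- p_fav * (1 - cfg$h * s) + (1 - p_fav) * (1 - s)
        w <- ifelse(cls[names(v)] == favored, w_fav, w_dis)
        v * w / sum(v * w)
      }
      apply_mig <- function(v, w) (1 - cfg$m) * v + cfg$m * w

      if (cfg$order == "migration_first") {
        x1 <- apply_mig(x, y); y1 <- apply_mig(y, x)
        x1 <- apply_sel(x1, cfg$s_deme1[l], "A")
        y1 <- apply_sel(y1, cfg$s_deme2[l], "a")
      } else {
        xs <- apply_sel(x, cfg$s_deme1[l], "A")
        ys <- apply_sel(y, cfg$s_deme2[l], "a")
        x1 <- apply_mig(xs, ys); y1 <- apply_mig(ys, xs)
      }
      mx <- stepwise_mutate(x1, cls, cfg$mu, cfg$mu_step)
      my <- stepwise_mutate(y1, mx$classes, cfg$mu, cfg$mu_step)
      cls <- my$classes
      class_of[[l]] <- cls
      al2 <- align_freqs(mx$x, my$x)
      cx <- rmultinom(1, n2, al2$x)[, 1] / n2
      cy <- rmultinom(1, n2, al2$y)[, 1] / n2
      names(cx) <- names(cy) <- al2$alleles
      pools[[l]] <- list(cx[cx > 0 | cy > 0], cy[cx > 0 | cy > 0])
    }
  }

  # Sample diploid individuals without replacement from the final pool.
  geno_rows <- list()
  for (d in 1:2) {
    for (l in seq_len(cfg$n_loci)) {
      v <- pools[[l]][[d]]
      counts <- round(v * n2)
      counts[which.max(counts)] <- counts[which.max(counts)] +
        (n2 - sum(counts))
      copies <- rmvhyper(counts, 2 * cfg$n_sample)
      drawn <- sample(rep(as.integer(names(copies)), copies))
      geno_rows[[length(geno_rows) + 1]] <- tibble::tibble(
        individual = paste0("deme", d, "_", rep(seq_len(cfg$n_sample), 1)),
        population = paste0("deme", d),
        locus = paste0("L", l),
        allele_1 = drawn[seq(1, 2 * cfg$n_sample, by = 2)],
        allele_2 = drawn[seq(2, 2 * cfg$n_sample, by = 2)]
      )
    }
  }
  genotypes <- dplyr::bind_rows(geno_rows)

  freqs_true <- tibble::tibble(
    locus = rep(paste0("L", seq_len(cfg$n_loci)), each = 2),
    population = rep(c("deme1", "deme2"), cfg$n_loci),
    p_class_a = unlist(lapply(seq_len(cfg$n_loci), function(l) {
      c(
        class_freq(pools[[l]][[1]], class_of[[l]]),
        class_freq(pools[[l]][[2]], class_of[[l]])
      )
    }))
  )
  meta <- tibble::tibble(
    population = c("deme1", "deme2"), taxon = c("deme1", "deme2"),
    latitude = c(40, 40), n = cfg$n_sample
  )
  list(
    genotypes = genotypes, meta = meta, freqs_true = freqs_true,
    truth = list(
      m = cfg$m, s_deme1 = cfg$s_deme1, s_deme2 = cfg$s_deme2, h = cfg$h,
      Ne = cfg$Ne, mu = cfg$mu, classes = class_of, seed = cfg$seed
    )
  )
}

#' Configure and simulate latitudinal clines
#'
#' Clinal loci get class-allele frequencies linearly interpolated along
#' latitude between a northern and a southern endpoint; non-clinal loci share
#' one frequency across demes. Genotypes are drawn under Hardy-Weinberg with
#' binomial sampling noise.
#'
#' @param latitudes Strictly monotone vector of deme latitudes (>= 5 demes).
#' @param clinal Tibble with columns `locus`, `p_north`, `p_south` (frequency
#'   of the focal allele at the endpoints) and optionally `allele_a`,
#'   `allele_b` labels.
#' @param nonclinal Tibble with columns `locus`, `p` and optional labels.
#' @param n_per_deme Diploid individuals sampled per deme.
#' @param seed Integer seed.
#' @return A `cline_config` list.
#' @export
cline_config <- function(latitudes, clinal, nonclinal = NULL,
                         n_per_deme = 50L, seed = 1L) {
  if (length(latitudes) < 5) abort("A cline needs at least 5 demes.")
  d <- diff(latitudes)
  if (!(all(d > 0) || all(d < 0))) {
    abort("`latitudes` must be strictly monotone along the transect.")
  }
  fill_labels <- function(tb, base) {
    if (is.null(tb)) return(tb)
    if (!"allele_a" %in% names(tb)) {
      tb$allele_a <- base + 20L * seq_len(nrow(tb))
    }
    if (!"allele_b" %in% names(tb)) tb$allele_b <- tb$allele_a + 2L
    tb
  }
  structure(
    list(
      latitudes = latitudes, clinal = fill_labels(clinal, 100L),
      nonclinal = fill_labels(nonclinal, 500L),
      n_per_deme = as.integer(n_per_deme), seed = as.integer(seed)
    ),
    class = "cline_config"
  )
}

#' @rdname cline_config
#' @param cfg A `cline_config`.
#' @return `simulate_cline()`: a list with `genotypes` (long tibble), `meta`
#'   (with latitudes) and `freqs_true` (expected focal-allele frequency per
#'   deme and locus).
#' @export
simulate_cline <- function(cfg) {
  stopifnot(inherits(cfg, "cline_config"))
  set.seed(cfg$seed)
  lat <- cfg$latitudes
  rel <- (lat - min(lat)) / (max(lat) - min(lat))
  pops <- paste0("deme_", sprintf("%02d", seq_along(lat)))
  n <- cfg$n_per_deme

  loci <- dplyr::bind_rows(
    if (!is.null(cfg$clinal)) dplyr::mutate(cfg$clinal, clinal = TRUE),
    if (!is.null(cfg$nonclinal)) {
      dplyr::mutate(cfg$nonclinal, p_north = .data$p, p_south = .data$p,
                    clinal = FALSE)
    }
  )
  rows <- list()
  truth <- list()
  for (i in seq_len(nrow(loci))) {
    li <- loci[i, ]
    p_deme <- li$p_south + (li$p_north - li$p_south) * rel
    for (d in seq_along(lat)) {
      copies <- rbinom(2 * n, 1, p_deme[d])
      lbl <- ifelse(copies == 1, li$allele_a, li$allele_b)
      rows[[length(rows) + 1]] <- tibble::tibble(
        individual = paste0(pops[d], "_", seq_len(n)),
        population = pops[d], locus = li$locus,
        allele_1 = lbl[seq(1, 2 * n, 2)], allele_2 = lbl[seq(2, 2 * n, 2)]
      )
    }
    truth[[li$locus]] <- tibble::tibble(
      locus = li$locus, population = pops, latitude = lat, p_expected = p_deme,
      clinal = li$clinal
    )
  }
  list(
    genotypes = dplyr::bind_rows(rows),
    meta = tibble::tibble(
      population = pops, taxon = "ancestral", latitude = lat, n = n
    ),
    freqs_true = dplyr::bind_rows(truth)
  )
}
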