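# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive quantities from first principles rather than
# calling the package's own computation paths.

# ---- genotype / frequency builders ----------------------------------------

# Long genotype tibble from a list: pops -> loci -> matrix with 2 columns
# (one row per individual, NA allowed).
build_geno <- function(spec) {
  rows <- list()
  for (pop in names(spec)) {
    loci <- spec[[pop]]
    n <- nrow(loci[[1]])
    for (loc in names(loci)) {
      m <- loci[[loc]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        individual = paste0(pop, "_", seq_len(n)),
        population = pop, locus = loc,
        allele_1 = as.integer(m[, 1]), allele_2 = as.integer(m[, 2])
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Allele-frequency table straight from named count vectors:
# counts = list(pop = list(locus = c(`100` = 12, `102` = 8))).
build_freqs <- function(counts) {
  rows <- list()
  for (pop in names(counts)) {
    for (loc in names(counts[[pop]])) {
      v <- counts[[pop]][[loc]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        population = pop, locus = loc,
        allele = as.integer(names(v)),
        freq = as.numeric(v) / sum(v),
        n_copies = as.integer(sum(v))
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Random Hardy-Weinberg genotypes for one population from allele freqs.
hwe_geno <- function(pop, loci_freqs, n) {
  rows <- list()
  for (loc in names(loci_freqs)) {
    v <- loci_freqs[[loc]]
    idx <- sample.int(length(v), 2 * n, replace = TRUE,
                      prob = as.numeric(v))
    copies <- as.integer(names(v))[idx]
    rows[[length(rows) + 1]] <- tibble::tibble(
      individual = paste0(pop, "_", seq_len(n)), population = pop,
      locus = loc, allele_1 = copies[seq(1, 2 * n, 2)],
      allele_2 = copies[seq(2, 2 * n, 2)]
    )
  }
  dplyr::bind_rows(rows)
}

# ---- rarefaction oracle ---------------------------------------------------

# Expected distinct alleles in a subsample of g copies, by exhaustive
# enumeration of all C(N, g) subsets of the gene-copy pool.
enumerate_alpha <- function(counts, g) {
  pool <- rep(seq_along(counts), counts)
  subsets <- utils::combn(length(pool), g)
  mean(apply(subsets, 2, function(idx) length(unique(pool[idx]))))
}

# All partitions of N into at most k positive parts (allele count configs).
partitions_of <- function(n, k, max_part = n) {
  if (n == 0) return(list(integer()))
  out <- list()
  for (p in seq_len(min(n, max_part))) {
    if (k == 0) break
    for (rest in partitions_of(n - p, k - 1, p)) {
      out[[length(out) + 1]] <- c(p, rest)
    }
  }
  out
}

# ---- selection-solver oracle ----------------------------------------------

# One generation of diploid viability selection on the favored class,
# written independently of the package (explicit genotype bookkeeping).
oracle_select <- function(p, s, h) {
  q <- 1 - p
  w_aa <- 1
  w_ab <- 1 - h * s
  w_bb <- 1 - s
  (p^2 * w_aa + p * q * w_ab) /
    (p^2 * w_aa + 2 * p * q * w_ab + q^2 * w_bb)
}

# Bisection on s over the full diploid update. compensatory: selection gain
# at the resident frequency equals the migration loss. sequential: migration
# first, then selection must return the frequency to p_f (the equilibrium
# one-generation condition).
oracle_required_s <- function(p_f, p_i, m, h = 0.5,
                              convention = "compensatory",
                              tol = 1e-12) {
  delta <- m * (p_f - p_i)
  if (delta <= 0) return(0)
  gap <- function(s) {
    if (convention == "compensatory") {
      (oracle_select(p_f, s, h) - p_f) - delta
    } else {
      p_star <- (1 - m) * p_f + m * p_i
      oracle_select(p_star, s, h) - p_f
    }
  }
  if (gap(1) < 0) return(Inf)  # not maintainable with s <= 1
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (gap(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# ---- Nei-Chesser D_EST oracle (from-scratch second implementation) --------

oracle_dest <- function(counts_a, counts_b) {
  al <- union(names(counts_a), names(counts_b))
  xa <- sapply(al, function(k) ifelse(k %in% names(counts_a),
                                      counts_a[[k]], 0))
  xb <- sapply(al, function(k) ifelse(k %in% names(counts_b),
                                      counts_b[[k]], 0))
  n_a <- sum(xa) / 2
  n_b <- sum(xb) / 2
  pa <- xa / sum(xa)
  pb <- xb / sum(xb)
  n_h <- 2 / (1 / n_a + 1 / n_b)
  hs <- (2 * n_h / (2 * n_h - 1)) * (1 - (sum(pa^2) + sum(pb^2)) / 2)
  ht <- (1 - sum(((pa + pb) / 2)^2)) + hs / (4 * n_h)
  2 * (ht - hs) / (1 - hs)
}

# ---- cline / mosaic fixture ----------------------------------------------

# Ancestral transect of 14 demes plus a 3-population derived taxon whose
# clinal loci copy either the northern or the southern endpoint frequency.
# Non-clinal loci share a flat frequency everywhere.
make_mosaic_fixture <- function(seed, n_anc = 60, n_der = 40,
                                northern_loci = c("C1", "C2", "C3"),
                                southern_loci = c("C4", "C5", "C6", "C7")) {
  set.seed(seed)
  lats <- seq(30, 45, length.out = 14)
  clinal <- tibble::tibble(
    locus = c(northern_loci, southern_loci),
    p_north = 0.85, p_south = 0.15
  )
  nonclinal <- tibble::tibble(
    locus = paste0("N", 1:12),
    p = runif(12, 0.35, 0.65)
  )
  cfg <- divflow::cline_config(lats, clinal, nonclinal,
                               n_per_deme = n_anc, seed = seed)
  anc <- divflow::simulate_cline(cfg)

  # derived populations at mid latitudes carrying endpoint frequencies
  der_lats <- c(36, 37, 38)
  rows <- list()
  for (i in seq_along(der_lats)) {
    pop <- paste0("derived_", i)
    for (j in seq_len(nrow(clinal))) {
      loc <- clinal$locus[j]
      p <- if (loc %in% northern_loci) 0.85 else 0.15
      lbl_a <- cfg$clinal$allele_a[match(loc, cfg$clinal$locus)]
      lbl_b <- cfg$clinal$allele_b[match(loc, cfg$clinal$locus)]
      copies <- ifelse(rbinom(2 * n_der, 1, p) == 1, lbl_a, lbl_b)
      rows[[length(rows) + 1]] <- tibble::tibble(
        individual = paste0(pop, "_", seq_len(n_der)), population = pop,
        locus = loc, allele_1 = copies[seq(1, 2 * n_der, 2)],
        allele_2 = copies[seq(2, 2 * n_der, 2)]
      )
    }
    for (j in seq_len(nrow(nonclinal))) {
      loc <- nonclinal$locus[j]
      lbl_a <- cfg$nonclinal$allele_a[match(loc, cfg$nonclinal$locus)]
      lbl_b <- cfg$nonclinal$allele_b[match(loc, cfg$nonclinal$locus)]
      copies <- ifelse(rbinom(2 * n_der, 1, nonclinal$p[j]) == 1,
                       lbl_a, lbl_b)
      rows[[length(rows) + 1]] <- tibble::tibble(
        individual = paste0(pop, "_", seq_len(n_der)), population = pop,
        locus = loc, allele_1 = copies[seq(1, 2 * n_der, 2)],
        allele_2 = copies[seq(2, 2 * n_der, 2)]
      )
    }
  }
  geno <- dplyr::bind_rows(c(list(anc$genotypes), rows))
  meta <- dplyr::bind_rows(
    anc$meta,
    tibble::tibble(
      population = paste0("derived_", 1:3), taxon = "derived",
      latitude = der_lats, n = n_der
    )
  )
  list(
    genotypes = geno, meta = meta,
    ancestral_pops = anc$meta$population,
    clinal_loci = clinal$locus,
    northern_loci = northern_loci, southern_loci = southern_loci
  )
}

# ---- hybrid simulation ----------------------------------------------------

# Draw one diploid individual of a given class from two parental frequency
# pools (named vectors per locus).
sim_hybrid_individual <- function(id, pop, class, pools_a, pools_b) {
  draw <- function(v) {
    as.integer(names(v))[sample.int(length(v), 1, prob = as.numeric(v))]
  }
  rows <- lapply(names(pools_a), function(loc) {
    fa <- pools_a[[loc]]
    fb <- pools_b[[loc]]
    mix <- function() if (runif(1) < 0.5) draw(fa) else draw(fb)
    g <- switch(class,
      pure = c(draw(fa), draw(fa)),
      migrant = c(draw(fb), draw(fb)),
      f1 = c(draw(fa), draw(fb)),
      bc1 = c(draw(fa), mix())
    )
    tibble::tibble(
      individual = id, population = pop, locus = loc,
      allele_1 = g[1], allele_2 = g[2]
    )
  })
  dplyr::bind_rows(rows)
}
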