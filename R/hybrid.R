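# Likelihood classification of individuals from a sympatric population pair
# into pure natal, pure migrant, F1 and backcross genotypic classes. This is
# a transparent simplification that conditions on two predefined parental
# allele pools; it does not jointly infer clusters the way admixture MCMC
# programs do, and its output should not be read as a reproduction of them.

HYBRID_CLASSES <- c("pure_natal", "migrant", "f1", "bc_natal", "bc_other")

# Probability of drawing allele `x` from a gamete pool `f` (named freq
# vector), with a pseudo-frequency floor for alleles unseen in the pool so
# likelihoods stay finite.
gamete_prob <- function(x, f, floor) {
  key <- as.character(x)
  p <- if (key %in% names(f)) f[[key]] else 0
  max(p, floor)
}

#' Per-locus genotype probability under a hybrid-class gamete model
#'
#' Each class determines the origin of the two gametes: pure natal = both
#' from the natal pool; migrant = both from the other pool; F1 = one from
#' each; backcross to a pool = one gamete from that pool and one from the
#' F1 gamete mixture `(natal + other)/2`. A factor 2 applies to
#' heterozygotes when the two gamete sources are exchangeable.
#'
#' @param a1,a2 The two allele labels of the diploid call.
#' @param freq_natal,freq_other Named allele-frequency vectors of the natal
#'   and other parental pool.
#' @param class One of `"pure_natal"`, `"migrant"`, `"f1"`, `"bc_natal"`,
#'   `"bc_other"`.
#' @param floor_natal,floor_other Pseudo-frequency floors for alleles unseen
#'   in a pool (default `1/(2N+1)` with `N` the pool's gene-copy count is
#'   applied by [classify_individuals()]; here any small positive value).
#' @return Genotype probability (not log).
#' @export
genotype_class_prob <- function(a1, a2, freq_natal, freq_other, class,
                                floor_natal = 1e-4, floor_other = 1e-4) {
  class <- match.arg(class, HYBRID_CLASSES)
  mix <- function(x) {
    (gamete_prob(x, freq_natal, floor_natal) +
       gamete_prob(x, freq_other, floor_other)) / 2
  }
  g <- switch(class,
    pure_natal = list(
      function(x) gamete_prob(x, freq_natal, floor_natal),
      function(x) gamete_prob(x, freq_natal, floor_natal)
    ),
    migrant = list(
      function(x) gamete_prob(x, freq_other, floor_other),
      function(x) gamete_prob(x, freq_other, floor_other)
    ),
    f1 = list(
      function(x) gamete_prob(x, freq_natal, floor_natal),
      function(x) gamete_prob(x, freq_other, floor_other)
    ),
    bc_natal = list(
      function(x) gamete_prob(x, freq_natal, floor_natal), mix
    ),
    bc_other = list(
      function(x) gamete_prob(x, freq_other, floor_other), mix
    )
  )
  if (a1 == a2) {
    g[[1]](a1) * g[[2]](a1)
  } else {
    g[[1]](a1) * g[[2]](a2) + g[[1]](a2) * g[[2]](a1)
  }
}

allele_counts_by_locus <- function(geno) {
  long <- tidyr::pivot_longer(
    geno[, c("locus", "allele_1", "allele_2")],
    cols = c("allele_1", "allele_2"), values_to = "allele"
  )
  long <- long[!is.na(long$allele), ]
  split(long$allele, long$locus) |> lapply(table)
}

#' Classify individuals of a sympatric pair into genotypic classes
#'
#' Computes, for every individual of two populations, the posterior over
#' five genotypic classes — pure natal, pure parental migrant, F1 hybrid,
#' backcross to the natal population, backcross to the other — from the
#' product of per-locus genotype probabilities ([genotype_class_prob()])
#' and a migration prior. The prior mass `migration_prior` is split evenly
#' over the four non-natal-history classes (a flat two-generation ancestry
#' prior); the remainder goes to pure natal. Parental pool frequencies are
#' estimated from the data, leave-one-out for the focal individual's natal
#' population. Alleles unseen in a pool are floored at `1/(2N+1)`.
#'
#' When the two pools are weakly differentiated (mean Jost's D_EST across
#' loci below `min_dest`) genotypic classification is not well supported
#' and a warning is emitted.
#'
#' @param geno Long-format genotype tibble holding the individuals to
#'   classify.
#' @param pop_a,pop_b Population ids.
#' @param migration_prior Prior probability of a non-natal genotypic
#'   history (default 0.01).
#' @param min_dest Differentiation floor below which a warning is emitted.
#' @param ref_geno Genotype table the parental pool frequencies are
#'   estimated from (>= 10 individuals per population); defaults to `geno`
#'   itself. Supply an uncontaminated reference sample when the individuals
#'   under classification should not contribute to the pools.
#' @param leave_one_out Subtract the focal individual's own gene copies
#'   from its natal pool before computing likelihoods (default `TRUE`;
#'   applies only when the individual is part of `ref_geno`).
#' @return A tibble: `individual, population, n_loci`, one posterior column
#'   per class, `top_class`, and `non_natal_posterior` (1 - pure natal).
#'   Individuals missing at all loci are dropped with a warning.
#' @export
classify_individuals <- function(geno, pop_a, pop_b, migration_prior = 0.01,
                                 min_dest = 0.05, ref_geno = geno,
                                 leave_one_out = TRUE) {
  assert_genotypes(geno)
  if (migration_prior <= 0 || migration_prior >= 1) {
    abort("`migration_prior` must lie in (0, 1).")
  }
  ga <- geno[geno$population == pop_a, , drop = FALSE]
  gb <- geno[geno$population == pop_b, , drop = FALSE]
  ra <- ref_geno[ref_geno$population == pop_a, , drop = FALSE]
  rb <- ref_geno[ref_geno$population == pop_b, , drop = FALSE]
  for (g in list(ra, rb)) {
    if (dplyr::n_distinct(g$individual) < 10) {
      abort("Both populations need >= 10 individuals for pool frequencies.")
    }
  }
  counts <- list(allele_counts_by_locus(ra), allele_counts_by_locus(rb))
  names(counts) <- c(pop_a, pop_b)
  ref_ids <- unique(ref_geno$individual)

  freqs <- allele_frequencies(dplyr::bind_rows(ra, rb))
  dest <- jost_dest(freqs, pop_a, pop_b)
  if (mean(dest$dest) < min_dest) {
    warn(sprintf(
      "Mean D_EST between pools is %.3f (< %.2f): insufficient differentiation for reliable genotypic detection of migrants and hybrids.",
      mean(dest$dest), min_dest
    ))
  }

  prior <- c(1 - migration_prior, rep(migration_prior / 4, 4))
  names(prior) <- HYBRID_CLASSES

  classify_one <- function(ind_rows, natal, other) {
    ind_rows <- ind_rows[!is.na(ind_rows$allele_1), , drop = FALSE]
    if (nrow(ind_rows) == 0) return(NULL)
    ll <- setNames(numeric(length(HYBRID_CLASSES)), HYBRID_CLASSES)
    for (i in seq_len(nrow(ind_rows))) {
      loc <- ind_rows$locus[i]
      a1 <- ind_rows$allele_1[i]
      a2 <- ind_rows$allele_2[i]
      cn <- counts[[natal]][[loc]]
      co <- counts[[other]][[loc]]
      if (is.null(co) || is.null(cn)) next   # pool unscored: uninformative
      if (leave_one_out && ind_rows$individual[1] %in% ref_ids) {
        # leave-one-out removal of the focal individual's own gene copies
        cn <- cn - table(factor(c(a1, a2), levels = names(cn)))
        cn <- pmax(cn, 0)
        cn <- cn[cn > 0]
      }
      if (length(cn) == 0) next
      fn <- as.numeric(cn) / sum(cn)
      names(fn) <- names(cn)
      fo <- as.numeric(co) / sum(co)
      names(fo) <- names(co)
      fl_n <- 1 / (sum(cn) + 1)
      fl_o <- 1 / (sum(co) + 1)
      for (cls in HYBRID_CLASSES) {
        ll[cls] <- ll[cls] + log(genotype_class_prob(
          a1, a2, fn, fo, cls, fl_n, fl_o
        ))
      }
    }
    log_post <- log(prior) + ll
    post <- exp(log_post - max(log_post))
    post <- post / sum(post)
    tibble::tibble(
      individual = ind_rows$individual[1], population = natal,
      n_loci = nrow(ind_rows),
      !!!setNames(as.list(post), HYBRID_CLASSES),
      top_class = HYBRID_CLASSES[which.max(post)],
      non_natal_posterior = 1 - post[["pure_natal"]]
    )
  }

  out <- list()
  for (side in list(list(g = ga, natal = pop_a, other = pop_b),
                    list(g = gb, natal = pop_b, other = pop_a))) {
    for (ind in unique(side$g$individual)) {
      res <- classify_one(side$g[side$g$individual == ind, ],
                          side$natal, side$other)
      if (is.null(res)) {
        warn(sprintf("Individual %s is missing at all loci; dropped.", ind))
      } else {
        out[[length(out) + 1]] <- res
      }
    }
  }
  dplyr::bind_rows(out)
}
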