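test_that("hypergeometric rarefaction equals exhaustive enumeration", {
  # the (5,3,2), g = 4 case and a handful of other configurations
  cases <- list(
    list(counts = c(5, 3, 2), g = 4),
    list(counts = c(5, 3, 2), g = 7),
    list(counts = c(6, 4), g = 3),
    list(counts = c(4, 3, 2, 1), g = 5),
    list(counts = c(9, 1), g = 2)
  )
  for (cs in cases) {
    N <- sum(cs$counts)
    fr <- build_freqs(list(p = list(
      L1 = setNames(cs$counts, 100 + 2 * seq_along(cs$counts))
    )))
    got <- rarefied_richness(fr, g = cs$g)
    expect_equal(got$alpha, enumerate_alpha(cs$counts, cs$g),
                 tolerance = 1e-10)
  }
})

test_that("rarefaction limits: monomorphic locus, full sample, bad g", {
  fr <- build_freqs(list(p = list(
    MONO = c(`212` = 20),
    POLY = c(`100` = 8, `102` = 7, `104` = 5)
  )))
  a_mono <- rarefied_richness(fr, g = 5)
  expect_equal(a_mono$alpha[a_mono$locus == "MONO"], 1)
  a_full <- rarefied_richness(fr, g = 20)
  expect_equal(a_full$alpha[a_full$locus == "POLY"], 3, tolerance = 1e-12)
  expect_error(rarefied_richness(fr, g = 21), "exceeds N")
})

test_that("alpha_g is monotone in g and under allele splitting", {
  fr <- build_freqs(list(p = list(L1 = c(`100` = 5, `102` = 3, `104` = 2))))
  curve <- rarefied_richness(fr, g = 2:10)
  expect_true(all(diff(curve$alpha) >= -1e-12))
  # splitting one allele into two of the same total never decreases alpha_g
  fr_split <- build_freqs(list(p = list(
    L1 = c(`100` = 5, `102` = 3, `104` = 1, `106` = 1)
  )))
  curve_split <- rarefied_richness(fr_split, g = 2:10)
  expect_true(all(curve_split$alpha - curve$alpha >= -1e-12))
})

test_that("default g range standardizes to the smallest gene-copy count", {
  fr <- build_freqs(list(
    big = list(L1 = c(`100` = 30, `102` = 10)),
    small = list(L1 = c(`100` = 4, `102` = 4))
  ))
  curve <- rarefied_richness(fr)
  expect_equal(max(curve$g), 8)
  expect_equal(min(curve$g), 2)
})

test_that("the asymptotic fit recovers exact saturating curves", {
  g <- 2:40
  curve <- tibble::tibble(
    population = "p", locus = "L1", g = g, alpha = 12 * (1 - exp(-g / 5))
  )
  fit <- fit_asymptote(curve)
  expect_equal(fit$a_inf, 12, tolerance = 1e-6)
  expect_equal(fit$b, 5, tolerance = 1e-5)
  expect_false(fit$degenerate)

  flat <- tibble::tibble(
    population = "p", locus = "MONO", g = 2:10, alpha = 1
  )
  ffit <- fit_asymptote(flat)
  expect_equal(ffit$a_inf, 1)
  expect_true(ffit$degenerate)

  expect_error(
    fit_asymptote(curve[1:3, ]), ">= 4 distinct g"
  )
})

test_that("fitted asymptotes bracket the true allele count in simulation", {
  set.seed(31)
  for (r in 1:20) {
    counts <- as.vector(rmultinom(1, 60, rep(1 / 15, 15)))
    counts <- counts[counts > 0]
    fr <- build_freqs(list(p = list(
      L1 = setNames(counts, 100 + 2 * seq_along(counts))
    )))
    curve <- rarefied_richness(fr)
    fit <- fit_asymptote(curve)
    expect_gte(fit$a_inf, max(curve$alpha) - 1e-9)
    expect_lte(fit$a_inf, 15 * 1.2)
  }
})

test_that("private alleles obey the reference-absence and min-pops rules", {
  meta <- tibble::tibble(
    population = c("f1", "f2", "f3", "f4", "f5", "r1", "r2"),
    taxon = c(rep("focal", 5), rep("ref", 2))
  )
  # allele 250 in a single focal population only
  fr <- build_freqs(list(
    f1 = list(L1 = c(`100` = 10, `250` = 10)),
    f2 = list(L1 = c(`100` = 20)),
    f3 = list(L1 = c(`100` = 20)),
    f4 = list(L1 = c(`100` = 20)),
    f5 = list(L1 = c(`100` = 20)),
    r1 = list(L1 = c(`100` = 20)),
    r2 = list(L1 = c(`100` = 20, `102` = 2))
  ))
  strict <- private_alleles(fr, meta, "focal", "ref", min_pops = 2)
  expect_equal(nrow(strict), 0)
  single <- private_alleles(fr, meta, "focal", "ref", min_pops = 1)
  expect_equal(single$allele, 250L)

  # focal allele set a subset of the reference: empty report
  sub <- build_freqs(list(
    f1 = list(L1 = c(`100` = 10, `102` = 10)),
    f2 = list(L1 = c(`100` = 12, `102` = 8)),
    r1 = list(L1 = c(`100` = 10, `102` = 6, `104` = 4))
  ))
  meta2 <- tibble::tibble(population = c("f1", "f2", "r1"),
                          taxon = c("focal", "focal", "ref"))
  expect_equal(nrow(private_alleles(sub, meta2, "focal", "ref")), 0)
  expect_error(private_alleles(sub, meta2, "nope", "ref"), "Unknown taxon")
})

test_that("taxon-wide private frequency is gene-copy weighted", {
  # allele at frequency 0.5 in 2 of 4 equal-sized focal populations
  meta <- tibble::tibble(
    population = c("f1", "f2", "f3", "f4", "r1"),
    taxon = c(rep("focal", 4), "ref")
  )
  fr <- build_freqs(list(
    f1 = list(L1 = c(`100` = 10, `900` = 10)),
    f2 = list(L1 = c(`100` = 10, `900` = 10)),
    f3 = list(L1 = c(`100` = 20)),
    f4 = list(L1 = c(`100` = 20)),
    r1 = list(L1 = c(`100` = 20))
  ))
  rep <- private_alleles(fr, meta, "focal", "ref")
  expect_equal(rep$allele, 900L)
  expect_equal(rep$freq, 0.25)
  expect_equal(rep$n_pops, 2L)
})

test_that("private-allele reports are invariant to population structure", {
  meta <- tibble::tibble(
    population = c("f1", "f2", "r1"),
    taxon = c("focal", "focal", "ref")
  )
  fr <- build_freqs(list(
    f1 = list(L1 = c(`100` = 12, `900` = 8)),
    f2 = list(L1 = c(`100` = 15, `900` = 5)),
    r1 = list(L1 = c(`100` = 30))
  ))
  base <- private_alleles(fr, meta, "focal", "ref")
  # population order
  shuffled <- fr[rev(seq_len(nrow(fr))), ]
  expect_equal(
    tibble::as_tibble(private_alleles(shuffled, meta, "focal", "ref")),
    tibble::as_tibble(base)
  )
  # splitting f1 into two halves with the same pooled counts
  meta_split <- tibble::tibble(
    population = c("f1a", "f1b", "f2", "r1"),
    taxon = c("focal", "focal", "focal", "ref")
  )
  fr_split <- build_freqs(list(
    f1a = list(L1 = c(`100` = 6, `900` = 4)),
    f1b = list(L1 = c(`100` = 6, `900` = 4)),
    f2 = list(L1 = c(`100` = 15, `900` = 5)),
    r1 = list(L1 = c(`100` = 30))
  ))
  split_rep <- private_alleles(fr_split, meta_split, "focal", "ref")
  expect_equal(split_rep$freq, base$freq)
})

test_that("richness ANOVA: degenerate equality, group separation, letters", {
  rich_eq <- tibble::tibble(
    population = paste0("p", 1:6),
    richness = rep(c(4, 5, 6), 2)
  )
  groups <- tibble::tibble(
    population = paste0("p", 1:6),
    group = rep(c("g1", "g2"), each = 3)
  )
  fit <- compare_richness(rich_eq, groups)
  expect_equal(fit$f, 0, tolerance = 1e-12)

  # one taxon with halved richness lands in its own letter group
  set.seed(5)
  rich <- tibble::tibble(
    population = paste0("p", 1:12),
    richness = c(rnorm(4, 10, 0.3), rnorm(4, 10, 0.3), rnorm(4, 5, 0.3))
  )
  groups3 <- tibble::tibble(
    population = paste0("p", 1:12),
    group = rep(c("anc", "derived", "halved"), each = 4)
  )
  fit3 <- compare_richness(rich, groups3)
  expect_lt(fit3$p_value, 0.001)
  letters <- setNames(fit3$letters$letter, fit3$letters$group)
  expect_false(letters[["halved"]] %in% letters[c("anc", "derived")])

  # singleton groups are excluded, all-singletons error
  expect_message(
    compare_richness(
      rbind(rich, tibble::tibble(population = "solo", richness = 8)),
      rbind(groups3, tibble::tibble(population = "solo", group = "lone"))
    ),
    "Excluding single-population"
  )
  expect_error(
    compare_richness(
      tibble::tibble(population = c("a", "b"), richness = c(1, 2)),
      tibble::tibble(population = c("a", "b"), group = c("g1", "g2"))
    ),
    ">= 2 groups"
  )
})

test_that("richness ANOVA type-I error is calibrated under the null", {
  set.seed(99)
  reps <- 1000
  pvals <- numeric(reps)
  groups <- tibble::tibble(
    population = paste0("p", 1:12),
    group = rep(c("g1", "g2", "g3"), each = 4)
  )
  for (r in seq_len(reps)) {
    rich <- tibble::tibble(
      population = paste0("p", 1:12),
      richness = rnorm(12, 8, 1)
    )
    pvals[r] <- compare_richness(rich, groups)$p_value
  }
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
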