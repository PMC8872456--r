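test_that("migration alone homogenizes and isolation fixes favored alleles", {
  cfg <- two_island_config(m = 0.1, s_deme1 = 0, s_deme2 = 0,
                           p_init = matrix(c(0.9, 0.1), nrow = 2))
  eq <- iterate_two_island_deterministic(cfg, tol = 1e-13)
  expect_equal(eq$p1, 0.5, tolerance = 1e-9)
  expect_equal(eq$p2, 0.5, tolerance = 1e-9)

  cfg0 <- two_island_config(m = 0, s_deme1 = 0.2, s_deme2 = 0.2,
                            p_init = matrix(c(0.6, 0.4), nrow = 2))
  eq0 <- iterate_two_island_deterministic(cfg0, tol = 1e-13,
                                          max_gen = 1e6)
  expect_equal(eq0$p1, 1, tolerance = 1e-5)   # deme 1 fixes its favored A
  expect_equal(eq0$p2, 0, tolerance = 1e-5)   # deme 2 fixes its favored a
})

test_that("the recursion returns a verified stable fixed point", {
  cfg <- two_island_config(m = 0.05, s_deme1 = 0.3, s_deme2 = 0.3,
                           p_init = 0.5)
  for (order in c("migration_first", "selection_first")) {
    eq <- iterate_two_island_deterministic(cfg, order = order, tol = 1e-12)
    expect_gt(eq$p1, 0.5)
    expect_lt(eq$p2, 0.5)
    # one further generation moves nothing beyond tol
    one_more <- iterate_two_island_deterministic(
      cfg, p1 = eq$p1, p2 = eq$p2, order = order, tol = Inf, max_gen = 1
    )
    expect_lt(max(abs(one_more$p1 - eq$p1), abs(one_more$p2 - eq$p2)),
              1e-11)
  }
})

test_that("non-convergence raises an error carrying the last state", {
  cfg <- two_island_config(m = 0.05, s_deme1 = 0.3, s_deme2 = 0.3,
                           p_init = 0.5)
  err <- tryCatch(
    iterate_two_island_deterministic(cfg, tol = 1e-15, max_gen = 3),
    divflow_no_convergence = function(e) e
  )
  expect_s3_class(err, "divflow_no_convergence")
  expect_equal(err$data$generations, 3)
  expect_true(is.numeric(err$data$p1))
})

test_that("config invariants are enforced", {
  expect_error(two_island_config(m = 0.6), "0, 0.5")
  expect_error(two_island_config(m = 0.1, h = 1.5), "0, 1")
  expect_error(two_island_config(m = 0.1, s_deme1 = -0.1), ">= 0")
  expect_error(two_island_config(m = 0.1, Ne = Inf, mu = 1e-3),
               "Deterministic")
})

test_that("a huge panmictic population shows no differentiation", {
  cfg <- two_island_config(m = 0.5, s_deme1 = 0, n_loci = 5, Ne = 1e6,
                           mu = 0, generations = 100, n_sample = 100,
                           seed = 3)
  sim <- simulate_two_island(cfg)
  fst <- sim$freqs_true |>
    tidyr::pivot_wider(names_from = population, values_from = p_class_a)
  expect_lt(max(abs(fst$deme1 - fst$deme2)), 0.005)
})

test_that("drift erodes heterozygosity at the analytic rate", {
  # 50 isolated loci act as replicates; E[H_t] = H_0 (1 - 1/(2Ne))^t
  Ne <- 50; t <- 80
  cfg <- two_island_config(m = 0, s_deme1 = 0, n_loci = 50, Ne = Ne,
                           mu = 0, generations = t, n_sample = Ne,
                           seed = 5)
  sim <- simulate_two_island(cfg)
  p <- sim$freqs_true$p_class_a[sim$freqs_true$population == "deme1"]
  h_mean <- mean(2 * p * (1 - p))
  h_expected <- 0.5 * (1 - 1 / (2 * Ne))^t
  expect_equal(h_mean, h_expected, tolerance = 0.35)
})

test_that("neutral two-island F_ST matches the island-model expectation", {
  Ne <- 100; m <- 0.025; mu <- 5e-4
  cfg <- two_island_config(m = m, s_deme1 = 0, n_loci = 50, Ne = Ne,
                           mu = mu, generations = 1200, n_sample = Ne,
                           seed = 9)
  sim <- simulate_two_island(cfg)
  fr <- allele_frequencies(sim$genotypes)
  # Nei G_ST as a ratio of sums across loci from full-deme frequencies
  hs_sum <- ht_sum <- 0
  for (loc in unique(fr$locus)) {
    x <- fr$freq[fr$population == "deme1" & fr$locus == loc]
    names(x) <- fr$allele[fr$population == "deme1" & fr$locus == loc]
    y <- fr$freq[fr$population == "deme2" & fr$locus == loc]
    names(y) <- fr$allele[fr$population == "deme2" & fr$locus == loc]
    al <- union(names(x), names(y))
    xa <- ifelse(al %in% names(x), x[al], 0)
    ya <- ifelse(al %in% names(y), y[al], 0)
    hs_sum <- hs_sum + 1 - (sum(xa^2) + sum(ya^2)) / 2
    ht_sum <- ht_sum + 1 - sum(((xa + ya) / 2)^2)
  }
  fst <- (ht_sum - hs_sum) / ht_sum
  # island-model expectation 1/(1 + 4 Ne m_eff); with d = 2 demes the
  # migration rate scales by (d/(d-1))^2 = 4 (finite-island correction)
  expected <- 1 / (1 + 4 * Ne * 4 * (m + mu))
  expect_gt(fst, expected * 0.75)
  expect_lt(fst, expected * 1.25)
})

test_that("stepwise mutation only creates labels 2 bp from existing ones", {
  cfg <- two_island_config(m = 0.05, s_deme1 = 0, n_loci = 3, Ne = 200,
                           mu = 0.02, generations = 150, n_sample = 50,
                           seed = 4)
  sim <- simulate_two_island(cfg)
  labels <- sort(unique(c(sim$genotypes$allele_1, sim$genotypes$allele_2)))
  # initial labels 100,102 and 120,122 are all even; +/-2 steps stay even
  expect_true(all(labels %% 2 == 0))
  expect_true(length(labels) > 4)  # mutation actually created new labels
})

test_that("the same seed reproduces the simulation byte for byte", {
  cfg <- two_island_config(m = 0.03, s_deme1 = 0.2, n_loci = 4, Ne = 500,
                           mu = 1e-3, generations = 50, n_sample = 30,
                           seed = 21)
  expect_identical(simulate_two_island(cfg), simulate_two_island(cfg))
})

test_that("simulated clines are monotone and non-clinal loci flat", {
  cfg <- cline_config(
    latitudes = seq(30, 45, length.out = 10),
    clinal = tibble::tibble(locus = "C1", p_north = 0.9, p_south = 0.1),
    nonclinal = tibble::tibble(locus = "N1", p = 0.5),
    n_per_deme = 100, seed = 2
  )
  sim <- simulate_cline(cfg)
  fr <- allele_frequencies(sim$genotypes)
  lbl <- cfg$clinal$allele_a
  f_clinal <- fr$freq[fr$locus == "C1" & fr$allele == lbl]
  expect_gt(cor(f_clinal, sim$meta$latitude), 0.95)
  lbl_n <- cfg$nonclinal$allele_a
  f_flat <- fr$freq[fr$locus == "N1" & fr$allele == lbl_n]
  # every deme within a generous binomial CI of 0.5 (n = 200 copies)
  expect_true(all(abs(f_flat - 0.5) < 4 * sqrt(0.25 / 200)))
  expect_error(
    cline_config(seq(30, 33, length.out = 4), cfg$clinal),
    "5 demes"
  )
  expect_error(
    cline_config(c(30, 32, 31, 33, 34), cfg$clinal),
    "monotone"
  )
})

test_that("the synthetic survey fixture has the advertised structure", {
  fx <- make_rpsg_fixture(seed = 1)
  expect_equal(dplyr::n_distinct(fx$meta$population), 33L)
  expect_equal(dplyr::n_distinct(fx$meta$taxon), 6L)
  expect_equal(dplyr::n_distinct(fx$genotypes$locus), 19L)
  expect_gte(sum(fx$meta$n), 1500)
  expect_lte(sum(fx$meta$n), 1650)
  expect_true(all(fx$meta$n >= 26 & fx$meta$n <= 105))
  # deterministic for the seed
  expect_identical(make_rpsg_fixture(seed = 1)$genotypes, fx$genotypes)
  expect_false(identical(make_rpsg_fixture(seed = 2)$genotypes,
                         fx$genotypes))
})

test_that("injected private alleles are recovered exactly by construction", {
  fx <- make_rpsg_fixture(seed = 1)
  fr <- allele_frequencies(fx$genotypes)
  ref <- c("pomonella_hawthorn", "pomonella_apple")
  zeph <- private_alleles(fr, fx$meta, "zephyria", ref)
  expect_setequal(unique(zeph$locus), names(fx$truth$private$zephyria))
  corn <- private_alleles(fr, fx$meta, "cornivora", ref, min_pops = 1)
  expect_setequal(unique(corn$locus), names(fx$truth$private$cornivora))
  # the two fixed private alleles really are fixed differences
  fixed <- summary(corn)
  expect_equal(fixed$freq[fixed$locus %in% c("P3", "P9")], c(1, 1))
})
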