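test_that("allele pooling follows the majority rule with tie handling", {
  # identical maps: everything ties into the ancestral class, delta = 0
  same <- pool_alleles(c(A = 0.5, B = 0.5), c(A = 0.5, B = 0.5))
  expect_equal(same$a1, same$a2)
  expect_setequal(same$ancestral_class, c("A", "B"))

  two <- pool_alleles(c(A = 0.7, B = 0.3), c(A = 0.2, B = 0.8))
  expect_equal(two$ancestral_class, "A")
  expect_equal(two$a1, 0.7)
  expect_equal(two$a2, 0.2)

  three <- pool_alleles(c(A = 0.5, B = 0.3, C = 0.2),
                        c(A = 0.1, B = 0.5, C = 0.4))
  expect_equal(three$ancestral_class, "A")
  expect_equal(three$a1, 0.5)
  expect_equal(three$a2, 0.1)
  # derived-class complements sum to one
  expect_equal((1 - three$a1) + three$a1, 1)
  expect_equal(1 - three$a2, 0.9)

  expect_gte(
    pool_alleles(c(A = 0.6, B = 0.4), c(A = 0.6, B = 0.4))$a1,
    pool_alleles(c(A = 0.6, B = 0.4), c(A = 0.6, B = 0.4))$a2
  )
  expect_error(pool_alleles(c(A = 0.5), c(A = 0.5, B = 0.6)), "sum to 1")
})

test_that("required_s is zero without a difference or without migration", {
  expect_equal(required_s(0.6, 0.6, 0.05)$s, 0)
  expect_equal(required_s(0.9, 0.1, 0)$s, 0)
})

test_that("the sequential solution matches the recursion-bisection oracle", {
  got <- required_s(0.9, 0.1, 0.05, convention = "sequential")
  expect_equal(got$s, oracle_required_s(0.9, 0.1, 0.05,
                                        convention = "sequential"),
               tolerance = 1e-9)
  expect_equal(got$s, 0.608, tolerance = 1e-3)
  expect_false(got$capped)
})

test_that("closed-form s equals bisection over the diploid recursion", {
  for (conv in c("compensatory", "sequential")) {
    for (m in c(0.01, 0.05)) {
      for (p_f in c(0.55, 0.75, 0.95)) {
        for (p_i in c(0.05, 0.25, 0.5)) {
          oracle <- oracle_required_s(p_f, p_i, m, convention = conv)
          got <- required_s(p_f, p_i, m, convention = conv)
          if (is.infinite(oracle)) {
            expect_true(got$capped)
          } else {
            expect_equal(got$s, oracle, tolerance = 1e-8)
          }
        }
      }
    }
  }
})

test_that("general dominance is solved numerically and matches the oracle", {
  for (h in c(0, 0.25, 1)) {
    oracle <- oracle_required_s(0.8, 0.2, 0.04, h = h)
    got <- required_s(0.8, 0.2, 0.04, h = h)
    expect_equal(got$s, oracle, tolerance = 1e-7)
  }
})

test_that("unmaintainable differences cap at s = 1 with a flag", {
  got <- required_s(0.995, 0.005, 0.1)
  expect_true(is.infinite(oracle_required_s(0.995, 0.005, 0.1)) ||
                oracle_required_s(0.995, 0.005, 0.1) > 1)
  expect_equal(got$s, 1)
  expect_true(got$capped)
  # fixed resident class: degenerate and capped
  degen <- required_s(1, 0.2, 0.05)
  expect_true(degen$capped && degen$degenerate)
})

test_that("s increases with m and with the frequency difference", {
  s_m <- vapply(c(0.01, 0.03, 0.05, 0.1), function(m) {
    required_s(0.8, 0.3, m)$s
  }, numeric(1))
  expect_true(all(diff(s_m) > 0))
  s_gap <- vapply(c(0.7, 0.5, 0.3, 0.1), function(p_i) {
    required_s(0.8, p_i, 0.03)$s
  }, numeric(1))
  expect_true(all(diff(s_gap) > 0))
})

test_that("profiles invert deterministic equilibria exactly", {
  set.seed(41)
  n_loci <- 19
  s_anc <- runif(n_loci, 0.05, 0.5)
  s_der <- runif(n_loci, 0.05, 0.5)
  m <- 0.03
  cfg <- two_island_config(m = m, s_deme1 = s_anc, s_deme2 = s_der,
                           n_loci = n_loci,
                           p_init = matrix(rep(c(0.9, 0.1), n_loci),
                                           nrow = 2))
  eq <- iterate_two_island_deterministic(cfg, tol = 1e-14, max_gen = 1e6)
  # two shared class labels per locus: 100 (ancestral class), 102 (derived)
  counts <- list(anc = list(), der = list())
  for (l in seq_len(n_loci)) {
    loc <- paste0("L", l)
    counts$anc[[loc]] <- c(`100` = eq$p1[l] * 1e6,
                           `102` = (1 - eq$p1[l]) * 1e6)
    counts$der[[loc]] <- c(`100` = eq$p2[l] * 1e6,
                           `102` = (1 - eq$p2[l]) * 1e6)
  }
  fr <- build_freqs(counts)
  pooled <- pool_pair(fr, "anc", "der", m = m)
  prof <- pair_selection_profile(pooled, convention = "sequential")
  expect_equal(prof$per_locus$s_in_ancestral, s_anc, tolerance = 1e-6)
  expect_equal(prof$per_locus$s_in_derived, s_der, tolerance = 1e-6)
  expect_false(any(prof$per_locus$capped_ancestral |
                     prof$per_locus$capped_derived))
})

test_that("profiles are invariant to relabeling and class splitting", {
  fr <- build_freqs(list(
    anc = list(L1 = c(`100` = 70, `102` = 30)),
    der = list(L1 = c(`100` = 20, `102` = 80))
  ))
  base <- pair_selection_profile(pool_pair(fr, "anc", "der", m = 0.04))
  # split the ancestral-class allele into two with the same summed freq
  fr_split <- build_freqs(list(
    anc = list(L1 = c(`100` = 40, `104` = 30, `102` = 30)),
    der = list(L1 = c(`100` = 12, `104` = 8, `102` = 80))
  ))
  split <- pair_selection_profile(pool_pair(fr_split, "anc", "der",
                                            m = 0.04))
  expect_equal(split$per_locus$s_in_ancestral,
               base$per_locus$s_in_ancestral, tolerance = 1e-12)
  expect_equal(split$per_locus$s_in_derived,
               base$per_locus$s_in_derived, tolerance = 1e-12)
})

test_that("degenerate profiles: no difference anywhere means s = 0", {
  fr <- build_freqs(list(
    anc = list(L1 = c(`100` = 50, `102` = 50),
               L2 = c(`200` = 30, `202` = 70)),
    der = list(L1 = c(`100` = 50, `102` = 50),
               L2 = c(`200` = 30, `202` = 70))
  ))
  prof <- pair_selection_profile(pool_pair(fr, "anc", "der", m = 0.05))
  expect_true(all(prof$per_locus$s_in_ancestral == 0))
  expect_true(all(prof$per_locus$s_in_derived == 0))
  expect_equal(prof$summary$mean, c(0, 0))
})

test_that("symmetric frequencies give identical s in both directions", {
  a1 <- c(0.8, 0.65, 0.9)
  fr <- build_freqs(list(
    anc = list(L1 = c(`100` = a1[1] * 100, `102` = (1 - a1[1]) * 100),
               L2 = c(`200` = a1[2] * 100, `202` = (1 - a1[2]) * 100),
               L3 = c(`300` = a1[3] * 100, `302` = (1 - a1[3]) * 100)),
    der = list(L1 = c(`100` = (1 - a1[1]) * 100, `102` = a1[1] * 100),
               L2 = c(`200` = (1 - a1[2]) * 100, `202` = a1[2] * 100),
               L3 = c(`300` = (1 - a1[3]) * 100, `302` = a1[3] * 100))
  ))
  prof <- pair_selection_profile(pool_pair(fr, "anc", "der", m = 0.03))
  expect_equal(prof$per_locus$s_in_ancestral, prof$per_locus$s_in_derived,
               tolerance = 1e-12)
  at <- asymmetry_tests(prof)
  expect_equal(at$statistic[at$test == "paired_t"], 0)
  expect_equal(at$statistic[at$test == "variance_f"], 1)
})

test_that("summaries are computed on capped values", {
  fr <- build_freqs(list(
    anc = list(L1 = c(`100` = 995, `102` = 5),
               L2 = c(`200` = 70, `202` = 30)),
    der = list(L1 = c(`100` = 5, `102` = 995),
               L2 = c(`200` = 40, `202` = 60))
  ))
  prof <- pair_selection_profile(pool_pair(fr, "anc", "der", m = 0.1))
  expect_true(any(prof$per_locus$capped_ancestral))
  expect_equal(prof$summary$max, c(1, 1))
  expect_lte(max(prof$per_locus$s_in_ancestral), 1)
})

test_that("asymmetry F test detects a large variance ratio", {
  set.seed(77)
  hits <- 0
  reps <- 100
  for (r in seq_len(reps)) {
    s_anc <- pmax(0.01, rnorm(19, 0.15, 0.03))
    s_der <- pmax(0.01, rnorm(19, 0.15, 0.03 * sqrt(8)))
    prof <- structure(
      list(per_locus = tibble::tibble(s_in_ancestral = s_anc,
                                      s_in_derived = s_der)),
      class = "selection_profile"
    )
    at <- asymmetry_tests(prof)
    if (at$p_value[at$test == "variance_f"] < 0.01) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("paired t type-I error is nominal under exchangeable directions", {
  set.seed(78)
  reps <- 1000
  rejections <- 0
  for (r in seq_len(reps)) {
    s_anc <- pmax(0.01, rnorm(19, 0.15, 0.05))
    s_der <- pmax(0.01, rnorm(19, 0.15, 0.05))
    prof <- structure(
      list(per_locus = tibble::tibble(s_in_ancestral = s_anc,
                                      s_in_derived = s_der)),
      class = "selection_profile"
    )
    at <- asymmetry_tests(prof)
    if (at$p_value[at$test == "paired_t"] < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / reps, 0.03)
  expect_lte(rejections / reps, 0.07)
})
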