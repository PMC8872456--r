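#' Jost's D_EST for a sympatric population pair
#'
#' Per-locus differentiation based on the effective-number partition of
#' diversity, using the Nei-Chesser bias-corrected within- and total-
#' heterozygosity estimators with the harmonic mean sample size:
#' `D = (n/(n-1)) * (H_T - H_S) / (1 - H_S)` with `n = 2` demes. Chosen over
#' F_ST-family measures because the loci are highly polymorphic within
#' populations. Slightly negative estimates (identical populations plus
#' sampling noise) are clamped to 0 and flagged; the raw value is kept in
#' `dest_raw`. A locus monomorphic across both populations is 0 by
#' convention and flagged.
#'
#' @param freqs Allele-frequency table ([allele_frequencies()]).
#' @param pop_a,pop_b Population ids.
#' @param loci Optional locus subset (default: loci scored in both).
#' @return A tibble of class `dest_tbl`: `locus, n_a, n_b, h_s, h_t,
#'   dest_raw, dest, monomorphic, clamped`.
#' @export
jost_dest <- function(freqs, pop_a, pop_b, loci = NULL) {
  assert_frequencies(freqs)
  loci_a <- unique(freqs$locus[freqs$population == pop_a &
                                 freqs$n_copies > 0])
  loci_b <- unique(freqs$locus[freqs$population == pop_b &
                                 freqs$n_copies > 0])
  loci <- loci %||% intersect(loci_a, loci_b)
  if (length(loci) == 0) abort("No shared scored loci for this pair.")

  rows <- purrr::map(loci, function(loc) {
    x <- freq_vector(freqs, pop_a, loc)
    y <- freq_vector(freqs, pop_b, loc)
    n_a <- copies_at(freqs, pop_a, loc) / 2
    n_b <- copies_at(freqs, pop_b, loc) / 2
    if (n_a == 0 || n_b == 0) {
      abort(sprintf("Population unscored at locus %s.", loc))
    }
    al <- align_freqs(x, y)
    n_harm <- 2 / (1 / n_a + 1 / n_b)
    hs_raw <- 1 - mean(c(sum(al$x^2), sum(al$y^2)))
    hs <- (2 * n_harm / (2 * n_harm - 1)) * hs_raw
    pbar <- (al$x + al$y) / 2
    ht <- (1 - sum(pbar^2)) + hs / (4 * n_harm)
    mono <- length(al$alleles) == 1 ||
      (max(al$x) == 1 && max(al$y) == 1 &&
         names(which.max(al$x)) == names(which.max(al$y)))
    d_raw <- if (mono) 0 else 2 * (ht - hs) / (1 - hs)
    tibble::tibble(
      locus = loc, n_a = n_a, n_b = n_b, h_s = hs, h_t = ht,
      dest_raw = d_raw, dest = max(0, min(1, d_raw)),
      monomorphic = mono, clamped = d_raw < 0 | d_raw > 1
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, pair = c(pop_a, pop_b),
            class = c("dest_tbl", class(out)))
}

#' Welch comparison of two per-locus D_EST distributions
#'
#' Two-sample t-test (Welch by default; set `var_equal = TRUE` for the
#' pooled variant) on per-locus D_EST values of two pairs.
#'
#' @param a,b `dest_tbl` objects (or tibbles with a `dest` column).
#' @param var_equal Pool the variances?
#' @return A one-row tibble `statistic, df, p_value, mean_a, mean_b, method`.
#' @export
dest_distribution_compare <- function(a, b, var_equal = FALSE) {
  da <- a$dest
  db <- b$dest
  if (length(da) < 2 || length(db) < 2) abort("Need >= 2 loci per pair.")
  if (sd(da) == 0 && sd(db) == 0) {
    warn("Zero variance in both distributions; test undefined.")
    return(tibble::tibble(
      statistic = NA_real_, df = NA_real_, p_value = NA_real_,
      mean_a = mean(da), mean_b = mean(db), method = "undefined"
    ))
  }
  tt <- t.test(da, db, var.equal = var_equal)
  tibble::tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, mean_a = mean(da), mean_b = mean(db),
    method = tt$method
  )
}

#' Nei's (1972) standard genetic distance
#'
#' `D = -ln I` with the identity `I` formed from sums over all loci jointly:
#' `I = sum_l sum_k x y / sqrt(sum x^2 * sum y^2)`. Populations sharing no
#' alleles anywhere get `D = Inf` with a warning.
#'
#' @param freqs Allele-frequency table.
#' @param pop_a,pop_b Population ids.
#' @param loci Optional locus subset.
#' @return Non-negative distance (scalar).
#' @export
nei_d <- function(freqs, pop_a, pop_b, loci = NULL) {
  assert_frequencies(freqs)
  loci <- loci %||% intersect(
    unique(freqs$locus[freqs$population == pop_a & freqs$n_copies > 0]),
    unique(freqs$locus[freqs$population == pop_b & freqs$n_copies > 0])
  )
  if (length(loci) == 0) abort("Populations share no scored loci.")
  jxy <- jx <- jy <- 0
  for (loc in loci) {
    x <- freq_vector(freqs, pop_a, loc)
    y <- freq_vector(freqs, pop_b, loc)
    al <- align_freqs(x, y)
    jxy <- jxy + sum(al$x * al$y)
    jx <- jx + sum(al$x^2)
    jy <- jy + sum(al$y^2)
  }
  i_hat <- jxy / sqrt(jx * jy)
  if (i_hat <= 0) {
    warn("No shared alleles at any locus; distance is infinite.")
    return(Inf)
  }
  max(0, -log(min(1, i_hat)))
}

#' Pairwise Nei's D matrix over populations
#'
#' @param freqs Allele-frequency table.
#' @param loci Optional locus subset.
#' @param populations Optional population subset/order.
#' @return Symmetric matrix with zero diagonal.
#' @export
nei_d_matrix <- function(freqs, loci = NULL, populations = NULL) {
  pops <- populations %||% unique(freqs$population)
  dm <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) {
    for (j in seq_len(i - 1L)) {
      d <- nei_d(freqs, pops[i], pops[j], loci = loci)
      dm[i, j] <- dm[j, i] <- d
    }
  }
  dm
}

#' Neighbor-joining population tree
#'
#' Saitou-Nei neighbor joining on a genetic distance matrix. Negative branch
#' lengths (which NJ can produce from non-additive distances) are clamped to
#' zero with the deficit transferred to the adjacent branch so path lengths
#' are approximately preserved.
#'
#' @param dm Symmetric distance matrix with labelled rows/columns.
#' @return An unrooted `phylo` tree (class from the ape package).
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    abort("`dm` must be a square matrix.")
  }
  if (nrow(dm) < 3) abort("Neighbor joining needs >= 3 populations.")
  if (any(is.na(dm)) || any(!is.finite(dm))) {
    abort("`dm` contains NA or non-finite distances.")
  }
  if (max(abs(dm - t(dm))) > 1e-8) abort("`dm` must be symmetric.")
  tree <- ape::nj(dm)
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    child <- tree$edge[e, 2]
    parent <- tree$edge[e, 1]
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    into_parent <- which(tree$edge[, 2] == parent)
    if (length(into_parent) == 1) {
      tree$edge.length[into_parent] <-
        max(0, tree$edge.length[into_parent] + deficit)
    }
  }
  tree
}

#' Bootstrap-over-loci support for a population tree
#'
#' Recomputes Nei's D and the NJ tree on locus sets resampled with
#' replacement and reports, for every internal bipartition of the
#' all-loci tree, the percentage of replicates containing it. Supports are
#' stored as internal node labels of the returned tree (root label empty).
#'
#' @param freqs Allele-frequency table.
#' @param reps Bootstrap replicates (default 10000; < 100 warns).
#' @param seed Integer seed.
#' @param loci Optional locus subset.
#' @param populations Optional population subset.
#' @return A list of class `pop_tree`: `tree` (phylo with `node.label`
#'   percent supports), `support` (tibble `node, support`), `reps`, `seed`.
#' @export
bootstrap_support <- function(freqs, reps = 10000, seed = 1L, loci = NULL,
                              populations = NULL) {
  assert_frequencies(freqs)
  loci <- loci %||% sort(unique(freqs$locus))
  if (length(loci) < 2) abort("Bootstrap over loci needs >= 2 loci.")
  if (reps < 100) warn("Fewer than 100 bootstrap replicates is unreliable.")
  pops <- populations %||% unique(freqs$population)
  n_pop <- length(pops)

  # Per-locus identity components for every ordered pair: joint sums over a
  # locus resample are then just sums over these arrays.
  L <- length(loci)
  jxy <- jx <- array(0, c(n_pop, n_pop, L))
  for (l in seq_len(L)) {
    vecs <- lapply(pops, function(p) freq_vector(freqs, p, loci[l]))
    sq <- vapply(vecs, function(v) sum(v^2), numeric(1))
    for (i in seq_len(n_pop)) {
      jx[i, i, l] <- sq[i]
      for (j in seq_len(i - 1L)) {
        al <- align_freqs(vecs[[i]], vecs[[j]])
        cp <- sum(al$x * al$y)
        jxy[i, j, l] <- jxy[j, i, l] <- cp
      }
    }
  }
  d_from <- function(idx) {
    sxy <- apply(jxy[, , idx, drop = FALSE], c(1, 2), sum)
    sxx <- vapply(seq_len(n_pop), function(i) sum(jx[i, i, idx]), numeric(1))
    i_mat <- sxy / sqrt(outer(sxx, sxx))
    diag(i_mat) <- 1
    dm <- i_mat
    dm[] <- -log(pmin(1, pmax(i_mat, 1e-300)))
    dimnames(dm) <- list(pops, pops)
    dm
  }

  point_tree <- nj_tree(d_from(seq_len(L)))
  set.seed(seed)
  boot_trees <- vector("list", reps)
  for (r in seq_len(reps)) {
    boot_trees[[r]] <- nj_tree(d_from(sample.int(L, L, replace = TRUE)))
  }
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(point_tree, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / reps
  tree <- point_tree
  tree$node.label <- formatC(support, format = "f", digits = 1)
  tree$node.label[1] <- ""   # root of the unrooted representation
  structure(
    list(
      tree = tree,
      support = tibble::tibble(
        node = seq_along(support) + length(tree$tip.label),
        support = support
      ),
      reps = reps, seed = seed
    ),
    class = "pop_tree"
  )
}

#' @export
print.pop_tree <- function(x, ...) {
  cat(sprintf(
    "Neighbor-joining population tree: %d tips, %d bootstrap reps over loci\n",
    length(x$tree$tip.label), x$reps
  ))
  invisible(x)
}

#' Write a population tree with supports to a Newick file
#'
#' @param x A `pop_tree` (or bare `phylo`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(x, path) {
  tree <- if (inherits(x, "pop_tree")) x$tree else x
  ape::write.tree(tree, file = path)
  invisible(path)
}
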