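# Orchestration: one call that takes genotypes + metadata + pair
# definitions through frequencies, F_IS, diversity, differentiation,
# clines, selection profiles and hybrid classification, writing tabular
# reports and a machine-readable manifest.

#' Assemble a pipeline configuration
#'
#' A configuration is an ordinary list; this helper fills defaults and
#' validates the cross-references (every population mentioned by a pair
#' must exist, and each pair's populations must belong to the taxa the pair
#' declares) before any computation runs. Either in-memory tibbles
#' (`genotypes`, `meta`, `pairs`) or CSV paths (`genotypes_csv`,
#' `meta_csv`) may be supplied; a YAML file with the same fields can be
#' loaded via `config_path`.
#'
#' @param genotypes,meta,pairs Tibbles (see [read_genotypes_csv()],
#'   [read_population_meta()]; `pairs` needs `pair, ancestral, derived,
#'   ancestral_taxon, derived_taxon, m`).
#' @param ancestral_taxa Taxon labels considered ancestral for
#'   private-allele and cline reference (default: taxa named in
#'   `pairs$ancestral_taxon`).
#' @param out_dir Output directory for report files.
#' @param seed Master seed; stage seeds derive from it deterministically.
#' @param params Named list of stage parameters overriding the defaults:
#'   `fis_boot`, `tree_boot`, `r_threshold`, `alpha`, `ci_reps`,
#'   `migration_prior`, `convention`, `min_pops`.
#' @param config_path Optional YAML file; fields found there are used as
#'   defaults for any argument not given.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes = NULL, meta = NULL, pairs = NULL,
                            ancestral_taxa = NULL, out_dir = tempfile("run_"),
                            seed = 1L, params = list(),
                            config_path = NULL) {
  if (!is.null(config_path)) {
    y <- yaml::read_yaml(config_path)
    genotypes <- genotypes %||% read_genotypes_csv(y$genotypes_csv)
    meta <- meta %||% read_population_meta(y$meta_csv)
    pairs <- pairs %||% tibble::as_tibble(
      dplyr::bind_rows(lapply(y$pairs, tibble::as_tibble))
    )
    ancestral_taxa <- ancestral_taxa %||% y$ancestral_taxa
    out_dir <- y$out_dir %||% out_dir
    seed <- y$seed %||% seed
    params <- utils::modifyList(y$params %||% list(), params)
  }
  if (is.null(genotypes) || is.null(meta) || is.null(pairs)) {
    abort("`genotypes`, `meta` and `pairs` are all required.")
  }
  assert_genotypes(genotypes)
  defaults <- list(
    fis_boot = 1000, tree_boot = 1000, r_threshold = 0.8, alpha = 0.05,
    ci_reps = 500, migration_prior = 0.01, convention = "compensatory",
    min_pops = 2
  )
  params <- utils::modifyList(defaults, params)

  pops_known <- unique(meta$population)
  missing_pops <- setdiff(
    unique(c(genotypes$population, pairs$ancestral, pairs$derived)),
    pops_known
  )
  if (length(missing_pops) > 0) {
    abort(paste0(
      "Population(s) missing from metadata: ",
      paste(missing_pops, collapse = ", ")
    ))
  }
  taxon_of <- setNames(meta$taxon, meta$population)
  bad_anc <- pairs$pair[taxon_of[pairs$ancestral] != pairs$ancestral_taxon]
  bad_der <- pairs$pair[taxon_of[pairs$derived] != pairs$derived_taxon]
  if (length(c(bad_anc, bad_der)) > 0) {
    abort(paste0(
      "Pair(s) whose populations do not match the declared taxa: ",
      paste(unique(c(bad_anc, bad_der)), collapse = ", ")
    ))
  }
  structure(
    list(
      genotypes = genotypes, meta = meta, pairs = pairs,
      ancestral_taxa = ancestral_taxa %||%
        unique(pairs$ancestral_taxon),
      out_dir = out_dir, seed = as.integer(seed), params = params
    ),
    class = "pipeline_config"
  )
}

write_stage <- function(tbl, dir, name) {
  path <- file.path(dir, name)
  readr::write_csv(tbl, path)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured dataset and writes the report
#' bundle to `config$out_dir`: allele-frequency table, per-population F_IS,
#' allelic richness with the across-taxa ANOVA, private-allele reports per
#' derived taxon, per-pair Jost's D_EST tables, the NJ population tree with
#' bootstrap-over-loci supports (Newick), the clinal scan and derived-taxon
#' classifications, per-pair selection profiles with asymmetry tests, hybrid
#' posteriors per pair, and a JSON manifest (package version, seeds,
#' parameters, file list) sufficient to reproduce every table. All
#' randomness derives from `config$seed`, so a rerun is byte-identical.
#'
#' A failing stage aborts with the stage name in the error message.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list with every stage's in-memory result and
#'   the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  meta <- config$meta
  results <- list()
  files <- character()
  stage <- function(name, expr) {
    inform(paste0("[divflow] stage: ", name))
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  results$freqs <- stage("allele_frequencies", {
    allele_frequencies(config$genotypes)
  })
  files["freqs"] <- write_stage(results$freqs, config$out_dir,
                                "allele_frequencies.csv")

  results$fis <- stage("f_is", {
    purrr::map(unique(meta$population), function(pop) {
      est <- tryCatch(
        f_is(config$genotypes, pop, nboot = p$fis_boot,
             seed = child_seed(config$seed, paste0("fis_", pop))),
        error = function(e) NULL
      )
      if (is.null(est)) NULL else glance(est)
    }) |> dplyr::bind_rows()
  })
  files["fis"] <- write_stage(results$fis, config$out_dir, "fis.csv")

  results$richness <- stage("allelic_richness", {
    allelic_richness(results$freqs)
  })
  files["richness"] <- write_stage(results$richness, config$out_dir,
                                   "richness.csv")

  results$richness_anova <- stage("compare_richness", {
    groups <- tibble::tibble(population = meta$population,
                             group = meta$taxon)
    tryCatch(compare_richness(results$richness, groups),
             error = function(e) NULL)
  })

  results$private <- stage("private_alleles", {
    derived <- setdiff(unique(meta$taxon), config$ancestral_taxa)
    purrr::map(derived, function(tx) {
      n_pops <- sum(meta$taxon == tx)
      rep <- private_alleles(
        results$freqs, meta, tx, config$ancestral_taxa,
        min_pops = min(p$min_pops, n_pops)
      )
      dplyr::mutate(tibble::as_tibble(rep), taxon = tx, .before = 1)
    }) |> dplyr::bind_rows()
  })
  files["private"] <- write_stage(results$private, config$out_dir,
                                  "private_alleles.csv")

  results$dest <- stage("jost_dest", {
    purrr::pmap(config$pairs, function(pair, ancestral, derived, ...) {
      d <- jost_dest(results$freqs, ancestral, derived)
      dplyr::mutate(tibble::as_tibble(d), pair = pair, .before = 1)
    }) |> dplyr::bind_rows()
  })
  files["dest"] <- write_stage(results$dest, config$out_dir,
                               "dest_per_locus.csv")

  results$tree <- stage("bootstrap_tree", {
    bootstrap_support(results$freqs, reps = p$tree_boot,
                      seed = child_seed(config$seed, "tree"))
  })
  files["tree"] <- write_tree_newick(
    results$tree, file.path(config$out_dir, "nj_tree.nwk")
  )

  results$clinal <- stage("clinal_scan", {
    anc_pops <- meta$population[meta$taxon %in% config$ancestral_taxa[1]]
    detect_clinal_loci(results$freqs, meta, anc_pops,
                       r_threshold = p$r_threshold, alpha = p$alpha)
  })
  files["clinal"] <- write_stage(tibble::as_tibble(results$clinal),
                                 config$out_dir, "clinal_scan.csv")

  results$mosaic <- stage("project_and_classify", {
    derived <- setdiff(unique(meta$taxon), config$ancestral_taxa)
    if (any(results$clinal$clinal)) {
      project_and_classify(
        results$clinal, results$freqs, meta, derived,
        ci_reps = p$ci_reps, seed = child_seed(config$seed, "mosaic")
      )
    } else {
      tibble::tibble()
    }
  })
  files["mosaic"] <- write_stage(results$mosaic, config$out_dir,
                                 "clinal_classification.csv")

  results$selection <- stage("selection_profiles", {
    usable <- config$pairs[!is.na(config$pairs$m), , drop = FALSE]
    purrr::pmap(usable, function(pair, ancestral, derived, m, ...) {
      pooled <- pool_pair(results$freqs, ancestral, derived, m = m,
                          pair_id = pair)
      prof <- pair_selection_profile(pooled, convention = p$convention)
      list(profile = prof, tests = asymmetry_tests(prof))
    })
  })
  files["selection"] <- write_stage(
    purrr::map(results$selection, ~ tidy(.x$profile)) |> dplyr::bind_rows(),
    config$out_dir, "selection_profiles.csv"
  )
  files["selection_summary"] <- write_stage(
    purrr::map(results$selection, ~ glance(.x$profile)) |>
      dplyr::bind_rows(),
    config$out_dir, "selection_summary.csv"
  )
  files["asymmetry"] <- write_stage(
    purrr::map2(
      results$selection,
      purrr::map_chr(results$selection, ~ .x$profile$pair_id),
      ~ dplyr::mutate(.x$tests, pair = .y, .before = 1)
    ) |> dplyr::bind_rows(),
    config$out_dir, "asymmetry_tests.csv"
  )

  results$hybrids <- stage("hybrid_classification", {
    purrr::pmap(config$pairs, function(pair, ancestral, derived, ...) {
      post <- tryCatch(
        withCallingHandlers(
          classify_individuals(config$genotypes, ancestral, derived,
                               migration_prior = p$migration_prior),
          warning = function(w) {
            inform(paste0("[divflow] pair ", pair, ": ",
                          conditionMessage(w)))
            rlang::cnd_muffle(w)
          }
        ),
        error = function(e) NULL
      )
      if (is.null(post)) NULL else dplyr::mutate(post, pair = pair,
                                                 .before = 1)
    }) |> dplyr::bind_rows()
  })
  files["hybrids"] <- write_stage(results$hybrids, config$out_dir,
                                  "hybrid_posteriors.csv")

  manifest <- list(
    package = "divflow",
    version = as.character(utils::packageVersion("divflow")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    params = p,
    populations = nrow(meta),
    loci = dplyr::n_distinct(config$genotypes$locus),
    pairs = config$pairs$pair,
    files = as.list(setNames(basename(files), names(files)))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
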