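#' Read a GENEPOP genotype file
#'
#' Parses the classic GENEPOP text format (2- or 3-digit allele codes) into a
#' long-format tibble of diploid microsatellite calls. Allele codes of
#' `"00"`/`"000"` mark missing data; a call containing a zero code on either
#' side is treated as wholly missing, following GENEPOP convention.
#'
#' Population labels are not part of the GENEPOP format proper. If every
#' individual label has the form `"<population>:<individual>"` (the convention
#' used by [write_genepop()]) the prefix is used as the population id;
#' otherwise populations are labelled `pop_1`, `pop_2`, ... in file order.
#'
#' @param path Path to a GENEPOP file.
#' @param allele_map Optional data frame with columns `locus`, `code`, `bp`
#'   mapping in-file allele codes to fragment lengths in base pairs. When
#'   supplied, allele labels in the result are the mapped `bp` values; codes
#'   absent from the map raise an error. Without a map, codes are used as
#'   allele labels directly.
#'
#' @return A tibble with columns `individual`, `population`, `locus`,
#'   `allele_1`, `allele_2` (integer allele labels in bp, `NA` = missing),
#'   one row per individual x locus. Populations appear in file order.
#' @export
read_genepop <- function(path, allele_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) abort("GENEPOP file too short: no loci/populations.")
  lines <- sub("\r$", "", lines)

  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3) {
    abort("Malformed GENEPOP header: no 'Pop' line after the locus list.")
  }
  locus_lines <- lines[2:(first_pop - 1)]
  loci <- unlist(strsplit(locus_lines, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0) abort("Malformed GENEPOP header: no locus names.")

  pop_breaks <- which(is_pop)
  records <- list()
  pop_index <- 0L
  width <- NA_integer_
  for (i in seq(first_pop, length(lines))) {
    line <- lines[i]
    if (is_pop[i]) {
      pop_index <- pop_index + 1L
      next
    }
    if (!nzchar(trimws(line))) next
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) != 2) {
      abort(sprintf("Line %d: expected '<id> , <genotypes>'.", i))
    }
    id <- trimws(parts[1])
    tokens <- strsplit(trimws(parts[2]), "[ \t]+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) != length(loci)) {
      abort(sprintf(
        "Line %d: %d genotype fields for %d loci.", i, length(tokens),
        length(loci)
      ))
    }
    widths <- unique(nchar(tokens))
    if (length(widths) != 1 || !(widths %in% c(4L, 6L))) {
      abort(sprintf(
        "Line %d: allele codes must be uniformly 2- or 3-digit.", i
      ))
    }
    if (is.na(width)) width <- widths / 2L
    if (widths / 2L != width) {
      abort(sprintf("Line %d: mixed allele-code widths in file.", i))
    }
    a1 <- as.integer(substr(tokens, 1, width))
    a2 <- as.integer(substr(tokens, width + 1, 2 * width))
    miss <- a1 == 0L | a2 == 0L
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
    records[[length(records) + 1]] <- tibble::tibble(
      individual = id, pop_index = pop_index, locus = loci,
      allele_1 = a1, allele_2 = a2
    )
  }
  if (length(records) == 0) abort("GENEPOP file contains no individuals.")
  geno <- dplyr::bind_rows(records)

  ids <- unique(geno$individual)
  if (all(grepl(":", ids))) {
    geno$population <- sub(":.*$", "", geno$individual)
    geno$individual <- sub("^[^:]*:", "", geno$individual)
  } else {
    geno$population <- paste0("pop_", geno$pop_index)
  }
  geno$pop_index <- NULL

  if (!is.null(allele_map)) {
    key_file <- paste(geno$locus, geno$allele_1)
    key_map <- paste(allele_map$locus, allele_map$code)
    for (col in c("allele_1", "allele_2")) {
      idx <- match(paste(geno$locus, geno[[col]]), key_map)
      bad <- !is.na(geno[[col]]) & is.na(idx)
      if (any(bad)) {
        abort(paste0(
          "Allele codes without a bp mapping at locus ",
          paste(unique(geno$locus[bad]), collapse = ", "), "."
        ))
      }
      geno[[col]] <- ifelse(is.na(geno[[col]]), NA_integer_,
                            as.integer(allele_map$bp[idx]))
    }
  }
  out <- geno[, GENO_COLS]
  assert_genotypes(out)
  out
}

#' Write genotypes to a GENEPOP file
#'
#' Inverse of [read_genepop()]. Individual labels are written as
#' `"<population>:<individual>"` so that population identity survives a
#' round trip. Missing calls are written as zero codes.
#'
#' @param geno Long-format genotype tibble (see [read_genepop()]).
#' @param path Output file path.
#' @param digits Allele code width, 2 or 3. All allele labels must fit;
#'   use an explicit code map upstream for fragment lengths above the limit.
#' @param title First (comment) line of the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(geno, path, digits = 3,
                          title = "divflow genotype export") {
  assert_genotypes(geno)
  if (!digits %in% c(2, 3)) abort("`digits` must be 2 or 3.")
  limit <- 10^digits - 1
  labels <- c(geno$allele_1, geno$allele_2)
  if (any(labels > limit, na.rm = TRUE)) {
    abort(sprintf(
      "Allele labels exceed the %d-digit GENEPOP limit; map codes first.",
      digits
    ))
  }
  loci <- unique(geno$locus)
  pops <- unique(geno$population)
  fmt <- function(x) {
    x[is.na(x)] <- 0L
    sprintf(paste0("%0", digits, "d"), x)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(loci, con)
  for (pop in pops) {
    writeLines("Pop", con)
    sub_pop <- geno[geno$population == pop, , drop = FALSE]
    for (id in unique(sub_pop$individual)) {
      rows <- sub_pop[sub_pop$individual == id, , drop = FALSE]
      rows <- rows[match(loci, rows$locus), , drop = FALSE]
      tokens <- paste0(fmt(rows$allele_1), fmt(rows$allele_2))
      writeLines(paste0(pop, ":", id, " , ", paste(tokens, collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read/write long-format genotype and metadata CSV files
#'
#' `read_genotypes_csv()` expects columns `individual`, `population`, `locus`,
#' `allele_1`, `allele_2`. `read_population_meta()` expects at least
#' `population` and `taxon`, typically with `host`, `site`, `latitude`,
#' `longitude`, `year` and `n` as in a field-survey design table.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_genotypes_csv <- function(path) {
  geno <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols())
  geno$allele_1 <- as.integer(geno$allele_1)
  geno$allele_2 <- as.integer(geno$allele_2)
  assert_genotypes(geno)
  tibble::as_tibble(geno[, GENO_COLS])
}

#' @rdname read_genotypes_csv
#' @export
read_population_meta <- function(path) {
  meta <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols())
  if (!all(c("population", "taxon") %in% names(meta))) {
    abort("Metadata must contain `population` and `taxon` columns.")
  }
  if ("latitude" %in% names(meta) &&
      any(meta$latitude < 0 | meta$latitude > 90, na.rm = TRUE)) {
    abort("Latitudes must lie in [0, 90] degrees north.")
  }
  tibble::as_tibble(meta)
}
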