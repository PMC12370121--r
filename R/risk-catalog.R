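#' Curated risk-variant catalogs
#'
#' A curated catalog is a tibble of risk variants (one row per variant) that
#' carries a filter log recording every curation rule applied to it and how
#' many rows each rule removed. Columns:
#'
#' * `rsid` — dbSNP-style variant identifier.
#' * `chromosome` — chromosome label (character, so "X" and compound labels
#'   survive).
#' * `gene` — gene symbol or compound locus label (e.g. `"GTF2IRD1-NCF1"`);
#'   compound labels are kept verbatim as single entries.
#' * `odds_ratio` — association effect size (unitless, positive); `NA` when
#'   the source study did not report one.
#' * `pmids` — list-column of deduplicated PubMed-ID strings.
#' * `population` — one of `"Asian"`, `"European"`, `"other"`, `"unknown"`.
#' * `sample_size` — GWAS sample size; `NA` when unreported.
#'
#' @name curated_catalog
NULL

CATALOG_COLUMNS <- c("rsid", "chromosome", "gene", "odds_ratio", "pmids",
                     "population", "sample_size")
POPULATION_LEVELS <- c("Asian", "European", "other", "unknown")

new_curated_catalog <- function(variants, filter_log = NULL) {
  if (is.null(filter_log)) {
    filter_log <- tibble::tibble(rule = character(), n_removed = integer())
  }
  variants <- tibble::as_tibble(variants)
  structure(variants,
            filter_log = filter_log,
            class = c("curated_catalog", class(tibble::tibble())))
}

#' Retrieve the filter log of a curated catalog
#'
#' @param catalog A [curated_catalog].
#' @return A tibble with columns `rule` and `n_removed`, one row per curation
#'   rule applied so far, in application order.
#' @export
filter_log <- function(catalog) {
  log <- attr(catalog, "filter_log")
  if (is.null(log)) tibble::tibble(rule = character(), n_removed = integer())
  else log
}

append_filter_log <- function(catalog, rule, n_removed) {
  log <- dplyr::bind_rows(
    filter_log(catalog),
    tibble::tibble(rule = rule, n_removed = as.integer(n_removed))
  )
  new_curated_catalog(catalog, log)
}

#' Strip a catalog to a plain tibble
#'
#' @param x A [curated_catalog].
#' @param ... Unused.
#' @return The variant table without the catalog class or filter log.
#' @exportS3Method tibble::as_tibble
as_tibble.curated_catalog <- function(x, ...) {
  attr(x, "filter_log") <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' @export
print.curated_catalog <- function(x, ...) {
  cat("<curated_catalog> ", nrow(x), " variants, ",
      length(unique(x$gene)), " genes\n", sep = "")
  log <- filter_log(x)
  if (nrow(log) > 0) {
    cat("filter log:\n")
    for (i in seq_len(nrow(log))) {
      cat("  - ", log$rule[i], ": removed ", log$n_removed[i], "\n", sep = "")
    }
  }
  NextMethod()
}

normalize_population <- function(x) {
  x <- as.character(x)
  x[is.na(x) | !nzchar(x)] <- "unknown"
  x[!x %in% POPULATION_LEVELS] <- "other"
  x
}

split_pmids <- function(x) {
  purrr::map(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) return(character())
    unique(stringr::str_trim(stringr::str_split_1(s, "[,;]")))
  })
}

#' Read a risk-variant table
#'
#' Reads a tab-separated risk-variant catalog (the dialect used by
#' literature-curated GWAS tables: one row per reported variant, with the
#' variant rsID, chromosome, mapped gene symbol, odds ratio and supporting
#' PubMed IDs). Column names in the file can differ from the canonical ones;
#' supply `col_map` to translate.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param col_map Optional named character vector (or path to a YAML
#'   key-value file) mapping canonical column names (`rsid`, `chromosome`,
#'   `gene`, `odds_ratio`, `pmids`, `population`, `sample_size`) to the names
#'   used in the file.
#' @return A [curated_catalog] with one row per data row of the file.
#'   Missing odds ratios and sample sizes are stored as `NA`, never zero.
#' @examples
#' path <- system.file("extdata", "table1_risk_variants.tsv",
#'                     package = "ratarget")
#' catalog <- read_variant_table(path)
#' nrow(catalog)
#' @export
read_variant_table <- function(path, col_map = NULL) {
  if (!file.exists(path)) {
    stop("variant table not found: ", path, call. = FALSE)
  }
  if (is.character(col_map) && length(col_map) == 1 && file.exists(col_map)) {
    col_map <- unlist(yaml::read_yaml(col_map))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[canon]]] <- canon
      }
    }
  }
  mandatory <- c("rsid", "gene", "odds_ratio")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop("variant table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  or_chr <- stringr::str_trim(raw$odds_ratio)
  or_chr[!is.na(or_chr) & !nzchar(or_chr)] <- NA_character_
  or_num <- suppressWarnings(as.numeric(or_chr))
  bad <- which(!is.na(or_chr) & is.na(or_num))
  if (length(bad) > 0) {
    stop("unparseable odds ratio ", sQuote(or_chr[bad[1]]),
         " at line ", bad[1] + 1L, " of ", path, call. = FALSE)
  }
  n <- nrow(raw)
  size_num <- if ("sample_size" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$sample_size))
  } else {
    rep(NA_real_, n)
  }
  variants <- tibble::tibble(
    rsid = as.character(raw$rsid),
    chromosome = if ("chromosome" %in% names(raw)) {
      as.character(raw$chromosome)
    } else {
      rep(NA_character_, n)
    },
    gene = as.character(raw$gene),
    odds_ratio = or_num,
    pmids = split_pmids(if ("pmids" %in% names(raw)) raw$pmids else rep(NA, n)),
    population = normalize_population(
      if ("population" %in% names(raw)) raw$population else rep(NA, n)),
    sample_size = size_num
  )
  new_curated_catalog(variants)
}

#' Write a risk-variant table
#'
#' Writes the catalog back in the same tab-separated dialect that
#' [read_variant_table()] consumes (PubMed IDs collapsed with `", "`), plus a
#' JSON sidecar `<path>.filterlog.json` recording the filter log.
#'
#' @param catalog A [curated_catalog].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(catalog, path) {
  out <- tibble::as_tibble(catalog)
  out$pmids <- purrr::map_chr(out$pmids, paste, collapse = ", ")
  readr::write_tsv(out, path, progress = FALSE)
  jsonlite::write_json(filter_log(catalog),
                       paste0(path, ".filterlog.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Deduplicate a risk-variant catalog by rsID
#'
#' Literature-mined catalogs report the same variant from several source
#' articles. Records sharing an rsID are merged into one: PubMed-ID sets are
#' unioned, all other fields keep their first-seen values.
#'
#' @param catalog A [curated_catalog].
#' @return A [curated_catalog] with unique rsIDs; the filter log gains a
#'   `"deduplicate_rsid"` entry with the number of rows removed.
#' @export
deduplicate_variants <- function(catalog) {
  n_before <- nrow(catalog)
  tbl <- tibble::as_tibble(catalog)
  if (n_before == 0) {
    return(append_filter_log(catalog, "deduplicate_rsid", 0L))
  }
  merged <- tbl |>
    dplyr::group_by(.data$rsid) |>
    dplyr::summarise(
      dplyr::across(-"pmids", dplyr::first),
      pmids = list(unique(unlist(.data$pmids))),
      .groups = "drop"
    )
  # restore first-appearance order of rsids
  merged <- merged[match(unique(tbl$rsid), merged$rsid), CATALOG_COLUMNS]
  out <- new_curated_catalog(merged, filter_log(catalog))
  append_filter_log(out, "deduplicate_rsid", n_before - nrow(merged))
}

#' Apply the catalog quality-control filters
#'
#' Retains variants from adequately powered GWAS in the admissible
#' populations with an odds ratio strictly above the threshold. The
#' numeric odds-ratio rule is applied literally (strict `> min_or`), even
#' though odds ratios below 1 are protective; the threshold is a parameter
#' so other policies can be expressed. Rows whose sample size, population
#' or odds ratio is unrecorded are retained: published top-variant tables
#' typically omit these columns, and the curation is designed so such
#' tables survive their own filters.
#'
#' @param catalog A [curated_catalog].
#' @param min_sample Minimum GWAS sample size (default 500).
#' @param min_or Odds-ratio threshold; retained rows need `odds_ratio`
#'   strictly greater than this (default 0.7).
#' @param allowed_populations Populations to keep (default Asian and
#'   European); rows tagged `"unknown"` are always kept.
#' @return A filtered [curated_catalog]; the filter log gains one entry per
#'   rule (`"min_sample_size"`, `"min_odds_ratio"`, `"population"`).
#' @export
filter_variants <- function(catalog, min_sample = 500, min_or = 0.7,
                            allowed_populations = c("Asian", "European")) {
  stopifnot(min_sample > 0, min_or > 0)
  tbl <- tibble::as_tibble(catalog)
  out <- new_curated_catalog(tbl, filter_log(catalog))

  keep <- is.na(tbl$sample_size) | tbl$sample_size >= min_sample
  out <- append_filter_log(new_curated_catalog(tbl[keep, ], filter_log(out)),
                           "min_sample_size", sum(!keep))
  tbl <- tibble::as_tibble(out)

  keep <- is.na(tbl$odds_ratio) | tbl$odds_ratio > min_or
  out <- append_filter_log(new_curated_catalog(tbl[keep, ], filter_log(out)),
                           "min_odds_ratio", sum(!keep))
  tbl <- tibble::as_tibble(out)

  keep <- tbl$population %in% c(allowed_populations, "unknown")
  out <- append_filter_log(new_curated_catalog(tbl[keep, ], filter_log(out)),
                           "population", sum(!keep))
  out
}

#' Extract the risk-gene set of a catalog
#'
#' @param catalog A [curated_catalog].
#' @return Character vector of unique gene labels in first-appearance order.
#'   Compound locus labels (e.g. `"AGR3-AHR"`) are kept verbatim.
#' @export
genes_from_variants <- function(catalog) {
  unique(tibble::as_tibble(catalog)$gene)
}
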