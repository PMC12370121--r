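#' Annotation maps for over-representation analysis
#'
#' An annotation map pairs a set of functional terms (each a gene set) with
#' the background universe the query list is drawn from. The background must
#' be supplied explicitly — enrichment p-values are only meaningful relative
#' to a stated universe.
#'
#' @param term_to_genes Named list of character vectors (term ID -> genes),
#'   or a two-column data frame `(term, gene)`.
#' @param background Character vector: the gene universe. Every annotated
#'   gene must be contained in it.
#' @return An `annotation_map` object.
#' @examples
#' ann <- annotation_map(list(T1 = c("A", "B"), T2 = c("B", "C")),
#'                       background = c("A", "B", "C", "D"))
#' @export
annotation_map <- function(term_to_genes, background) {
  if (is.data.frame(term_to_genes)) {
    stopifnot(ncol(term_to_genes) >= 2)
    term_to_genes <- split(as.character(term_to_genes[[2]]),
                           as.character(term_to_genes[[1]]))
  }
  term_to_genes <- purrr::map(term_to_genes, ~ unique(as.character(.x)))
  background <- unique(as.character(background))
  if (any(lengths(term_to_genes) == 0)) {
    stop("annotation terms must be nonempty", call. = FALSE)
  }
  stray <- setdiff(unique(unlist(term_to_genes)), background)
  if (length(stray) > 0) {
    stop("annotated gene(s) missing from background: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(term_to_genes = term_to_genes, background = background),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("<annotation_map> ", length(x$term_to_genes), " terms over ",
      length(x$background), " background genes\n", sep = "")
  invisible(x)
}

#' Read an annotation map from files
#'
#' @param term_path Two-column TSV (term, gene), no header required; a
#'   header line is detected and skipped if its first field is `term`.
#' @param background_path Text file with one gene symbol per line.
#' @return An [annotation_map()].
#' @export
read_annotation_map <- function(term_path, background_path) {
  tbl <- readr::read_tsv(term_path, col_names = c("term", "gene"),
                         col_types = "cc", progress = FALSE)
  if (nrow(tbl) > 0 && tolower(tbl$term[1]) == "term") tbl <- tbl[-1, ]
  background <- readr::read_lines(background_path)
  background <- background[nzchar(stringr::str_trim(background))]
  annotation_map(tbl, background)
}

#' Fold enrichment of a gene-set overlap
#'
#' The ratio of a term's frequency in the query list to its frequency in
#' the background: `(k/n) / (K/N)` where `k` of the `n` query genes and `K`
#' of the `N` background genes carry the term.
#'
#' @param k Query genes annotated to the term.
#' @param n Query-list size.
#' @param K Background genes annotated to the term.
#' @param N Background size.
#' @return Fold enrichment (vectorized); greater than 1 when the term is
#'   over-represented in the query.
#' @examples
#' fold_enrichment(5, 10, 20, 100) # 2.5
#' @export
fold_enrichment <- function(k, n, K, N) {
  check_contingency(k, n, K, N)
  (k / n) / (K / N)
}

check_contingency <- function(k, n, K, N) {
  if (any(n <= 0) || any(K <= 0) || any(N <= 0)) {
    stop("n, K and N must be positive", call. = FALSE)
  }
  if (any(K > N) || any(n > N)) {
    stop("term size K and query size n cannot exceed background size N",
         call. = FALSE)
  }
  if (any(k > n) || any(k > K) || any(k < 0)) {
    stop("impossible overlap: require 0 <= k <= min(n, K)", call. = FALSE)
  }
  invisible(TRUE)
}

#' One-sided Fisher (hypergeometric) over-representation p-value
#'
#' Right-tail probability `P(X >= k)` where `X` is the overlap of a random
#' draw of `n` genes from a background of `N` containing `K` term genes.
#' This is the one-sided Fisher's exact test for over-representation;
#' depletion is never tested.
#'
#' @inheritParams fold_enrichment
#' @return P-value in `[0, 1]` (vectorized).
#' @export
fisher_pvalue <- function(k, n, K, N) {
  check_contingency(k, n, K, N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values, order-aligned with the input and
#' clipped to `[0, 1]`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Tests every annotation term that overlaps the query list (k >= 1) with
#' the one-sided Fisher test, adjusts over all tested terms with
#' Benjamini-Hochberg, and reports fold enrichment. Query genes outside the
#' background are dropped with a warning.
#'
#' @param query Character vector of gene symbols.
#' @param annotation An [annotation_map()].
#' @param fdr_cutoff Terms with adjusted p strictly below this are flagged
#'   significant (default 0.05).
#' @return A tibble sorted by ascending p-value with columns `term`, `k`,
#'   `n`, `K`, `N`, `fold`, `p_value`, `q_value`, `significant`.
#' @examples
#' ann <- annotation_map(list(T1 = c("A", "B"), T2 = c("C", "D")),
#'                       background = LETTERS[1:10])
#' enrich(c("A", "B"), ann)
#' @export
enrich <- function(query, annotation, fdr_cutoff = 0.05) {
  stopifnot(inherits(annotation, "annotation_map"))
  query <- unique(as.character(query))
  dropped <- setdiff(query, annotation$background)
  if (length(dropped) > 0) {
    warning(length(dropped), " query gene(s) outside the background dropped",
            call. = FALSE)
  }
  query <- intersect(query, annotation$background)
  empty <- tibble::tibble(
    term = character(), k = integer(), n = integer(), K = integer(),
    N = integer(), fold = double(), p_value = double(), q_value = double(),
    significant = logical()
  )
  if (length(query) == 0) {
    warning("empty query after intersecting with background", call. = FALSE)
    return(empty)
  }
  n <- length(query)
  N <- length(annotation$background)
  res <- purrr::imap(annotation$term_to_genes, function(genes, term) {
    tibble::tibble(term = term,
                   k = length(intersect(query, genes)),
                   K = length(genes))
  }) |>
    purrr::list_rbind() |>
    dplyr::filter(.data$k >= 1)
  if (nrow(res) == 0) return(empty)
  res |>
    dplyr::mutate(
      n = n, N = N,
      fold = fold_enrichment(.data$k, n, .data$K, N),
      p_value = fisher_pvalue(.data$k, n, .data$K, N),
      q_value = bh_adjust(.data$p_value),
      significant = .data$q_value < fdr_cutoff
    ) |>
    dplyr::arrange(.data$p_value, .data$term) |>
    dplyr::select("term", "k", "n", "K", "N", "fold", "p_value", "q_value",
                  "significant")
}
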