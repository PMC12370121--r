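#' Min-max scaling to the unit interval
#'
#' `(v - min) / (max - min)` over the supplied values. When all values are
#' equal the scaled values are all 0 (rather than NaN), a deliberate
#' degenerate-input policy that keeps downstream weighted sums defined.
#'
#' @param values Numeric vector with at least one finite value.
#' @return Values rescaled into `[0, 1]`, order-aligned with the input.
#' @examples
#' min_max(c(2, 4, 6)) # 0, 0.5, 1
#' @export
min_max <- function(values) {
  if (length(values) == 0) stop("min_max of empty input", call. = FALSE)
  if (any(!is.finite(values))) {
    stop("min_max requires finite values", call. = FALSE)
  }
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Scoring weights for target inference
#'
#' Bundles the weights of the integrated inference score. `w_d`, `w_m`,
#' `w_b`, `w_k` weight the disease-mapping, molecular-interaction,
#' biomedical-knowledge and knowledge-graph components and must sum to 1;
#' the defaults (0.30 / 0.30 / 0.20 / 0.20) balance disease associations
#' and molecular interactions against the two knowledge layers. `alpha`,
#' `beta`, `gamma` are the scaling factors mixing degree, betweenness and
#' closeness centrality inside the molecular-interaction component; they
#' also sum to 1 and default to equal thirds (a symmetric prior over the
#' three centrality notions).
#'
#' @param w_d,w_m,w_b,w_k Component weights, nonnegative, summing to 1.
#' @param alpha,beta,gamma Centrality scaling factors, nonnegative,
#'   summing to 1.
#' @return A `scoring_weights` object.
#' @export
scoring_weights <- function(w_d = 0.3, w_m = 0.3, w_b = 0.2, w_k = 0.2,
                            alpha = 1 / 3, beta = 1 / 3, gamma = 1 / 3) {
  w <- c(w_d = w_d, w_m = w_m, w_b = w_b, w_k = w_k)
  s <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(w < 0) || any(s < 0)) {
    stop("weights must be nonnegative", call. = FALSE)
  }
  if (abs(sum(w) - 1) > 1e-9) {
    stop("component weights w_d + w_m + w_b + w_k must sum to 1",
         call. = FALSE)
  }
  if (abs(sum(s) - 1) > 1e-9) {
    stop("centrality scaling factors alpha + beta + gamma must sum to 1",
         call. = FALSE)
  }
  structure(as.list(c(w, s)), class = "scoring_weights")
}

#' @export
print.scoring_weights <- function(x, ...) {
  cat("<scoring_weights> components:",
      sprintf("w_d=%.2f w_m=%.2f w_b=%.2f w_k=%.2f", x$w_d, x$w_m, x$w_b,
              x$w_k),
      "| centralities:",
      sprintf("alpha=%.3f beta=%.3f gamma=%.3f", x$alpha, x$beta, x$gamma),
      "\n")
  invisible(x)
}

#' Disease-mapping score from literature evidence
#'
#' The fraction of curated studies that report each protein's association
#' with the disease: `study_count / catalog_total`. Because this is already
#' a ratio in `[0, 1]` it is not re-normalized by default, so a protein
#' reported by every study scores exactly 1; set `renormalize = TRUE` to
#' min-max it across proteins instead.
#'
#' @param evidence Tibble with columns `protein`, `study_count` and
#'   `catalog_total` (the latter identical across rows and positive: the
#'   total number of studies in the curated catalog).
#' @param renormalize Min-max the ratios across proteins (default `FALSE`).
#' @return Tibble with columns `protein`, `s_d`.
#' @export
compute_sd <- function(evidence, renormalize = FALSE) {
  evidence <- tibble::as_tibble(evidence)
  total <- unique(evidence$catalog_total)
  if (length(total) != 1 || total <= 0) {
    stop("catalog_total must be a single positive value across records",
         call. = FALSE)
  }
  if (any(evidence$study_count < 0 | evidence$study_count > total)) {
    stop("study_count must lie in [0, catalog_total]", call. = FALSE)
  }
  s_d <- evidence$study_count / total
  if (renormalize) s_d <- min_max(s_d)
  tibble::tibble(protein = evidence$protein, s_d = s_d)
}

#' Molecular-interaction score from network centralities
#'
#' Mixes degree, betweenness and closeness centrality with the scaling
#' factors `alpha`, `beta`, `gamma`, then min-max-normalizes the mixture
#' across proteins.
#'
#' @param cents Centrality tibble from [centralities()] (columns `protein`,
#'   `c_d`, `c_b`, `c_c`).
#' @param weights A [scoring_weights()] object.
#' @return Tibble with columns `protein`, `s_m`.
#' @export
compute_sm <- function(cents, weights = scoring_weights()) {
  cents <- tibble::as_tibble(cents)
  raw <- weights$alpha * cents$c_d + weights$beta * cents$c_b +
    weights$gamma * cents$c_c
  tibble::tibble(protein = cents$protein, s_m = min_max(raw))
}

#' Biomedical-knowledge score from expression
#'
#' Min-max-normalizes per-protein expression in disease-relevant samples.
#' If a protein appears in several expression contexts its values are
#' averaged before scaling.
#'
#' @param expr Tibble with columns `protein`, `expression` and optionally
#'   `context`.
#' @return Tibble with columns `protein`, `s_b`.
#' @export
compute_sb <- function(expr) {
  expr <- tibble::as_tibble(expr)
  if (nrow(expr) == 0) stop("no expression records", call. = FALSE)
  agg <- expr |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(expression = mean(.data$expression), .groups = "drop")
  tibble::tibble(protein = agg$protein, s_b = min_max(agg$expression))
}

#' Knowledge-graph score from raw evidence sums
#'
#' Min-max-normalizes the raw knowledge-graph evidence (the weighted sums
#' from [raw_kg_score()]) across proteins.
#'
#' @param raw_scores Tibble with columns `protein`, `raw_score`.
#' @return Tibble with columns `protein`, `s_k`.
#' @export
compute_sk <- function(raw_scores) {
  raw_scores <- tibble::as_tibble(raw_scores)
  if (nrow(raw_scores) == 0) stop("no knowledge-graph scores", call. = FALSE)
  tibble::tibble(protein = raw_scores$protein,
                 s_k = min_max(raw_scores$raw_score))
}

#' Integrated inference score
#'
#' The convex combination `w_d*s_d + w_m*s_m + w_b*s_b + w_k*s_k` of the
#' four component scores. With components in `[0, 1]` and weights summing
#' to 1 the result is guaranteed to lie in `[0, 1]`.
#'
#' @param components Tibble with columns `protein`, `s_d`, `s_m`, `s_b`,
#'   `s_k`, each in `[0, 1]`. Missing components for a protein are treated
#'   as errors, not zeros.
#' @param weights A [scoring_weights()] object.
#' @return The input tibble with an `i_p` column appended.
#' @export
compute_inference_score <- function(components, weights = scoring_weights()) {
  components <- tibble::as_tibble(components)
  comp_cols <- c("s_d", "s_m", "s_b", "s_k")
  missing_cols <- setdiff(comp_cols, names(components))
  if (length(missing_cols) > 0) {
    stop("missing component column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(components[comp_cols])
  if (any(is.na(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("component scores must lie in [0, 1] with no missing values",
         call. = FALSE)
  }
  components$i_p <- weights$w_d * components$s_d +
    weights$w_m * components$s_m +
    weights$w_b * components$s_b +
    weights$w_k * components$s_k
  components
}

#' Join component scores across evidence layers
#'
#' Full-joins the four per-protein component tibbles on `protein`,
#' filling proteins absent from a layer with that layer's minimum evidence
#' (score 0), and appends the integrated inference score.
#'
#' @param sd_tbl,sm_tbl,sb_tbl,sk_tbl Component tibbles from
#'   [compute_sd()], [compute_sm()], [compute_sb()], [compute_sk()].
#' @param weights A [scoring_weights()] object.
#' @return Tibble with `protein`, the four components and `i_p`.
#' @export
score_targets <- function(sd_tbl, sm_tbl, sb_tbl, sk_tbl,
                          weights = scoring_weights()) {
  components <- list(sd_tbl, sm_tbl, sb_tbl, sk_tbl) |>
    purrr::reduce(dplyr::full_join, by = "protein") |>
    dplyr::mutate(dplyr::across(c("s_d", "s_m", "s_b", "s_k"),
                                ~ dplyr::coalesce(.x, 0)))
  compute_inference_score(components, weights)
}

#' Rank proteins and flag high-confidence targets
#'
#' Sorts proteins by descending inference score (ties broken by ascending
#' protein identifier, so ranking is reproducible) and classifies each as
#' `high_confidence` when its score is strictly above the threshold, else
#' `candidate`. The strict inequality matters at the boundary: a protein
#' scoring exactly the threshold is a candidate, not a high-confidence
#' target.
#'
#' @param scores Tibble with columns `protein` and `i_p` (and optionally
#'   the component columns, which are carried through).
#' @param threshold Classification threshold (default 0.85).
#' @return A `ranked_targets` tibble: the input plus `rank` (1 = best) and
#'   `classification`, sorted by rank, with the threshold stored as an
#'   attribute.
#' @export
rank_and_classify <- function(scores, threshold = 0.85) {
  scores <- tibble::as_tibble(scores)
  out <- scores |>
    dplyr::arrange(dplyr::desc(.data$i_p), .data$protein) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      classification = dplyr::if_else(.data$i_p > threshold,
                                      "high_confidence", "candidate")
    )
  structure(out,
            threshold = threshold,
            class = c("ranked_targets", class(tibble::tibble())))
}

#' Count novel high-confidence targets
#'
#' @param ranked A `ranked_targets` tibble from [rank_and_classify()].
#' @param known_registry Character vector of previously studied targets
#'   and biomarkers.
#' @return Number of high-confidence proteins absent from the registry.
#' @export
count_novel_high_confidence <- function(ranked, known_registry) {
  hc <- ranked$protein[ranked$classification == "high_confidence"]
  sum(!hc %in% known_registry)
}

#' Strip a ranking to a plain tibble
#'
#' @param x A `ranked_targets` object.
#' @param ... Unused.
#' @return The ranking table without the class or threshold attribute.
#' @exportS3Method tibble::as_tibble
as_tibble.ranked_targets <- function(x, ...) {
  attr(x, "threshold") <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' @export
print.ranked_targets <- function(x, ...) {
  cat("<ranked_targets> ", nrow(x), " proteins, ",
      sum(x$classification == "high_confidence"),
      " high-confidence (threshold ", attr(x, "threshold"), ")\n", sep = "")
  NextMethod()
}

#' Tidy a ranked-targets table
#'
#' @param x A `ranked_targets` object.
#' @param ... Unused.
#' @return A plain tibble of the ranking (one row per protein).
#' @exportS3Method generics::tidy
tidy.ranked_targets <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a ranking
#'
#' @param x A `ranked_targets` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_proteins`, `n_high_confidence`,
#'   `top_protein`, `max_score`, `threshold`.
#' @exportS3Method generics::glance
glance.ranked_targets <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    n_high_confidence = sum(x$classification == "high_confidence"),
    top_protein = if (nrow(x) > 0) x$protein[1] else NA_character_,
    max_score = if (nrow(x) > 0) max(x$i_p) else NA_real_,
    threshold = attr(x, "threshold")
  )
}
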