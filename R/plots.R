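#' Dot plot of enrichment results
#'
#' Fold enrichment of the top terms against significance, the usual way
#' over-representation panels are read: dot position is fold enrichment,
#' color is -log10 of the adjusted p-value.
#'
#' @param results Enrichment tibble from [enrich()].
#' @param top_n Number of top (smallest-p) terms to show (default 15).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results, top_n = 15) {
  dat <- utils::head(results, top_n)
  if (nrow(dat) == 0) stop("no enrichment results to plot", call. = FALSE)
  dat$term <- factor(dat$term, levels = rev(dat$term))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$fold, y = .data$term,
    color = -log10(pmax(.data$q_value, 1e-300)), size = .data$k)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_viridis_c(name = expression(-log[10] ~ FDR)) +
    ggplot2::labs(x = "Fold enrichment", y = NULL, size = "Genes") +
    ggplot2::theme_minimal()
}

#' Plot a target ranking
#'
#' Inference score by rank, colored by classification, with the
#' high-confidence threshold drawn as a dashed line.
#'
#' @param object A `ranked_targets` tibble from [rank_and_classify()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ranked_targets <- function(object, ...) {
  threshold <- attr(object, "threshold")
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(
    x = .data$rank, y = .data$i_p, color = .data$classification)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(high_confidence = "#c0392b",
                                           candidate = "#7f8c8d")) +
    ggplot2::labs(x = "Rank", y = "Inference score",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of component scores for the top-ranked proteins
#'
#' Shows how each of the four evidence components contributes to the
#' integrated score of the highest-ranked proteins.
#'
#' @param ranked A `ranked_targets` tibble carrying the component columns
#'   `s_d`, `s_m`, `s_b`, `s_k`.
#' @param top_n Number of top proteins to show (default 20).
#' @return A ggplot object.
#' @export
plot_score_components <- function(ranked, top_n = 20) {
  comp_cols <- c("s_d", "s_m", "s_b", "s_k")
  if (!all(comp_cols %in% names(ranked))) {
    stop("ranking does not carry component scores", call. = FALSE)
  }
  dat <- utils::head(tibble::as_tibble(ranked), top_n) |>
    tidyr::pivot_longer(dplyr::all_of(comp_cols),
                        names_to = "component", values_to = "score")
  dat$protein <- factor(dat$protein, levels = rev(unique(dat$protein)))
  dat$component <- factor(dat$component, levels = comp_cols,
                          labels = c("disease", "molecular", "biomedical",
                                     "knowledge graph"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$component, y = .data$protein,
                                    fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Score") +
    ggplot2::theme_minimal()
}
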