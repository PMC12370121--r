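test_that("min-max scaling maps to [0,1] with the degenerate-input policy", {
  expect_equal(min_max(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(min_max(5), 0)
  expect_equal(min_max(c(3, 3, 3)), c(0, 0, 0))
  expect_error(min_max(numeric()), "empty")
  expect_error(min_max(c(1, NA)), "finite")

  withr::local_seed(31)
  for (i in 1:20) {
    v <- stats::rnorm(sample(2:50, 1), sd = 10)
    s <- min_max(v)
    expect_true(all(s >= 0 & s <= 1))
    # idempotence on non-degenerate input
    if (max(v) > min(v)) expect_equal(min_max(s), s)
  }
})

test_that("scoring weights validate their two simplex constraints", {
  w <- scoring_weights()
  expect_equal(w$w_d + w$w_m + w$w_b + w$w_k, 1)
  expect_error(scoring_weights(w_d = 0.5), "sum to 1")
  expect_error(scoring_weights(alpha = 0.5, beta = 0.5, gamma = 0.5),
               "sum to 1")
  expect_error(scoring_weights(w_d = -0.1, w_m = 0.7), "nonnegative")
})

test_that("disease-mapping score is the supporting-study fraction", {
  ev <- tibble::tibble(protein = c("A", "B", "C"),
                       study_count = c(3, 0, 10), catalog_total = 10)
  sd_tbl <- compute_sd(ev)
  expect_equal(sd_tbl$s_d, c(0.3, 0, 1))
  expect_error(compute_sd(dplyr::mutate(ev, catalog_total = c(10, 10, 9))),
               "single positive")
  expect_error(compute_sd(dplyr::mutate(ev, study_count = c(11, 0, 1))),
               "catalog_total")
  # optional renormalization maps the extremes to 0 and 1
  expect_equal(compute_sd(ev, renormalize = TRUE)$s_d, c(0.3, 0, 1))
})

test_that("molecular score mixes centralities then min-max normalizes", {
  # path A - B - C with equal scaling factors:
  # raw(B) = (1 + 1 + 1)/3 = 1, raw(A) = raw(C) = (0.5 + 0 + 2/3)/3 = 7/18
  cents <- centralities(edges_network(tibble::tibble(
    protein_a = c("A", "B"), protein_b = c("B", "C"))))
  sm <- compute_sm(cents) |> dplyr::arrange(protein)
  expect_equal(sm$s_m, c(0, 1, 0))

  # identical centralities degenerate to all zero
  flat <- tibble::tibble(protein = c("A", "B"), c_d = 0.5, c_b = 0.5,
                         c_c = 0.5)
  expect_equal(compute_sm(flat)$s_m, c(0, 0))

  # alpha = 1 reduces the ordering to the degree ordering
  w_deg <- scoring_weights(alpha = 1, beta = 0, gamma = 0)
  sm_deg <- compute_sm(cents, w_deg)
  expect_equal(order(-sm_deg$s_m), order(-cents$c_d))
})

test_that("biomedical and knowledge-graph scores min-max their inputs", {
  expr <- tibble::tibble(protein = c("A", "B", "C"),
                         expression = c(0, 5, 10))
  expect_equal(compute_sb(expr)$s_b, c(0, 0.5, 1))
  expect_error(compute_sb(expr[0, ]), "no expression")
  # repeated contexts are averaged before scaling
  expr2 <- tibble::tibble(protein = c("A", "A", "B"),
                          expression = c(0, 10, 10),
                          context = c("t1", "t2", "t1"))
  expect_equal(compute_sb(expr2)$s_b, c(0, 1))

  raw <- tibble::tibble(protein = c("A", "B", "C"),
                        raw_score = c(0.7, 0.35, 0))
  expect_equal(compute_sk(raw)$s_k, c(1, 0.5, 0))
  expect_equal(compute_sk(raw[1, ])$s_k, 0)
  expect_equal(compute_sk(dplyr::mutate(raw, raw_score = 0))$s_k, c(0, 0, 0))
})

test_that("the inference score is the stated convex combination", {
  comp <- function(s_d, s_m, s_b, s_k) {
    tibble::tibble(protein = "P", s_d = s_d, s_m = s_m, s_b = s_b, s_k = s_k)
  }
  expect_equal(compute_inference_score(comp(1, 1, 1, 1))$i_p, 1)
  expect_equal(compute_inference_score(comp(0.9, 0.9, 0.8, 0.8))$i_p, 0.86)
  expect_equal(compute_inference_score(comp(0, 0, 0, 0))$i_p, 0)
  expect_error(compute_inference_score(comp(1.2, 0, 0, 0)), "\\[0, 1\\]")
  expect_error(compute_inference_score(comp(NA, 0, 0, 0)), "missing")
})

test_that("the inference score is bounded and monotone under random weights", {
  withr::local_seed(17)
  for (i in 1:25) {
    raw_w <- stats::runif(4)
    w <- raw_w / sum(raw_w)
    weights <- scoring_weights(w[1], w[2], w[3], w[4])
    s <- stats::runif(4)
    base <- compute_inference_score(
      tibble::tibble(protein = "P", s_d = s[1], s_m = s[2], s_b = s[3],
                     s_k = s[4]), weights)$i_p
    expect_gte(base, 0)
    expect_lte(base, 1)
    # bumping any one component never lowers the score
    j <- sample(4, 1)
    s_up <- s
    s_up[j] <- min(1, s_up[j] + stats::runif(1, 0, 1 - s_up[j]))
    up <- compute_inference_score(
      tibble::tibble(protein = "P", s_d = s_up[1], s_m = s_up[2],
                     s_b = s_up[3], s_k = s_up[4]), weights)$i_p
    expect_gte(up, base - 1e-12)
  }
})

test_that("ranking is deterministic with strict classification at 0.85", {
  scores <- tibble::tibble(protein = c("B", "A", "C", "D"),
                           i_p = c(0.851, 0.85, 0.9, 0.851))
  ranked <- rank_and_classify(scores)
  expect_equal(ranked$protein, c("C", "B", "D", "A"))
  expect_equal(ranked$rank, 1:4)
  cls <- stats::setNames(ranked$classification, ranked$protein)
  expect_equal(cls[["B"]], "high_confidence") # 0.851 > 0.85
  expect_equal(cls[["A"]], "candidate")       # exactly 0.85 is not above
  # shuffle invariance
  reshuffled <- rank_and_classify(scores[sample(4), ])
  expect_equal(reshuffled$protein, ranked$protein)
  expect_equal(sort(ranked$rank), 1:4)
})

test_that("the published target table ranks and counts novel targets", {
  targets <- readr::read_tsv(table3_fixture(), show_col_types = FALSE)
  ranked <- rank_and_classify(
    tibble::tibble(protein = targets$protein, i_p = targets$inference_score))
  expect_equal(max(ranked$i_p), 0.93)
  expect_equal(ranked$i_p[1], max(targets$inference_score))

  registry <- targets$protein[targets$novelty == "Previously studied"]
  expect_equal(count_novel_high_confidence(ranked, registry), 9)
  expect_equal(count_novel_high_confidence(ranked, character()),
               sum(ranked$classification == "high_confidence"))
  expect_equal(count_novel_high_confidence(ranked, targets$protein), 0)
})

test_that("tidy and glance summarize rankings broom-style", {
  scores <- tibble::tibble(protein = c("A", "B"), s_d = c(1, 0),
                           s_m = c(1, 0), s_b = c(1, 0), s_k = c(1, 0)) |>
    compute_inference_score()
  ranked <- rank_and_classify(scores)
  td <- tidy(ranked)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "ranked_targets"))
  gl <- glance(ranked)
  expect_equal(gl$n_proteins, 2)
  expect_equal(gl$n_high_confidence, 1)
  expect_equal(gl$top_protein, "A")
  expect_equal(gl$max_score, 1)
})

test_that("score_targets joins layers and fills absent proteins with zero", {
  sd_tbl <- tibble::tibble(protein = c("A", "B"), s_d = c(0.5, 1))
  sm_tbl <- tibble::tibble(protein = c("A", "C"), s_m = c(1, 0.5))
  sb_tbl <- tibble::tibble(protein = "A", s_b = 1)
  sk_tbl <- tibble::tibble(protein = "A", s_k = 1)
  joined <- score_targets(sd_tbl, sm_tbl, sb_tbl, sk_tbl)
  expect_equal(sort(joined$protein), c("A", "B", "C"))
  expect_equal(joined$i_p[joined$protein == "A"], 0.5 * 0.3 + 0.3 + 0.2 + 0.2)
  expect_equal(joined$i_p[joined$protein == "B"], 0.3)
})
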