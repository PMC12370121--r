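write_edge_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("protein1\tprotein2\tcombined_score", lines), path)
  path
}

test_that("interaction reader handles dialects, loops and duplicates", {
  # STRING 0-999 integer dialect is auto-detected and rescaled
  p <- write_edge_file("A\tB\t900")
  rec <- read_interactions(p)
  expect_equal(rec$combined_score, 0.9)

  # unit-scale files pass through unchanged
  p <- write_edge_file("A\tB\t0.85")
  expect_equal(read_interactions(p)$combined_score, 0.85)

  # A-B and B-A are the same unordered pair
  p <- write_edge_file(c("A\tB\t900", "B\tA\t800"))
  expect_warning(rec <- read_interactions(p), "duplicate")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$combined_score, 0.9) # max per channel

  # self-loops are dropped with a warning
  p <- write_edge_file(c("A\tA\t900", "A\tB\t700"))
  expect_warning(rec <- read_interactions(p), "1 self-loop")
  expect_equal(nrow(rec), 1)
})

test_that("confidence combination sums channels and min-max normalizes", {
  rec <- tibble::tibble(protein_a = c("A", "B", "C"),
                        protein_b = c("B", "C", "D"),
                        ch1 = c(0.9, 0.6, 0.3),
                        ch2 = c(0.8, 0.4, 0.2))
  out <- combine_confidence(rec)
  expect_equal(out$combined_raw, c(1.7, 1.0, 0.5))
  expect_equal(out$combined_norm, c(1, 0.5 / 1.2, 0))

  single <- combine_confidence(rec[1, ])
  expect_equal(single$combined_norm, 0)
  equal_raws <- combine_confidence(
    tibble::tibble(protein_a = c("A", "B"), protein_b = c("B", "C"),
                   ch1 = c(0.5, 0.5)))
  expect_equal(equal_raws$combined_norm, c(0, 0))
  expect_error(combine_confidence(rec[0, ]), "at least one")
})

test_that("confidence thresholding is inclusive at the boundary", {
  rec <- tibble::tibble(protein_a = c("A", "B", "C"),
                        protein_b = c("B", "C", "D"),
                        combined_score = c(0.95, 0.90, 0.89))
  expect_equal(nrow(threshold_interactions(rec)), 2)
  expect_equal(nrow(threshold_interactions(rec, min_conf = 0)), 3)
  expect_equal(nrow(threshold_interactions(rec[0, ])), 0)
})

test_that("role labeling partitions nodes into risk/neighbor/other", {
  rec <- tibble::tibble(protein_a = c("R1", "X"), protein_b = c("X", "Y"),
                        combined_score = c(0.95, 0.95))
  net <- build_network(rec, risk_set = "R1")
  roles <- stats::setNames(net$nodes$role, net$nodes$protein)
  expect_equal(roles[["R1"]], "risk")
  expect_equal(roles[["X"]], "neighbor")
  expect_equal(roles[["Y"]], "other")

  net2 <- build_network(rec, risk_set = "Z99")
  expect_true(all(net2$nodes$role == "other"))

  tri <- tibble::tibble(protein_a = c("R1", "R2", "R1"),
                        protein_b = c("R2", "X", "X"),
                        combined_score = rep(0.95, 3))
  net3 <- build_network(tri, risk_set = c("R1", "R2"))
  expect_equal(net3$nodes$role[net3$nodes$protein == "X"], "neighbor")
  # partition property
  expect_equal(sum(table(net3$nodes$role)), nrow(net3$nodes))
})

test_that("per-risk-protein edge capping keeps the strongest, ties by id", {
  rec <- tibble::tibble(
    protein_a = c("R", "R", "R"),
    protein_b = c("X", "Y", "Z"),
    combined_score = c(0.99, 0.95, 0.91)) |>
    combine_confidence()
  top2 <- top_interactions_per_risk(rec, "R", limit = 2)
  expect_equal(sort(top2$protein_b), c("X", "Y"))
  expect_equal(nrow(top_interactions_per_risk(rec, "R", limit = 10)), 3)

  tied <- tibble::tibble(protein_a = c("R", "A"), protein_b = c("B", "R"),
                         combined_score = c(0.95, 0.95)) |>
    combine_confidence()
  top1 <- top_interactions_per_risk(tied, "R", limit = 1)
  expect_equal(nrow(top1), 1)
  # partner A sorts before partner B
  expect_true("A" %in% c(top1$protein_a, top1$protein_b))
})

test_that("connected components partition, order and cover the node set", {
  rec <- tibble::tibble(protein_a = c("A", "C"), protein_b = c("B", "D"),
                        combined_score = c(0.95, 0.95))
  comps <- connected_components(build_network(rec, character()))
  expect_length(comps, 2)
  expect_equal(purrr::map_int(comps, ~ nrow(.x$nodes)), c(2L, 2L))
  # tie on size broken by smallest member id: {A,B} before {C,D}
  expect_equal(sort(comps[[1]]$nodes$protein), c("A", "B"))

  one <- connected_components(build_network(
    tibble::tibble(protein_a = "A", protein_b = "B",
                   combined_score = 0.9), character()))
  expect_length(one, 1)

  iso <- connected_components(build_network(
    rec[0, ], character(), extra_nodes = paste0("I", 1:5)))
  expect_length(iso, 5)

  # disjoint cover property on a random graph
  withr::local_seed(11)
  g <- random_graph(8)
  comps <- connected_components(edges_network(g$edges, g$nodes))
  all_members <- unlist(purrr::map(comps, ~ .x$nodes$protein))
  expect_equal(sort(all_members), sort(g$nodes))
  expect_false(any(duplicated(all_members)))
})

test_that("centralities match hand-derived values on canonical graphs", {
  # path A - B - C
  path3 <- edges_network(tibble::tibble(protein_a = c("A", "B"),
                                        protein_b = c("B", "C")))
  cent <- centralities(path3) |> dplyr::arrange(protein)
  expect_equal(cent$c_d, c(0.5, 1, 0.5))
  expect_equal(cent$c_b, c(0, 1, 0))
  expect_equal(cent$c_c, c(2 / 3, 1, 2 / 3))

  # complete graph K4: max degree and closeness, no brokerage
  k4 <- t(utils::combn(LETTERS[1:4], 2))
  net4 <- edges_network(tibble::tibble(protein_a = k4[, 1],
                                       protein_b = k4[, 2]))
  cent4 <- centralities(net4)
  expect_true(all(cent4$c_d == 1))
  expect_true(all(cent4$c_b == 0))
  expect_true(all(cent4$c_c == 1))

  # star K1,3: the hub brokers all three leaf pairs
  star <- edges_network(tibble::tibble(protein_a = rep("H", 3),
                                       protein_b = c("L1", "L2", "L3")))
  cent_star <- centralities(star)
  hub <- cent_star[cent_star$protein == "H", ]
  expect_equal(hub$c_d, 1)
  expect_equal(hub$c_b, 1)
  expect_equal(hub$c_c, 1)

  # singleton network scores zero everywhere
  lone <- edges_network(tibble::tibble(protein_a = character(),
                                       protein_b = character()),
                        nodes = "A")
  expect_equal(unlist(centralities(lone)[, c("c_d", "c_b", "c_c")]),
               c(c_d = 0, c_b = 0, c_c = 0))
})

test_that("centralities agree with the brute-force oracle on random graphs", {
  withr::local_seed(202)
  for (i in 1:12) {
    n <- sample(2:8, 1)
    g <- random_graph(n, edge_prob = stats::runif(1, 0.2, 0.7))
    net <- edges_network(g$edges, g$nodes)
    got <- centralities(net) |> dplyr::arrange(protein)
    want <- oracle_centralities(g$nodes, g$edges) |>
      dplyr::arrange(protein)
    expect_equal(got$c_d, want$c_d, tolerance = 1e-12)
    expect_equal(got$c_b, want$c_b, tolerance = 1e-12)
    expect_equal(got$c_c, want$c_c, tolerance = 1e-12)
  }
})

test_that("functional clustering merges components by term-set Jaccard", {
  background <- paste0("G", 1:40)
  comp_genes <- list(background[1:5], background[6:10], background[11:15])
  comps <- purrr::map(comp_genes, function(genes) {
    edges <- tibble::tibble(protein_a = genes[-length(genes)],
                            protein_b = genes[-1])
    edges_network(edges, genes)
  })

  # both components significant for the same single term -> one cluster
  shared_ann <- annotation_map(
    list(t = c(comp_genes[[1]], comp_genes[[2]])), background)
  cl <- cluster_by_function(comps[1:2], shared_ann, 1)
  expect_equal(cl$cluster, c(1, 1))

  # disjoint term sets stay separate at threshold 0.5
  disjoint_ann <- annotation_map(
    list(a = comp_genes[[1]], c = comp_genes[[2]]), background)
  cl2 <- cluster_by_function(comps[1:2], disjoint_ann, 0.5)
  expect_equal(length(unique(cl2$cluster)), 2)

  # term sets {a,b} and {b,c}: Jaccard 1/3 merges at threshold 1/3
  ann3 <- annotation_map(
    list(a = comp_genes[[1]],
         b = c(comp_genes[[1]], comp_genes[[2]]),
         c = comp_genes[[2]]), background)
  cl3 <- cluster_by_function(comps[1:2], ann3, 1 / 3)
  expect_equal(cl3$cluster, c(1, 1))
  cl3b <- cluster_by_function(comps[1:2], ann3, 0.5)
  expect_equal(length(unique(cl3b$cluster)), 2)

  # a component with no significant terms is a singleton "unassigned"
  cl4 <- cluster_by_function(comps, disjoint_ann, 0.5)
  expect_equal(cl4$label[3], "unassigned")
})
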