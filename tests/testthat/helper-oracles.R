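# Independent oracles used to cross-check the package's computations.
# Deliberately brute-force and free of igraph / stats shortcuts.

# Right-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) draws from a universe 1:N whose first K elements are marked.
oracle_hyper_tail_enum <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# Same tail probability by summing the hypergeometric pmf in closed form.
oracle_hyper_tail_pmf <- function(k, n, K, N) {
  j <- k:min(n, K)
  if (k > min(n, K)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Benjamini-Hochberg step-up, hand-stepped: p * m / i with a running
# minimum from the largest p down, clipped to 1, in input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Brute-force centralities: BFS distances plus explicit enumeration of
# every shortest path for betweenness credit.
oracle_centralities <- function(nodes, edges) {
  n_total <- length(nodes)
  adj <- stats::setNames(vector("list", n_total), nodes)
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[[1]][i]
      b <- edges[[2]][i]
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  dist <- matrix(Inf, n_total, n_total, dimnames = list(nodes, nodes))
  diag(dist) <- 0
  for (s in nodes) {
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      nxt <- character()
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (!is.finite(dist[s, w])) nxt <- union(nxt, w)
        }
      }
      d <- d + 1
      dist[s, nxt] <- d
      frontier <- nxt
    }
  }
  # enumerate all shortest s-t paths; count how many pass through each
  # interior node
  shortest_paths_through <- function(s, t) {
    total <- 0
    through <- stats::setNames(numeric(n_total), nodes)
    walk <- function(v, interior) {
      if (v == t) {
        total <<- total + 1
        through[interior] <<- through[interior] + 1
        return(invisible())
      }
      for (w in adj[[v]]) {
        if (is.finite(dist[w, t]) && dist[w, t] == dist[v, t] - 1) {
          walk(w, if (w == t) interior else c(interior, w))
        }
      }
    }
    walk(s, character())
    list(total = total, through = through)
  }
  c_b <- stats::setNames(numeric(n_total), nodes)
  if (n_total >= 3) {
    pair_idx <- utils::combn(nodes, 2, simplify = FALSE)
    for (pr in pair_idx) {
      if (!is.finite(dist[pr[1], pr[2]])) next
      sp <- shortest_paths_through(pr[1], pr[2])
      if (sp$total > 0) c_b <- c_b + sp$through / sp$total
    }
    c_b <- c_b / ((n_total - 1) * (n_total - 2) / 2)
  }
  c_d <- vapply(nodes, function(v) length(adj[[v]]), numeric(1)) /
    max(1, n_total - 1)
  c_c <- vapply(nodes, function(v) {
    dv <- dist[v, nodes != v]
    reach <- dv[is.finite(dv)]
    n_c <- length(reach) + 1
    if (n_c == 1 || n_total == 1) return(0)
    ((n_c - 1) / sum(reach)) * ((n_c - 1) / (n_total - 1))
  }, numeric(1))
  if (n_total == 1) {
    c_d[] <- 0
    c_b[] <- 0
    c_c[] <- 0
  }
  tibble::tibble(protein = nodes, c_d = unname(c_d), c_b = unname(c_b),
                 c_c = unname(c_c))
}

# Random small graph for property tests.
random_graph <- function(n_nodes, edge_prob = 0.35) {
  nodes <- paste0("N", seq_len(n_nodes))
  if (n_nodes < 2) {
    return(list(nodes = nodes,
                edges = tibble::tibble(protein_a = character(),
                                       protein_b = character())))
  }
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < edge_prob
  list(nodes = nodes,
       edges = tibble::tibble(protein_a = pairs[keep, 1],
                              protein_b = pairs[keep, 2]))
}

edges_network <- function(edges, nodes = NULL) {
  build_network(edges, risk_set = character(), extra_nodes = nodes)
}

# Small catalog builder for curation tests.
toy_catalog <- function(rsid, gene = rsid, odds_ratio = 1.2,
                        pmids = vector("list", length(rsid)),
                        population = "unknown",
                        sample_size = NA_real_,
                        chromosome = "1") {
  ratarget:::new_curated_catalog(tibble::tibble(
    rsid = rsid,
    chromosome = rep_len(chromosome, length(rsid)),
    gene = rep_len(gene, length(rsid)),
    odds_ratio = rep_len(odds_ratio, length(rsid)),
    pmids = purrr::map(rep_len(pmids, length(rsid)), as.character),
    population = rep_len(population, length(rsid)),
    sample_size = rep_len(as.numeric(sample_size), length(rsid))
  ))
}

table1_fixture <- function() {
  system.file("extdata", "table1_risk_variants.tsv", package = "ratarget")
}

table3_fixture <- function() {
  system.file("extdata", "table3_targets.tsv", package = "ratarget")
}
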