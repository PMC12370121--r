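#' Read a protein-interaction edge table
#'
#' Reads an edge table in the STRING-export dialect: two protein-identifier
#' columns followed by one or more numeric confidence channels. Channels on
#' STRING's 0-999 integer scale are auto-detected (any value above 1) and
#' divided by 1000 to the 0-1 scale; already-unit-scaled files pass through.
#' Self-loops are dropped and duplicate unordered pairs collapsed to the
#' per-channel maximum, each with a warning.
#'
#' @param path Path to a TSV file with a header row; the first two columns
#'   are protein identifiers, all remaining numeric columns are confidence
#'   channels.
#' @param dialect `"auto"` (default), `"string999"` (force /1000), or
#'   `"unit"` (scores already in 0-1).
#' @return A tibble with columns `protein_a`, `protein_b` (sorted within
#'   each pair) and one 0-1 column per channel.
#' @export
read_interactions <- function(path, dialect = c("auto", "string999", "unit")) {
  dialect <- match.arg(dialect)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) < 3) {
    stop("interaction table needs two protein columns and >=1 channel",
         call. = FALSE)
  }
  channels <- names(tbl)[-(1:2)]
  numeric_ok <- purrr::map_lgl(tbl[channels], is.numeric)
  if (!all(numeric_ok)) {
    stop("non-numeric channel column(s): ",
         paste(channels[!numeric_ok], collapse = ", "), call. = FALSE)
  }
  rec <- tibble::tibble(
    protein_a = as.character(tbl[[1]]),
    protein_b = as.character(tbl[[2]])
  )
  rec <- dplyr::bind_cols(rec, tbl[channels])
  if (dialect == "auto") {
    dialect <- if (any(unlist(tbl[channels]) > 1, na.rm = TRUE)) {
      "string999"
    } else {
      "unit"
    }
  }
  if (dialect == "string999") {
    rec <- dplyr::mutate(rec,
                         dplyr::across(dplyr::all_of(channels), ~ .x / 1000))
  }
  loops <- rec$protein_a == rec$protein_b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
    rec <- rec[!loops, ]
  }
  # canonical unordered pair
  swap <- rec$protein_a > rec$protein_b
  tmp <- rec$protein_a[swap]
  rec$protein_a[swap] <- rec$protein_b[swap]
  rec$protein_b[swap] <- tmp
  dup <- duplicated(rec[c("protein_a", "protein_b")])
  if (any(dup)) {
    warning(sum(dup), " duplicate unordered pair(s) collapsed to max",
            call. = FALSE)
    rec <- rec |>
      dplyr::group_by(.data$protein_a, .data$protein_b) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(channels), max),
                       .groups = "drop")
  }
  rec
}

channel_columns <- function(records) {
  setdiff(names(records)[purrr::map_lgl(records, is.numeric)],
          c("combined_raw", "combined_norm"))
}

#' Combine per-channel confidences into one edge weight
#'
#' Sums all confidence channels of each interaction and min-max-normalizes
#' the sums across the edge set, yielding a 0-1 combined weight per edge.
#' If every edge has the same summed confidence the normalized weight is 0
#' for all (degenerate min-max policy), keeping downstream weighted sums
#' defined.
#'
#' @param records Interaction tibble from [read_interactions()].
#' @return The same tibble with `combined_raw` (channel sum) and
#'   `combined_norm` (min-max of the sums) appended.
#' @export
combine_confidence <- function(records) {
  if (nrow(records) == 0) {
    stop("combine_confidence needs at least one interaction", call. = FALSE)
  }
  channels <- channel_columns(records)
  records$combined_raw <- rowSums(as.matrix(records[channels]))
  records$combined_norm <- min_max(records$combined_raw)
  records
}

#' Keep only high-confidence interactions
#'
#' Retains interactions whose primary confidence channel is at or above the
#' threshold (inclusive). The default 0.9 is the conventional
#' highest-confidence cut for STRING combined scores, applied to the native
#' 0-1 combined channel before any summation or renormalization.
#'
#' @param records Interaction tibble.
#' @param min_conf Inclusive confidence threshold (default 0.9).
#' @param channel Channel to threshold on; defaults to `combined_score` if
#'   present, otherwise the first channel column.
#' @return The retained rows.
#' @export
threshold_interactions <- function(records, min_conf = 0.9, channel = NULL) {
  if (nrow(records) == 0) return(records)
  if (is.null(channel)) {
    channels <- channel_columns(records)
    channel <- if ("combined_score" %in% channels) {
      "combined_score"
    } else {
      channels[1]
    }
  }
  if (!channel %in% names(records)) {
    stop("no such confidence channel: ", channel, call. = FALSE)
  }
  records[records[[channel]] >= min_conf, ]
}

#' Build a role-labeled interaction network
#'
#' Constructs an undirected simple network from an interaction table and
#' labels each protein `risk` (in the supplied risk set), `neighbor`
#' (not risk but adjacent to a risk protein), or `other`.
#'
#' @param records Interaction tibble (edges).
#' @param risk_set Character vector of risk-protein identifiers.
#' @param extra_nodes Optional identifiers to include as isolated nodes.
#' @return A `ppi_network`: list with `nodes` (tibble `protein`, `role`) and
#'   `edges` (the interaction tibble).
#' @export
build_network <- function(records, risk_set, extra_nodes = NULL) {
  proteins <- unique(c(records$protein_a, records$protein_b,
                       as.character(extra_nodes)))
  risk <- proteins %in% risk_set
  adj_risk <- proteins %in% c(records$protein_b[records$protein_a %in% risk_set],
                              records$protein_a[records$protein_b %in% risk_set])
  role <- dplyr::case_when(risk ~ "risk",
                           adj_risk ~ "neighbor",
                           TRUE ~ "other")
  structure(list(nodes = tibble::tibble(protein = proteins, role = role),
                 edges = records),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  tab <- table(factor(x$nodes$role, levels = c("risk", "neighbor", "other")))
  cat("<ppi_network> ", nrow(x$nodes), " proteins (",
      tab[["risk"]], " risk, ", tab[["neighbor"]], " neighbor, ",
      tab[["other"]], " other), ", nrow(x$edges), " interactions\n", sep = "")
  invisible(x)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[c("protein_a", "protein_b")],
    directed = FALSE,
    vertices = network$nodes["protein"]
  )
}

#' Keep each risk protein's strongest interactions
#'
#' For every risk protein, retains its `limit` highest-combined-confidence
#' incident edges; the result is the union over risk proteins. Ties are
#' broken by ascending partner identifier so output is reproducible.
#'
#' @param records Interaction tibble with `combined_raw` computed (see
#'   [combine_confidence()]).
#' @param risk_set Character vector of risk-protein identifiers.
#' @param limit Edges to keep per risk protein.
#' @return The retained interaction rows (each at most once).
#' @export
top_interactions_per_risk <- function(records, risk_set, limit) {
  stopifnot(limit >= 1)
  if (!"combined_raw" %in% names(records)) {
    stop("combined scores missing; run combine_confidence() first",
         call. = FALSE)
  }
  records$.row <- seq_len(nrow(records))
  keep <- purrr::map(risk_set, function(rp) {
    inc <- records[records$protein_a == rp | records$protein_b == rp, ]
    if (nrow(inc) == 0) return(integer())
    partner <- ifelse(inc$protein_a == rp, inc$protein_b, inc$protein_a)
    ord <- order(-inc$combined_raw, partner)
    inc$.row[ord[seq_len(min(limit, nrow(inc)))]]
  })
  rows <- sort(unique(unlist(keep)))
  out <- records[rows, ]
  out$.row <- NULL
  out
}

#' Split a network into connected components
#'
#' @param network A `ppi_network`.
#' @return List of `ppi_network` objects, one per maximal connected
#'   subgraph, ordered by descending node count, ties by ascending smallest
#'   member identifier. Role labels are inherited from the parent network.
#' @export
connected_components <- function(network) {
  if (nrow(network$nodes) == 0) return(list())
  g <- as_igraph(network)
  comp <- igraph::components(g)
  membership <- comp$membership[network$nodes$protein]
  groups <- split(network$nodes$protein, membership)
  ord <- order(-lengths(groups),
               purrr::map_chr(groups, ~ min(sort(.x))))
  purrr::map(groups[ord], function(members) {
    structure(list(
      nodes = network$nodes[network$nodes$protein %in% members, ],
      edges = network$edges[network$edges$protein_a %in% members &
                              network$edges$protein_b %in% members, ]
    ), class = "ppi_network")
  }) |> unname()
}

#' Degree, betweenness and closeness centralities
#'
#' Computes the three centralities used to score molecular interactions,
#' each normalized to `[0, 1]` network-wide:
#'
#' * degree centrality `c_d` = degree / (N - 1);
#' * betweenness centrality `c_b` = shortest-path betweenness (each
#'   unordered pair counted once, credit split equally among equal-length
#'   shortest paths) divided by `(N - 1)(N - 2) / 2`;
#' * closeness centrality `c_c` = within-component closeness
#'   `(n_c - 1) / sum(d)` scaled by `(n_c - 1) / (N - 1)` (the
#'   Wasserman-Faust correction), so scores stay comparable across
#'   components of a disconnected network.
#'
#' `N` is the node count of the full network, `n_c` the node's component
#' size. Isolated nodes score 0 on all three, as does every node of a
#' single-node network.
#'
#' @param network A `ppi_network`.
#' @return Tibble with columns `protein`, `role`, `c_d`, `c_b`, `c_c`.
#' @export
centralities <- function(network) {
  nodes <- network$nodes
  n_total <- nrow(nodes)
  if (n_total == 0) stop("network has no nodes", call. = FALSE)
  out <- tibble::tibble(protein = nodes$protein, role = nodes$role,
                        c_d = 0, c_b = 0, c_c = 0)
  if (n_total == 1) return(out)
  g <- as_igraph(network)
  deg <- igraph::degree(g)[nodes$protein]
  out$c_d <- unname(deg) / (n_total - 1)
  if (n_total >= 3) {
    btw <- igraph::betweenness(g, directed = FALSE)[nodes$protein]
    out$c_b <- unname(btw) / ((n_total - 1) * (n_total - 2) / 2)
  }
  d <- igraph::distances(g)[nodes$protein, nodes$protein, drop = FALSE]
  cc <- purrr::map_dbl(seq_len(n_total), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    n_c <- length(reach) + 1L
    if (n_c == 1) return(0)
    ((n_c - 1) / sum(reach)) * ((n_c - 1) / (n_total - 1))
  })
  out$c_c <- cc
  out
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Group network components by functional similarity
#'
#' Summarizes each component by its significantly enriched annotation terms
#' and merges components whose term sets have Jaccard similarity at or
#' above the threshold (single linkage). Components with no significant
#' term stay singleton clusters labeled `"unassigned"`.
#'
#' @param components List of `ppi_network` objects (from
#'   [connected_components()]).
#' @param annotation An [annotation_map()] over the network's proteins.
#' @param similarity_threshold Jaccard threshold in `[0, 1]` for merging.
#' @param fdr_cutoff FDR cutoff for a term to count as significant
#'   (default 0.05).
#' @return Tibble with one row per component: `component` (index into the
#'   input list), `n_proteins`, `cluster` (cluster index), `terms`
#'   (list-column of the component's significant terms) and `label` (the
#'   cluster's union term set collapsed with `";"`, or `"unassigned"`).
#' @export
cluster_by_function <- function(components, annotation, similarity_threshold,
                                fdr_cutoff = 0.05) {
  stopifnot(length(components) > 0)
  term_sets <- purrr::map(components, function(comp) {
    res <- suppressWarnings(
      enrich(comp$nodes$protein, annotation, fdr_cutoff = fdr_cutoff))
    res$term[res$significant]
  })
  m <- length(components)
  assigned <- lengths(term_sets) > 0
  # single linkage: connected components of the Jaccard >= threshold graph
  cluster <- seq_len(m)
  if (sum(assigned) >= 2) {
    pairs <- utils::combn(which(assigned), 2, simplify = FALSE)
    for (p in pairs) {
      if (jaccard(term_sets[[p[1]]], term_sets[[p[2]]]) >=
            similarity_threshold) {
        merged <- cluster %in% cluster[p]
        cluster[merged] <- min(cluster[p])
      }
    }
  }
  cluster <- match(cluster, sort(unique(cluster)))
  label <- purrr::map_chr(seq_len(m), function(i) {
    members <- which(cluster == cluster[i])
    terms <- sort(unique(unlist(term_sets[members])))
    if (length(terms) == 0) "unassigned" else paste(terms, collapse = ";")
  })
  tibble::tibble(
    component = seq_len(m),
    n_proteins = purrr::map_int(components, ~ nrow(.x$nodes)),
    cluster = cluster,
    terms = term_sets,
    label = label
  )
}
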