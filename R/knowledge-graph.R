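KG_KINDS <- c("gene", "protein", "disease", "pathway", "drug", "kinase",
              "tissue", "cell_type")
KG_RELATIONS <- c("interacts", "associated_with", "phosphorylates",
                  "upregulated_by", "member_of", "expressed_in",
                  "co_expressed")

#' Assemble a multi-layer knowledge graph
#'
#' Unions typed edge tables from several evidence layers (interaction,
#' disease-association, pathway-membership, drug, kinase, expression ...)
#' into one graph. Edges are deduplicated on `(src, dst, relation, layer)`,
#' so the same relationship asserted by two layers is kept once per layer.
#' The node set is the closure of all edge endpoints plus the declared
#' disease-relevant entities.
#'
#' Each edge carries a relationship strength `R` in `[0, 1]` and a
#' nonnegative importance weight `w`; the per-protein evidence score sums
#' `w * R` over edges that touch a disease-relevant entity (see
#' [raw_kg_score()]).
#'
#' @param layer_tables List of tibbles with columns `src_id`, `src_kind`,
#'   `dst_id`, `dst_kind`, `relation`, `strength`, `importance` and
#'   optionally `layer`; when `layer` is absent the list name is used as
#'   the layer tag.
#' @param ra_entities Character vector of node identifiers designated
#'   disease-relevant (the "RA-related entities" of the evidence sum).
#'   Entities not appearing in any edge are added as isolated `disease`
#'   nodes.
#' @return A `knowledge_graph`: list with `nodes` (tibble `id`, `kind`),
#'   `edges` (tibble with an `inferred` flag, `FALSE` for assembled edges)
#'   and `ra_entities`.
#' @export
assemble_kg <- function(layer_tables, ra_entities = character()) {
  edge_cols <- c("src_id", "src_kind", "dst_id", "dst_kind", "relation",
                 "strength", "importance")
  tagged <- purrr::imap(layer_tables, function(tbl, nm) {
    tbl <- tibble::as_tibble(tbl)
    missing_cols <- setdiff(edge_cols, names(tbl))
    if (length(missing_cols) > 0) {
      stop("knowledge-graph layer ", nm, " is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    if (!"layer" %in% names(tbl)) tbl$layer <- as.character(nm)
    tbl[c(edge_cols, "layer")]
  })
  edges <- purrr::list_rbind(tagged)
  if (length(tagged) == 0 || nrow(edges) == 0) {
    edges <- tibble::tibble(
      src_id = character(), src_kind = character(), dst_id = character(),
      dst_kind = character(), relation = character(), strength = double(),
      importance = double(), layer = character())
  }
  if (nrow(edges) > 0) {
    bad_id <- !nzchar(edges$src_id) | !nzchar(edges$dst_id) |
      is.na(edges$src_id) | is.na(edges$dst_id)
    if (any(bad_id)) {
      stop("malformed node identifier in knowledge-graph edge row ",
           which(bad_id)[1], call. = FALSE)
    }
    bad_rel <- !edges$relation %in% KG_RELATIONS
    if (any(bad_rel)) {
      stop("unknown relation(s): ",
           paste(unique(edges$relation[bad_rel]), collapse = ", "),
           "; expected one of ", paste(KG_RELATIONS, collapse = ", "),
           call. = FALSE)
    }
    if (any(edges$strength < 0 | edges$strength > 1)) {
      stop("edge strength must lie in [0, 1]", call. = FALSE)
    }
    if (any(edges$importance < 0)) {
      stop("edge importance must be nonnegative", call. = FALSE)
    }
    edges <- dplyr::distinct(
      edges, .data$src_id, .data$dst_id, .data$relation, .data$layer,
      .keep_all = TRUE)
  }
  edges$inferred <- rep(FALSE, nrow(edges))
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = edges$src_id, kind = edges$src_kind),
    tibble::tibble(id = edges$dst_id, kind = edges$dst_kind)
  ) |> dplyr::distinct()
  missing_entities <- setdiff(ra_entities, nodes$id)
  if (length(missing_entities) > 0) {
    nodes <- dplyr::bind_rows(
      nodes, tibble::tibble(id = missing_entities, kind = "disease"))
  }
  bad_kind <- !nodes$kind %in% KG_KINDS
  if (any(bad_kind)) {
    stop("unknown node kind(s): ",
         paste(unique(nodes$kind[bad_kind]), collapse = ", "), call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges,
                 ra_entities = unique(as.character(ra_entities))),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("<knowledge_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", sum(x$edges$inferred), " inferred), ",
      length(x$ra_entities), " disease-relevant entities\n", sep = "")
  print(table(x$nodes$kind))
  invisible(x)
}

#' Raw knowledge-graph evidence score
#'
#' For each protein, sums `importance * strength` over the graph edges that
#' connect it to a disease-relevant entity (an `ra_entities` member at the
#' opposite endpoint). Inferred edges are excluded unless
#' `include_inferred = TRUE`: proposed links must be explicitly accepted
#' before they contribute evidence.
#'
#' @param kg A `knowledge_graph` from [assemble_kg()].
#' @param proteins Identifiers to score; defaults to all `protein`- and
#'   `gene`-kind nodes. Proteins absent from the graph score 0 with a
#'   warning.
#' @param include_inferred Include inferred edges in the sum (default
#'   `FALSE`).
#' @return Tibble with columns `protein` and `raw_score` (nonnegative).
#' @export
raw_kg_score <- function(kg, proteins = NULL, include_inferred = FALSE) {
  stopifnot(inherits(kg, "knowledge_graph"))
  if (is.null(proteins)) {
    proteins <- kg$nodes$id[kg$nodes$kind %in% c("protein", "gene")]
  }
  proteins <- as.character(proteins)
  absent <- setdiff(proteins, kg$nodes$id)
  if (length(absent) > 0) {
    warning(length(absent), " protein(s) not in the knowledge graph score 0",
            call. = FALSE)
  }
  edges <- kg$edges
  if (!include_inferred) edges <- edges[!edges$inferred, ]
  contrib <- dplyr::bind_rows(
    edges[edges$dst_id %in% kg$ra_entities,
          c("src_id", "strength", "importance")] |>
      dplyr::rename(protein = "src_id"),
    edges[edges$src_id %in% kg$ra_entities,
          c("dst_id", "strength", "importance")] |>
      dplyr::rename(protein = "dst_id")
  )
  contrib <- contrib[contrib$protein %in% proteins, ]
  sums <- contrib |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(raw_score = sum(.data$importance * .data$strength),
                     .groups = "drop")
  tibble::tibble(protein = proteins) |>
    dplyr::left_join(sums, by = "protein") |>
    dplyr::mutate(raw_score = dplyr::coalesce(.data$raw_score, 0))
}

kg_neighbor_sets <- function(kg) {
  edges <- kg$edges
  nbrs <- split(c(edges$dst_id, edges$src_id),
                c(edges$src_id, edges$dst_id))
  purrr::map(nbrs, unique)
}

#' Propose missing protein-disease associations
#'
#' Looks at every (protein, disease-relevant entity) pair with no existing
#' `associated_with` edge and proposes one when the two nodes share at
#' least `min_shared` common neighbors. The proposed strength is the
#' Jaccard similarity of the neighbor sets; the importance is 0 and must be
#' assigned by the analyst before the proposal can contribute to any
#' score. Proposals are flagged `inferred`.
#'
#' @param kg A `knowledge_graph`.
#' @param min_shared Minimum number of shared neighbors (>= 1).
#' @return Tibble of proposed edges in the graph's edge schema with
#'   `inferred = TRUE`; zero rows when nothing qualifies.
#' @export
infer_links <- function(kg, min_shared = 1) {
  stopifnot(inherits(kg, "knowledge_graph"), min_shared >= 1)
  proteins <- kg$nodes$id[kg$nodes$kind %in% c("protein", "gene")]
  diseases <- intersect(kg$ra_entities, kg$nodes$id)
  nbrs <- kg_neighbor_sets(kg)
  existing <- kg$edges[kg$edges$relation == "associated_with", ]
  has_edge <- function(p, d) {
    any((existing$src_id == p & existing$dst_id == d) |
          (existing$src_id == d & existing$dst_id == p))
  }
  proposals <- purrr::map(proteins, function(p) {
    purrr::map(diseases, function(d) {
      if (p == d || has_edge(p, d)) return(NULL)
      np <- setdiff(nbrs[[p]] %||% character(), c(p, d))
      nd <- setdiff(nbrs[[d]] %||% character(), c(p, d))
      shared <- intersect(np, nd)
      if (length(shared) < min_shared) return(NULL)
      tibble::tibble(
        src_id = p,
        src_kind = kg$nodes$kind[match(p, kg$nodes$id)],
        dst_id = d,
        dst_kind = kg$nodes$kind[match(d, kg$nodes$id)],
        relation = "associated_with",
        strength = jaccard(np, nd),
        importance = 0,
        layer = "inferred",
        inferred = TRUE
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  if (is.null(proposals) || nrow(proposals) == 0) {
    return(tibble::tibble(
      src_id = character(), src_kind = character(), dst_id = character(),
      dst_kind = character(), relation = character(), strength = double(),
      importance = double(), layer = character(), inferred = logical()
    ))
  }
  proposals
}

#' Accept inferred links into a knowledge graph
#'
#' @param kg A `knowledge_graph`.
#' @param proposals Tibble from [infer_links()], with `importance`
#'   reassigned by the analyst where the proposal should carry weight.
#' @return The graph with the proposals appended (still flagged
#'   `inferred`; pass `include_inferred = TRUE` to [raw_kg_score()] to let
#'   them contribute).
#' @export
accept_links <- function(kg, proposals) {
  stopifnot(inherits(kg, "knowledge_graph"))
  kg$edges <- dplyr::bind_rows(kg$edges, proposals)
  kg
}

#' Read knowledge-graph layer tables from TSV files
#'
#' @param paths Named character vector of TSV paths; names are used as
#'   layer tags when the files carry no `layer` column.
#' @param ra_entities_path Optional file with one disease-relevant node
#'   identifier per line.
#' @return A `knowledge_graph`.
#' @export
read_kg_layers <- function(paths, ra_entities_path = NULL) {
  tables <- purrr::map(paths, function(p) {
    readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
  })
  ra <- character()
  if (!is.null(ra_entities_path)) {
    ra <- readr::read_lines(ra_entities_path)
    ra <- ra[nzchar(stringr::str_trim(ra))]
  }
  assemble_kg(tables, ra_entities = ra)
}
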