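#' Build a thresholded sequence-similarity network
#'
#' From an all-vs-all pairwise table (BLAST-style), self-hits are dropped,
#' reciprocal duplicates of the same unordered pair are merged keeping the
#' maximum identity, and an edge is retained iff
#' `identity >= identity_min` **and** `min(coverage_a, coverage_b) >=
#' coverage_min` (coverage is enforced symmetrically on both sequences;
#' thresholds are inclusive).
#'
#' @param pairs Tibble with columns `id_a`, `id_b`, `identity` (percent)
#'   and either `coverage` or `coverage_a`/`coverage_b` (percent).
#' @param identity_min,coverage_min Inclusive thresholds, defaults 50 and
#'   80 — the survey's network cut-offs.
#' @param nodes Optional character vector of node ids to include even when
#'   isolated (defaults to all ids seen in `pairs`).
#' @return A `similarity_graph`: list with the retained `edges` tibble,
#'   the `nodes` vector, the backing igraph object and the thresholds.
#' @export
build_sequence_network <- function(pairs, identity_min = 50, coverage_min = 80,
                                   nodes = NULL) {
  stopifnot(all(c("id_a", "id_b", "identity") %in% names(pairs)))
  if (!"coverage_a" %in% names(pairs)) {
    stopifnot("coverage" %in% names(pairs))
    pairs$coverage_a <- pairs$coverage
    pairs$coverage_b <- pairs$coverage
  }
  rng_ok <- function(x) all(x >= 0 & x <= 100, na.rm = TRUE)
  if (!rng_ok(pairs$identity) || !rng_ok(pairs$coverage_a) ||
      !rng_ok(pairs$coverage_b)) {
    stop("identity and coverage must lie in [0, 100]", call. = FALSE)
  }
  all_nodes <- nodes %||% sort(unique(c(pairs$id_a, pairs$id_b)))
  edges <- pairs |>
    dplyr::filter(.data$id_a != .data$id_b) |>
    dplyr::mutate(
      lo = pmin(.data$id_a, .data$id_b),
      hi = pmax(.data$id_a, .data$id_b),
      cov_min = pmin(.data$coverage_a, .data$coverage_b)
    ) |>
    dplyr::group_by(.data$lo, .data$hi) |>
    dplyr::slice_max(.data$identity, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$identity >= identity_min,
                  .data$cov_min >= coverage_min) |>
    dplyr::transmute(id_a = .data$lo, id_b = .data$hi,
                     weight = .data$identity, coverage = .data$cov_min) |>
    dplyr::arrange(.data$id_a, .data$id_b)
  new_similarity_graph(all_nodes, edges, mode = "sequence",
                       thresholds = c(identity_min = identity_min,
                                      coverage_min = coverage_min))
}

#' Build a thresholded structure-similarity network
#'
#' Models with mean pLDDT below `plddt_min` are excluded before any edge
#' is considered. Asymmetric TM-scores for the same unordered pair are
#' averaged, and an edge is retained iff the averaged score is
#' `>= tm_min` (inclusive).
#'
#' @param tm_pairs Tibble with `id_a`, `id_b`, `tm_score` in `[0, 1]`
#'   (one or both directions per pair), or a square numeric matrix with
#'   dimnames.
#' @param plddt Named numeric vector (or tibble with `id`, `plddt`) of
#'   per-model mean pLDDT; models absent from it are kept.
#' @param tm_min,plddt_min Inclusive thresholds, defaults 0.9 and 70.
#' @return A `similarity_graph` (see [build_sequence_network()]).
#' @export
build_structure_network <- function(tm_pairs, plddt = NULL, tm_min = 0.9,
                                    plddt_min = 70) {
  if (is.matrix(tm_pairs)) {
    stopifnot(!is.null(rownames(tm_pairs)), !is.null(colnames(tm_pairs)))
    tm_pairs <- tibble::as_tibble(as.table(tm_pairs), .name_repair = "minimal") |>
      stats::setNames(c("id_a", "id_b", "tm_score")) |>
      dplyr::mutate(id_a = as.character(.data$id_a),
                    id_b = as.character(.data$id_b))
  }
  stopifnot(all(c("id_a", "id_b", "tm_score") %in% names(tm_pairs)))
  if (any(tm_pairs$tm_score < 0 | tm_pairs$tm_score > 1, na.rm = TRUE)) {
    stop("TM-scores must lie in [0, 1]", call. = FALSE)
  }
  if (is.data.frame(plddt)) plddt <- stats::setNames(plddt$plddt, plddt$id)
  all_nodes <- sort(unique(c(tm_pairs$id_a, tm_pairs$id_b)))
  if (!is.null(plddt)) {
    scored <- all_nodes[all_nodes %in% names(plddt)]
    drop <- scored[plddt[scored] < plddt_min]
    all_nodes <- setdiff(all_nodes, drop)
    tm_pairs <- dplyr::filter(tm_pairs, !.data$id_a %in% drop,
                              !.data$id_b %in% drop)
  }
  edges <- tm_pairs |>
    dplyr::filter(.data$id_a != .data$id_b) |>
    dplyr::mutate(lo = pmin(.data$id_a, .data$id_b),
                  hi = pmax(.data$id_a, .data$id_b)) |>
    dplyr::group_by(.data$lo, .data$hi) |>
    dplyr::summarise(weight = mean(.data$tm_score), .groups = "drop") |>
    dplyr::filter(.data$weight >= tm_min) |>
    dplyr::transmute(id_a = .data$lo, id_b = .data$hi, weight = .data$weight) |>
    dplyr::arrange(.data$id_a, .data$id_b)
  new_similarity_graph(all_nodes, edges, mode = "structure",
                       thresholds = c(tm_min = tm_min, plddt_min = plddt_min))
}

new_similarity_graph <- function(nodes, edges, mode, thresholds) {
  g <- igraph::graph_from_data_frame(
    edges[, c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  structure(
    list(nodes = nodes, edges = edges, graph = g, mode = mode,
         thresholds = thresholds),
    class = "similarity_graph"
  )
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph [%s]> %d nodes, %d edges; thresholds: %s\n",
              x$mode, length(x$nodes), nrow(x$edges),
              paste(names(x$thresholds), x$thresholds,
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Cluster a similarity network by connected components
#'
#' Clusters are the connected components of the thresholded graph, labeled
#' 1, 2, ... in order of descending size, ties broken by the
#' lexicographically smallest member. Each cluster's hub is its
#' maximum-degree member (ties broken lexicographically). Singletons are
#' reported as their own clusters and flagged.
#'
#' @param graph A `similarity_graph`.
#' @return A `dcr_clustering`: list with `membership` (tibble `id`,
#'   `cluster`, `degree`, `is_hub`), `clusters` (tibble `cluster`, `size`,
#'   `hub`, `is_singleton`), and `n_clusters`.
#' @export
cluster_components <- function(graph) {
  stopifnot(inherits(graph, "similarity_graph"))
  comp <- igraph::components(graph$graph)
  ids <- igraph::V(graph$graph)$name
  deg <- igraph::degree(graph$graph)
  memb <- tibble::tibble(id = ids, comp = unname(comp$membership),
                         degree = unname(deg))
  ord <- memb |>
    dplyr::group_by(.data$comp) |>
    dplyr::summarise(size = dplyr::n(), min_id = min(.data$id),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$min_id) |>
    dplyr::mutate(cluster = dplyr::row_number())
  membership <- memb |>
    dplyr::left_join(ord[, c("comp", "cluster")], by = "comp") |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(is_hub = .data$id ==
                    .data$id[order(-.data$degree, .data$id)][1L]) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$cluster, .data$id) |>
    dplyr::select("id", "cluster", "degree", "is_hub")
  clusters <- membership |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(size = dplyr::n(), hub = .data$id[.data$is_hub],
                     .groups = "drop") |>
    dplyr::mutate(is_singleton = .data$size == 1L)
  structure(
    list(membership = membership, clusters = clusters,
         n_clusters = nrow(clusters), mode = graph$mode),
    class = "dcr_clustering"
  )
}

#' @export
print.dcr_clustering <- function(x, ...) {
  cat(sprintf("<dcr_clustering [%s]> %d clusters over %d nodes (%d singletons)\n",
              x$mode, x$n_clusters, nrow(x$membership),
              sum(x$clusters$is_singleton)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a clustering into one row per node
#' @param x A `dcr_clustering`.
#' @param ... Unused.
#' @return The membership tibble (`id`, `cluster`, `degree`, `is_hub`).
#' @method tidy dcr_clustering
#' @export
tidy.dcr_clustering <- function(x, ...) x$membership

#' One-row clustering summary
#' @param x A `dcr_clustering`.
#' @param ... Unused.
#' @method glance dcr_clustering
#' @export
glance.dcr_clustering <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$membership),
    n_clusters = x$n_clusters,
    n_singletons = sum(x$clusters$is_singleton),
    largest = max(x$clusters$size)
  )
}

#' Write cluster membership / edges to TSV
#' @param clustering A `dcr_clustering`.
#' @param graph A `similarity_graph`.
#' @param path Output path.
#' @return The written tibble, invisibly.
#' @export
write_clusters_tsv <- function(clustering, path) {
  readr::write_tsv(clustering$membership, path)
  invisible(clustering$membership)
}

#' @rdname write_clusters_tsv
#' @export
write_edges_tsv <- function(graph, path) {
  readr::write_tsv(graph$edges, path)
  invisible(graph$edges)
}
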