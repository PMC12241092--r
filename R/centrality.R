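# Centrality and bridge analysis of a weighted partial-correlation network.
# Distances use the inverse-absolute-weight edge length 1/|w|, the usual
# convention for psychometric networks: strong edges are short.

as_weight_matrix <- function(x) {
  if (inherits(x, "network_model")) x$W else as.matrix(x)
}

weight_graph <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(abs(W), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$length <- 1 / igraph::E(g)$weight
  g
}

#' Node strength
#'
#' Sum of the absolute weights of a node's connections,
#' `s_i = sum_j |w_ij|`.
#'
#' @param W A `network_model` or weight matrix.
#' @return Named numeric vector.
#' @export
strength <- function(W) {
  W <- as_weight_matrix(W)
  rowSums(abs(W))
}

#' Expected influence
#'
#' Signed analogue of [strength()]: `ei_i = sum_j w_ij`, so negative edges
#' subtract rather than add.
#'
#' @inheritParams strength
#' @return Named numeric vector.
#' @export
expected_influence <- function(W) {
  W <- as_weight_matrix(W)
  rowSums(W)
}

#' Shortest-path distance matrix
#'
#' Dijkstra distances under the edge length `1/|w_ij|`; `Inf` between
#' disconnected nodes, zero diagonal.
#'
#' @inheritParams strength
#' @return p x p distance matrix.
#' @export
shortest_path_distances <- function(W) {
  W <- as_weight_matrix(W)
  g <- weight_graph(W)
  D <- igraph::distances(g, weights = igraph::E(g)$length,
                         algorithm = "dijkstra")
  dimnames(D) <- dimnames(W)
  D
}

#' Closeness centrality
#'
#' Multiplicative inverse of the total shortest-path length from a node to
#' every other reachable node; isolated nodes get closeness 0.
#'
#' @inheritParams strength
#' @return Named numeric vector.
#' @export
closeness <- function(W) {
  D <- shortest_path_distances(W)
  diag(D) <- NA
  vapply(seq_len(nrow(D)), function(i) {
    d <- D[i, ]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else 1 / sum(d)
  }, numeric(1)) |> setNames(rownames(D))
}

#' Betweenness centrality
#'
#' Number of times a node lies on the shortest path between two other nodes,
#' with fractional credit split over tied geodesics (Brandes accumulation);
#' each unordered pair is counted once.
#'
#' @inheritParams strength
#' @return Named numeric vector.
#' @export
betweenness <- function(W) {
  W <- as_weight_matrix(W)
  g <- weight_graph(W)
  b <- igraph::betweenness(g, weights = igraph::E(g)$length, directed = FALSE)
  setNames(as.numeric(b), rownames(W))
}

#' Centrality table of a network
#'
#' Strength, expected influence, closeness and betweenness per node, with
#' optional z-scored columns for plotting.
#'
#' @param model A `network_model`.
#' @param standardize Add `z_`-prefixed standardized columns (default
#'   `FALSE`; raw values are the canonical output).
#' @return A `data.frame`, one row per node.
#' @export
centrality_table <- function(model, standardize = FALSE) {
  stopifnot(inherits(model, "network_model"))
  out <- data.frame(
    node_id = model$nodes$node_id,
    domain = model$nodes$domain,
    strength = as.numeric(strength(model)),
    expected_influence = as.numeric(expected_influence(model)),
    closeness = as.numeric(closeness(model)),
    betweenness = as.numeric(betweenness(model)),
    stringsAsFactors = FALSE
  )
  if (standardize) {
    for (v in c("strength", "expected_influence", "closeness",
                "betweenness")) {
      s <- sd(out[[v]])
      out[[paste0("z_", v)]] <-
        if (s > 0) (out[[v]] - mean(out[[v]])) / s else 0
    }
  }
  out
}

#' Bridge strength across clinical domains
#'
#' Sum of the absolute weights of a node's edges to nodes in *other*
#' declared domains, `bs_i = sum_(j: domain(j) != domain(i)) |w_ij|` — the
#' node's capacity to connect distinct clinical domains. A signed variant
#' (plain sum) is available but can cancel across edges.
#'
#' @param W A `network_model`, or a weight matrix (then `nodes` is
#'   required).
#' @param nodes Node metadata with a `domain` column.
#' @param signed Use signed instead of absolute weights (default `FALSE`).
#' @return A `data.frame` with `node_id`, `domain`, `bridge_strength`.
#' @export
bridge_strength <- function(W, nodes = NULL, signed = FALSE) {
  if (inherits(W, "network_model")) {
    nodes <- nodes %||% W$nodes
    W <- W$W
  }
  if (is.null(nodes) || is.null(nodes$domain)) {
    stop("bridge strength needs node metadata with a domain per node")
  }
  if (anyNA(nodes$domain)) {
    stop("missing domain for node(s): ",
         paste(nodes$node_id[is.na(nodes$domain)], collapse = ", "))
  }
  cross <- outer(nodes$domain, nodes$domain, `!=`)
  Wx <- if (signed) W else abs(W)
  data.frame(
    node_id = nodes$node_id,
    domain = nodes$domain,
    bridge_strength = rowSums(Wx * cross),
    stringsAsFactors = FALSE
  )
}

#' Cross-domain network reconstruction
#'
#' Removes every connection within a clinical domain, keeping only edges
#' that link different domains; the node set is unchanged. Node strength on
#' the reconstructed network equals bridge strength on the original one.
#'
#' @param model A `network_model`.
#' @return A `network_model` with within-domain weights set to zero.
#' @export
cross_domain_network <- function(model) {
  stopifnot(inherits(model, "network_model"))
  cross <- outer(model$nodes$domain, model$nodes$domain, `!=`)
  W <- model$W * cross
  as_network_model(W, model$nodes, lambda = model$lambda,
                   gamma = model$gamma, n = model$n)
}

#' Write centrality or bridge tables as TSV
#'
#' @param table A `data.frame` from [centrality_table()] or
#'   [bridge_strength()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_node_table <- function(table, path) {
  out <- table
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
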