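# Graph-topology features for proteins from an interaction edge list.
# Centralities follow the NetworkAnalyzer conventions: closeness and
# related path measures are computed within connected components; isolated
# nodes get closeness 0 and clustering 0.

#' Read an undirected interaction edge list
#'
#' Accepts a two-column TSV (`A<TAB>B`, optional header detected when the
#' first line repeats as ids nowhere else matters) or SIF
#' (`A interaction B`). Duplicate edges (in either orientation) are
#' collapsed and self-loops dropped; the number of dropped self-loops is
#' recorded in the `n_self_loops` attribute.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"sif"`.
#' @return An undirected simple [igraph::graph] of class
#'   `interaction_graph`.
#' @export
read_edge_list <- function(path, format = c("auto", "tsv", "sif")) {
  format <- arg_match(format)
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    attr(g, "n_self_loops") <- 0L
    class(g) <- c("interaction_graph", class(g))
    return(g)
  }
  parse_line <- function(ln, i) {
    parts <- strsplit(trimws(ln), "[\t ]+")[[1L]]
    if (format == "sif") {
      if (length(parts) < 3L) {
        abort(paste0("malformed SIF line ", i, ": '", ln, "'"))
      }
      c(parts[1L], parts[3L])
    } else {
      if (length(parts) < 2L) {
        abort(paste0("malformed edge line ", i, ": '", ln, "'"))
      }
      parts[1:2]
    }
  }
  pairs <- t(vapply(seq_along(lines),
                    function(i) parse_line(lines[i], i), character(2)))
  self <- pairs[, 1L] == pairs[, 2L]
  n_self <- sum(self)
  pairs <- pairs[!self, , drop = FALSE]
  key <- apply(pairs, 1L, function(e) paste(sort(e), collapse = "\r"))
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  attr(g, "n_self_loops") <- n_self
  class(g) <- c("interaction_graph", class(g))
  g
}

TOPOLOGY_MEASURES <- c("degree", "betweenness", "betweenness_normalized",
                       "closeness", "clustering", "eccentricity",
                       "avg_shortest_path", "eigenvector",
                       "neighborhood_connectivity", "stress", "radiality",
                       "topological_coefficient")

#' Node centralities and topology features
#'
#' Computes the named measures for every node and returns them as feature
#' columns joinable to a feature table by node id. Supported measures:
#' `degree`; `betweenness` (Brandes, unnormalized) and
#' `betweenness_normalized` (divided by `(n-1)(n-2)/2`); `closeness`
#' (within the node's connected component, `(n_c - 1) / sum of distances`,
#' 0 for isolated nodes); `clustering` (local transitivity, 0 for degree
#' < 2); `eccentricity` and `avg_shortest_path` (within component);
#' `eigenvector`; `neighborhood_connectivity` (mean neighbour degree);
#' `stress` (number of shortest paths passing through the node);
#' `radiality`; `topological_coefficient`.
#'
#' @param graph An [read_edge_list()] graph (or any undirected igraph).
#' @param measures Character vector of measures (default: all).
#' @return Tibble with `node` plus one column per measure.
#' @export
#' @examples
#' g <- igraph::make_graph(~ A - B, B - C)
#' compute_centralities(g, c("degree", "betweenness", "closeness"))
compute_centralities <- function(graph, measures = TOPOLOGY_MEASURES) {
  unknown <- setdiff(measures, TOPOLOGY_MEASURES)
  if (length(unknown) > 0L) {
    abort(paste0("unknown measure(s): ", paste(unknown, collapse = ", ")))
  }
  n <- igraph::vcount(graph)
  if (n == 0L) abort("graph is empty")
  ids <- igraph::V(graph)$name
  if (is.null(ids)) ids <- as.character(seq_len(n))
  out <- tibble(node = ids)
  deg <- igraph::degree(graph)
  needs_dist <- any(measures %in% c("closeness", "eccentricity",
                                    "avg_shortest_path", "radiality"))
  if (needs_dist) {
    D <- igraph::distances(graph)
  }
  comp <- igraph::components(graph)
  comp_size <- comp$csize[comp$membership]
  for (ms in measures) {
    out[[ms]] <- switch(ms,
      degree = unname(deg),
      betweenness = unname(igraph::betweenness(graph, directed = FALSE)),
      betweenness_normalized = {
        b <- igraph::betweenness(graph, directed = FALSE)
        norm <- (n - 1) * (n - 2) / 2
        unname(if (norm > 0) b / norm else b * 0)
      },
      closeness = vapply(seq_len(n), function(i) {
        reach <- is.finite(D[i, ]) & seq_len(n) != i
        if (!any(reach)) return(0)
        sum(reach) / sum(D[i, reach])
      }, numeric(1)),
      clustering = {
        cl <- igraph::transitivity(graph, type = "local", isolates = "zero")
        unname(ifelse(is.nan(cl), 0, cl))
      },
      eccentricity = vapply(seq_len(n), function(i) {
        reach <- is.finite(D[i, ]) & seq_len(n) != i
        if (!any(reach)) return(0)
        max(D[i, reach])
      }, numeric(1)),
      avg_shortest_path = vapply(seq_len(n), function(i) {
        reach <- is.finite(D[i, ]) & seq_len(n) != i
        if (!any(reach)) return(0)
        mean(D[i, reach])
      }, numeric(1)),
      eigenvector = unname(igraph::eigen_centrality(graph)$vector),
      neighborhood_connectivity = vapply(seq_len(n), function(i) {
        nb <- as.integer(igraph::neighbors(graph, i))
        if (length(nb) == 0L) return(0)
        mean(deg[nb])
      }, numeric(1)),
      stress = stress_centrality(graph),
      radiality = {
        # (diameter + 1 - mean distance) / diameter, within the component
        vapply(seq_len(n), function(i) {
          reach <- is.finite(D[i, ]) & seq_len(n) != i
          if (!any(reach)) return(0)
          members <- comp$membership == comp$membership[i]
          diam <- max(D[members, members][is.finite(D[members, members])])
          if (diam == 0) return(0)
          (diam + 1 - mean(D[i, reach])) / diam
        }, numeric(1))
      },
      topological_coefficient = topological_coefficient(graph, deg))
  }
  out
}

# Stress centrality: the raw count of shortest paths (between all ordered
# source-target pairs, halved for undirected) passing through each node.
# Brandes-style BFS accumulation with path counts.
stress_centrality <- function(graph) {
  n <- igraph::vcount(graph)
  adj <- igraph::as_adj_list(graph)
  adj <- map(adj, as.integer)
  stress <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    distv <- rep(-1L, n); distv[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- c(s)
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (distv[w] < 0L) {
          distv[w] <- distv[v] + 1L
          queue <- c(queue, w)
        }
        if (distv[w] == distv[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    # delta[v] = number of shortest paths from s through v (v != endpoint)
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] * (1 + delta[w] / sigma[w])
      }
    }
    delta[s] <- 0
    stress <- stress + delta
  }
  stress / 2  # each unordered pair counted from both endpoints
}

# Fraction of shared neighbours with other nodes, averaged (Cytoscape
# NetworkAnalyzer definition).
topological_coefficient <- function(graph, deg) {
  n <- igraph::vcount(graph)
  adj <- map(igraph::as_adj_list(graph), as.integer)
  vapply(seq_len(n), function(i) {
    if (deg[i] < 1L) return(0)
    nb <- adj[[i]]
    # nodes sharing at least one neighbour with i (excluding i)
    cand <- setdiff(unique(unlist(adj[nb])), i)
    if (length(cand) == 0L) return(0)
    jvals <- vapply(cand, function(j) {
      shared <- length(intersect(adj[[j]], nb))
      shared + as.integer(j %in% nb)
    }, numeric(1))
    mean(jvals) / deg[i]
  }, numeric(1))
}

#' Join topology features onto a feature table
#'
#' @param data A feature table whose [sample_ids()] are node ids.
#' @param topo Output of [compute_centralities()].
#' @param fill Value for samples absent from the graph.
#' @return A feature table with the topology columns appended (tagged
#'   continuous).
#' @export
add_topology_features <- function(data, topo, fill = 0) {
  ids <- sample_ids(data)
  m <- topo[match(ids, topo$node), setdiff(names(topo), "node"), drop = FALSE]
  m[is.na(m)] <- fill
  out <- bind_cols(as_tibble(data), as_tibble(m))
  kinds <- c(feature_kinds(data),
             setNames(rep("continuous", ncol(m)), names(m)))
  feature_table(out, kinds = kinds, sample_ids = ids)
}
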