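#' Build a role-labelled PPI graph
#'
#' Constructs an undirected simple graph (self-loops and duplicate edges
#' removed) from a two-column edge list and labels every node as `crosstalk`,
#' `neuropeptide`, or `other`. A gene appearing in both role lists is
#' rejected: the two classes are disjoint by definition.
#'
#' @param edges Data frame whose first two columns are the edge endpoints
#'   (gene symbols).
#' @param crosstalk,neuropeptides Character vectors of gene symbols.
#' @return An \pkg{igraph} graph with vertex attribute `role`.
#' @export
ppi_graph <- function(edges, crosstalk = character(), neuropeptides = character()) {
  crosstalk <- toupper(crosstalk); neuropeptides <- toupper(neuropeptides)
  both <- intersect(crosstalk, neuropeptides)
  if (length(both)) {
    abort(paste0("genes with both roles: ", paste(head(both, 5), collapse = ", ")))
  }
  el <- cbind(toupper(as.character(edges[[1]])), toupper(as.character(edges[[2]])))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  nm <- igraph::V(g)$name
  role <- rep("other", length(nm))
  role[nm %in% crosstalk] <- "crosstalk"
  role[nm %in% neuropeptides] <- "neuropeptide"
  igraph::V(g)$role <- role
  g
}

#' Direct crosstalk-neuropeptide interaction pairs
#'
#' All edges of the graph joining a crosstalk gene to a neuropeptide gene
#' directly (order of endpoint roles is irrelevant).
#'
#' @param graph A role-labelled graph from [ppi_graph()].
#' @return A tibble `crosstalk`, `neuropeptide`, sorted; zero rows when no
#'   such edge exists.
#' @export
direct_pairs <- function(graph) {
  el <- igraph::as_edgelist(graph)
  role <- setNames(igraph::V(graph)$role, igraph::V(graph)$name)
  if (nrow(el) == 0) return(tibble(crosstalk = character(), neuropeptide = character()))
  r1 <- role[el[, 1]]; r2 <- role[el[, 2]]
  hit_fwd <- r1 == "crosstalk" & r2 == "neuropeptide"
  hit_rev <- r1 == "neuropeptide" & r2 == "crosstalk"
  tibble(
    crosstalk = c(el[hit_fwd, 1], el[hit_rev, 2]),
    neuropeptide = c(el[hit_fwd, 2], el[hit_rev, 1])
  ) |> distinct() |> arrange(.data$crosstalk, .data$neuropeptide)
}

#' One-step bridged crosstalk-neuropeptide pairs
#'
#' Enumerates every path crosstalk--bridge--neuropeptide where the bridge is a
#' node of role `other` adjacent to both endpoints. Returns the unique triples
#' and the subnetwork induced by their edges.
#'
#' @param graph A role-labelled graph from [ppi_graph()].
#' @return A list: `triples` (tibble `crosstalk`, `bridge`, `neuropeptide`,
#'   deterministically ordered) and `subgraph` (igraph; union of the triple
#'   edges).
#' @export
bridge_pairs <- function(graph) {
  role <- setNames(igraph::V(graph)$role, igraph::V(graph)$name)
  bridges <- names(role)[role == "other"]
  rows <- map(sort(bridges), function(b) {
    nb <- igraph::neighbors(graph, b)$name
    cs <- sort(nb[role[nb] == "crosstalk"])
    ns <- sort(nb[role[nb] == "neuropeptide"])
    if (length(cs) == 0 || length(ns) == 0) return(NULL)
    tibble(
      crosstalk = rep(cs, times = length(ns)),
      bridge = b,
      neuropeptide = rep(ns, each = length(cs))
    )
  })
  triples <- list_rbind(rows)
  if (nrow(triples) == 0) {
    triples <- tibble(crosstalk = character(), bridge = character(),
                      neuropeptide = character())
  }
  triples <- distinct(triples) |>
    arrange(.data$crosstalk, .data$bridge, .data$neuropeptide)
  edge_nodes <- unique(c(rbind(triples$crosstalk, triples$bridge),
                         rbind(triples$bridge, triples$neuropeptide)))
  if (nrow(triples) > 0) {
    el <- rbind(cbind(triples$crosstalk, triples$bridge),
                cbind(triples$bridge, triples$neuropeptide))
    sub <- igraph::simplify(igraph::graph_from_edgelist(unique(el), directed = FALSE))
    nm <- igraph::V(sub)$name
    igraph::V(sub)$role <- role[nm]
  } else {
    sub <- igraph::make_empty_graph(0, directed = FALSE)
  }
  list(triples = triples, subgraph = sub)
}

# Cytoscape topological coefficient: for node n with degree k(n), average over
# all nodes m (m != n) sharing at least one neighbor with n of
# J(n,m)/k(n), J(n,m) = |shared neighbors| + 1 if m adjacent to n.
topological_coefficient <- function(graph) {
  nm <- igraph::V(graph)$name
  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  deg <- rowSums(adj)
  shared <- adj %*% adj        # shared-neighbor counts
  n <- length(nm)
  tc <- numeric(n)
  for (i in seq_len(n)) {
    if (deg[i] == 0) next
    partners <- which(shared[i, ] > 0)
    partners <- partners[partners != i]
    if (length(partners) == 0) next
    j <- shared[i, partners] + adj[i, partners]
    tc[i] <- mean(j / deg[i])
  }
  setNames(tc, nm)
}

#' Node topology metrics
#'
#' Degree, average shortest path length, normalized betweenness, closeness
#' and the Cytoscape topological coefficient for every node, sorted by degree
#' in descending order. On disconnected graphs unreachable pairs are excluded
#' from the path-based averages (closeness = reachable count / sum of
#' distances to reachable nodes); betweenness is normalized by
#' `2 / ((N-1)(N-2))`.
#'
#' @param graph A role-labelled graph from [ppi_graph()] (any igraph works;
#'   missing roles are reported as `other`).
#' @param top_n Optionally keep only the `top_n` highest-degree rows.
#' @return A tibble `node`, `role`, `degree`, `avg_shortest_path`,
#'   `betweenness`, `closeness`, `topological_coefficient`.
#' @export
topology_metrics <- function(graph, top_n = NULL) {
  if (igraph::vcount(graph) == 0) abort("empty graph.")
  nm <- igraph::V(graph)$name
  role <- igraph::V(graph)$role %||% rep("other", length(nm))
  deg <- igraph::degree(graph)
  n <- length(nm)
  btw <- if (n > 2) {
    igraph::betweenness(graph, directed = FALSE, normalized = TRUE)
  } else {
    setNames(numeric(n), nm)
  }
  d <- igraph::distances(graph)
  diag(d) <- Inf
  avg_sp <- apply(d, 1, function(row) {
    reach <- row[is.finite(row)]
    if (length(reach) == 0) NA_real_ else mean(reach)
  })
  clo <- apply(d, 1, function(row) {
    reach <- row[is.finite(row)]
    if (length(reach) == 0) 0 else length(reach) / sum(reach)
  })
  tc <- topological_coefficient(graph)
  tibble(
    node = nm, role = role, degree = as.numeric(deg),
    avg_shortest_path = as.numeric(avg_sp),
    betweenness = as.numeric(btw),
    closeness = as.numeric(clo),
    topological_coefficient = as.numeric(tc)
  ) |>
    arrange(desc(.data$degree), .data$node) |>
    (\(x) if (is.null(top_n)) x else head(x, top_n))()
}

#' Tripartite crosstalk-pathway-neuropeptide network
#'
#' Keeps each pathway containing at least one crosstalk gene and one
#' neuropeptide, and emits edges crosstalk -> pathway and pathway ->
#' neuropeptide for the members.
#'
#' @param crosstalk,neuropeptides Character vectors of gene symbols.
#' @param pathways Named list of gene sets (see [read_gmt()]).
#' @return A tibble `from`, `to`, `edge_type`
#'   (`"crosstalk-pathway"` / `"pathway-neuropeptide"`).
#' @export
shared_pathway_network <- function(crosstalk, neuropeptides, pathways) {
  crosstalk <- toupper(crosstalk); neuropeptides <- toupper(neuropeptides)
  rows <- imap(pathways, function(members, name) {
    members <- toupper(members)
    cs <- sort(intersect(members, crosstalk))
    ns <- sort(intersect(members, neuropeptides))
    if (length(cs) == 0 || length(ns) == 0) return(NULL)
    bind_rows(
      tibble(from = cs, to = name, edge_type = "crosstalk-pathway"),
      tibble(from = name, to = ns, edge_type = "pathway-neuropeptide")
    )
  })
  out <- list_rbind(rows)
  if (nrow(out) == 0) {
    out <- tibble(from = character(), to = character(), edge_type = character())
  }
  out
}

#' Write a graph in GraphML for Cytoscape import
#'
#' @param graph An igraph object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
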