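# PPI network pruning, degree / betweenness topology, hub and bottleneck
# classification, and the quadratic degree-betweenness fit.

#' Build the pruned giant component of a PPI network
#'
#' Drops self-loop edges and duplicate pairs, optionally restricts the
#' network to a tissue-expressed gene list first, and keeps only the largest
#' connected component, discarding isolated nodes and small components.
#'
#' @param edges a data frame / matrix with two columns of node identifiers
#'   (as from [read_edge_list()]), or an igraph object.
#' @param node_filter optional character vector; only edges with both
#'   endpoints in this list are kept (e.g. hippocampus-expressed genes).
#' @param min_component_size alternative pruning rule: keep all components
#'   with at least this many nodes instead of only the largest one.  The
#'   result is then possibly disconnected; betweenness requires the default
#'   giant-component rule.
#' @return an undirected simple igraph object.
#' @export
build_giant_component <- function(edges, node_filter = NULL,
                                  min_component_size = NULL) {
  if (igraph::is_igraph(edges)) {
    g <- igraph::as_undirected(edges, mode = "collapse")
  } else {
    em <- as.matrix(edges[, 1:2])
    if (nrow(em) == 0) stop("empty edge list", call. = FALSE)
    mode(em) <- "character"
    if (!is.null(node_filter)) {
      node_filter <- trimws(node_filter)
      keep <- em[, 1] %in% node_filter & em[, 2] %in% node_filter
      em <- em[keep, , drop = FALSE]
    }
    if (nrow(em) == 0)
      stop("no edges remain after applying the node filter", call. = FALSE)
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (igraph::vcount(g) == 0) stop("empty graph after pruning", call. = FALSE)
  comp <- igraph::components(g)
  if (is.null(min_component_size)) {
    keep_ids <- which(comp$membership == which.max(comp$csize))
  } else {
    big <- which(comp$csize >= min_component_size)
    if (!length(big))
      stop("no component reaches min_component_size = ", min_component_size,
           call. = FALSE)
    keep_ids <- which(comp$membership %in% big)
  }
  igraph::induced_subgraph(g, keep_ids)
}

#' Per-node degree and betweenness centrality
#'
#' Degree is the number of distinct neighbors.  Betweenness is shortest-path
#' betweenness with endpoints excluded, normalized by (n-1)(n-2)/2 so values
#' lie in \[0, 1\] (the scale on which the bottleneck threshold 5e-4 is
#' meaningful); set `normalized = FALSE` for raw path counts.
#'
#' @param net a connected pruned igraph network (see
#'   [build_giant_component()]).
#' @param normalized logical; normalize betweenness to \[0, 1\].
#' @return a data frame `node`, `degree`, `betweenness`.
#' @export
node_topology <- function(net, normalized = TRUE) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0) stop("empty graph", call. = FALSE)
  if (igraph::components(net)$no > 1)
    stop("network is disconnected; prune to the giant component first",
         call. = FALSE)
  deg <- igraph::degree(net)
  n <- igraph::vcount(net)
  btw <- igraph::betweenness(net, directed = FALSE)
  if (normalized && n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)
  nm <- igraph::V(net)$name %||% as.character(seq_len(n))
  data.frame(node = nm, degree = as.integer(deg),
             betweenness = as.numeric(btw),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify hubs and high-betweenness bottlenecks
#'
#' Strict thresholds: a hub has degree strictly greater than
#' `hub_threshold`; a bottleneck has normalized betweenness strictly greater
#' than `bc_threshold`.
#'
#' @param topo data frame from [node_topology()].
#' @param hub_threshold degree threshold (default 50).
#' @param bc_threshold normalized betweenness threshold (default 5e-4).
#' @return `topo` with logical columns `is_hub`, `is_bottleneck` added.
#' @export
classify_hubs_bottlenecks <- function(topo, hub_threshold = 50,
                                      bc_threshold = 5e-4) {
  stopifnot(all(c("degree", "betweenness") %in% names(topo)))
  topo$is_hub <- topo$degree > hub_threshold
  topo$is_bottleneck <- topo$betweenness > bc_threshold
  topo
}

#' Quadratic fit of betweenness on degree
#'
#' Least-squares fit of betweenness as a second-degree polynomial in degree,
#' b = c0 + c1 k + c2 k^2.  `r` is the Pearson correlation between observed
#' and fitted betweenness (the square root of the fit's coefficient of
#' determination); `r_linear` is the plain Pearson correlation of degree and
#' betweenness, reported alongside because the two summaries can differ on
#' heavy-tailed networks.
#'
#' @param topo data frame from [node_topology()] (>= 10 nodes).
#' @return a list with `coefficients` (c0, c1, c2), `r`, `r_linear`, and the
#'   underlying `lm` fit.
#' @export
fit_degree_betweenness <- function(topo) {
  stopifnot(all(c("degree", "betweenness") %in% names(topo)))
  if (nrow(topo) < 10)
    stop("need at least 10 nodes for the degree-betweenness fit",
         call. = FALSE)
  k <- topo$degree
  b <- topo$betweenness
  if (length(unique(k)) == 1)
    stop("all degrees are equal; fit is degenerate", call. = FALSE)
  fit <- lm(b ~ k + I(k^2))
  fv <- fitted(fit)
  r <- if (sd(fv) == 0 || sd(b) == 0) 0 else cor(b, fv)
  list(
    coefficients = stats::setNames(as.numeric(coef(fit)), c("c0", "c1", "c2")),
    r = as.numeric(r),
    r_linear = as.numeric(cor(k, b)),
    fit = fit
  )
}

#' Attach topology attributes to a network
#'
#' Convenience: stores degree, betweenness, and hub/bottleneck flags as node
#' attributes so that [export_graphml()] carries them.
#'
#' @param net igraph network.
#' @param topo classified topology table ([classify_hubs_bottlenecks()]).
#' @return the igraph object with node attributes set.
#' @export
annotate_topology <- function(net, topo) {
  idx <- match(igraph::V(net)$name, topo$node)
  igraph::V(net)$degree <- topo$degree[idx]
  igraph::V(net)$betweenness <- topo$betweenness[idx]
  if (!is.null(topo$is_hub)) igraph::V(net)$is_hub <- topo$is_hub[idx]
  if (!is.null(topo$is_bottleneck))
    igraph::V(net)$is_bottleneck <- topo$is_bottleneck[idx]
  net
}
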