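# Inter-process statistics: stage-share coordinates, the three-space
# expression distance, inter-process PPI counts, and the dual-edge process
# link graph (solid = co-expression, dashed = PPI link).

#' Stage-share coordinates of retained processes
#'
#' For each process, the coordinates (x, y, z) are its shares of the
#' per-stage totals of aberrantly expressed genes: x = early count / early
#' total, y = medium count / medium total, z = late count / late total,
#' where each total is the sum over all retained processes at that stage.
#' By construction the shares at each stage sum to 1 across processes.
#'
#' @param counts a `stage_count_table` (or data frame with columns `process`,
#'   `early`, `medium`, `late`).
#' @return a data frame of class `process_stage_profile`: the input columns
#'   plus `x`, `y`, `z` and rounded display percentages `pct_early`,
#'   `pct_medium`, `pct_late` (one decimal, half away from zero).  The
#'   per-stage totals are kept in `attr(, "totals")`.
#' @export
stage_share_coordinates <- function(counts) {
  stopifnot(all(c("process", STAGE_LABELS) %in% names(counts)))
  totals <- colSums(counts[STAGE_LABELS])
  if (any(totals == 0))
    stop("per-stage total is zero for stage(s): ",
         paste(STAGE_LABELS[totals == 0], collapse = ", "), call. = FALSE)
  out <- as.data.frame(counts)
  out$x <- out$early / totals[["early"]]
  out$y <- out$medium / totals[["medium"]]
  out$z <- out$late / totals[["late"]]
  out$pct_early <- round_half_away(100 * out$x, 1)
  out$pct_medium <- round_half_away(100 * out$y, 1)
  out$pct_late <- round_half_away(100 * out$z, 1)
  attr(out, "totals") <- totals
  class(out) <- c("process_stage_profile", "data.frame")
  out
}

#' Expression distance between two processes
#'
#' Euclidean distance between two processes' stage-share coordinates,
#' treating (x, y, z) as a point in three-space.  Distances below 0.20
#' conventionally mark a coordinated expression trend.
#'
#' @param a,b numeric length-3 coordinate vectors, or single rows of a
#'   `process_stage_profile`.
#' @return the distance (a non-negative scalar).
#' @export
expression_distance <- function(a, b) {
  a <- profile_coords(a)
  b <- profile_coords(b)
  sqrt(sum((a - b)^2))
}

profile_coords <- function(p) {
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1, all(c("x", "y", "z") %in% names(p)))
    p <- c(p$x, p$y, p$z)
  }
  p <- as.numeric(p)
  if (length(p) != 3) stop("a stage-share coordinate has 3 components",
                           call. = FALSE)
  p
}

#' Pairwise expression distances
#'
#' @param profiles a `process_stage_profile` data frame.
#' @return a symmetric matrix of pairwise expression distances with process
#'   names as dimnames.
#' @export
process_distances <- function(profiles) {
  stopifnot(all(c("process", "x", "y", "z") %in% names(profiles)))
  m <- as.matrix(dist(profiles[, c("x", "y", "z")], method = "euclidean"))
  dimnames(m) <- list(profiles$process, profiles$process)
  m
}

#' Count PPI edges bridging two processes
#'
#' Number of network edges with one endpoint annotated to process A and the
#' other to process B (in either orientation), each physical edge counted
#' once.  Edges whose both endpoints lie in the shared membership A
#' intersect B are counted once by default (`shared = "count_once"`); set
#' `shared = "drop"` to exclude them.
#'
#' @param net a pruned igraph network.
#' @param set_a,set_b character vectors of member genes.
#' @param shared policy for edges internal to the shared membership.
#' @return integer edge count.
#' @export
count_interprocess_ppis <- function(net, set_a, set_b,
                                    shared = c("count_once", "drop")) {
  shared <- match.arg(shared)
  if (!length(set_a) || !length(set_b))
    stop("both gene sets must be nonempty", call. = FALSE)
  el <- igraph::as_edgelist(net, names = TRUE)
  u <- el[, 1]; v <- el[, 2]
  cross <- (u %in% set_a & v %in% set_b) | (u %in% set_b & v %in% set_a)
  if (shared == "drop") {
    both <- intersect(set_a, set_b)
    cross <- cross & !(u %in% both & v %in% both)
  }
  sum(cross)
}

#' Build the process link graph
#'
#' Nodes are the retained processes (with an up/down direction attribute
#' when available); a pair is joined by a solid edge when its expression
#' distance is strictly below `d_threshold` (coordinated expression trend)
#' and by a dashed edge when the number of PPIs bridging the two processes
#' is strictly above `ppi_threshold` (strong functional link).  Both edge
#' types may coexist between a pair.
#'
#' @param profiles a `process_stage_profile` data frame (optionally with a
#'   `direction` column).
#' @param net optional pruned igraph network; required unless `ppi_counts`
#'   is given.
#' @param process_sets optional named list mapping process name to member
#'   genes; required with `net`.
#' @param d_threshold solid-edge distance threshold (default 0.20).
#' @param ppi_threshold dashed-edge PPI-count threshold (default 20).
#' @param distances optional precomputed distance matrix
#'   ([process_distances()]).
#' @param ppi_counts optional precomputed symmetric matrix of inter-process
#'   PPI counts.
#' @return an igraph object with node attribute `direction` (when
#'   available) and edge attributes `type` (`"solid"`/`"dashed"`) and
#'   `weight` (the distance or the PPI count).
#' @export
build_process_link_graph <- function(profiles, net = NULL,
                                     process_sets = NULL,
                                     d_threshold = 0.20, ppi_threshold = 20,
                                     distances = NULL, ppi_counts = NULL) {
  procs <- profiles$process
  if (is.null(distances)) distances <- process_distances(profiles)
  if (is.null(ppi_counts)) {
    if (!is.null(net) && !is.null(process_sets)) {
      ppi_counts <- matrix(0L, length(procs), length(procs),
                           dimnames = list(procs, procs))
      if (length(procs) >= 2) {
        for (i in seq_len(length(procs) - 1)) for (j in (i + 1):length(procs)) {
          cnt <- count_interprocess_ppis(net, process_sets[[procs[i]]],
                                         process_sets[[procs[j]]])
          ppi_counts[i, j] <- ppi_counts[j, i] <- cnt
        }
      }
    }
  }
  from <- character(0); to <- character(0)
  type <- character(0); weight <- numeric(0)
  if (length(procs) >= 2) {
    for (i in seq_len(length(procs) - 1)) for (j in (i + 1):length(procs)) {
      d <- distances[procs[i], procs[j]]
      if (d < d_threshold) {
        from <- c(from, procs[i]); to <- c(to, procs[j])
        type <- c(type, "solid"); weight <- c(weight, d)
      }
      if (!is.null(ppi_counts)) {
        cnt <- ppi_counts[procs[i], procs[j]]
        if (cnt > ppi_threshold) {
          from <- c(from, procs[i]); to <- c(to, procs[j])
          type <- c(type, "dashed"); weight <- c(weight, cnt)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(procs), name = procs)
  if (!is.null(profiles$direction))
    igraph::V(g)$direction <- profiles$direction
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(match(from, procs), match(to, procs)),
                           type = type, weight = weight)
  }
  g
}
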