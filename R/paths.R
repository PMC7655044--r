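#' Build a cascade object from an explicit DAG
#'
#' Utility for constructing a \code{cascade_result} directly from a causal
#' edge list (e.g. a worked example or an imported cascade) rather than
#' from an ALT run.
#'
#' @param sources character vector of source node names.
#' @param edges data.frame with character columns \code{src}, \code{tgt};
#'   must be acyclic.
#' @param nodes optional node universe (defaults to the nodes appearing in
#'   \code{sources} and \code{edges}); its order is the tie-breaking order
#'   used by the greedy tau-core.
#' @return A \code{cascade_result}.
#' @export
cascade_from_dag <- function(sources, edges, nodes = NULL) {
  sources <- as.character(sources)
  edges <- data.frame(src = as.character(edges$src),
                      tgt = as.character(edges$tgt),
                      stringsAsFactors = FALSE)
  involved <- unique(c(sources, edges$src, edges$tgt))
  if (is.null(nodes)) nodes <- involved
  if (!all(involved %in% nodes))
    stop("edges refer to nodes outside the node universe", call. = FALSE)
  .topo_order(nodes, edges)   # errors on cycles
  ta <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  ta[involved] <- NA  # times unknown for hand-built DAGs
  structure(list(sources = sources, activation_time = ta, dag = edges,
                 nodes = nodes, complete = NA, theta = NA_real_),
            class = "cascade_result")
}

#' Bundle cascades from distinct sources into a collection
#'
#' @param ... \code{cascade_result} objects, or a single list of them.
#' @return A list of class \code{cascade_collection}.
#' @export
cascade_collection <- function(...) {
  casc <- list(...)
  if (length(casc) == 1 && !inherits(casc[[1]], "cascade_result"))
    casc <- casc[[1]]
  if (!all(vapply(casc, inherits, logical(1), "cascade_result")))
    stop("all elements must be cascade_result objects", call. = FALSE)
  keys <- vapply(casc, function(x) paste(sort(x$sources), collapse = "+"),
                 character(1))
  if (anyDuplicated(keys))
    stop("cascade sources must be distinct", call. = FALSE)
  structure(casc, class = "cascade_collection")
}

# Kahn topological order over `nodes` restricted to `edges`; errors on cycles.
.topo_order <- function(nodes, edges) {
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  indeg <- integer(n)
  out <- vector("list", n)
  if (nrow(edges)) {
    si <- idx[edges$src]; ti <- idx[edges$tgt]
    tb <- tabulate(ti, nbins = n)
    indeg <- tb
    out <- split(ti, factor(si, levels = seq_len(n)))
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (w in out[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) != n)
    stop("input graph is not acyclic", call. = FALSE)
  nodes[order]
}

.check_count <- function(x) {
  if (any(x > 2^53))
    stop("path count exceeds 2^53; exact integer arithmetic in doubles ",
         "is no longer guaranteed", call. = FALSE)
  x
}

# Core path-count dynamic program on one cascade DAG.
# f(v): number of source->v paths; g(v): number of v->terminal paths, where
# `terminals` is a fixed target set (the DAG's own sinks by default).
# `deleted` nodes are removed together with incident edges before counting,
# but `terminals` keeps its original meaning, so no newly exposed dead end
# ever counts as a path target. Paths must contain at least one edge: a
# source with no outgoing edges is not a terminal and contributes no paths.
.path_dp <- function(cascade, deleted = character(0), terminals = NULL) {
  edges <- cascade$dag
  sources <- cascade$sources
  involved <- unique(c(sources, edges$src, edges$tgt))
  if (is.null(terminals)) {
    terminals <- setdiff(involved, edges$src)        # no outgoing edge
    terminals <- setdiff(terminals, setdiff(sources, edges$tgt))
  }
  keep_nodes <- setdiff(involved, deleted)
  e <- edges[edges$src %in% keep_nodes & edges$tgt %in% keep_nodes, ,
             drop = FALSE]
  ord <- .topo_order(keep_nodes, e)
  f <- stats::setNames(numeric(length(keep_nodes)), keep_nodes)
  g <- f
  f[intersect(sources, keep_nodes)] <- 1
  in_by <- split(e$src, factor(e$tgt, levels = ord))
  out_by <- split(e$tgt, factor(e$src, levels = ord))
  for (v in ord) {
    ins <- in_by[[v]]
    if (length(ins)) f[v] <- f[v] + sum(f[ins])
  }
  term_here <- intersect(terminals, keep_nodes)
  g[term_here] <- 1
  for (v in rev(ord)) {
    outs <- out_by[[v]]
    if (length(outs)) g[v] <- g[v] + sum(g[outs])
  }
  .check_count(f); .check_count(g)
  list(nodes = keep_nodes, f = f, g = g, through = .check_count(f * g),
       total = sum(f[term_here]), terminals = terminals)
}

#' Count source-target paths in a cascade DAG
#'
#' A source-target path starts at a cascade source and ends at a terminal
#' (a node with no outgoing causal edges); it must contain at least one
#' edge, so a cascade that activates only its source has zero paths.
#' Counts are computed exactly by dynamic programming in topological
#' order; in a multi-source cascade each source seeds one unit of path
#' mass.
#'
#' @param cascade a \code{cascade_result} (from \code{\link{run_alt}} or
#'   \code{\link{cascade_from_dag}}).
#' @return A list of class \code{path_stats} with per-node \code{f}
#'   (source-to-node path counts), \code{g} (node-to-terminal counts),
#'   \code{through = f * g}, the \code{total} path count and the
#'   \code{terminals}.
#' @export
count_paths <- function(cascade) {
  stopifnot(inherits(cascade, "cascade_result"))
  structure(.path_dp(cascade), class = "path_stats")
}

.collection_node_order <- function(coll) {
  unique(unlist(lapply(coll, function(x) x$nodes)))
}

#' Path centrality over a collection of cascades
#'
#' P(v) is the fraction of all source-target paths, pooled across all
#' cascades in the collection, that traverse node v. Within its own
#' cascade a source is traversed by every path, but its pooled centrality
#' can still be low.
#'
#' @param coll a \code{\link{cascade_collection}} (or list of cascades).
#' @return A list of class \code{path_centrality}: \code{centrality}
#'   (named vector P(v)), \code{paths_through} (pooled counts),
#'   \code{total_paths}, and \code{per_cascade} totals.
#' @export
path_centrality <- function(coll) {
  if (!inherits(coll, "cascade_collection")) coll <- cascade_collection(coll)
  nodes <- .collection_node_order(coll)
  through <- stats::setNames(numeric(length(nodes)), nodes)
  totals <- numeric(length(coll))
  for (k in seq_along(coll)) {
    dp <- .path_dp(coll[[k]])
    through[dp$nodes] <- through[dp$nodes] + dp$through
    totals[k] <- dp$total
  }
  if (sum(totals) == 0)
    stop("all cascades are degenerate (zero source-target paths)",
         call. = FALSE)
  structure(list(centrality = through / sum(totals),
                 paths_through = through,
                 total_paths = sum(totals), per_cascade = totals),
            class = "path_centrality")
}

#' @export
print.path_centrality <- function(x, ...) {
  top <- sort(x$centrality, decreasing = TRUE)
  top <- utils::head(top, 5)
  cat(sprintf("<path centrality> %g source-target paths over %d cascades\n",
              x$total_paths, length(x$per_cascade)))
  cat("  top nodes:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Greedy tau-core of a cascade collection
#'
#' The tau-core is a (greedily approximated) minimal node set that jointly
#' covers at least a fraction tau of all source-target paths across the
#' collection — the "waist" of the hourglass when it is small. Each
#' iteration selects the node traversed by the most not-yet-covered paths;
#' that node is then deleted from every cascade DAG and the remaining
#' paths are recounted, always against the ORIGINAL terminal set, so
#' deletions never create spurious new path targets. Ties are broken
#' towards the node appearing earliest in the collection's node order.
#' Sources are eligible by default.
#'
#' @param coll a \code{\link{cascade_collection}}.
#' @param tau target coverage fraction in (0, 1].
#' @param exclude_sources if TRUE, source nodes cannot join the core.
#' @return A list of class \code{tau_core_result}: \code{tau},
#'   \code{members} (in selection order), \code{marginal_coverage},
#'   \code{cumulative_coverage}, \code{attained}, \code{total_paths}.
#' @export
tau_core <- function(coll, tau = 0.9, exclude_sources = FALSE) {
  if (!inherits(coll, "cascade_collection")) coll <- cascade_collection(coll)
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) ||
      tau <= 0 || tau > 1)
    stop("tau must be a scalar in (0, 1]", call. = FALSE)
  nodes <- .collection_node_order(coll)
  base <- lapply(coll, .path_dp)
  terminals <- lapply(base, `[[`, "terminals")
  total0 <- sum(vapply(base, `[[`, numeric(1), "total"))
  if (total0 == 0)
    stop("collection has no source-target paths", call. = FALSE)
  banned <- if (exclude_sources)
    unique(unlist(lapply(coll, `[[`, "sources"))) else character(0)

  deleted <- character(0)
  members <- character(0)
  marginal <- numeric(0)
  covered <- 0
  repeat {
    through <- stats::setNames(numeric(length(nodes)), nodes)
    for (k in seq_along(coll)) {
      dp <- .path_dp(coll[[k]], deleted = deleted,
                     terminals = terminals[[k]])
      through[dp$nodes] <- through[dp$nodes] + dp$through
    }
    through[banned] <- 0
    through[deleted] <- 0
    if (max(through) <= 0) break
    pick <- nodes[which.max(through)]   # first max = earliest in node order
    deleted <- c(deleted, pick)
    members <- c(members, pick)
    marginal <- c(marginal, through[[pick]])
    covered <- covered + through[[pick]]
    if (covered / total0 >= tau - 1e-12) break
  }
  cum <- cumsum(marginal) / total0
  structure(list(tau = tau, members = members,
                 marginal_coverage = marginal / total0,
                 cumulative_coverage = cum,
                 attained = length(cum) > 0 && cum[length(cum)] >= tau - 1e-12,
                 total_paths = total0),
            class = "tau_core_result")
}

#' @export
print.tau_core_result <- function(x, ...) {
  cat(sprintf("<tau-core> tau = %.2f: %d member(s)%s\n", x$tau,
              length(x$members),
              if (isTRUE(x$attained)) "" else " (target not attained)"))
  if (length(x$members))
    cat("  ", paste(sprintf("%s (+%.1f%%)", x$members,
                            100 * x$marginal_coverage), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Cumulative greedy path-coverage curve
#'
#' Runs the greedy tau-core to full coverage and reports the cumulative
#' fraction of source-target paths covered by the top 1..n greedy nodes.
#' The curve is nondecreasing and reaches 1 at or before n nodes; entries
#' beyond full coverage are padded with 1.
#'
#' @param coll a \code{\link{cascade_collection}}.
#' @param exclude_sources passed to \code{\link{tau_core}}.
#' @return data.frame with columns \code{size}, \code{node} (NA in the
#'   padded tail) and \code{coverage}.
#' @export
coverage_curve <- function(coll, exclude_sources = FALSE) {
  if (!inherits(coll, "cascade_collection")) coll <- cascade_collection(coll)
  core <- tau_core(coll, tau = 1, exclude_sources = exclude_sources)
  n <- length(.collection_node_order(coll))
  k <- length(core$members)
  data.frame(
    size = seq_len(n),
    node = c(core$members, rep(NA_character_, n - k)),
    coverage = c(core$cumulative_coverage,
                 rep(if (k) core$cumulative_coverage[k] else 0, n - k)))
}
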