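#' Construct a directed weighted spatial connectome
#'
#' A connectome is a directed graph whose nodes are brain regions of interest
#' (ROIs) with 3D centroids (mm), volumes (mm^3), an anatomical class
#' (cortical/subcortical) and a sensory-source flag, and whose edges carry a
#' connection-density weight, a statistical confidence p-value, a Euclidean
#' length (mm) and a communication delay. The delay of every edge is
#' \code{conduction_factor * length_mm}; the factor is in time units per mm,
#' so with the default 1 the delays equal the lengths and all activation
#' times are in the same arbitrary time unit (relative orderings are
#' invariant to the factor).
#'
#' @param nodes data.frame with columns \code{acronym} (unique, the join key),
#'   \code{x_mm}, \code{y_mm}, \code{z_mm}; optionally \code{name},
#'   \code{region_class} ("cortical"/"subcortical", default cortical),
#'   \code{volume_mm3} (> 0, default 1) and \code{is_source} (default FALSE).
#' @param edges data.frame with columns \code{src}, \code{tgt} (acronyms),
#'   \code{weight} (>= 0), \code{p_value} (in [0,1]); optionally
#'   \code{length_mm} (> 0). Missing lengths are computed from centroids.
#' @param conduction_factor positive scalar, time units per mm.
#' @return An object of class \code{connectome}: a list with elements
#'   \code{nodes}, \code{edges} (with \code{delay} column) and
#'   \code{conduction_factor}.
#' @export
connectome <- function(nodes, edges, conduction_factor = 1) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (!is.numeric(conduction_factor) || length(conduction_factor) != 1 ||
      !is.finite(conduction_factor) || conduction_factor <= 0)
    stop("conduction_factor must be a positive scalar", call. = FALSE)

  need_n <- c("acronym", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need_n, names(nodes))
  if (length(miss)) stop("node table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  nodes$acronym <- as.character(nodes$acronym)
  if (anyDuplicated(nodes$acronym))
    stop("node acronyms must be unique", call. = FALSE)
  if (is.null(nodes$name)) nodes$name <- nodes$acronym
  if (is.null(nodes$region_class)) nodes$region_class <- "cortical"
  nodes$region_class <- as.character(nodes$region_class)
  if (!all(nodes$region_class %in% c("cortical", "subcortical")))
    stop("region_class must be 'cortical' or 'subcortical'", call. = FALSE)
  if (is.null(nodes$volume_mm3)) nodes$volume_mm3 <- 1
  if (any(!is.finite(nodes$volume_mm3)) || any(nodes$volume_mm3 <= 0))
    stop("node volumes must be finite and > 0", call. = FALSE)
  if (is.null(nodes$is_source)) nodes$is_source <- FALSE
  nodes$is_source <- as.logical(nodes$is_source)
  cent <- as.matrix(nodes[, c("x_mm", "y_mm", "z_mm")])
  if (!all(is.finite(cent)))
    stop("node centroids must be finite", call. = FALSE)

  need_e <- c("src", "tgt", "weight", "p_value")
  miss <- setdiff(need_e, names(edges))
  if (length(miss)) stop("edge table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  edges$src <- as.character(edges$src)
  edges$tgt <- as.character(edges$tgt)
  bad <- !(edges$src %in% nodes$acronym)
  if (any(bad))
    stop("edge row(s) ", paste(which(bad), collapse = ", "),
         ": unknown source acronym ",
         paste(unique(edges$src[bad]), collapse = ", "), call. = FALSE)
  bad <- !(edges$tgt %in% nodes$acronym)
  if (any(bad))
    stop("edge row(s) ", paste(which(bad), collapse = ", "),
         ": unknown target acronym ",
         paste(unique(edges$tgt[bad]), collapse = ", "), call. = FALSE)
  if (any(edges$src == edges$tgt))
    stop("self-loop edge(s) not allowed: row(s) ",
         paste(which(edges$src == edges$tgt), collapse = ", "), call. = FALSE)
  key <- paste(edges$src, edges$tgt, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate directed edge(s): ",
         paste(unique(sub("\r", " -> ", key[duplicated(key)])),
               collapse = ", "), call. = FALSE)
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0))
    stop("edge weights must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(edges$p_value)) || any(edges$p_value < 0) ||
      any(edges$p_value > 1))
    stop("edge p-values must lie in [0, 1]", call. = FALSE)

  obj <- structure(
    list(nodes = nodes[, c("acronym", "name", "region_class",
                           "x_mm", "y_mm", "z_mm", "volume_mm3", "is_source")],
         edges = edges, conduction_factor = conduction_factor),
    class = "connectome")
  if (is.null(edges$length_mm)) {
    obj <- compute_edge_lengths(obj)
  } else {
    if (any(!is.finite(edges$length_mm)) || any(edges$length_mm <= 0))
      stop("edge lengths must be finite and > 0", call. = FALSE)
    obj$edges$delay <- conduction_factor * obj$edges$length_mm
  }
  rownames(obj$nodes) <- NULL
  rownames(obj$edges) <- NULL
  obj
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d nodes, %d directed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  cat(sprintf("  sources: %d | subcortical: %d | conduction factor: %g\n",
              sum(x$nodes$is_source),
              sum(x$nodes$region_class == "subcortical"),
              x$conduction_factor))
  invisible(x)
}

.read_table_auto <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Load a connectome from node and edge tables
#'
#' Reads comma- or tab-delimited tables (delimiter sniffed from the header
#' line). The node table must have columns
#' \code{acronym,name,region_class,x_mm,y_mm,z_mm,volume_mm3,is_source}
#' (only \code{acronym} and the coordinates are mandatory) and the edge
#' table \code{src_acronym,tgt_acronym,weight,p_value[,length_mm]}
#' (\code{src}/\code{tgt} accepted as synonyms). Edge rows with missing
#' weight or p-value are dropped with a warning; unknown acronyms and
#' duplicate directed edges are errors naming the offending rows.
#'
#' @param node_file,edge_file paths to delimited text files.
#' @param conduction_factor positive scalar, time units per mm.
#' @return A \code{\link{connectome}}.
#' @export
load_connectome <- function(node_file, edge_file, conduction_factor = 1) {
  nodes <- .read_table_auto(node_file)
  edges <- .read_table_auto(edge_file)
  if (!"src" %in% names(edges) && "src_acronym" %in% names(edges))
    edges[["src"]] <- edges[["src_acronym"]]
  if (!"tgt" %in% names(edges) && "tgt_acronym" %in% names(edges))
    edges[["tgt"]] <- edges[["tgt_acronym"]]
  drop <- is.na(edges$weight) | is.na(edges$p_value)
  if (any(drop)) {
    warning(sum(drop), " edge row(s) with missing weight or p-value dropped",
            call. = FALSE)
    edges <- edges[!drop, , drop = FALSE]
  }
  keep <- intersect(c("src", "tgt", "weight", "p_value", "length_mm"),
                    names(edges))
  connectome(nodes, edges[, keep, drop = FALSE], conduction_factor)
}

#' Write a connectome to node and edge CSV tables
#'
#' Inverse of \code{\link{load_connectome}}: the written pair of files
#' round-trips to an identical connectome.
#'
#' @param c a connectome.
#' @param node_file,edge_file output CSV paths.
#' @export
write_connectome <- function(c, node_file, edge_file) {
  stopifnot(inherits(c, "connectome"))
  utils::write.csv(c$nodes, node_file, row.names = FALSE)
  e <- c$edges
  names(e)[names(e) == "src"] <- "src_acronym"
  names(e)[names(e) == "tgt"] <- "tgt_acronym"
  e$delay <- NULL
  utils::write.csv(e, edge_file, row.names = FALSE)
  invisible(c(node_file, edge_file))
}

#' Export a connectome as GraphML
#'
#' @param c a connectome.
#' @param path output .graphml path.
#' @export
export_graphml <- function(c, path) {
  igraph::write_graph(as_igraph(c), path, format = "graphml")
  invisible(path)
}

#' Convert a connectome to an igraph object
#'
#' Vertices carry the node metadata, edges the weight/p-value/length/delay
#' attributes.
#'
#' @param c a connectome.
#' @return An \code{igraph} directed graph.
#' @export
as_igraph <- function(c) {
  stopifnot(inherits(c, "connectome"))
  v <- c$nodes
  names(v)[1] <- "name"     # igraph vertex name
  v$roi_name <- c$nodes$name
  igraph::graph_from_data_frame(c$edges, directed = TRUE, vertices = v)
}

#' Filter connectome edges by statistical confidence
#'
#' Retains exactly the edges with \code{p_value <= alpha} (the boundary
#' value is kept); nodes are untouched, so isolated nodes may remain.
#' Idempotent and monotone in \code{alpha}.
#'
#' @param c a connectome.
#' @param alpha significance threshold in (0, 1]; 0.05 is the conventional
#'   choice for tracer-derived connectivity.
#' @return The filtered connectome.
#' @export
filter_edges_by_pvalue <- function(c, alpha = 0.05) {
  stopifnot(inherits(c, "connectome"))
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha > 1)
    stop("alpha must be a scalar in (0, 1]", call. = FALSE)
  c$edges <- c$edges[c$edges$p_value <= alpha, , drop = FALSE]
  rownames(c$edges) <- NULL
  c
}

#' Recompute edge lengths from node centroids
#'
#' Sets every edge length to the Euclidean distance (mm) between the
#' centroids of its endpoints and refreshes delays via the stored
#' conduction factor. Distinct connected nodes with coincident centroids
#' are an error (they would give a zero, ill-posed delay).
#'
#' @param c a connectome.
#' @return The connectome with updated \code{length_mm} and \code{delay}.
#' @export
compute_edge_lengths <- function(c) {
  stopifnot(inherits(c, "connectome"))
  cent <- as.matrix(c$nodes[, c("x_mm", "y_mm", "z_mm")])
  rownames(cent) <- c$nodes$acronym
  d <- cent[c$edges$src, , drop = FALSE] - cent[c$edges$tgt, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  if (any(len == 0))
    stop("coincident centroids for connected node pair(s): ",
         paste(paste(c$edges$src[len == 0], c$edges$tgt[len == 0],
                     sep = " -> "), collapse = ", "), call. = FALSE)
  c$edges$length_mm <- unname(len)
  c$edges$delay <- c$conduction_factor * c$edges$length_mm
  c
}

# Fagiolo (2007) directed total clustering coefficient per node, from the
# binary adjacency matrix: C_i = [(A + A')^3]_ii / (2 [dtot_i (dtot_i - 1)
# - 2 dbi_i]); nodes with a zero denominator are excluded from the average.
.fagiolo_clustering <- function(A) {
  S <- A + t(A)
  num <- diag(S %*% S %*% S)
  dtot <- rowSums(A) + colSums(A)
  dbi <- diag(A %*% A)
  den <- 2 * (dtot * (dtot - 1) - 2 * dbi)
  ok <- den > 0
  list(per_node = ifelse(ok, num / den, NA_real_),
       mean = if (any(ok)) mean(num[ok] / den[ok]) else NA_real_)
}

#' Summarize a connectome's topology
#'
#' Reports node/edge counts, density m/(n(n-1)), the unweighted directed
#' diameter and mean shortest path in hops (over reachable ordered pairs
#' only, with a flag if any pair is unreachable), in/out-degree statistics,
#' the directed clustering coefficient (Fagiolo 2007, total variant,
#' averaged over nodes with at least one closed-triangle opportunity),
#' weight quantiles and the edge-length range.
#'
#' @param c a nonempty connectome.
#' @return A list of class \code{network_summary}.
#' @export
network_summary <- function(c) {
  stopifnot(inherits(c, "connectome"))
  n <- nrow(c$nodes); m <- nrow(c$edges)
  if (n == 0) stop("connectome has no nodes", call. = FALSE)
  g <- as_igraph(c)
  dmat <- igraph::distances(g, mode = "out", weights = NA)
  off <- dmat[row(dmat) != col(dmat)]
  reach <- is.finite(off)
  A <- matrix(0, n, n, dimnames = list(c$nodes$acronym, c$nodes$acronym))
  if (m > 0) A[cbind(c$edges$src, c$edges$tgt)] <- 1
  cl <- .fagiolo_clustering(A)
  indeg <- colSums(A); outdeg <- rowSums(A)
  structure(list(
    n_nodes = n, n_edges = m,
    density = m / (n * (n - 1)),
    diameter_hops = if (any(reach)) max(off[reach]) else NA_real_,
    mean_shortest_path_hops = if (any(reach)) mean(off[reach]) else NA_real_,
    all_pairs_reachable = all(reach),
    in_degree_mean = mean(indeg),
    in_degree_sd = stats::sd(indeg),
    out_degree_sd = stats::sd(outdeg),
    clustering_coefficient = cl$mean,
    clustering_per_node = cl$per_node,
    weight_quantiles = stats::quantile(c$edges$weight,
                                       c(0, 0.25, 0.5, 0.8, 0.95, 1)),
    length_range = range(c$edges$length_mm)), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<network summary> %d nodes, %d edges, density %.3f\n",
    "  diameter %s hops, mean path %.2f hops%s\n",
    "  in-degree %.1f (sd %.1f), out-degree sd %.1f\n",
    "  directed clustering %.3f; weight q80 %.2f, max %.2f\n",
    "  edge lengths %.2f-%.2f mm\n"),
    x$n_nodes, x$n_edges, x$density,
    format(x$diameter_hops), x$mean_shortest_path_hops,
    if (x$all_pairs_reachable) "" else " (unreachable pairs excluded)",
    x$in_degree_mean, x$in_degree_sd, x$out_degree_sd,
    x$clustering_coefficient, x$weight_quantiles[["80%"]],
    x$weight_quantiles[["100%"]], x$length_range[1], x$length_range[2]))
  invisible(x)
}
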