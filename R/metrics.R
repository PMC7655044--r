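#' Jaccard similarity between two cascade DAGs
#'
#' The ratio of the causal connections shared by two cascades to the total
#' number of distinct causal connections in either: |E_a ∩ E_b| / |E_a ∪ E_b|.
#'
#' @param a,b \code{cascade_result} objects.
#' @return Scalar in [0, 1].
#' @export
jaccard_similarity <- function(a, b) {
  stopifnot(inherits(a, "cascade_result"), inherits(b, "cascade_result"))
  ea <- unique(paste(a$dag$src, a$dag$tgt, sep = "\r"))
  eb <- unique(paste(b$dag$src, b$dag$tgt, sep = "\r"))
  if (length(ea) == 0 && length(eb) == 0)
    stop("both cascades have empty edge sets", call. = FALSE)
  length(intersect(ea, eb)) / length(union(ea, eb))
}

#' Hierarchical clustering of cascades by edge-set similarity
#'
#' Agglomerative clustering of a cascade collection on the distance
#' 1 - Jaccard(edge sets), with average, single (merges the most similar
#' clusters' closest pair) or complete linkage. Merge heights are the
#' linkage distances at each merge.
#'
#' @param coll a \code{\link{cascade_collection}} with >= 2 cascades.
#' @param linkage one of "average", "single", "complete".
#' @return A list of class \code{cascade_dendrogram} with the
#'   \code{hclust} tree, the pairwise \code{similarity} matrix and the
#'   \code{linkage} used. Serialize with
#'   \code{\link{write_dendrogram_newick}}.
#' @export
cascade_dendrogram <- function(coll, linkage = c("average", "single",
                                                 "complete")) {
  linkage <- match.arg(linkage)
  if (!inherits(coll, "cascade_collection")) coll <- cascade_collection(coll)
  if (length(coll) < 2) stop("need at least 2 cascades", call. = FALSE)
  labs <- vapply(coll, function(x) paste(x$sources, collapse = "+"),
                 character(1))
  n <- length(coll)
  sim <- diag(1, n)
  dimnames(sim) <- list(labs, labs)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    sim[i, j] <- sim[j, i] <- jaccard_similarity(coll[[i]], coll[[j]])
  hc <- stats::hclust(stats::as.dist(1 - sim), method = linkage)
  structure(list(hclust = hc, similarity = sim, linkage = linkage),
            class = "cascade_dendrogram")
}

#' Write a cascade dendrogram as Newick
#'
#' Branch lengths encode the merge heights (1 - similarity at merge).
#'
#' @param dend a \code{cascade_dendrogram}.
#' @param path output .nwk path.
#' @export
write_dendrogram_newick <- function(dend, path) {
  stopifnot(inherits(dend, "cascade_dendrogram"))
  ape::write.tree(ape::as.phylo(dend$hclust), file = path)
  invisible(path)
}

#' Hop distance of every node from the cascade source
#'
#' Unweighted shortest-path (BFS) distance from the cascade's source(s)
#' within the causal DAG; sources are at distance 0, nodes outside the
#' cascade are NA.
#'
#' @param cascade a \code{cascade_result}.
#' @return Named integer vector over the cascade's node universe.
#' @export
source_distance <- function(cascade) {
  stopifnot(inherits(cascade, "cascade_result"))
  dist <- stats::setNames(rep(NA_integer_, length(cascade$nodes)),
                          cascade$nodes)
  dist[cascade$sources] <- 0L
  frontier <- cascade$sources
  d <- 0L
  out_by <- split(cascade$dag$tgt, cascade$dag$src)
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(out_by[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Downstream influence of every node in a cascade
#'
#' The number of nodes reachable from each node within the causal DAG,
#' including the node itself; a terminal has influence 1 and a source's
#' influence equals the number of activated nodes it reaches. Nodes
#' outside the cascade are NA.
#'
#' @param cascade a \code{cascade_result}.
#' @return Named numeric vector over the cascade's node universe.
#' @export
influence <- function(cascade) {
  stopifnot(inherits(cascade, "cascade_result"))
  involved <- unique(c(cascade$sources, cascade$dag$src, cascade$dag$tgt))
  ord <- .topo_order(involved, cascade$dag)
  n <- length(involved)
  reach <- matrix(FALSE, n, n, dimnames = list(involved, involved))
  diag(reach) <- TRUE
  out_by <- split(cascade$dag$tgt, cascade$dag$src)
  for (v in rev(ord)) {
    outs <- out_by[[v]]
    if (length(outs) == 1) {
      reach[v, ] <- reach[v, ] | reach[outs, ]
    } else if (length(outs) > 1) {
      reach[v, ] <- reach[v, ] | (colSums(reach[outs, , drop = FALSE]) > 0)
    }
  }
  res <- stats::setNames(rep(NA_real_, length(cascade$nodes)),
                         cascade$nodes)
  res[involved] <- rowSums(reach)
  res
}

#' Classify cascade paths by cortico-subcortical crossings
#'
#' Every source-target path is labelled by how it interacts with the
#' cortical/subcortical boundary: \code{C} — entirely cortical;
#' \code{CS} — crosses the boundary exactly once and terminates
#' subcortically; \code{CSC_plus} — crosses at least twice and returns to
#' terminate in cortex; everything else (e.g. crossing twice or more yet
#' ending subcortically) is reported separately as \code{residual}. The
#' four counts partition the total exactly. Counting is done by dynamic
#' programming over (node, capped crossing count) states, never by path
#' enumeration.
#'
#' @param cascade a \code{cascade_result}.
#' @param region_class named character vector ("cortical"/"subcortical")
#'   covering every node of the cascade DAG.
#' @return List with counts \code{C}, \code{CS}, \code{CSC_plus},
#'   \code{residual} and \code{total}.
#' @export
classify_paths <- function(cascade, region_class) {
  stopifnot(inherits(cascade, "cascade_result"))
  edges <- cascade$dag
  involved <- unique(c(cascade$sources, edges$src, edges$tgt))
  missing <- setdiff(involved, names(region_class))
  if (length(missing))
    stop("unclassified node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cls <- region_class[involved]
  if (!all(cls %in% c("cortical", "subcortical")))
    stop("region_class values must be 'cortical' or 'subcortical'",
         call. = FALSE)
  dp <- .path_dp(cascade)
  terminals <- intersect(dp$terminals, involved)
  ord <- .topo_order(involved, edges)
  # f[v, k]: source->v path counts with k boundary crossings (k capped at 2)
  f <- matrix(0, length(involved), 3, dimnames = list(involved, NULL))
  f[cascade$sources, 1] <- 1
  in_by <- split(seq_len(nrow(edges)), factor(edges$tgt, levels = ord))
  for (v in ord) {
    for (ei in in_by[[v]]) {
      u <- edges$src[ei]
      if (cls[[u]] == cls[[v]]) {
        f[v, ] <- f[v, ] + f[u, ]
      } else {
        f[v, 2] <- f[v, 2] + f[u, 1]
        f[v, 3] <- f[v, 3] + f[u, 2] + f[u, 3]
      }
    }
  }
  .check_count(f)
  cortical_t <- terminals[cls[terminals] == "cortical"]
  subcort_t <- terminals[cls[terminals] == "subcortical"]
  n_C <- sum(f[cortical_t, 1])
  n_CS <- sum(f[subcort_t, 2])
  n_CSC <- sum(f[cortical_t, 3])
  total <- sum(f[terminals, ])
  list(C = n_C, CS = n_CS, CSC_plus = n_CSC,
       residual = total - n_C - n_CS - n_CSC, total = total)
}

#' Brain-volume fraction occupied by a node set
#'
#' The summed ROI volume of the core members divided by the summed volume
#' of all nodes in the analyzed connectome.
#'
#' @param core a \code{tau_core_result} or character vector of acronyms.
#' @param c the connectome whose volumes to use.
#' @return Scalar in [0, 1].
#' @export
volume_fraction <- function(core, c) {
  stopifnot(inherits(c, "connectome"))
  members <- if (inherits(core, "tau_core_result")) core$members
             else as.character(core)
  vol <- stats::setNames(c$nodes$volume_mm3, c$nodes$acronym)
  if (anyNA(vol)) stop("missing node volume(s)", call. = FALSE)
  missing <- setdiff(members, names(vol))
  if (length(missing))
    stop("core member(s) not in connectome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  sum(vol[members]) / sum(vol)
}
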