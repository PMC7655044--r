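#' Parameters for the asynchronous linear threshold model
#'
#' @param theta activation threshold (> 0). A node activates at the first
#'   instant at which the summed weights of inputs that have already
#'   arrived from active in-neighbors strictly exceed \code{theta}; an
#'   input sum exactly equal to \code{theta} does not activate.
#' @param weight_mode \code{"raw"} applies \code{theta} to the connection
#'   weights as given; \code{"in_normalized"} first rescales each node's
#'   in-weights to sum to 1, so \code{theta} reads as a fraction of total
#'   afferent drive.
#' @param max_time optional simulation horizon; arrivals after it are
#'   discarded.
#' @return A list of class \code{alt_params}.
#' @export
alt_params <- function(theta = 0.98, weight_mode = c("raw", "in_normalized"),
                       max_time = Inf) {
  if (!is.numeric(theta) || length(theta) != 1 || is.na(theta) || theta <= 0)
    stop("theta must be a positive scalar", call. = FALSE)
  weight_mode <- match.arg(weight_mode)
  structure(list(theta = theta, weight_mode = weight_mode,
                 max_time = max_time), class = "alt_params")
}

# absolute-plus-relative tolerance for comparing event times built from
# sums of floating-point delays
.time_tol <- function(t) 1e-9 * (1 + abs(t))

.alt_edge_weights <- function(c, weight_mode) {
  w <- c$edges$weight
  if (weight_mode == "in_normalized") {
    insum <- tapply(w, c$edges$tgt, sum)
    tot <- as.numeric(insum[c$edges$tgt])
    if (any(tot <= 0))
      stop("in_normalized weight mode requires positive in-weight sums",
           call. = FALSE)
    w <- w / tot
  }
  w
}

#' Run the asynchronous linear threshold (ALT) model
#'
#' Event-driven simulation of threshold diffusion with per-edge delays.
#' The designated source nodes are active at time 0; every activation of a
#' node j schedules one input arrival per out-edge (j -> i) at time
#' t_j + delay(j,i) carrying weight w(j,i). Node i activates at the
#' earliest arrival instant at which its accumulated input strictly
#' exceeds \code{theta}. Activation is monotone (nodes never deactivate)
#' and candidate activation times are exactly the arrival instants, so a
#' continuous-time event queue is exact: no clock discretization is used.
#' Arrivals sharing a timestamp (within floating-point tolerance) are
#' summed before the threshold test.
#'
#' @param c a \code{\link{connectome}}.
#' @param sources character vector of source acronyms (nonempty).
#' @param params an \code{\link{alt_params}} object.
#' @return An object of class \code{cascade_result}: list with
#'   \code{sources}, \code{activation_time} (named vector over all nodes,
#'   \code{NA} for never-activated nodes), \code{dag} (data.frame of causal
#'   edges \code{src,tgt} with endpoint activation times), \code{nodes}
#'   (the node universe), \code{complete} (all nodes activated) and
#'   \code{theta}.
#' @export
run_alt <- function(c, sources, params = alt_params()) {
  stopifnot(inherits(c, "connectome"), inherits(params, "alt_params"))
  nodes <- c$nodes$acronym
  if (length(sources) == 0) stop("sources must be nonempty", call. = FALSE)
  sources <- as.character(sources)
  unknown <- setdiff(sources, nodes)
  if (length(unknown))
    stop("unknown source node(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  w <- .alt_edge_weights(c, params$weight_mode)
  esrc <- c$edges$src; etgt <- c$edges$tgt; edel <- c$edges$delay
  out_idx <- split(seq_along(esrc), factor(esrc, levels = nodes))

  t_act <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  t_act[sources] <- 0
  acc <- stats::setNames(numeric(length(nodes)), nodes)

  # pending arrival events
  ev_t <- numeric(0); ev_tgt <- character(0); ev_w <- numeric(0)
  schedule <- function(j, tj) {
    idx <- out_idx[[j]]
    if (length(idx)) {
      tt <- tj + edel[idx]
      keep <- tt <= params$max_time
      ev_t <<- c(ev_t, tt[keep])
      ev_tgt <<- c(ev_tgt, etgt[idx][keep])
      ev_w <<- c(ev_w, w[idx][keep])
    }
  }
  for (s in sources) schedule(s, 0)

  while (length(ev_t)) {
    tmin <- min(ev_t)
    sel <- ev_t <= tmin + .time_tol(tmin)
    tgts <- ev_tgt[sel]; ws <- ev_w[sel]
    ev_t <- ev_t[!sel]; ev_tgt <- ev_tgt[!sel]; ev_w <- ev_w[!sel]
    live <- is.na(t_act[tgts])
    if (any(live)) {
      add <- tapply(ws[live], tgts[live], sum)
      acc[names(add)] <- acc[names(add)] + as.numeric(add)
      fired <- names(add)[acc[names(add)] > params$theta]
      # deterministic processing order for simultaneous activations
      for (i in sort(fired)) {
        t_act[i] <- tmin
        schedule(i, tmin)
      }
    }
  }

  dag <- build_cascade_dag(c, t_act, sources,
                           weight_mode = params$weight_mode)
  structure(list(sources = sources, activation_time = t_act, dag = dag,
                 nodes = nodes, complete = !anyNA(t_act),
                 theta = params$theta),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf(
    "<cascade> source(s) %s | %d/%d nodes active | %d causal edges%s\n",
    paste(x$sources, collapse = ","), sum(!is.na(x$activation_time)),
    length(x$nodes), nrow(x$dag), if (x$complete) " | complete" else ""))
  invisible(x)
}

#' Construct the causal activation-cascade DAG
#'
#' Given per-node activation times from an ALT run, the causal edge
#' (j -> i) is included exactly when j is an in-neighbor of i, both are
#' activated, and \code{t_i >= t_j + delay(j,i)} — i.e. j's input had
#' arrived by the time i activated and therefore contributed to it.
#' Because delays are strictly positive the result is acyclic by
#' construction. Every activated non-source node must acquire at least
#' one incoming causal edge; times violating that are an integrity error.
#'
#' @param c a connectome.
#' @param activation_time named numeric vector over the connectome's nodes
#'   (\code{NA} = never activated).
#' @param sources character vector of source acronyms (activation time 0).
#' @param weight_mode kept for interface symmetry with \code{run_alt};
#'   the causal rule itself uses only delays.
#' @return data.frame with columns \code{src}, \code{tgt}, \code{t_src},
#'   \code{t_tgt}.
#' @export
build_cascade_dag <- function(c, activation_time, sources,
                              weight_mode = "raw") {
  stopifnot(inherits(c, "connectome"))
  ta <- activation_time[c$edges$src]
  tb <- activation_time[c$edges$tgt]
  keep <- !is.na(ta) & !is.na(tb) &
    tb >= ta + c$edges$delay - .time_tol(tb)
  dag <- data.frame(src = c$edges$src[keep], tgt = c$edges$tgt[keep],
                    t_src = unname(ta[keep]), t_tgt = unname(tb[keep]),
                    stringsAsFactors = FALSE)
  active <- names(activation_time)[!is.na(activation_time)]
  orphan <- setdiff(active, c(sources, dag$tgt))
  if (length(orphan))
    stop("integrity error: activated non-source node(s) without any ",
         "causal in-edge: ", paste(orphan, collapse = ", "), call. = FALSE)
  rownames(dag) <- NULL
  dag
}

#' Cascade size as a function of the activation threshold
#'
#' Re-runs the ALT model from one source over an ascending grid of
#' thresholds and reports the fraction of nodes activated at each; the
#' fraction is non-increasing in theta.
#'
#' @param c a connectome.
#' @param source single source acronym.
#' @param theta_grid ascending positive thresholds (nonempty).
#' @param weight_mode passed to \code{\link{alt_params}}.
#' @return data.frame with columns \code{theta}, \code{fraction_active},
#'   \code{complete}.
#' @export
theta_sweep <- function(c, source, theta_grid, weight_mode = "raw") {
  if (length(theta_grid) == 0) stop("theta_grid is empty", call. = FALSE)
  if (is.unsorted(theta_grid))
    stop("theta_grid must be sorted ascending", call. = FALSE)
  res <- vapply(theta_grid, function(th) {
    r <- run_alt(c, source, alt_params(theta = th, weight_mode = weight_mode))
    c(mean(!is.na(r$activation_time)), as.numeric(r$complete))
  }, numeric(2))
  data.frame(theta = theta_grid, fraction_active = res[1, ],
             complete = res[2, ] == 1)
}

#' Largest threshold giving complete cascades from every source
#'
#' Evaluates the ALT model at each grid value and returns the largest
#' theta at which all listed sources produce a complete cascade (every
#' node activated). Operationally this is the working threshold: it keeps
#' the dynamics as close as possible to the no-cascade regime while still
#' letting every sensory stream reach the whole network.
#'
#' @param c a connectome.
#' @param sources character vector of source acronyms.
#' @param grid nonempty numeric vector of candidate thresholds.
#' @param weight_mode passed to \code{\link{alt_params}}.
#' @return The selected theta, or \code{NA_real_} if no grid value yields
#'   complete cascades for all sources.
#' @export
find_critical_theta <- function(c, sources, grid, weight_mode = "raw") {
  if (length(grid) == 0) stop("grid is empty", call. = FALSE)
  ok <- vapply(grid, function(th) {
    all(vapply(sources, function(s) {
      run_alt(c, s, alt_params(theta = th,
                               weight_mode = weight_mode))$complete
    }, logical(1)))
  }, logical(1))
  if (!any(ok)) return(NA_real_)
  max(grid[ok])
}

#' Export a cascade DAG
#'
#' Writes the causal DAG as CSV (\code{src,tgt,t_src,t_tgt}) or GraphML.
#'
#' @param cascade a \code{cascade_result}.
#' @param path output path.
#' @param format \code{"csv"} or \code{"graphml"}.
#' @export
export_cascade <- function(cascade, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(cascade$dag, path, row.names = FALSE)
  } else {
    act <- cascade$nodes[!is.na(cascade$activation_time[cascade$nodes])]
    g <- igraph::graph_from_data_frame(
      cascade$dag, directed = TRUE,
      vertices = data.frame(
        name = act,
        activation_time = unname(cascade$activation_time[act])))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
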