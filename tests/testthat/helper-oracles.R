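# Independent brute-force oracles used to check the package's event-driven
# simulator, dynamic programs and greedy heuristics on small instances.

# Random small connectome with integer delays (given directly as lengths,
# conduction factor 1), suitable for the discrete time-stepping oracle.
rand_connectome <- function(n, p_edge, seed, max_delay = 5,
                            weight_max = 2) {
  withr::with_seed(seed, {
    acr <- sprintf("N%02d", seq_len(n))
    pairs <- expand.grid(src = acr, tgt = acr, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$src != pairs$tgt, ]
    pairs <- pairs[stats::runif(nrow(pairs)) < p_edge, , drop = FALSE]
    nodes <- data.frame(acronym = acr,
                        x_mm = stats::runif(n), y_mm = stats::runif(n),
                        z_mm = stats::runif(n), stringsAsFactors = FALSE)
    if (nrow(pairs) == 0)   # guarantee at least one edge
      pairs <- data.frame(src = acr[1], tgt = acr[2],
                          stringsAsFactors = FALSE)
    pairs$weight <- stats::runif(nrow(pairs), 0.05, weight_max)
    pairs$p_value <- stats::runif(nrow(pairs))
    pairs$length_mm <- sample(seq_len(max_delay), nrow(pairs),
                              replace = TRUE)
    connectome(nodes, pairs, conduction_factor = 1)
  })
}

# Discrete time-stepping ALT oracle: valid when all delays are integers.
# At each integer tick, a node activates if the summed weights of inputs
# from in-neighbors active at least one delay earlier strictly exceed
# theta. Returns named activation times (NA = never).
oracle_alt_times <- function(con, sources, theta,
                             weight_mode = "raw") {
  acr <- con$nodes$acronym
  w <- con$edges$weight
  if (weight_mode == "in_normalized") {
    insum <- tapply(w, con$edges$tgt, sum)
    w <- w / as.numeric(insum[con$edges$tgt])
  }
  d <- con$edges$delay
  t_act <- stats::setNames(rep(NA_real_, length(acr)), acr)
  t_act[sources] <- 0
  t_max <- length(acr) * max(d) + 1
  for (t in seq_len(t_max)) {
    inact <- names(t_act)[is.na(t_act)]
    newly <- character(0)
    for (i in inact) {
      ein <- which(con$edges$tgt == i)
      arrived <- !is.na(t_act[con$edges$src[ein]]) &
        t_act[con$edges$src[ein]] <= t - d[ein]
      if (sum(w[ein][arrived]) > theta) newly <- c(newly, i)
    }
    t_act[newly] <- t
  }
  t_act
}

# Exhaustive DFS enumeration of source-target paths in a cascade DAG.
# Returns a list of character vectors (node sequences, >= 1 edge each).
enum_paths <- function(cascade) {
  edges <- cascade$dag
  out_by <- split(edges$tgt, edges$src)
  terminals <- setdiff(unique(c(edges$src, edges$tgt)), edges$src)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    outs <- out_by[[v]]
    if (is.null(outs)) {
      if (length(path) > 1 && v %in% terminals)
        paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (u in outs) walk(c(path, u))
  }
  for (s in intersect(cascade$sources, edges$src)) walk(s)
  paths
}

# Greedy tau-core oracle on explicitly enumerated path sets: each
# iteration picks the node covering the most uncovered paths (ties ->
# earliest node in `node_order`), removes those paths, and repeats until
# coverage >= tau.
oracle_tau_core <- function(coll, tau, node_order) {
  all_paths <- unlist(lapply(coll, enum_paths), recursive = FALSE)
  total <- length(all_paths)
  stopifnot(total > 0)
  uncovered <- rep(TRUE, total)
  members <- character(0); marginal <- numeric(0)
  repeat {
    cnt <- stats::setNames(numeric(length(node_order)), node_order)
    for (k in which(uncovered))
      cnt[unique(all_paths[[k]])] <- cnt[unique(all_paths[[k]])] + 1
    cnt[members] <- 0
    if (max(cnt) <= 0) break
    pick <- node_order[which.max(cnt)]
    members <- c(members, pick)
    hit <- vapply(all_paths, function(p) pick %in% p, logical(1)) &
      uncovered
    marginal <- c(marginal, sum(hit))
    uncovered[hit] <- FALSE
    if (sum(!uncovered) / total >= tau - 1e-12) break
  }
  list(members = members, marginal = marginal,
       cumulative = cumsum(marginal) / total)
}

# Random cascade DAG on n nodes: random topological order, each forward
# pair is an edge with probability p; source = first node (optionally
# relabelled so collections have distinct sources while sharing the
# remaining node names). Returns a cascade_result (edges oriented along
# the order, hence acyclic).
rand_dag_cascade <- function(n, p_edge, seed, src_label = NULL) {
  withr::with_seed(seed, {
    acr <- sample(sprintf("V%02d", seq_len(n)))
    if (!is.null(src_label)) acr[1] <- src_label
    edges <- data.frame(src = character(0), tgt = character(0))
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (stats::runif(1) < p_edge)
        edges <- rbind(edges, data.frame(src = acr[i], tgt = acr[j]))
    # keep only nodes reachable from the source so the DAG is a cascade
    keep <- acr[1]
    repeat {
      nxt <- unique(edges$tgt[edges$src %in% keep])
      if (all(nxt %in% keep)) break
      keep <- union(keep, nxt)
    }
    edges <- edges[edges$src %in% keep & edges$tgt %in% keep, ,
                   drop = FALSE]
    cascade_from_dag(acr[1], edges, nodes = sort(keep))
  })
}

# Brute-force directed clustering per Fagiolo: for node i sum, over
# ordered neighbor pairs (j,k), the directed-triangle weight
# (a_ij+a_ji)(a_jk+a_kj)(a_ki+a_ik), and divide by twice the number of
# possible triangle configurations (the normalization that gives 1 on a
# complete directed graph).
oracle_fagiolo <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    tri <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j == i || k == i || j == k) next
      tri <- tri + (A[i, j] + A[j, i]) * (A[j, k] + A[k, j]) *
        (A[k, i] + A[i, k])
    }
    dtot <- sum(A[i, ]) + sum(A[, i])
    dbi <- sum(A[i, ] * A[, i])
    den <- 2 * (dtot * (dtot - 1) - 2 * dbi)
    if (den <= 0) NA_real_ else tri / den
  })
}

# Enumeration oracle for cortico-subcortical path classification.
oracle_classify <- function(cascade, region_class) {
  paths <- enum_paths(cascade)
  lab <- vapply(paths, function(p) {
    cl <- region_class[p]
    crossings <- sum(cl[-1] != cl[-length(cl)])
    last <- cl[length(cl)]
    if (crossings == 0 && last == "cortical") "C"
    else if (crossings == 1 && last == "subcortical") "CS"
    else if (crossings >= 2 && last == "cortical") "CSC_plus"
    else "residual"
  }, character(1))
  list(C = sum(lab == "C"), CS = sum(lab == "CS"),
       CSC_plus = sum(lab == "CSC_plus"),
       residual = sum(lab == "residual"), total = length(lab))
}

# The documented worked example: three cascades with 5, 3 and 4
# source-target paths of which 10 pass through node w.
fig1c_collection <- function() {
  c1 <- cascade_from_dag("u", data.frame(
    src = c("u", "w", "w", "w", "w", "u"),
    tgt = c("w", "a1", "a2", "a3", "a4", "a5")))
  c2 <- cascade_from_dag("v", data.frame(
    src = c("v", "w", "w", "w"),
    tgt = c("w", "b1", "b2", "b3")))
  c3 <- cascade_from_dag("y", data.frame(
    src = c("y", "w", "w", "w", "y"),
    tgt = c("w", "c1", "c2", "c3", "c4")))
  cascade_collection(c1, c2, c3)
}
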