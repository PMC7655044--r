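#' Randomize edge weights, preserving topology
#'
#' Reallocates the connectome's weights across its edges by a uniform
#' random permutation: the weight multiset is conserved exactly and
#' topology, lengths and delays are untouched.
#'
#' @param c a connectome.
#' @param seed integer seed; the result is a deterministic function of it.
#' @return The randomized connectome.
#' @export
randomize_weights <- function(c, seed) {
  stopifnot(inherits(c, "connectome"))
  withr::with_seed(seed, {
    c$edges$weight <- .permute(c$edges$weight)
  })
  c
}

# uniform random permutation, safe for length-1 vectors
.permute <- function(x) x[sample.int(length(x))]

#' Randomize edge lengths, preserving topology
#'
#' Permutes the physical lengths across edges (delays are refreshed from
#' the conduction factor); the length multiset is conserved exactly and
#' topology and weights are untouched.
#'
#' @inheritParams randomize_weights
#' @return The randomized connectome.
#' @export
randomize_lengths <- function(c, seed) {
  stopifnot(inherits(c, "connectome"))
  withr::with_seed(seed, {
    c$edges$length_mm <- .permute(c$edges$length_mm)
  })
  c$edges$delay <- c$conduction_factor * c$edges$length_mm
  c
}

#' Randomize both weights and lengths independently
#'
#' Two independent permutations, deliberately destroying any
#' weight-length correlation present in the original connectome.
#'
#' @inheritParams randomize_weights
#' @return The randomized connectome.
#' @export
randomize_weights_and_lengths <- function(c, seed) {
  stopifnot(inherits(c, "connectome"))
  withr::with_seed(seed, {
    c$edges$weight <- .permute(c$edges$weight)
    c$edges$length_mm <- .permute(c$edges$length_mm)
  })
  c$edges$delay <- c$conduction_factor * c$edges$length_mm
  c
}

#' Degree-preserving topology randomization (double-edge swaps)
#'
#' Repeatedly selects two edges (a -> b), (c -> d) and rewires them to
#' (a -> d), (c -> b), rejecting swaps that would create a self-loop or a
#' duplicate edge; this preserves every node's in- and out-degree exactly.
#' Weights travel with their (rewired) edges; by default lengths and
#' delays are recomputed from the new endpoint centroids (physically
#' consistent), or carried with the edges when \code{carry_lengths = TRUE}.
#' If no valid swap can be found (e.g. a 2-cycle), the input is returned
#' unchanged with attribute \code{no_valid_swap = TRUE} and a warning.
#'
#' @inheritParams randomize_weights
#' @param swap_multiplier accepted swaps performed per edge (default 10,
#'   a standard Markov-chain mixing heuristic).
#' @param carry_lengths keep each edge's original length instead of
#'   recomputing from centroids.
#' @return The randomized connectome.
#' @export
randomize_topology <- function(c, seed, swap_multiplier = 10,
                               carry_lengths = FALSE) {
  stopifnot(inherits(c, "connectome"))
  m <- nrow(c$edges)
  if (m < 2) {
    warning("fewer than 2 edges; topology unchanged", call. = FALSE)
    attr(c, "no_valid_swap") <- TRUE
    return(c)
  }
  src <- c$edges$src; tgt <- c$edges$tgt
  key <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(m)) assign(paste(src[i], tgt[i]), TRUE, envir = key)
  target_swaps <- swap_multiplier * m
  max_attempts <- 200 * target_swaps
  accepted <- 0L
  withr::with_seed(seed, {
    attempts <- 0L
    while (accepted < target_swaps && attempts < max_attempts) {
      attempts <- attempts + 1L
      ij <- sample.int(m, 2)
      a <- src[ij[1]]; b <- tgt[ij[1]]
      cc <- src[ij[2]]; d <- tgt[ij[2]]
      if (a == d || cc == b) next
      k1 <- paste(a, d); k2 <- paste(cc, b)
      if (exists(k1, envir = key, inherits = FALSE) ||
          exists(k2, envir = key, inherits = FALSE)) next
      rm(list = c(paste(a, b), paste(cc, d)), envir = key)
      assign(k1, TRUE, envir = key); assign(k2, TRUE, envir = key)
      tgt[ij[1]] <- d; tgt[ij[2]] <- b
      accepted <- accepted + 1L
    }
  })
  if (accepted == 0L) {
    warning("no valid double-edge swap exists; topology unchanged",
            call. = FALSE)
    attr(c, "no_valid_swap") <- TRUE
    return(c)
  }
  c$edges$src <- src
  c$edges$tgt <- tgt
  if (carry_lengths) {
    c$edges$delay <- c$conduction_factor * c$edges$length_mm
    c
  } else {
    compute_edge_lengths(c)
  }
}

.randomize_by_mode <- function(c, mode, seed, swap_multiplier = 10,
                               carry_lengths = FALSE) {
  switch(mode,
         weights = randomize_weights(c, seed),
         lengths = randomize_lengths(c, seed),
         weights_and_lengths = randomize_weights_and_lengths(c, seed),
         topology = randomize_topology(c, seed, swap_multiplier,
                                       carry_lengths),
         stop("unknown randomization mode: ", mode, call. = FALSE))
}

#' Tau-core robustness across a randomized-connectome ensemble
#'
#' For each replicate: randomize the connectome under the requested mode,
#' re-run the ALT model from every source, and recompute the greedy
#' coverage trajectory; the core size at each tau in \code{tau_grid} is
#' the number of greedy nodes needed to reach that coverage. Reports
#' 5/50/95 percentile bands of core size per tau and, at
#' \code{membership_tau}, the fraction of replicates in which each node
#' appears in the core. Fully reproducible from the seed; replicates that
#' fail (e.g. a degenerate randomized cascade) are skipped and logged.
#'
#' @param c a connectome.
#' @param mode one of "weights", "lengths", "weights_and_lengths",
#'   "topology".
#' @param sources source acronyms (default: the connectome's flagged
#'   sources).
#' @param params an \code{\link{alt_params}}.
#' @param tau_grid coverage fractions at which to record core size.
#' @param n_replicates ensemble size (paper-scale default 100).
#' @param seed integer master seed; replicate r uses seed + r.
#' @param membership_tau tau at which core membership is tallied.
#' @param swap_multiplier,carry_lengths passed to
#'   \code{\link{randomize_topology}}.
#' @return A list of class \code{ensemble_summary}: \code{core_size}
#'   (replicate x tau matrix), \code{size_bands} (5/50/95 percentiles per
#'   tau), \code{membership_frequency} (named vector),
#'   \code{failed_replicates}, plus the spec fields.
#' @export
ensemble_tau_core <- function(c, mode, sources = NULL,
                              params = alt_params(),
                              tau_grid = seq(0.1, 1, by = 0.1),
                              n_replicates = 100, seed = 1,
                              membership_tau = 0.9,
                              swap_multiplier = 10,
                              carry_lengths = FALSE) {
  stopifnot(inherits(c, "connectome"), n_replicates >= 1)
  if (is.null(sources)) sources <- c$nodes$acronym[c$nodes$is_source]
  if (length(sources) == 0) stop("no source nodes", call. = FALSE)
  nodes <- c$nodes$acronym
  sizes <- matrix(NA_integer_, n_replicates, length(tau_grid),
                  dimnames = list(NULL, paste0("tau_", tau_grid)))
  member_count <- stats::setNames(numeric(length(nodes)), nodes)
  failed <- integer(0)
  n_ok <- 0
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      cr <- .randomize_by_mode(c, mode, seed + r, swap_multiplier,
                               carry_lengths)
      coll <- cascade_collection(lapply(sources, function(s)
        run_alt(cr, s, params)))
      core <- tau_core(coll, tau = 1)
      core
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, r)
      message("replicate ", r, " skipped: ", conditionMessage(res))
      next
    }
    n_ok <- n_ok + 1
    cum <- res$cumulative_coverage
    sizes[r, ] <- vapply(tau_grid, function(tv) {
      i <- which(cum >= tv - 1e-12)
      if (length(i)) i[1] else NA_integer_
    }, integer(1))
    i90 <- which(cum >= membership_tau - 1e-12)
    memb <- if (length(i90)) res$members[seq_len(i90[1])] else res$members
    member_count[memb] <- member_count[memb] + 1
  }
  bands <- apply(sizes, 2, stats::quantile, probs = c(0.05, 0.5, 0.95),
                 na.rm = TRUE)
  structure(list(mode = mode, n_replicates = n_replicates, seed = seed,
                 tau_grid = tau_grid, membership_tau = membership_tau,
                 core_size = sizes, size_bands = bands,
                 membership_frequency = member_count / max(n_ok, 1),
                 failed_replicates = failed),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble> mode=%s, %d replicates (%d failed)\n",
              x$mode, x$n_replicates, length(x$failed_replicates)))
  cat(sprintf("  core size at tau=%.2f: median %s [5-95%%: %s-%s]\n",
              x$membership_tau,
              format(x$size_bands["50%",
                paste0("tau_", x$membership_tau)]),
              format(x$size_bands["5%", paste0("tau_", x$membership_tau)]),
              format(x$size_bands["95%",
                paste0("tau_", x$membership_tau)])))
  invisible(x)
}
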