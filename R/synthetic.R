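#' Specification for the mouse-cortex-like connectome generator
#'
#' Defaults emulate the published summary statistics of the right-
#' hemisphere mouse cortical network: 67 nodes, density 13.9%, directed
#' clustering about 0.60, skewed connection-density weights (80th
#' percentile about 5, maximum about 40), edge lengths spanning roughly
#' 1-7 mm, and 10 designated primary sensory source nodes. Edges are
#' drawn with a sharply distance-decaying probability so that clustering
#' emerges from the spatial embedding of a thin cortical-sheet-like
#' placement volume; a fraction of drawn edges is reciprocated to reach
#' cortical levels of clustering.
#'
#' @param n_nodes number of ROIs.
#' @param target_density edge density m/(n(n-1)).
#' @param target_clustering directed (Fagiolo) clustering target.
#' @param density_tol relative tolerance on realized density (0.10).
#' @param clustering_tol absolute tolerance on realized clustering (0.10).
#' @param weight_q80 80th-percentile anchor of the log-normal weights.
#' @param weight_max cap / extreme-quantile anchor of the weights.
#' @param box_mm length-3 placement box (mm). The default is a thin
#'   sheet, mirroring the quasi-2D cortical surface; its lateral extent
#'   is chosen so realized edge lengths span roughly 1-7 mm.
#' @param decay_exponent exponent k of the edge kernel
#'   p(d) = exp(-(d/lambda)^k); large k approaches a hard geometric
#'   threshold, which maximizes spatial clustering.
#' @param n_sources number of sensory source nodes.
#' @param p_sig_frac fraction of edges drawn with p <= 0.05 (the rest are
#'   uniform on (0.05, 1], so the p-value filter is exercised).
#' @param recip_prob probability that a drawn edge is reciprocated;
#'   raises clustering, mirroring the high reciprocity of cortical
#'   connectivity.
#' @param subcortical_frac fraction of nodes labelled subcortical (0 for
#'   the cortex-only network).
#' @param seed integer seed.
#' @return A list of class \code{connectome_gen_spec}.
#' @export
connectome_gen_spec <- function(n_nodes = 67, target_density = 0.139,
                                target_clustering = 0.60,
                                density_tol = 0.10, clustering_tol = 0.10,
                                weight_q80 = 5, weight_max = 40,
                                box_mm = c(17, 17, 0.85),
                                decay_exponent = 6, n_sources = 10,
                                p_sig_frac = 0.9, recip_prob = 0.6,
                                subcortical_frac = 0, seed = 1) {
  stopifnot(target_density > 0, target_density < 1, n_sources < n_nodes,
            n_nodes >= 2)
  if (length(box_mm) == 1) box_mm <- rep(box_mm, 3)
  stopifnot(length(box_mm) == 3, all(box_mm > 0))
  structure(as.list(environment()), class = "connectome_gen_spec")
}

# log-normal parameters hit the q80 anchor exactly and place weight_max at
# the (1 - 1/m) quantile for the edge count m; for very small m the max
# quantile is floored above q80 so sdlog stays positive
.weight_lnorm_params <- function(q80, wmax, m) {
  zq <- stats::qnorm(0.8)
  zm <- max(stats::qnorm(1 - 1 / max(m, 2)), zq + 0.5)
  sdlog <- (log(wmax) - log(q80)) / (zm - zq)
  meanlog <- log(q80) - zq * sdlog
  c(meanlog = meanlog, sdlog = sdlog)
}

#' Generate a connectome with mouse-cortex-like statistics
#'
#' Nodes are placed uniformly in a thin box (a cortical-sheet-like
#' volume); directed edges are drawn independently with probability
#' p(d) = exp(-(d/lambda)^k) in the centroid distance d, with lambda
#' calibrated by bisection so the expected density hits the target, and
#' a fraction of edges reciprocated. Weights are i.i.d. anchored
#' log-normal, p-values a
#' mixture straddling 0.05, lengths Euclidean, delays = lengths
#' (conduction factor 1). The emulated network has a finite directed
#' diameter (every node reachable from every other), and its published
#' summary statistics describe the confidence-filtered connectome, so
#' draws are conditioned on strong connectivity of the significant-edge
#' (p <= 0.05) subgraph: a draw failing that is discarded and redrawn
#' from a seed derived deterministically from \code{spec$seed}. Errors if the realized
#' density or clustering misses its tolerance band (with diagnostics).
#' Deterministic for a given spec.
#'
#' @param spec a \code{\link{connectome_gen_spec}}.
#' @return A \code{\link{connectome}}.
#' @export
generate_connectome <- function(spec = connectome_gen_spec()) {
  stopifnot(inherits(spec, "connectome_gen_spec"))
  for (attempt in 0:49) {
    out <- .generate_connectome_once(spec, spec$seed + 7907 * attempt)
    g <- as_igraph(filter_edges_by_pvalue(out$connectome, 0.05))
    if (igraph::is_connected(g, mode = "strong")) break
    out <- NULL
  }
  if (is.null(out))
    stop("generator failed to produce a strongly connected network in ",
         "50 attempts (seed = ", spec$seed, ")", call. = FALSE)
  con <- out$connectome
  lambda <- out$lambda
  s <- network_summary(con)
  if (abs(s$density - spec$target_density) >
      spec$density_tol * spec$target_density)
    stop(sprintf(paste0("generator calibration failed: realized density ",
                        "%.4f outside %.1f%% of target %.4f ",
                        "(lambda = %.3f, seed = %d)"),
                 s$density, 100 * spec$density_tol, spec$target_density,
                 lambda, spec$seed), call. = FALSE)
  if (!is.na(s$clustering_coefficient) &&
      abs(s$clustering_coefficient - spec$target_clustering) >
      spec$clustering_tol)
    stop(sprintf(paste0("generator calibration failed: realized ",
                        "clustering %.3f outside +/-%.2f of target %.2f ",
                        "(lambda = %.3f, recip_prob = %.2f, seed = %d)"),
                 s$clustering_coefficient, spec$clustering_tol,
                 spec$target_clustering, lambda, spec$recip_prob,
                 spec$seed), call. = FALSE)
  con
}

.generate_connectome_once <- function(spec, seed) {
  n <- spec$n_nodes
  withr::with_seed(seed, {
    cent <- cbind(stats::runif(n, 0, spec$box_mm[1]),
                  stats::runif(n, 0, spec$box_mm[2]),
                  stats::runif(n, 0, spec$box_mm[3]))
    dmat <- as.matrix(stats::dist(cent))
    offd <- row(dmat) != col(dmat)

    # expected density for decay scale lambda, including reciprocation:
    # P(edge) = p + recip_prob * p * (1 - p) on each ordered pair
    exp_density <- function(lambda) {
      p <- exp(-(dmat[offd] / lambda)^spec$decay_exponent)
      mean(p + spec$recip_prob * p * (1 - p))
    }
    lo <- 1e-3; hi <- 10 * max(spec$box_mm)
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (exp_density(mid) < spec$target_density) lo <- mid else hi <- mid
    }
    lambda <- (lo + hi) / 2

    p <- exp(-(dmat / lambda)^spec$decay_exponent)
    draw <- matrix(stats::runif(n * n), n, n) < p
    diag(draw) <- FALSE
    recip <- t(draw) & (matrix(stats::runif(n * n), n, n) < spec$recip_prob)
    A <- draw | recip
    diag(A) <- FALSE

    m <- sum(A)
    wl <- .weight_lnorm_params(spec$weight_q80, spec$weight_max, m)
    weights <- pmin(stats::rlnorm(m, wl["meanlog"], wl["sdlog"]),
                    spec$weight_max)
    sig <- stats::runif(m) < spec$p_sig_frac
    pvals <- ifelse(sig, stats::runif(m, 0, 0.05),
                    stats::runif(m, 0.05, 1))
    src_i <- row(A)[A]; tgt_i <- col(A)[A]

    acr <- sprintf("R%02d", seq_len(n))
    n_sub <- round(spec$subcortical_frac * n)
    cls <- c(rep("subcortical", n_sub), rep("cortical", n - n_sub))
    cls <- sample(cls)
    src_nodes <- sample(which(cls == "cortical"), spec$n_sources)
    nodes <- data.frame(
      acronym = acr, name = paste("region", acr),
      region_class = cls,
      x_mm = cent[, 1], y_mm = cent[, 2], z_mm = cent[, 3],
      volume_mm3 = stats::rlnorm(n, log(3), 0.8),
      is_source = seq_len(n) %in% src_nodes,
      stringsAsFactors = FALSE)
    edges <- data.frame(src = acr[src_i], tgt = acr[tgt_i],
                        weight = weights, p_value = pvals,
                        stringsAsFactors = FALSE)
  })
  list(connectome = connectome(nodes, edges, conduction_factor = 1),
       lambda = lambda)
}

#' Generate a planted-hourglass connectome
#'
#' A three-layer network in which all information flow from the source
#' layer to the downstream layer is routed through a small waist: every
#' source projects to every waist node and every waist node to every
#' downstream node, plus an optional leakage fraction of direct
#' source-to-downstream edges. At leakage 0 the waist covers every
#' source-target path, making it the unique minimum path cover — the
#' ground truth for hourglass (tau-core) recovery tests. All weights are
#' 2 so any threshold below 2 propagates along single edges.
#'
#' @param n_sources,n_waist,n_downstream layer sizes.
#' @param leakage probability of a direct source->downstream edge.
#' @param seed integer seed (placement jitter and leakage draws).
#' @return A \code{\link{connectome}} with acronyms S*, W*, D*.
#' @export
generate_hourglass <- function(n_sources = 10, n_waist = 3,
                               n_downstream = 40, leakage = 0, seed = 1) {
  stopifnot(n_waist >= 1, n_sources >= 1, n_downstream >= 1)
  acr <- c(sprintf("S%02d", seq_len(n_sources)),
           sprintf("W%02d", seq_len(n_waist)),
           sprintf("D%02d", seq_len(n_downstream)))
  layer_x <- rep(c(0, 2, 4), c(n_sources, n_waist, n_downstream))
  withr::with_seed(seed, {
    nodes <- data.frame(
      acronym = acr, name = acr, region_class = "cortical",
      x_mm = layer_x,
      y_mm = c(seq_len(n_sources), seq_len(n_waist),
               seq_len(n_downstream)) * 0.5,
      z_mm = stats::runif(length(acr), 0, 0.1),
      volume_mm3 = 1,
      is_source = grepl("^S", acr), stringsAsFactors = FALSE)
    e1 <- expand.grid(src = acr[grepl("^S", acr)],
                      tgt = acr[grepl("^W", acr)],
                      stringsAsFactors = FALSE)
    e2 <- expand.grid(src = acr[grepl("^W", acr)],
                      tgt = acr[grepl("^D", acr)],
                      stringsAsFactors = FALSE)
    edges <- rbind(e1, e2)
    if (leakage > 0) {
      e3 <- expand.grid(src = acr[grepl("^S", acr)],
                        tgt = acr[grepl("^D", acr)],
                        stringsAsFactors = FALSE)
      e3 <- e3[stats::runif(nrow(e3)) < leakage, , drop = FALSE]
      edges <- rbind(edges, e3)
    }
  })
  edges$weight <- 2
  edges$p_value <- 0.01
  connectome(nodes, edges, conduction_factor = 1)
}

#' Synthesize a VSD-like image stack from ROI activation times
#'
#' Each ROI's continuous activation time is quantized to a 0-based frame,
#' floor(t / frame_interval); every pixel of the ROI then carries a
#' Gaussian temporal intensity bump centered at that frame plus i.i.d.
#' Gaussian noise. The stimulus frame is 0. With zero noise,
#' \code{\link{pixel_activation_time}} recovers the planted frames
#' exactly.
#'
#' @param labels H x W integer ROI label map (0 = background).
#' @param roi_times named numeric vector of activation times (ms), named
#'   by ROI label (or by \code{roi_names} entries).
#' @param frame_interval_ms frame interval (default 6.67 ms).
#' @param noise_sd standard deviation of additive pixel noise, in units
#'   of the unit-amplitude bump.
#' @param seed integer seed.
#' @param bump_sd_frames temporal width of the activation bump.
#' @param roi_names optional names giving the label -> name mapping used
#'   in \code{roi_times}.
#' @return A \code{\link{vsd_stack}}.
#' @export
generate_vsd_stack <- function(labels, roi_times, frame_interval_ms = 6.67,
                               noise_sd = 0.05, seed = 1,
                               bump_sd_frames = 1.5, roi_names = NULL) {
  labels <- as.matrix(labels)
  ids <- sort(unique(labels[labels > 0]))
  keys <- if (is.null(roi_names)) as.character(ids) else roi_names[ids]
  missing <- keys[!(keys %in% names(roi_times))]
  if (length(missing))
    stop("ROI(s) without an activation time: ",
         paste(missing, collapse = ", "), call. = FALSE)
  t_roi <- roi_times[keys]
  frame0 <- floor(t_roi / frame_interval_ms)
  tmax <- as.integer(max(frame0) + ceiling(3 * bump_sd_frames) + 2)
  h <- nrow(labels); w <- ncol(labels)
  f0_px <- matrix(NA_real_, h, w)
  for (i in seq_along(ids)) f0_px[labels == ids[i]] <- frame0[i]
  frames <- array(0, c(tmax + 1L, h, w))
  withr::with_seed(seed, {
    for (f in 0:tmax) {
      bump <- exp(-((f - f0_px)^2) / (2 * bump_sd_frames^2))
      bump[is.na(bump)] <- 0
      frames[f + 1L, , ] <- bump +
        if (noise_sd > 0) stats::rnorm(h * w, 0, noise_sd) else 0
    }
  })
  vsd_stack(frames, frame_interval_ms, stim_frame = 0)
}

#' Partition an image into a grid ROI label map
#'
#' Convenience label map for synthetic stacks: tiles an H x W image into
#' rectangular blocks labelled 1..n_rois in row-major block order (excess
#' blocks beyond \code{n_rois} become background).
#'
#' @param h,w image size in pixels.
#' @param block pixel side length of each square block.
#' @param n_rois number of labelled blocks.
#' @return H x W integer matrix.
#' @export
grid_label_map <- function(h, w, block, n_rois) {
  nbx <- w %/% block
  lab <- matrix(0L, h, w)
  for (r in seq_len(h %/% block)) for (cb in seq_len(nbx)) {
    id <- (r - 1L) * nbx + cb
    if (id <= n_rois)
      lab[((r - 1) * block + 1):(r * block),
          ((cb - 1) * block + 1):(cb * block)] <- id
  }
  lab
}

#' Four-node worked-example network
#'
#' A small constructed toy used throughout the documentation and tests:
#' edges A->B (delay 1, weight 2), A->C (delay 2, weight 0.6), B->C
#' (delay 1, weight 0.6) and C->D (delay 1, weight 2), with centroids on
#' a line so Euclidean lengths equal the stated delays. With theta = 1
#' and source A the cascade completes with activation times A:0, B:1,
#' C:2 (the two 0.6 inputs accumulate at t = 2), D:3, and the causal DAG
#' contains all four edges — including the individually sub-threshold
#' contributor A->C.
#'
#' @return A \code{\link{connectome}}.
#' @export
toy_fig1_network <- function() {
  nodes <- data.frame(
    acronym = c("A", "B", "C", "D"),
    name = c("A", "B", "C", "D"),
    region_class = "cortical",
    x_mm = c(0, 1, 2, 3), y_mm = 0, z_mm = 0,
    volume_mm3 = 1,
    is_source = c(TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    src = c("A", "A", "B", "C"),
    tgt = c("B", "C", "C", "D"),
    weight = c(2, 0.6, 0.6, 2),
    p_value = 0.01,
    stringsAsFactors = FALSE)
  connectome(nodes, edges, conduction_factor = 1)
}
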