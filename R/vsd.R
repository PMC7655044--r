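#' Construct a VSD-like image stack
#'
#' @param frames numeric array T x H x W of fluorescence intensities.
#' @param frame_interval_ms nominal frame interval (the source recordings
#'   run at 6.67 ms/frame).
#' @param stim_frame 0-based index of the stimulus frame; frame f is
#'   stored at array slice f + 1.
#' @return A list of class \code{vsd_stack}.
#' @export
vsd_stack <- function(frames, frame_interval_ms = 6.67, stim_frame = 0) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (dim(frames)[1] < 2) stop("stack needs >= 2 frames", call. = FALSE)
  if (stim_frame < 0 || stim_frame >= dim(frames)[1])
    stop("stim_frame out of range", call. = FALSE)
  structure(list(frames = frames, frame_interval_ms = frame_interval_ms,
                 stim_frame = as.integer(stim_frame)),
            class = "vsd_stack")
}

#' Read / write a VSD stack as multi-frame TIFF
#'
#' \code{write_vsd_stack} rescales intensities linearly to [0, 1] (TIFF
#' storage range); activation-time extraction is argmax-based and thus
#' invariant to this monotone rescaling. Frame metadata is not stored in
#' the TIFF and must be re-supplied on read.
#'
#' @param stack a \code{vsd_stack}.
#' @param path TIFF path.
#' @param frame_interval_ms,stim_frame metadata for the read stack.
#' @return \code{read_vsd_stack} returns a \code{vsd_stack}.
#' @export
write_vsd_stack <- function(stack, path) {
  stopifnot(inherits(stack, "vsd_stack"))
  f <- stack$frames
  rng <- range(f)
  if (diff(rng) > 0) f <- (f - rng[1]) / diff(rng)
  tiff::writeTIFF(lapply(seq_len(dim(f)[1]), function(i) f[i, , ]),
                  path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_vsd_stack
#' @export
read_vsd_stack <- function(path, frame_interval_ms = 6.67, stim_frame = 0) {
  fr <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(length(fr), nrow(fr[[1]]), ncol(fr[[1]])))
  for (i in seq_along(fr)) arr[i, , ] <- fr[[i]]
  vsd_stack(arr, frame_interval_ms, stim_frame)
}

#' Least-squares affine registration of landmark point sets
#'
#' Fits the affine map y = A x + b minimizing the summed squared error
#' over matched landmark pairs (the registration step that aligns a
#' native cortical surface to atlas coordinates using primary-sensory
#' landmarks). Requires at least d + 1 points in d dimensions in general
#' position; collinear (2D) or coplanar (3D) configurations are an error.
#'
#' @param atlas_pts,native_pts k x d matrices of matched coordinates
#'   (atlas -> native).
#' @return A list of class \code{affine_fit}: matrix \code{A}, offset
#'   \code{b}, \code{rms} residual, and \code{transform(points)}.
#' @export
fit_affine_landmarks <- function(atlas_pts, native_pts) {
  atlas_pts <- as.matrix(atlas_pts); native_pts <- as.matrix(native_pts)
  if (!all(dim(atlas_pts) == dim(native_pts)))
    stop("point sets must have identical dimensions", call. = FALSE)
  k <- nrow(atlas_pts); d <- ncol(atlas_pts)
  if (k < d + 1)
    stop("need at least ", d + 1, " landmark pairs in ", d, "D",
         call. = FALSE)
  X <- cbind(atlas_pts, 1)
  if (qr(X)$rank < d + 1)
    stop("degenerate landmark configuration (collinear/coplanar points)",
         call. = FALSE)
  B <- qr.solve(X, native_pts)          # (d+1) x d
  A <- t(B[seq_len(d), , drop = FALSE])
  b <- as.numeric(B[d + 1, ])
  resid <- X %*% B - native_pts
  rms <- sqrt(mean(rowSums(resid^2)))
  structure(list(A = A, b = b, rms = rms,
                 transform = function(p) {
                   p <- as.matrix(p)
                   sweep(p %*% t(A), 2, -b)
                 }),
            class = "affine_fit")
}

#' Per-pixel activation time from a VSD stack
#'
#' The activation time of a pixel is the frame of its maximum
#' poststimulus intensity; ties resolve to the earliest frame. Pixels
#' with a constant poststimulus trace are unreliable (no peak) and are
#' assigned the earliest frame with a flag.
#'
#' @param stack a \code{vsd_stack}.
#' @param window poststimulus window length in frames (default: through
#'   the end of the stack).
#' @return A list with \code{frame} (H x W matrix of 0-based frame
#'   indices) and \code{unreliable} (H x W logical).
#' @export
pixel_activation_time <- function(stack, window = NULL) {
  stopifnot(inherits(stack, "vsd_stack"))
  tmax <- dim(stack$frames)[1]
  first <- stack$stim_frame + 1L
  last <- if (is.null(window)) tmax else stack$stim_frame + 1L + window
  if (last > tmax)
    stop("poststimulus window extends beyond the stack", call. = FALSE)
  sub <- stack$frames[first:last, , , drop = FALSE]
  tm <- dim(sub)[1]
  m <- matrix(sub, nrow = tm)                      # T' x (H*W)
  peak <- max.col(t(m), ties.method = "first")     # first max = earliest
  flat <- .col_constant(m)
  h <- dim(sub)[2]; w <- dim(sub)[3]
  list(frame = matrix(stack$stim_frame + peak - 1L, h, w),
       unreliable = matrix(flat, h, w))
}

.col_constant <- function(m) apply(m, 2, function(x) max(x) == min(x))

#' Per-ROI activation time from pixel activation times
#'
#' An ROI's activation frame is the modal pixel activation frame within
#' it (the frame shared by the most pixels); modal ties resolve to the
#' earliest frame. An ROI label with no pixels is an error naming it.
#'
#' @param pixel_times result of \code{\link{pixel_activation_time}} (or a
#'   plain H x W matrix of frames).
#' @param labels H x W integer ROI label map, 0 = background.
#' @param roi_names optional character vector naming labels 1..max.
#' @return Named numeric vector of 0-based activation frames per ROI.
#' @export
roi_activation_time <- function(pixel_times, labels, roi_names = NULL) {
  fr <- if (is.list(pixel_times)) pixel_times$frame else pixel_times
  labels <- as.matrix(labels)
  if (!all(dim(fr) == dim(labels)))
    stop("label map shape does not match the stack", call. = FALSE)
  ids <- sort(unique(labels[labels > 0]))
  if (!is.null(roi_names)) {
    if (max(ids) > length(roi_names))
      stop("roi_names shorter than the largest label", call. = FALSE)
  }
  empty <- setdiff(seq_len(max(ids)), ids)
  if (length(empty))
    stop("ROI label(s) with no pixels: ",
         paste(empty, collapse = ", "), call. = FALSE)
  out <- vapply(ids, function(L) {
    tab <- table(fr[labels == L])
    as.numeric(names(tab)[which.max(tab)])  # which.max -> earliest on ties
  }, numeric(1))
  names(out) <- if (is.null(roi_names)) as.character(ids)
                else roi_names[ids]
  out
}

#' Temporal agreement between model and experimental activation orders
#'
#' Compares the relative activation order of every unordered ROI pair
#' common to both inputs. Pairs where the model assigns (numerically)
#' equal times are excluded from the denominator — the continuous-time
#' model is expected to always rank a pair, so such ties carry no
#' ordering information. For the remaining pairs: same experimental
#' frame -> insufficient temporal resolution; same ordering -> agreement;
#' opposite -> disagreement. The three fractions sum to one exactly
#' (integer pair counts). Also reports Kendall's tau-b between model
#' times and experimental frames (tau-b because frames are heavily tied),
#' which is invariant to any strictly monotone transform of the model
#' times.
#'
#' @param model_times named numeric vector of continuous model activation
#'   times.
#' @param exp_frames named numeric vector of experimental activation
#'   frames.
#' @return A list of class \code{agreement_result}: \code{n_pairs},
#'   \code{frac_agree}, \code{frac_disagree}, \code{frac_insufficient},
#'   \code{kendall_tau}, and the pair-level \code{table}.
#' @export
temporal_agreement <- function(model_times, exp_frames) {
  common <- intersect(names(model_times), names(exp_frames))
  if (length(common) < 2)
    stop("need at least 2 ROIs common to model and experiment",
         call. = FALSE)
  mt <- model_times[common]; ef <- exp_frames[common]
  pairs <- utils::combn(common, 2)
  dm <- mt[pairs[1, ]] - mt[pairs[2, ]]
  de <- ef[pairs[1, ]] - ef[pairs[2, ]]
  informative <- abs(dm) > .time_tol(pmax(abs(mt[pairs[1, ]]),
                                          abs(mt[pairs[2, ]])))
  verdict <- ifelse(!informative, "model_tie",
             ifelse(de == 0, "insufficient",
             ifelse(sign(dm) == sign(de), "agree", "disagree")))
  tab <- data.frame(X = pairs[1, ], Y = pairs[2, ], verdict = verdict,
                    stringsAsFactors = FALSE, row.names = NULL)
  n <- sum(informative)
  if (n == 0) stop("no model-ranked ROI pairs", call. = FALSE)
  kt <- suppressWarnings(stats::cor(mt, ef, method = "kendall"))
  structure(list(
    n_pairs = n,
    frac_agree = sum(verdict == "agree") / n,
    frac_disagree = sum(verdict == "disagree") / n,
    frac_insufficient = sum(verdict == "insufficient") / n,
    kendall_tau = kt, table = tab), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(paste0("<temporal agreement> %d ranked ROI pairs\n",
                     "  agree %.1f%% | disagree %.1f%% | ",
                     "insufficient resolution %.1f%% | Kendall tau-b %.3f\n"),
              x$n_pairs, 100 * x$frac_agree, 100 * x$frac_disagree,
              100 * x$frac_insufficient, x$kendall_tau))
  invisible(x)
}

#' Shuffled experimental baseline
#'
#' Randomly reassigns ROIs to activation frames while preserving the
#' number of ROI activations in each frame (the per-frame histogram),
#' giving the chance-level ordering against which model agreement is
#' judged.
#'
#' @param exp_frames named numeric vector of experimental frames.
#' @param seed integer seed.
#' @return Named numeric vector with the same names and the same frame
#'   multiset.
#' @export
shuffled_baseline <- function(exp_frames, seed) {
  withr::with_seed(seed, {
    stats::setNames(sample(unname(exp_frames)), names(exp_frames))
  })
}
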