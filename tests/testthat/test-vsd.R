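test_that("affine landmark fit recovers exact and noisy maps", {
  pts <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0.3, 0.7), ncol = 2,
                byrow = TRUE)
  fit <- fit_affine_landmarks(pts, pts)
  expect_equal(fit$A, diag(2), tolerance = 1e-9)
  expect_equal(fit$b, c(0, 0), tolerance = 1e-9)
  expect_equal(fit$rms, 0, tolerance = 1e-9)

  # forward-generate by a known affine map, then recover it
  A <- matrix(c(1.2, -0.3, 0.4, 0.9), 2, 2)
  b <- c(2, -1)
  native <- t(A %*% t(pts)) + rep(b, each = nrow(pts))
  fit <- fit_affine_landmarks(pts, native)
  expect_equal(fit$A, A, tolerance = 1e-9)
  expect_equal(fit$b, b, tolerance = 1e-9)
  expect_lt(fit$rms, 1e-9)
  expect_equal(fit$transform(pts), native, tolerance = 1e-9)

  # five noisy landmark pairs: residual equals the normal-equation oracle
  withr::with_seed(8, {
    noisy <- native + matrix(stats::rnorm(10, 0, 0.05), ncol = 2)
  })
  fit <- fit_affine_landmarks(pts, noisy)
  X <- cbind(pts, 1)
  B <- solve(t(X) %*% X, t(X) %*% noisy)
  expect_equal(fit$rms,
               sqrt(mean(rowSums((X %*% B - noisy)^2))), tolerance = 1e-9)

  collinear <- cbind(1:4, (1:4) * 2)
  expect_error(fit_affine_landmarks(collinear, collinear), "degenerate")
  expect_error(fit_affine_landmarks(pts[1:2, ], pts[1:2, ]), "at least")
})

test_that("pixel activation time is the earliest poststimulus argmax", {
  tr <- function(peaks, t = 12) {
    arr <- array(0, c(t, 1, length(peaks)))
    for (k in seq_along(peaks)) arr[peaks[k] + 1, 1, k] <- 1
    arr
  }
  st <- vsd_stack(tr(c(7, 3)), stim_frame = 0)
  pt <- pixel_activation_time(st)
  expect_equal(as.vector(pt$frame), c(7, 3))
  expect_false(any(pt$unreliable))

  # two equal maxima at frames 5 and 9 -> 5
  arr <- array(0, c(12, 1, 1)); arr[c(6, 10), 1, 1] <- 1
  expect_equal(pixel_activation_time(vsd_stack(arr))$frame[1, 1], 5)

  # constant trace flagged unreliable, earliest frame returned
  flat <- vsd_stack(array(1, c(6, 1, 1)))
  pf <- pixel_activation_time(flat)
  expect_equal(pf$frame[1, 1], 0)
  expect_true(pf$unreliable[1, 1])

  # poststimulus window respected
  arr2 <- array(0, c(10, 1, 1)); arr2[2, 1, 1] <- 5; arr2[8, 1, 1] <- 1
  st2 <- vsd_stack(arr2, stim_frame = 3)
  expect_equal(pixel_activation_time(st2)$frame[1, 1], 7)
  expect_error(pixel_activation_time(vsd_stack(arr2), window = 40),
               "window")
})

test_that("ROI activation time is the modal pixel frame, earliest on ties", {
  labels <- matrix(c(1, 1, 1, 2, 2, 2, 2, 0), 2, 4)
  frames <- matrix(c(3, 3, 4, 2, 2, 5, 5, 9), 2, 4)
  rt <- roi_activation_time(frames, labels)
  expect_equal(unname(rt["1"]), 3)   # {3,3,4} -> 3
  expect_equal(unname(rt["2"]), 2)   # {2,2,5,5} -> earliest modal frame
  labels2 <- labels; labels2[labels2 == 2] <- 3
  expect_error(roi_activation_time(frames, labels2), "2")
  rt2 <- roi_activation_time(frames, labels, roi_names = c("VISp", "AUDp"))
  expect_equal(names(rt2), c("VISp", "AUDp"))
})

test_that("temporal agreement enumerates pairs exactly", {
  model <- c(A = 1, B = 2, C = 3)
  exp1 <- c(A = 1, B = 1, C = 2)
  ag <- temporal_agreement(model, exp1)
  expect_equal(ag$n_pairs, 3)
  expect_equal(ag$frac_agree, 2 / 3)
  expect_equal(ag$frac_insufficient, 1 / 3)
  expect_equal(ag$frac_disagree, 0)
  expect_equal(ag$frac_agree + ag$frac_disagree + ag$frac_insufficient, 1)

  exp_same <- c(A = 2, B = 5, C = 9)
  ag2 <- temporal_agreement(model, exp_same)
  expect_equal(ag2$frac_agree, 1)
  expect_equal(ag2$kendall_tau, 1)

  ag3 <- temporal_agreement(model, rev(c(A = 9, B = 5, C = 2)) [c("A","B","C")])
  expect_equal(ag3$frac_disagree, 1)
  expect_equal(ag3$kendall_tau, -1)

  # invariance to strictly monotone transforms of model times
  ag4 <- temporal_agreement(exp(model) + 5, exp1)
  expect_equal(ag4[c("frac_agree", "frac_disagree", "frac_insufficient")],
               ag[c("frac_agree", "frac_disagree", "frac_insufficient")])

  # model ties are excluded from the denominator
  ag5 <- temporal_agreement(c(A = 1, B = 1, C = 3), exp_same)
  expect_equal(ag5$n_pairs, 2)
  expect_error(temporal_agreement(c(A = 1), c(A = 1)), "at least 2")
})

test_that("shuffled baseline preserves the per-frame histogram", {
  ex <- c(A = 1, B = 1, C = 2, D = 3, E = 3, F = 3)
  sh <- shuffled_baseline(ex, seed = 9)
  expect_equal(names(sh), names(ex))
  expect_equal(sort(unname(sh)), sort(unname(ex)))
  expect_identical(shuffled_baseline(ex, 9), shuffled_baseline(ex, 9))
  # all ROIs in one frame: identity up to labelling
  expect_equal(unname(shuffled_baseline(c(A = 2, B = 2), 1)), c(2, 2))
})

test_that("synthetic stacks round-trip through extraction and TIFF", {
  labels <- grid_label_map(12, 12, block = 4, n_rois = 9)
  times <- stats::setNames(seq(0, 160, length.out = 9), as.character(1:9))
  st <- generate_vsd_stack(labels, times, noise_sd = 0, seed = 1)
  rt <- roi_activation_time(pixel_activation_time(st), labels)
  expect_equal(unname(rt), unname(floor(times / 6.67)))  # exact, zero noise

  # same seed -> identical stack; different seed -> different noise
  s1 <- generate_vsd_stack(labels, times, noise_sd = 0.1, seed = 2)
  s2 <- generate_vsd_stack(labels, times, noise_sd = 0.1, seed = 2)
  s3 <- generate_vsd_stack(labels, times, noise_sd = 0.1, seed = 3)
  expect_identical(s1$frames, s2$frames)
  expect_false(identical(s1$frames, s3$frames))

  # moderate noise, ROIs 3 frames apart: order still recovered
  t2 <- stats::setNames(c(0, 20, 40), as.character(1:3))
  lab2 <- grid_label_map(8, 12, block = 4, n_rois = 3)
  st2 <- generate_vsd_stack(lab2, t2, noise_sd = 0.2, seed = 5)
  r2 <- roi_activation_time(pixel_activation_time(st2), lab2)
  expect_true(all(diff(r2) > 0))

  # TIFF round-trip preserves argmax-based activation times
  path <- tempfile(fileext = ".tif")
  write_vsd_stack(st, path)
  st_back <- read_vsd_stack(path)
  expect_equal(dim(st_back$frames), dim(st$frames))
  expect_equal(pixel_activation_time(st_back)$frame,
               pixel_activation_time(st)$frame)

  expect_error(generate_vsd_stack(labels, times[1:5]), "without an")
})
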