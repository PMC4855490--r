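# Sliding-window probabilities, threshold calibration mechanics, segment
# extraction and per-segment fitting. Uses the packaged default model so
# these structural tests stay fast.

fake_probs <- function(O_B, O_C, O_D, dt = 0.1) {
  out <- data.frame(frame = seq_along(O_C) - 1L, O_B = O_B, O_C = O_C,
                    O_D = O_D, coverage = 31L)
  attr(out, "dt") <- dt
  attr(out, "S1") <- 31L
  class(out) <- c("spt_frameprobs", "data.frame")
  out
}

test_that("a trajectory of exactly one window gets that window's outputs everywhere", {
  net <- default_model()
  traj <- simulate_brownian(31, seed = 1)
  pr <- sliding_window_probabilities(traj, net, 31)
  o <- bpnn_forward(net, normalize_msd(compute_msd(traj, 29)))
  expect_equal(nrow(pr), 31)
  expect_equal(pr$coverage, rep(1L, 31))
  expect_equal(pr$O_B, rep(unname(o["Brownian"]), 31))
  expect_equal(pr$O_C, rep(unname(o["confined"]), 31))
  expect_equal(pr$O_D, rep(unname(o["directed"]), 31))
  expect_error(sliding_window_probabilities(simulate_brownian(30), net, 31),
               "too short")
})

test_that("window coverage counts frames correctly and averages stay in [0,1]", {
  net <- default_model()
  traj <- simulate_brownian(120, seed = 2)
  pr <- sliding_window_probabilities(traj, net, 31)
  expect_equal(pr$coverage[1], 1L)
  expect_equal(pr$coverage[120], 1L)
  expect_equal(pr$coverage[60], 31L)       # interior frame: all 31 windows
  expect_equal(pr$coverage[10], 10L)
  expect_true(all(pr$O_B >= 0 & pr$O_B <= 1))
  expect_true(all(pr$O_C >= 0 & pr$O_C <= 1))
  expect_true(all(pr$O_D >= 0 & pr$O_D <= 1))
  # pure Brownian input: Brownian output dominates on average
  set.seed(3)
  ob <- oc <- od <- numeric(0)
  for (i in 1:5) {
    p <- sliding_window_probabilities(simulate_brownian(300), net, 31)
    ob <- c(ob, p$O_B); oc <- c(oc, p$O_C); od <- c(od, p$O_D)
  }
  expect_gt(mean(ob), mean(oc))
  expect_gt(mean(ob), mean(od))
})

test_that("threshold curves are monotone, bounded and interpolate/clamp", {
  th <- default_thresholds()
  expect_true(all(diff(th$Y_C) <= 0))
  expect_true(all(diff(th$Y_D) <= 0))
  expect_true(all(th$Y_C >= 0 & th$Y_C <= 1))
  expect_equal(threshold_at(th, 5, "confined"), th$Y_C[1])
  expect_equal(threshold_at(th, 45, "confined"), th$Y_C[41])
  expect_equal(threshold_at(th, 2, "confined"), th$Y_C[1])   # clamped
  expect_equal(threshold_at(th, 90, "directed"), th$Y_D[41]) # clamped
  mid <- threshold_at(th, 10.5, "confined")
  expect_true(mid <= th$Y_C[6] && mid >= th$Y_C[7])
})

test_that("calibration at full confidence flags nothing on its own null ensemble", {
  net <- default_model()
  th <- calibrate_thresholds(net, n_null = 10, null_frames = 200,
                             confidence = 1.0, seed = 4)
  # zero false positives allowed: re-segmenting the calibration nulls
  # must produce no confined or directed run at all
  set.seed(4)
  for (i in 1:10) {
    traj <- simulate_brownian(200, 0.25, 0.1)
    res <- extract_segments(sliding_window_probabilities(traj, net, 31), th)
    expect_equal(res$segments$mode, "Brownian")
  }
})

test_that("segment extraction flags constructed probability traces exactly", {
  th <- default_thresholds()
  N <- 200
  # one clean confined block of 40 frames
  oc <- rep(0.01, N); oc[81:120] <- 0.99
  res <- extract_segments(fake_probs(rep(0.5, N), oc, rep(0.01, N)), th)
  segs <- res$segments
  conf <- segs[segs$mode == "confined", ]
  expect_equal(nrow(conf), 1)
  expect_equal(conf$start_frame, 80)
  expect_equal(conf$end_frame, 119)
  expect_equal(conf$n_frames, 40)
  expect_equal(conf$duration_s, 4.0)
  # everything below both curves: one Brownian segment spanning the lot
  res0 <- extract_segments(fake_probs(rep(0.9, N), rep(0.05, N),
                                      rep(0.05, N)), th)
  expect_equal(res0$segments$mode, "Brownian")
  expect_equal(res0$segments$n_frames, N)
  expect_equal(classify_trajectory(res0), "Brownian")
  # runs shorter than the minimum length are never accepted
  oc3 <- rep(0.01, N); oc3[50:52] <- 0.99
  res3 <- extract_segments(fake_probs(rep(0.5, N), oc3, rep(0.01, N)), th)
  expect_false(any(res3$segments$mode == "confined"))
})

test_that("overlapping confined/directed claims resolve to the stronger mode", {
  th <- default_thresholds()
  N <- 200
  oc <- rep(0.01, N); od <- rep(0.01, N)
  oc[61:110] <- 0.80          # confined claim, 50 frames
  od[91:140] <- 0.95          # directed claim overlaps frames 91-110
  res <- extract_segments(fake_probs(rep(0.2, N), oc, od), th)
  segs <- res$segments
  di <- segs[segs$mode == "directed", ]
  co <- segs[segs$mode == "confined", ]
  expect_equal(nrow(di), 1)
  expect_equal(di$start_frame, 90)      # directed wins the overlap
  expect_equal(di$end_frame, 139)
  expect_equal(nrow(co), 1)             # confined survives truncated
  expect_equal(co$start_frame, 60)
  expect_lte(co$end_frame, 89)
  expect_equal(classify_trajectory(res), "mixed")
})

test_that("segments partition the frame range without overlap", {
  net <- default_model(); th <- default_thresholds()
  for (s in 1:5) {
    traj <- simulate_composite(two_segment_recipe(), seed = 40 + s)
    res <- segment_trajectory(traj, net, th, fit = FALSE)
    segs <- res$segments[order(res$segments$start_frame), ]
    expect_equal(segs$start_frame[1], 0)
    expect_equal(segs$end_frame[nrow(segs)], 399)
    if (nrow(segs) > 1)
      expect_true(all(segs$start_frame[-1] == segs$end_frame[-nrow(segs)] + 1))
  }
})

test_that("per-segment fits use the matching model and flag unfittable segments", {
  th <- default_thresholds()
  # construct a segmentation over a known composite trajectory
  traj <- simulate_composite(two_segment_recipe(), seed = 77)
  probs <- fake_probs(rep(0.9, 400), rep(0.05, 400), rep(0.05, 400))
  res <- extract_segments(probs, th)
  res$segments <- data.frame(
    mode = c("Brownian", "confined", "directed", "confined"),
    start_frame = c(0L, 100L, 300L, 396L),
    end_frame = c(99L, 149L, 349L, 399L),
    n_frames = c(100L, 50L, 50L, 4L),
    duration_s = c(10, 5, 5, 0.4))
  out <- fit_segments(traj, res)$segments
  expect_gt(out$D[1], 0)                      # Brownian D estimated
  expect_true(is.na(out$L[1]) && is.na(out$V[1]))
  expect_gt(out$L[2], 0)                      # confined L
  expect_gt(out$V[3], 0)                      # directed V
  expect_true(is.na(out$D[4]) && is.na(out$L[4]))  # too short to fit
})
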