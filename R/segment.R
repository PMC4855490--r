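# Sliding-window segmentation of trajectories into diffusion modes.
#
# A window of S1 frames (default 31, odd) slides one frame at a time over
# the trajectory. Each window's normalized MSD curve is classified by the
# BPNN and the three outputs are attributed to every frame of the window;
# per-frame probabilities are the arithmetic means over all windows
# covering the frame. Confined/directed segments are then the runs of
# consecutive frames whose averaged output exceeds a run-length-dependent
# threshold calibrated so that pure Brownian trajectories produce fewer
# than 5% falsely flagged frames.

# All-window MSD curves of a trajectory, one row per window start.
# Uses the same displacement-pair convention as compute_msd restricted to
# each window: for a window starting at frame s (1-based) with S1 frames,
# MSD_w(n) = 1/(S1-1-n) * sum_{j=1}^{S1-1-n} d2[s+j, n].
window_msd_matrix <- function(traj, S1) {
  N <- n_frames(traj)
  n_win <- N - S1 + 1L
  n_lag <- S1 - 2L
  x <- traj$x; y <- traj$y
  out <- matrix(0, n_win, n_lag)
  for (n in seq_len(n_lag)) {
    i <- seq_len(N - n)
    d2 <- (x[i + n] - x[i])^2 + (y[i + n] - y[i])^2
    cs <- c(0, cumsum(d2))
    # window s needs pairs starting at absolute indices (s+1)..(s+S1-1-n)
    s <- seq_len(n_win)
    out[, n] <- (cs[s + S1 - n] - cs[s + 1L]) / (S1 - 1L - n)
  }
  out
}

#' Per-frame diffusion-mode probabilities from the sliding window
#'
#' Slides an `S1`-frame window over the trajectory, classifies each
#' window's normalized MSD curve with the BPNN, attributes the three
#' outputs to all frames of the window and averages per frame.
#'
#' @param traj trajectory with at least `S1` frames.
#' @param model trained [bpnn_new()] model with `m = S1 - 2` inputs.
#' @param S1 window length in frames (odd, default 31).
#' @return Object of class `spt_frameprobs`: data frame with columns
#'   `frame`, `O_B`, `O_C`, `O_D`, `coverage`, plus `dt` attribute.
#' @export
sliding_window_probabilities <- function(traj, model, S1 = 31L) {
  S1 <- check_count(S1, "S1", min = 5L)
  if (S1 %% 2L == 0L) stop("`S1` must be odd", call. = FALSE)
  N <- n_frames(traj)
  if (N < S1)
    stop(sprintf("trajectory too short: %d frames < window S1 = %d", N, S1),
         call. = FALSE)
  if (model$m != S1 - 2L)
    stop(sprintf("model expects m = %d inputs but window gives %d lags",
                 model$m, S1 - 2L), call. = FALSE)
  M <- window_msd_matrix(traj, S1)
  mx <- apply(M, 1L, max)
  ok <- mx > 0
  Xn <- M / pmax(mx, .Machine$double.eps)
  O <- matrix(NA_real_, nrow(M), 3L)
  if (any(ok)) O[ok, ] <- bpnn_forward_batch(model, Xn[ok, , drop = FALSE])
  n_win <- nrow(M)
  # frame f (1-based) is covered by windows s in [max(1, f-S1+1), min(f, n_win)]
  sums <- matrix(0, N, 3L)
  counts <- numeric(N)
  Ow <- O; Ow[!ok, ] <- 0
  csO <- rbind(0, apply(Ow, 2L, cumsum))
  csn <- c(0, cumsum(as.numeric(ok)))
  f <- seq_len(N)
  lo <- pmax(1L, f - S1 + 1L)
  hi <- pmin(f, n_win)
  for (k in 1:3) sums[, k] <- csO[hi + 1L, k] - csO[lo, k]
  counts <- csn[hi + 1L] - csn[lo]
  if (any(counts == 0))
    stop("some frames received no valid window attribution (degenerate MSD curves)",
         call. = FALSE)
  out <- data.frame(frame = traj$frame,
                    O_B = sums[, 1L] / counts,
                    O_C = sums[, 2L] / counts,
                    O_D = sums[, 3L] / counts,
                    coverage = as.integer(counts))
  attr(out, "dt") <- frame_interval(traj)
  attr(out, "S1") <- S1
  class(out) <- c("spt_frameprobs", "data.frame")
  out
}

# Fraction of frames lying in runs of >= k consecutive TRUEs, pooled over
# a list of logical run sources given as numeric vectors and a threshold.
flagged_fraction <- function(outputs, Y, k) {
  flagged <- 0L
  total <- 0L
  for (o in outputs) {
    total <- total + length(o)
    r <- rle(o > Y)
    sel <- r$values & r$lengths >= k
    if (any(sel)) flagged <- flagged + sum(r$lengths[sel])
  }
  flagged / total
}

# Fraction of frames flagged by the union-over-run-lengths detection rule
# (see union_runs) on a list of null output vectors.
union_flagged_fraction <- function(outputs, ks, Y) {
  th <- structure(list(k = ks, Y_C = Y, Y_D = Y), class = "spt_thresholds")
  flagged <- 0L; total <- 0L
  for (o in outputs) {
    total <- total + length(o)
    runs <- union_runs(o, th, "confined", min_run = min(ks))
    flagged <- flagged + sum(runs$len)
  }
  flagged / total
}

#' Calibrate run-length-dependent detection thresholds on Brownian nulls
#'
#' Generates `n_null` pure Brownian trajectories and computes their
#' per-frame averaged BPNN outputs. For every run length `k` the
#' threshold `Y(k)` is the smallest output value such that frames
#' belonging to runs of at least `k` consecutive frames above `Y(k)` make
#' up at most a fraction `q` of all null frames; the per-run-length level
#' `q` is then chosen (by bisection) so that the segment detector that
#' uses the whole threshold family — a frame is flagged when any
#' calibrated run length accepts it, see [extract_segments()] — falsely
#' flags at most `1 - confidence` of the null frames (5% at the default
#' 95% confidence). One curve is produced per non-Brownian mode (`Y_C`
#' for confined, `Y_D` for directed) and each is made non-increasing in
#' `k` by isotonic post-processing (raising a threshold can only reduce
#' false positives).
#'
#' @param model trained `bpnn`.
#' @param S1 window length (frames).
#' @param n_null number of null trajectories (default 100).
#' @param null_frames frames per null trajectory (default 1000).
#' @param D,dt diffusion coefficient (um^2/s) and frame interval (s) of
#'   the null ensemble (defaults 0.25 and 0.1).
#' @param run_lengths run lengths to tabulate (default 5:45).
#' @param confidence confidence level (default 0.95).
#' @param familywise control the false-positive rate of the full
#'   union-over-run-lengths detector (default) rather than of each run
#'   length separately.
#' @param seed RNG seed.
#' @return Object of class `spt_thresholds`: list with `k`, `Y_C`, `Y_D`
#'   and calibration metadata.
#' @export
calibrate_thresholds <- function(model, S1 = 31L, n_null = 100L,
                                 null_frames = 1000L, D = 0.25, dt = 0.1,
                                 run_lengths = 5:45, confidence = 0.95,
                                 familywise = TRUE, seed = NULL) {
  n_null <- check_count(n_null, "n_null", min = 10L)
  null_frames <- check_count(null_frames, "null_frames", min = S1)
  if (!(confidence > 0 && confidence <= 1))
    stop("`confidence` must be in (0, 1]", call. = FALSE)
  run_lengths <- sort(unique(as.integer(run_lengths)))
  fp_allow <- 1 - confidence
  iso <- function(y) rev(cummax(rev(y)))
  with_seed(seed, {
    oc <- vector("list", n_null)
    od <- vector("list", n_null)
    for (i in seq_len(n_null)) {
      traj <- simulate_brownian(null_frames, D, dt)
      pr <- sliding_window_probabilities(traj, model, S1)
      oc[[i]] <- pr$O_C
      od[[i]] <- pr$O_D
    }
    # per-run-length threshold family at per-k allowed fraction q
    family_at <- function(outputs, cand, q) {
      iso(vapply(run_lengths, function(k) {
        lo <- 1L; hi <- length(cand)
        while (lo < hi) {   # smallest candidate with flagged fraction <= q
          mid <- (lo + hi) %/% 2L
          if (flagged_fraction(outputs, cand[mid], k) <= q) hi <- mid
          else lo <- mid + 1L
        }
        cand[lo]
      }, 1.0))
    }
    calibrate_one <- function(outputs) {
      pooled <- sort(unique(round(unlist(outputs), 6)))
      cand <- if (length(pooled) > 4000L)
        unique(stats::quantile(pooled, probs = seq(0, 1, length.out = 4000L),
                               names = FALSE, type = 1L))
      else pooled
      cand <- c(cand, 1)   # Y = 1 always satisfies the bound (strict '>')
      Y <- family_at(outputs, cand, fp_allow)
      if (!familywise ||
          union_flagged_fraction(outputs, run_lengths, Y) <= fp_allow)
        return(Y)
      # bisect the per-k level until the union detector sits at fp_allow
      lo_q <- fp_allow / length(run_lengths); hi_q <- fp_allow
      for (it in 1:12) {
        mid_q <- (lo_q + hi_q) / 2
        Y <- family_at(outputs, cand, mid_q)
        if (union_flagged_fraction(outputs, run_lengths, Y) <= fp_allow)
          lo_q <- mid_q
        else hi_q <- mid_q
      }
      family_at(outputs, cand, lo_q)
    }
    structure(list(k = run_lengths, Y_C = calibrate_one(oc),
                   Y_D = calibrate_one(od),
                   meta = list(n_null = n_null, null_frames = null_frames,
                               D = D, dt = dt, S1 = S1,
                               confidence = confidence,
                               familywise = familywise, seed = seed)),
              class = "spt_thresholds")
  })
}

#' @export
print.spt_thresholds <- function(x, ...) {
  cat(sprintf(
    "<spt_thresholds> run lengths %d..%d, %g%% confidence (%d nulls x %d frames)\n",
    min(x$k), max(x$k), 100 * x$meta$confidence, x$meta$n_null,
    x$meta$null_frames))
  cat(sprintf("  Y_C: %.3f .. %.3f   Y_D: %.3f .. %.3f\n",
              x$Y_C[1L], x$Y_C[length(x$Y_C)],
              x$Y_D[1L], x$Y_D[length(x$Y_D)]))
  invisible(x)
}

#' Threshold value at a given run length (interpolated)
#'
#' Linear interpolation between tabulated run lengths, clamped to the
#' tabulated range.
#'
#' @param thresholds an `spt_thresholds` object.
#' @param k run length (frames).
#' @param mode `"confined"` or `"directed"`.
#' @export
threshold_at <- function(thresholds, k, mode = c("confined", "directed")) {
  mode <- match.arg(mode)
  y <- if (mode == "confined") thresholds$Y_C else thresholds$Y_D
  stats::approx(thresholds$k, y, xout = pmin(pmax(k, min(thresholds$k)),
                                             max(thresholds$k)),
                rule = 2L)$y
}

# Maximal runs of TRUE in a logical vector -> data.frame(start, end, len)
# (1-based inclusive indices).
true_runs <- function(b) {
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             len = r$lengths[keep])
}

# Flagged runs for one mode, mirroring the threshold calibration: a frame
# is flagged when, for some tabulated run length k, it belongs to a run
# of at least k consecutive frames whose output exceeds Y(k). Returns the
# maximal runs of flagged frames.
union_runs <- function(o, thresholds, mode, min_run) {
  flagged <- logical(length(o))
  ks <- thresholds$k[thresholds$k >= min_run]
  for (k in ks) {
    y <- threshold_at(thresholds, k, mode)
    runs <- true_runs(o > y)
    runs <- runs[runs$len >= k, , drop = FALSE]
    for (i in seq_len(nrow(runs)))
      flagged[runs$start[i]:runs$end[i]] <- TRUE
  }
  out <- true_runs(flagged)
  out[out$len >= min_run, , drop = FALSE]
}

#' Extract confined/directed segments from frame probabilities
#'
#' For each non-Brownian mode a frame is flagged when, for some
#' calibrated run length `k`, it belongs to a run of at least `k`
#' consecutive frames whose averaged output exceeds the threshold
#' `Y(k)` — the same construction the null calibration controls at 5%
#' false positives per run length. Maximal runs of flagged frames are the
#' candidate segments. When a confined and a directed candidate overlap,
#' the mode with the larger mean output over the overlap wins; the loser
#' is truncated and re-tested. All remaining frames are Brownian.
#'
#' @param probs frame probabilities from [sliding_window_probabilities()].
#' @param thresholds calibrated [calibrate_thresholds()] curves.
#' @param min_run minimum accepted run length in frames (default 5, the
#'   smallest calibrated run length).
#' @return Object of class `spt_segmentation`: list with `segments` (data
#'   frame: mode, start_frame, end_frame (0-based inclusive), n_frames,
#'   duration_s), the input `probs`, `n_frames` and `dt`.
#' @export
extract_segments <- function(probs, thresholds, min_run = 5L) {
  N <- nrow(probs)
  dt <- attr(probs, "dt") %||% NA_real_
  rc <- union_runs(probs$O_C, thresholds, "confined", min_run)
  rd <- union_runs(probs$O_D, thresholds, "directed", min_run)

  # resolve confined/directed overlaps
  repeat {
    ov <- NULL
    for (i in seq_len(nrow(rc))) {
      for (j in seq_len(nrow(rd))) {
        s <- max(rc$start[i], rd$start[j])
        e <- min(rc$end[i], rd$end[j])
        if (s <= e) { ov <- list(i = i, j = j, s = s, e = e); break }
      }
      if (!is.null(ov)) break
    }
    if (is.null(ov)) break
    mean_c <- mean(probs$O_C[ov$s:ov$e])
    mean_d <- mean(probs$O_D[ov$s:ov$e])
    if (mean_c >= mean_d) {   # confined wins; truncate the directed run
      rd <- truncate_run(rd, ov$j, ov$s, ov$e, probs$O_D, thresholds,
                         "directed", min_run)
    } else {
      rc <- truncate_run(rc, ov$i, ov$s, ov$e, probs$O_C, thresholds,
                         "confined", min_run)
    }
  }

  segs <- rbind(
    if (nrow(rc)) data.frame(mode = "confined", start = rc$start, end = rc$end),
    if (nrow(rd)) data.frame(mode = "directed", start = rd$start, end = rd$end))
  occupied <- logical(N)
  if (!is.null(segs) && nrow(segs))
    for (i in seq_len(nrow(segs)))
      occupied[segs$start[i]:segs$end[i]] <- TRUE
  br <- true_runs(!occupied)
  if (nrow(br))
    segs <- rbind(segs, data.frame(mode = "Brownian", start = br$start,
                                   end = br$end))
  segs <- segs[order(segs$start), , drop = FALSE]
  out <- data.frame(mode = segs$mode,
                    start_frame = segs$start - 1L,
                    end_frame = segs$end - 1L,
                    n_frames = segs$end - segs$start + 1L)
  out$duration_s <- out$n_frames * dt
  structure(list(segments = out, probs = probs, n_frames = N, dt = dt),
            class = "spt_segmentation")
}

# Remove the overlap [s, e] from run `idx`, re-test the remaining pieces
# with the same union-over-run-lengths rule (the piece's output values
# outside the overlap are unchanged, so re-scanning a masked copy works).
truncate_run <- function(runs, idx, s, e, o, thresholds, mode, min_run) {
  run <- runs[idx, ]
  rest <- runs[-idx, , drop = FALSE]
  masked <- rep(-Inf, length(o))
  keep <- setdiff(run$start:run$end, s:e)
  masked[keep] <- o[keep]
  pieces <- union_runs(masked, thresholds, mode, min_run)
  rbind(rest, pieces)
}

#' @export
print.spt_segmentation <- function(x, ...) {
  cat(sprintf("<spt_segmentation> %d frames -> %d segments (%s)\n",
              x$n_frames, nrow(x$segments), classify_trajectory(x)))
  print(x$segments)
  invisible(x)
}

#' Fit per-segment diffusion parameters
#'
#' Computes each segment's own MSD curve and fits the model matching its
#' mode: free diffusion for Brownian segments (`D`), the confined model
#' for confined segments (`D`, `L`), the directed model for directed
#' segments (`D`, `V`). Brownian segments use the apparent short-lag
#' estimate (first four MSD points, as in [estimate_d14()]): the long
#' lags of a single short segment's time-averaged MSD are strongly
#' downward biased and would drag a full-curve slope with them. Segments
#' too short to fit (< 6 frames) keep `NA` parameters.
#'
#' @param traj the segmented trajectory.
#' @param result an [extract_segments()] result on that trajectory.
#' @return The result with `D`, `L`, `V` columns added to `$segments`.
#' @export
fit_segments <- function(traj, result) {
  segs <- result$segments
  segs$D <- segs$L <- segs$V <- NA_real_
  for (i in seq_len(nrow(segs))) {
    idx <- (segs$start_frame[i]:segs$end_frame[i]) + 1L
    if (length(idx) < 6L) next
    sub <- new_trajectory(traj$x[idx], traj$y[idx], frame_interval(traj))
    curve <- compute_msd(sub)
    if (segs$mode[i] == "Brownian") {
      segs$D[i] <- estimate_d14(curve)
      next
    }
    fit <- switch(segs$mode[i],
                  confined = fit_confined(curve),
                  directed = fit_directed(curve))
    if (isTRUE(fit$converged)) {
      segs$D[i] <- fit$D
      segs$L[i] <- fit$L
      segs$V[i] <- fit$V
    }
  }
  result$segments <- segs
  result
}

#' Classify a segmented trajectory as pure or mixed
#'
#' @param result an `spt_segmentation`.
#' @return `"Brownian"`, `"confined"` or `"directed"` when a single mode
#'   covers the whole trajectory, otherwise `"mixed"`.
#' @export
classify_trajectory <- function(result) {
  modes <- unique(result$segments$mode)
  if (length(modes) == 1L) modes else "mixed"
}

#' Segment a trajectory end-to-end
#'
#' Convenience wrapper: sliding-window probabilities, threshold-based
#' segment extraction and per-segment parameter fits in one call.
#'
#' @param traj trajectory to segment.
#' @param model trained `bpnn`.
#' @param thresholds calibrated `spt_thresholds`.
#' @param S1 window length (frames, default taken from the calibration).
#' @param fit fit per-segment parameters (default TRUE).
#' @export
segment_trajectory <- function(traj, model, thresholds, S1 = NULL,
                               fit = TRUE) {
  S1 <- S1 %||% thresholds$meta$S1 %||% 31L
  probs <- sliding_window_probabilities(traj, model, S1)
  res <- extract_segments(probs, thresholds)
  if (fit) res <- fit_segments(traj, res)
  res
}
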