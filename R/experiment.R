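# Replicated detection experiments on composite synthetic trajectories.

# Build the composite segment list for one replicate: Brownian filler
# around the embedded segments (0-based starts), sampling any parameter
# given as a length-2 range.
build_recipe <- function(n_total, embedded) {
  embedded <- embedded[order(vapply(embedded, `[[`, 1, "start"))]
  segs <- list()
  cursor <- 0L
  for (e in embedded) {
    if (e$start < cursor)
      stop("embedded segments overlap or are unordered", call. = FALSE)
    if (e$start > cursor)
      segs[[length(segs) + 1L]] <- list(mode = "Brownian",
                                        length = e$start - cursor)
    seg <- list(mode = e$mode, length = e$length)
    if (!is.null(e$L)) seg$L <- sample_param(e$L)
    if (!is.null(e$V)) seg$V <- sample_param(e$V)
    segs[[length(segs) + 1L]] <- seg
    cursor <- e$start + e$length
  }
  if (cursor > n_total)
    stop("embedded segments exceed the trajectory length", call. = FALSE)
  if (cursor < n_total)
    segs[[length(segs) + 1L]] <- list(mode = "Brownian",
                                      length = n_total - cursor)
  segs
}

sample_param <- function(p) {
  if (length(p) == 2L) stats::runif(1L, p[1L], p[2L]) else p[1L]
}

# Does any reported segment of `mode` overlap >= `frac` of the true
# frames [start, start+len-1] (0-based)? Returns the index of the best
# such segment, or 0.
match_segment <- function(segments, mode, start, len, frac = 0.5) {
  truth <- start:(start + len - 1L)
  best <- 0L; best_ov <- 0L
  rows <- which(segments$mode == mode)
  for (i in rows) {
    ov <- length(intersect(truth,
                           segments$start_frame[i]:segments$end_frame[i]))
    if (ov > best_ov) { best_ov <- ov; best <- i }
  }
  if (best_ov >= frac * len) best else 0L
}

#' Run a replicated segmentation-detection experiment
#'
#' Simulates `n_traj` composite trajectories from a recipe of embedded
#' non-Brownian segments at fixed frame positions (parameters given as a
#' fixed value or a `c(lo, hi)` uniform range resampled per replicate),
#' segments each with the trained pipeline, and scores detection of every
#' embedded segment by the >= 50%-overlap rule: a true segment counts as
#' detected when one reported segment of the same mode overlaps at least
#' half of its frames.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{n_traj}{replicate count (>= 1).}
#'     \item{n_frames}{frames per trajectory.}
#'     \item{D, dt}{diffusion coefficient (um^2/s) and frame interval (s);
#'       defaults 0.25 and 0.1.}
#'     \item{segments}{list of embedded segments, each a list with `mode`
#'       (`"confined"`/`"directed"`), `start` (0-based frame), `length`
#'       (frames), and `L` or `V` (value or range).}
#'     \item{P_n}{optional positioning-noise amplitude in um (default 0).}
#'     \item{seed}{base seed; replicate i derives independent sub-seeds
#'       for its parameter draws, trajectory and noise, so the clean and
#'       noisy versions of an ensemble share the same trajectories.}
#'     \item{overlap}{detection overlap fraction (default 0.5).}
#'   }
#' @param model trained `bpnn`.
#' @param thresholds calibrated `spt_thresholds`.
#' @param S1 window length (frames).
#' @param fit fit parameters of matched segments (default TRUE).
#' @return List with `summary` (data frame: mode, length, n, n_detected,
#'   detection_rate in percent, mean_fitted_param), `specificity_pct`
#'   (percent of ground-truth Brownian frames not claimed by a
#'   confined/directed call), and the per-replicate `detected` matrix.
#' @export
run_experiment <- function(config, model, thresholds, S1 = 31L, fit = TRUE) {
  n_traj <- check_count(config$n_traj, "n_traj")
  n_total <- check_count(config$n_frames, "n_frames")
  D <- config$D %||% 0.25
  dt <- config$dt %||% 0.1
  P_n <- config$P_n %||% 0
  overlap <- config$overlap %||% 0.5
  seed <- config$seed %||% 1L
  emb <- config$segments %||% list()
  n_emb <- length(emb)

  detected <- matrix(FALSE, n_traj, n_emb)
  fitted_param <- matrix(NA_real_, n_traj, n_emb)
  brown_frames <- 0L
  brown_clean <- 0L

  for (r in seq_len(n_traj)) {
    recipe <- with_seed(seed + 1000000L + r, build_recipe(n_total, emb))
    traj <- simulate_composite(recipe, D = D, tau = dt, seed = seed + r)
    if (P_n > 0)
      traj <- add_positioning_noise(traj, P_n, seed = seed + 2000000L + r)
    res <- segment_trajectory(traj, model, thresholds, S1, fit = fit)
    segs <- res$segments
    cursor_emb <- emb
    for (j in seq_len(n_emb)) {
      idx <- match_segment(segs, cursor_emb[[j]]$mode,
                           cursor_emb[[j]]$start, cursor_emb[[j]]$length,
                           overlap)
      if (idx > 0L) {
        detected[r, j] <- TRUE
        if (fit)
          fitted_param[r, j] <- if (cursor_emb[[j]]$mode == "confined")
            segs$L[idx] else segs$V[idx]
      }
    }
    truth_brown <- traj$label == "Brownian"
    claimed <- logical(n_total)
    nb <- segs[segs$mode != "Brownian", , drop = FALSE]
    for (i in seq_len(nrow(nb)))
      claimed[(nb$start_frame[i]:nb$end_frame[i]) + 1L] <- TRUE
    brown_frames <- brown_frames + sum(truth_brown)
    brown_clean <- brown_clean + sum(truth_brown & !claimed)
  }

  summary <- if (n_emb > 0L) data.frame(
    mode = vapply(emb, `[[`, "", "mode"),
    length = vapply(emb, function(e) as.integer(e$length), 1L),
    n = n_traj,
    n_detected = colSums(detected),
    detection_rate = 100 * colMeans(detected),
    mean_fitted_param = apply(fitted_param, 2L, function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)))
  else data.frame(mode = character(0), length = integer(0), n = integer(0),
                  n_detected = integer(0), detection_rate = numeric(0),
                  mean_fitted_param = numeric(0))

  list(summary = summary,
       specificity_pct = if (brown_frames > 0)
         100 * brown_clean / brown_frames else NA_real_,
       detected = detected,
       fitted_param = fitted_param)
}

#' Recall accuracy of a trained network on fresh single-mode windows
#'
#' Simulates `n` naive windows per requested condition and reports the
#' fraction classified into the true mode by the argmax rule; this is the
#' window-level detection probability as a function of the confinement
#' diameter or drift speed.
#'
#' @param model trained `bpnn`.
#' @param mode `"confined"` or `"directed"`.
#' @param values grid of `L` (um) or `V` (um/s) values.
#' @param n windows per grid point (default 200).
#' @param window,D,tau simulation conditions (defaults 31 frames,
#'   0.25 um^2/s, 0.1 s).
#' @param seed RNG seed.
#' @return Data frame with `value` and `detection_rate` (percent).
#' @export
window_detection_curve <- function(model, mode = c("confined", "directed"),
                                   values, n = 200L, window = 31L,
                                   D = 0.25, tau = 0.1, seed = NULL) {
  mode <- match.arg(mode)
  n <- check_count(n, "n")
  with_seed(seed, {
    rate <- vapply(values, function(v) {
      hits <- 0L
      for (i in seq_len(n)) {
        traj <- if (mode == "confined")
          simulate_confined(window, D, tau, L = v)
        else simulate_directed(window, D, tau, V = v)
        x <- normalize_msd(compute_msd(traj, n_max = window - 2L))
        if (bpnn_classify(model, x) == mode) hits <- hits + 1L
      }
      100 * hits / n
    }, 1.0)
    data.frame(value = values, detection_rate = rate)
  })
}
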