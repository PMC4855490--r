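#' Construct a single-particle trajectory
#'
#' A trajectory is a data frame with columns `frame` (0-based integer),
#' `t` (seconds), `x`, `y` (micrometres) and optionally `label`
#' (per-frame ground-truth motion mode for simulated composites), carrying
#' the frame interval as an attribute. Frames must be uniformly spaced.
#'
#' @param x,y numeric coordinate vectors (micrometres), equal length >= 2.
#' @param dt frame interval in seconds.
#' @param t optional explicit time stamps; defaults to `(0:(N-1)) * dt`.
#' @param label optional character vector of per-frame mode labels
#'   (`"Brownian"`, `"confined"`, `"directed"`).
#' @return An object of class `spt_traj` (a data frame).
#' @export
new_trajectory <- function(x, y, dt, t = NULL, label = NULL) {
  if (length(x) != length(y))
    stop("`x` and `y` must have the same length", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("a trajectory needs at least 2 frames", call. = FALSE)
  check_positive(dt, "dt")
  if (is.null(t)) t <- (seq_len(n) - 1) * dt
  if (length(t) != n)
    stop("`t` must match the length of `x` and `y`", call. = FALSE)
  validate_uniform_times(t, dt)
  df <- data.frame(frame = seq_len(n) - 1L, t = t, x = x, y = y)
  if (!is.null(label)) {
    if (length(label) != n)
      stop("`label` must have one entry per frame", call. = FALSE)
    df$label <- label
  }
  attr(df, "frame_interval") <- dt
  class(df) <- c("spt_traj", "data.frame")
  df
}

validate_uniform_times <- function(t, dt, tol = 1e-6) {
  if (any(diff(t) <= 0))
    stop("time stamps must be strictly increasing", call. = FALSE)
  if (any(abs(diff(t) - dt) > tol * max(dt, 1))) {
    bad <- which(abs(diff(t) - dt) > tol * max(dt, 1))[1L]
    stop(sprintf(
      "non-uniform frame spacing: interval after sample %d is %.6g, expected %.6g",
      bad, diff(t)[bad], dt), call. = FALSE)
  }
  invisible(t)
}

#' @return Frame interval (seconds) of a trajectory.
#' @rdname new_trajectory
#' @param traj an `spt_traj` object.
#' @export
frame_interval <- function(traj) {
  dt <- attr(traj, "frame_interval")
  if (is.null(dt)) dt <- stats::median(diff(traj$t))
  dt
}

n_frames <- function(traj) nrow(traj)

#' @export
print.spt_traj <- function(x, ...) {
  cat(sprintf("<spt_traj> %d frames, dt = %g s, duration %.3g s\n",
              nrow(x), frame_interval(x), x$t[nrow(x)] - x$t[1L]))
  if (!is.null(x$label)) {
    tab <- table(x$label)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  utils::str(utils::head(as.data.frame(x), 3))
  invisible(x)
}
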