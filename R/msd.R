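# Mean square displacement (MSD) analysis.
#
# The time-averaged MSD of a uniformly sampled 2-D trajectory with N
# frames at times 0, dt, ..., (N-1)*dt is, for lag n*dt,
#
#   MSD(n*dt) = 1/(N-1-n) * sum_{j=1}^{N-1-n}
#               [x((j+n)dt) - x(j dt)]^2 + [y((j+n)dt) - y(j dt)]^2
#
# i.e. an average over the N-1-n displacement pairs starting from the
# second frame. Valid lags are n = 1 .. N-2.

#' Compute the MSD curve of a trajectory
#'
#' @param traj an [new_trajectory()] object (uniformly sampled).
#' @param n_max largest lag index to compute (defaults to `N - 2`, the
#'   largest valid lag).
#' @return An object of class `spt_msd`: a data frame with columns `lag`
#'   (seconds) and `msd` (um^2), carrying `n_frames_source` and `dt`
#'   attributes.
#' @export
compute_msd <- function(traj, n_max = NULL) {
  N <- n_frames(traj)
  dt <- frame_interval(traj)
  validate_uniform_times(traj$t, dt)
  if (is.null(n_max)) n_max <- N - 2L
  n_max <- check_count(n_max, "n_max")
  if (n_max > N - 2L)
    stop(sprintf("n_max = %d exceeds the largest valid lag N - 2 = %d",
                 n_max, N - 2L), call. = FALSE)
  x <- traj$x; y <- traj$y
  msd <- numeric(n_max)
  for (n in seq_len(n_max)) {
    # pairs j = 1 .. N-1-n, 0-based times: indices (j+1) and (j+n+1)
    j <- seq_len(N - 1L - n)
    dxx <- x[j + n + 1L] - x[j + 1L]
    dyy <- y[j + n + 1L] - y[j + 1L]
    msd[n] <- sum(dxx * dxx + dyy * dyy) / (N - 1L - n)
  }
  out <- data.frame(lag = seq_len(n_max) * dt, msd = msd)
  attr(out, "n_frames_source") <- N
  attr(out, "dt") <- dt
  class(out) <- c("spt_msd", "data.frame")
  out
}

#' Normalize an MSD curve for network input
#'
#' Divides the curve by its maximum so that values lie in `[0, 1]` with
#' the maximum exactly 1; the curve shape (linear, saturating, upward
#' curved) is what distinguishes the diffusion modes, not its scale.
#'
#' @param curve an `spt_msd` object or numeric vector of MSD values.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_msd <- function(curve) {
  v <- if (is.data.frame(curve)) curve$msd else as.numeric(curve)
  m <- max(v)
  if (!is.finite(m) || m <= 0)
    stop("degenerate MSD curve: no positive value to normalize by",
         call. = FALSE)
  v / m
}

fit_result <- function(model, D = NA_real_, V = NA_real_, L = NA_real_,
                       residual = Inf, converged = TRUE) {
  structure(list(model = model, D = D, V = V, L = L,
                 residual = residual, converged = converged),
            class = "spt_fit")
}

#' @export
print.spt_fit <- function(x, ...) {
  cat(sprintf("<spt_fit:%s> D = %.4g um2/s", x$model, x$D))
  if (!is.na(x$V)) cat(sprintf(", V = %.4g um/s", x$V))
  if (!is.na(x$L)) cat(sprintf(", L = %.4g um", x$L))
  cat(sprintf(", RSS = %.4g%s\n", x$residual,
              if (x$converged) "" else " (fit failed)"))
  invisible(x)
}

msd_parts <- function(curve) {
  if (is.data.frame(curve)) list(lag = curve$lag, msd = curve$msd)
  else stop("expected an `spt_msd` curve", call. = FALSE)
}

#' Fit the free-diffusion model MSD = 4 D t
#'
#' Ordinary least squares of the curve on lag (free intercept absorbs
#' static offsets); `D` is the slope over 4, clamped at 0. When the
#' unconstrained slope is negative the constrained optimum is the flat
#' line at the curve mean, which is what the residual reports.
#'
#' @param curve an `spt_msd` object.
#' @return An `spt_fit` with fields `model = "free"`, `D`, `residual`.
#' @export
fit_free <- function(curve) {
  p <- msd_parts(curve)
  if (length(p$lag) < 2L)
    stop("fit_free needs at least 2 lags", call. = FALSE)
  fit <- stats::lm(p$msd ~ p$lag)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0) {
    fit_result("free", D = slope / 4, residual = sum(stats::resid(fit)^2))
  } else {
    fit_result("free", D = 0, residual = sum((p$msd - mean(p$msd))^2))
  }
}

#' Fit the directed-diffusion model MSD = 4 D t + V^2 t^2
#'
#' Quadratic least squares; `V` is the square root of the quadratic
#' coefficient and `D` the linear coefficient over 4, both clamped at
#' their physical bound. A negative quadratic coefficient collapses the
#' model to the free fit with `V = 0`, so the directed residual never
#' exceeds the free residual.
#'
#' @param curve an `spt_msd` object.
#' @return An `spt_fit` with fields `D`, `V`, `residual`.
#' @export
fit_directed <- function(curve) {
  p <- msd_parts(curve)
  if (length(p$lag) < 2L)
    stop("fit_directed needs at least 2 lags", call. = FALSE)
  fit <- stats::lm(p$msd ~ p$lag + I(p$lag^2))
  co <- unname(stats::coef(fit))
  if (length(p$lag) == 2L || !is.na(co[3L]) && co[3L] >= 0) {
    quad <- if (length(co) >= 3L && !is.na(co[3L])) co[3L] else 0
    fit_result("directed", D = max(co[2L] / 4, 0), V = sqrt(max(quad, 0)),
               residual = sum(stats::resid(fit)^2))
  } else {
    f <- fit_free(curve)
    fit_result("directed", D = f$D, V = 0, residual = f$residual)
  }
}

#' Fit the confined-diffusion model MSD = (L^2/3) (1 - exp(-12 D t / L^2))
#'
#' Nonlinear least squares (Levenberg-Marquardt) with starting values
#' from the early slope (`D`) and the plateau (`L^2 = 3 * max(MSD)`).
#' Because the model degenerates to free diffusion (`MSD -> 4 D t`) as
#' `L` grows, `L` is unidentifiable on curves that never saturate; the
#' fit therefore constrains the model plateau `L^2/3` to at most twice
#' the largest observed MSD value. Non-convergence is reported as a
#' failed fit with infinite residual rather than an error.
#'
#' @param curve an `spt_msd` object with at least 3 lags.
#' @return An `spt_fit` with fields `D`, `L`, `residual`, `converged`.
#' @export
fit_confined <- function(curve) {
  p <- msd_parts(curve)
  if (length(p$lag) < 3L)
    stop("fit_confined needs at least 3 lags", call. = FALSE)
  mx <- max(p$msd)
  if (mx <= 0) return(fit_result("confined", converged = FALSE))
  D0 <- max(p$msd[1L] / (4 * p$lag[1L]), 1e-6)
  L0 <- max(sqrt(3 * mx), 1e-3)
  df <- data.frame(lag = p$lag, msd = p$msd)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      msd ~ (L^2 / 3) * (1 - exp(-12 * D * lag / L^2)),
      data = df, start = list(D = D0, L = L0),
      lower = c(D = 1e-9, L = 1e-6),
      upper = c(D = Inf, L = sqrt(6 * mx)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fit_result("confined", converged = FALSE))
  co <- stats::coef(fit)
  fit_result("confined", D = unname(co["D"]), L = unname(co["L"]),
             residual = sum(stats::resid(fit)^2))
}

#' Apparent diffusion coefficient from the first four MSD points (D_1-4)
#'
#' Slope over 4 of the least-squares line (free intercept) through the
#' first four lags of the curve, clamped at 0. This is the conventional
#' short-lag estimate of the apparent diffusion coefficient.
#'
#' @param curve an `spt_msd` object with at least 4 lags.
#' @return Apparent D in um^2/s.
#' @export
estimate_d14 <- function(curve) {
  p <- msd_parts(curve)
  if (length(p$lag) < 4L)
    stop("estimate_d14 needs at least 4 lags", call. = FALSE)
  lag <- p$lag[1:4]; v <- p$msd[1:4]
  slope <- unname(stats::coef(stats::lm(v ~ lag))[2L])
  max(slope / 4, 0)
}

#' Export an MSD curve as CSV
#'
#' @param curve an `spt_msd` object.
#' @param path output file path.
#' @export
write_msd <- function(curve, path) {
  utils::write.csv(
    data.frame(lag_s = curve$lag, msd_um2 = curve$msd),
    path, row.names = FALSE)
  invisible(path)
}
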