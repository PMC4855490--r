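# Synthetic 2-D trajectory generators.
#
# All generators share the same elementary step model: per-axis increments
# drawn from N(0, sd = sqrt(2 * D * tau)), the discrete random walk whose
# ensemble MSD is 4*D*t in two dimensions. Confinement and drift modify
# this base walk; static positioning noise is applied afterwards to the
# assembled positions.

step_sd <- function(D, tau) sqrt(2 * D * tau)

#' Simulate a free (Brownian) 2-D trajectory
#'
#' Each per-axis increment is an independent draw from a normal
#' distribution with zero mean and standard deviation `sqrt(2 * D * tau)`.
#'
#' @param n_frames number of frames (>= 2).
#' @param D diffusion coefficient in um^2/s.
#' @param tau frame interval in seconds.
#' @param seed optional RNG seed; identical seeds give identical
#'   trajectories. The caller's RNG state is left untouched when a seed is
#'   supplied.
#' @return An [new_trajectory()] object starting at the origin.
#' @export
simulate_brownian <- function(n_frames, D = 0.25, tau = 0.1, seed = NULL) {
  n_frames <- check_count(n_frames, "n_frames", min = 2L)
  check_positive(D, "D"); check_positive(tau, "tau")
  with_seed(seed, {
    s <- step_sd(D, tau)
    dx <- stats::rnorm(n_frames - 1L, 0, s)
    dy <- stats::rnorm(n_frames - 1L, 0, s)
    new_trajectory(c(0, cumsum(dx)), c(0, cumsum(dy)), tau,
                   label = rep("Brownian", n_frames))
  })
}

# One confined step from `pos` inside the circle of radius R about
# `centre`: redraw the free increment until the end point stays inside,
# which preserves the free-diffusion step distribution in the interior.
confined_step_reject <- function(pos, centre, R, s, max_tries = 100000L) {
  for (i in seq_len(max_tries)) {
    cand <- pos + stats::rnorm(2L, 0, s)
    if (sum((cand - centre)^2) <= R^2) return(cand)
  }
  stop("confined step rejection did not terminate; L is too small relative to the step size",
       call. = FALSE)
}

# Reflective alternative: fold the radial excess back inside.
confined_step_reflect <- function(pos, centre, R, s) {
  cand <- pos + stats::rnorm(2L, 0, s)
  repeat {
    d <- sqrt(sum((cand - centre)^2))
    if (d <= R) return(cand)
    cand <- centre + (cand - centre) / d * (2 * R - d)
  }
}

#' Simulate confined diffusion inside a circular domain
#'
#' Brownian steps restricted to a circular domain of diameter `L` centred
#' at the start position. By default a step that would leave the domain is
#' redrawn until it stays inside (`boundary = "rejection"`), which keeps
#' the interior step distribution identical to free diffusion;
#' `boundary = "reflection"` folds the radial excess back instead.
#'
#' @inheritParams simulate_brownian
#' @param L confinement domain diameter in um.
#' @param boundary boundary handling, `"rejection"` (default) or
#'   `"reflection"`.
#' @return Trajectory whose every position lies within `L/2` of the start.
#' @export
simulate_confined <- function(n_frames, D = 0.25, tau = 0.1, L,
                              boundary = c("rejection", "reflection"),
                              seed = NULL) {
  n_frames <- check_count(n_frames, "n_frames", min = 2L)
  check_positive(D, "D"); check_positive(tau, "tau"); check_positive(L, "L")
  boundary <- match.arg(boundary)
  with_seed(seed, {
    s <- step_sd(D, tau)
    step <- if (boundary == "rejection") confined_step_reject else confined_step_reflect
    pos <- matrix(0, n_frames, 2L)
    centre <- c(0, 0)
    for (i in 2:n_frames)
      pos[i, ] <- step(pos[i - 1L, ], centre, L / 2, s)
    new_trajectory(pos[, 1L], pos[, 2L], tau,
                   label = rep("confined", n_frames))
  })
}

#' Simulate directed diffusion (Brownian motion plus constant drift)
#'
#' Adds a deterministic drift of `V * tau` per frame along a single
#' direction, drawn once per trajectory uniformly on `[0, 2*pi)`, to the
#' free Brownian walk.
#'
#' @inheritParams simulate_brownian
#' @param V drift speed in um/s (>= 0).
#' @param angle optional fixed drift direction in radians; by default it
#'   is drawn from the seeded RNG.
#' @export
simulate_directed <- function(n_frames, D = 0.25, tau = 0.1, V,
                              angle = NULL, seed = NULL) {
  n_frames <- check_count(n_frames, "n_frames", min = 2L)
  check_positive(D, "D"); check_positive(tau, "tau")
  check_nonnegative(V, "V")
  with_seed(seed, {
    if (is.null(angle)) angle <- stats::runif(1L, 0, 2 * pi)
    s <- step_sd(D, tau)
    dx <- stats::rnorm(n_frames - 1L, 0, s) + V * tau * cos(angle)
    dy <- stats::rnorm(n_frames - 1L, 0, s) + V * tau * sin(angle)
    new_trajectory(c(0, cumsum(dx)), c(0, cumsum(dy)), tau,
                   label = rep("directed", n_frames))
  })
}

#' Add static positioning (localization) noise to a trajectory
#'
#' Models the static localization error of single-molecule detection:
#' every frame is displaced independently by a radial offset whose signed
#' magnitude is drawn from a Gaussian and whose direction is uniform on
#' `[0, 2*pi)`. The default law (`"radial"`) draws the magnitude from
#' `N(0, (2 * P_n)^2)`, i.e. the radial offset has root-mean-square
#' `2 * P_n`; `law = "per_axis"` instead perturbs each axis by
#' `N(0, P_n^2)` (radial rms `P_n * sqrt(2)`), the common alternative
#' reading of the same noise amplitude.
#'
#' @param traj trajectory to perturb (left unmodified).
#' @param P_n noise amplitude parameter in um (>= 0).
#' @param law `"radial"` (default) or `"per_axis"`, see Details.
#' @param seed optional RNG seed.
#' @return A new trajectory with noisy coordinates; labels are preserved.
#' @export
add_positioning_noise <- function(traj, P_n, law = c("radial", "per_axis"),
                                  seed = NULL) {
  check_nonnegative(P_n, "P_n")
  law <- match.arg(law)
  if (P_n == 0) return(traj)
  n <- n_frames(traj)
  with_seed(seed, {
    if (law == "radial") {
      r <- stats::rnorm(n, 0, 2 * P_n)
      th <- stats::runif(n, 0, 2 * pi)
      ox <- r * cos(th); oy <- r * sin(th)
    } else {
      ox <- stats::rnorm(n, 0, P_n); oy <- stats::rnorm(n, 0, P_n)
    }
    out <- traj
    out$x <- traj$x + ox
    out$y <- traj$y + oy
    out
  })
}

#' Simulate a composite (heterogeneous) trajectory
#'
#' Assembles a contiguous trajectory from an ordered list of segments,
#' each with its own motion mode, so that mode switches occur at known
#' frames. Segment entries are lists with elements `mode`
#' (`"Brownian"`, `"confined"` or `"directed"`), `length` (frames) and the
#' mode parameter (`L` for confined, `V` for directed); `D` may be
#' overridden per segment. A confined segment's domain is centred at the
#' position where the segment begins, so its first frame is inside by
#' construction; a directed segment draws a fresh drift direction.
#'
#' @param segments ordered list of segment specifications (see Details).
#' @param D,tau global diffusion coefficient (um^2/s) and frame interval (s).
#' @param n_frames optional expected total frame count; if supplied, the
#'   segment lengths must sum to it.
#' @param boundary confined boundary handling, as in [simulate_confined()].
#' @param seed optional RNG seed.
#' @return Trajectory with per-frame ground-truth `label`s.
#' @export
simulate_composite <- function(segments, D = 0.25, tau = 0.1,
                               n_frames = NULL,
                               boundary = c("rejection", "reflection"),
                               seed = NULL) {
  boundary <- match.arg(boundary)
  check_positive(D, "D"); check_positive(tau, "tau")
  if (!is.list(segments) || length(segments) == 0L)
    stop("`segments` must be a non-empty list", call. = FALSE)
  lens <- vapply(segments, function(s) check_count(s$length, "length"), 1L)
  total <- sum(lens)
  if (!is.null(n_frames) && total != n_frames)
    stop(sprintf("segment lengths sum to %d, expected n_frames = %d",
                 total, n_frames), call. = FALSE)
  if (total < 2L) stop("composite needs at least 2 frames", call. = FALSE)

  with_seed(seed, {
    pos <- matrix(0, total, 2L)
    labels <- character(total)
    filled <- 1L   # frames generated so far; frame 1 is the origin
    first_segment <- TRUE
    step_fun <- if (boundary == "rejection") confined_step_reject else confined_step_reflect

    for (seg in segments) {
      mode <- match.arg(seg$mode, c("Brownian", "confined", "directed"))
      k <- as.integer(seg$length)
      Dseg <- seg$D %||% D
      s <- step_sd(Dseg, tau)
      # frames belonging to this segment
      from <- if (first_segment) 1L else filled + 1L
      to <- from + k - 1L
      labels[from:to] <- mode
      # steps to generate: into frames max(from,2)..to
      n_steps <- to - max(from, 2L) + 1L
      if (n_steps > 0L) {
        entry <- pos[max(from, 2L) - 1L, ]
        if (mode == "Brownian") {
          dx <- stats::rnorm(n_steps, 0, s)
          dy <- stats::rnorm(n_steps, 0, s)
          idx <- max(from, 2L):to
          pos[idx, 1L] <- entry[1L] + cumsum(dx)
          pos[idx, 2L] <- entry[2L] + cumsum(dy)
        } else if (mode == "directed") {
          V <- seg$V
          check_nonnegative(V %||% stop("directed segment needs `V`",
                                        call. = FALSE), "V")
          angle <- seg$angle %||% stats::runif(1L, 0, 2 * pi)
          dx <- stats::rnorm(n_steps, 0, s) + V * tau * cos(angle)
          dy <- stats::rnorm(n_steps, 0, s) + V * tau * sin(angle)
          idx <- max(from, 2L):to
          pos[idx, 1L] <- entry[1L] + cumsum(dx)
          pos[idx, 2L] <- entry[2L] + cumsum(dy)
        } else {
          L <- seg$L
          check_positive(L %||% stop("confined segment needs `L`",
                                     call. = FALSE), "L")
          centre <- entry
          cur <- entry
          for (i in max(from, 2L):to) {
            cur <- step_fun(cur, centre, L / 2, s)
            pos[i, ] <- cur
          }
        }
      }
      filled <- to
      first_segment <- FALSE
    }
    new_trajectory(pos[, 1L], pos[, 2L], tau, label = labels)
  })
}
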