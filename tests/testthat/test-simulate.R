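# Trajectory simulators: step statistics, containment, drift, noise law,
# composites and the joint (D, V, L) scaling symmetry of normalized MSD.

test_that("Brownian increments have variance 2*D*tau and honour the seed", {
  D <- 0.25; tau <- 0.1
  traj <- simulate_brownian(1000, D, tau, seed = 1)
  for (dv in list(diff(traj$x), diff(traj$y))) {
    s2 <- stats::var(dv)
    se <- s2 * sqrt(2 / (length(dv) - 1))
    expect_lt(abs(s2 - 2 * D * tau), 3 * se)
    expect_lt(abs(mean(dv)), 3 * sqrt(2 * D * tau / length(dv)))
  }
  expect_identical(simulate_brownian(100, seed = 7),
                   simulate_brownian(100, seed = 7))
  # degenerate diffusion collapses onto the origin
  still <- simulate_brownian(100, D = 1e-12, seed = 2)
  expect_lt(max(abs(c(still$x, still$y))), 1e-4)
  expect_error(simulate_brownian(1), "n_frames")
  expect_error(simulate_brownian(100, D = -1), "D")
})

test_that("confined trajectories stay inside the domain and reduce to free diffusion for huge L", {
  traj <- simulate_confined(500, 0.25, 0.1, L = 1, seed = 3)
  expect_true(all(traj$x^2 + traj$y^2 <= (0.5)^2 + 1e-12))
  # a 100 um domain never rejects a step: same step law as free diffusion
  big <- simulate_confined(200, 0.25, 0.1, L = 100, seed = 4)
  free <- simulate_brownian(200, 0.25, 0.1, seed = 5)
  ft <- stats::var.test(diff(big$x), diff(free$x))
  expect_gt(ft$p.value, 0.001)
  # reflection variant also contained
  refl <- simulate_confined(300, 0.25, 0.1, L = 1, boundary = "reflection",
                            seed = 6)
  expect_true(all(refl$x^2 + refl$y^2 <= (0.5)^2 + 1e-12))
  expect_error(simulate_confined(100, L = -0.5), "L")
})

test_that("directed trajectories drift at V*tau per frame along a fixed direction", {
  n <- 400; V <- 1.2; tau <- 0.1; D <- 0.25
  traj <- simulate_directed(n, D, tau, V = V, seed = 8)
  disp <- sqrt(traj$x[n]^2 + traj$y[n]^2)
  drift <- V * (n - 1) * tau
  expect_lt(abs(disp - drift), 2 * 4 * sqrt(2 * D * (n - 1) * tau))
  # mean step along the drift direction is V*tau (t-test scale bound)
  ang <- atan2(traj$y[n], traj$x[n])
  along <- diff(traj$x) * cos(ang) + diff(traj$y) * sin(ang)
  expect_lt(abs(mean(along) - V * tau),
            3 * stats::sd(along) / sqrt(length(along)))
  # noiseless drift is a straight line with exact step length
  line <- simulate_directed(50, D = 1e-15, tau = 0.1, V = 1, seed = 9)
  steps <- sqrt(diff(line$x)^2 + diff(line$y)^2)
  expect_equal(steps, rep(0.1, 49), tolerance = 1e-5)
  expect_error(simulate_directed(50, V = -1), "V")
})

test_that("positioning noise follows the stated radial law and leaves the input unmodified", {
  traj <- simulate_brownian(10000, seed = 10)
  expect_identical(add_positioning_noise(traj, 0), traj)
  P_n <- 0.03
  noisy <- add_positioning_noise(traj, P_n, seed = 11)
  r <- sqrt((noisy$x - traj$x)^2 + (noisy$y - traj$y)^2)
  # radial offset rms equals 2*P_n = 0.06 um
  expect_equal(sqrt(mean(r^2)), 2 * P_n, tolerance = 0.05)
  expect_identical(traj, simulate_brownian(10000, seed = 10)) # untouched
  # per-axis variant: radial rms P_n * sqrt(2)
  pa <- add_positioning_noise(traj, P_n, law = "per_axis", seed = 12)
  r2 <- (pa$x - traj$x)^2 + (pa$y - traj$y)^2
  expect_equal(sqrt(mean(r2)), P_n * sqrt(2), tolerance = 0.05)
  # noise can push a confined trajectory outside its domain
  conf <- simulate_confined(2000, 0.25, 0.1, L = 0.3, seed = 13)
  nc <- add_positioning_noise(conf, 0.05, seed = 14)
  expect_gt(max(nc$x^2 + nc$y^2), 0.15^2)
  expect_error(add_positioning_noise(traj, -0.01), "P_n")
})

test_that("composite trajectories carry exact ground-truth labels and stay contiguous", {
  traj <- simulate_composite(two_segment_recipe(), D = 0.25, tau = 0.1,
                             n_frames = 400, seed = 15)
  expect_equal(nrow(traj), 400)
  expect_equal(sum(traj$label == "confined"), 50)
  expect_equal(sum(traj$label == "directed"), 50)
  expect_equal(which(traj$label == "confined"), 101:150)  # frames 100-149
  expect_equal(which(traj$label == "directed"), 301:350)
  # confined segment contained in a 1 um circle about its entry point
  centre <- c(traj$x[100], traj$y[100])
  d2 <- (traj$x[101:150] - centre[1])^2 + (traj$y[101:150] - centre[2])^2
  expect_true(all(d2 <= 0.5^2 + 1e-12))
  # no jumps anywhere: steps bounded by drift + 6 sigma
  steps <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  expect_lt(max(steps), 1.2 * 0.1 + 6 * sqrt(2 * 0.25 * 0.1))
  # length mismatch is an error
  expect_error(simulate_composite(list(list(mode = "Brownian", length = 10)),
                                  n_frames = 20), "sum to")
})

test_that("single-segment composites reproduce the single-mode simulators exactly", {
  for (cmp in list(
    list(spec = list(list(mode = "Brownian", length = 80)),
         ref = function(s) simulate_brownian(80, 0.25, 0.1, seed = s)),
    list(spec = list(list(mode = "confined", length = 80, L = 0.8)),
         ref = function(s) simulate_confined(80, 0.25, 0.1, L = 0.8, seed = s)),
    list(spec = list(list(mode = "directed", length = 80, V = 1.1)),
         ref = function(s) simulate_directed(80, 0.25, 0.1, V = 1.1, seed = s)))) {
    got <- simulate_composite(cmp$spec, D = 0.25, tau = 0.1, seed = 42)
    expect_equal(got$x, cmp$ref(42)$x, tolerance = 1e-12)
    expect_equal(got$y, cmp$ref(42)$y, tolerance = 1e-12)
  }
})

test_that("jointly rescaling (D, V) or (D, L) leaves the normalized MSD curve invariant", {
  # exact form: with a shared seed the rescaled trajectory is a scaled
  # copy, so the normalized MSD curves coincide
  for (s in 1:20) {
    a <- simulate_directed(31, D = 0.25, tau = 0.1, V = 1.0, seed = s)
    b <- simulate_directed(31, D = 0.5, tau = 0.1, V = 1.0 * sqrt(0.5 / 0.25),
                           seed = s)
    expect_equal(normalize_msd(compute_msd(a, 29)),
                 normalize_msd(compute_msd(b, 29)), tolerance = 1e-9)
    ca <- simulate_confined(31, D = 0.25, tau = 0.1, L = 0.8, seed = s)
    cb <- simulate_confined(31, D = 0.5, tau = 0.1, L = 0.8 * sqrt(2),
                            seed = s)
    expect_equal(normalize_msd(compute_msd(ca, 29)),
                 normalize_msd(compute_msd(cb, 29)), tolerance = 1e-9)
  }
  # statistical form: independent replicate ensembles agree pointwise
  set.seed(77)
  mean_curve <- function(D, V) {
    rowMeans(vapply(1:100, function(i)
      normalize_msd(compute_msd(simulate_directed(31, D, 0.1, V = V), 29)),
      numeric(29)))
  }
  d0 <- mean_curve(0.25, 1.0)
  d1 <- mean_curve(1.0, 1.0 * sqrt(1.0 / 0.25))
  expect_lt(mean(abs(d0 - d1)), 0.05)
})
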