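# Independent brute-force oracles, deliberately written as plain double
# loops so they share no code path with the package implementation.

# Time-averaged MSD by direct enumeration of the displacement pairs
# j = 1 .. N-1-n (frame times 0 .. (N-1)*dt).
msd_oracle <- function(traj, n_max) {
  x <- traj$x; y <- traj$y
  N <- nrow(traj)
  out <- numeric(n_max)
  for (n in seq_len(n_max)) {
    total <- 0
    for (j in seq_len(N - 1L - n)) {
      dx <- x[j + n + 1L] - x[j + 1L]
      dy <- y[j + n + 1L] - y[j + 1L]
      total <- total + dx^2 + dy^2
    }
    out[n] <- total / (N - 1L - n)
  }
  out
}

# Matrix-free feed-forward evaluation: explicit sums over nodes.
forward_oracle <- function(model, x) {
  sig <- function(z) 1 / (1 + exp(-z))
  h <- numeric(model$n_hidden)
  for (j in seq_len(model$n_hidden)) {
    a <- model$W1[1L, j]            # bias
    for (i in seq_len(model$m)) a <- a + model$W1[i + 1L, j] * x[i]
    h[j] <- sig(a)
  }
  o <- numeric(model$p)
  for (k in seq_len(model$p)) {
    a <- model$W2[1L, k]
    for (j in seq_len(model$n_hidden)) a <- a + model$W2[j + 1L, k] * h[j]
    o[k] <- sig(a)
  }
  o
}

# Central-difference gradient of the per-pattern error w.r.t. every weight.
numerical_gradients <- function(model, x, target, eps = 1e-6) {
  err <- function(m) 0.5 * sum((unname(bpnn_forward(m, x)) - target)^2)
  gW1 <- model$W1 * 0
  for (i in seq_along(gW1)) {
    mp <- model; mp$W1[i] <- mp$W1[i] + eps
    mm <- model; mm$W1[i] <- mm$W1[i] - eps
    gW1[i] <- (err(mp) - err(mm)) / (2 * eps)
  }
  gW2 <- model$W2 * 0
  for (i in seq_along(gW2)) {
    mp <- model; mp$W2[i] <- mp$W2[i] + eps
    mm <- model; mm$W2[i] <- mm$W2[i] - eps
    gW2[i] <- (err(mp) - err(mm)) / (2 * eps)
  }
  list(gW1 = gW1, gW2 = gW2)
}

# Random walk trajectory for oracle comparisons (not via the simulator).
random_traj <- function(n, dt = 0.1) {
  new_trajectory(cumsum(stats::rnorm(n)), cumsum(stats::rnorm(n)), dt)
}
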