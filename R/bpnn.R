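# Three-layer back-propagation neural network, written out explicitly.
#
# The network maps a normalized MSD curve (m input nodes) through one
# hidden sigmoid layer (n_hidden nodes, default 5) to three sigmoid
# output nodes, one per motion mode in the fixed order (Brownian,
# confined, directed):
#
#   O_k = f( sum_j W_jk * f( sum_i W_ij * X_i ) ),  f(z) = 1/(1+exp(-z))
#
# Bias units are carried as weights from a constant-1 input prepended to
# each layer (row 1 of each weight matrix). Training minimizes the
# per-pattern error E = 0.5 * sum_k (O_k - T_k)^2 by stochastic gradient
# descent with momentum,
#
#   dW(t+1) = -eta * dE/dW + alpha * dW(t)
#
# and stops early when the cross-validation MSE stops improving.

MODE_LEVELS <- c("Brownian", "confined", "directed")

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Create a three-layer BPNN with random initial weights
#'
#' @param m number of input nodes (length of the normalized MSD vector).
#' @param n_hidden number of hidden nodes (default 5).
#' @param p number of output nodes; fixed mode order (Brownian, confined,
#'   directed).
#' @param seed optional RNG seed for the initialization.
#' @param init_range weights are drawn uniformly from
#'   `[-init_range, init_range]`.
#' @return An object of class `bpnn` with weight matrices `W1`
#'   (`(m+1) x n_hidden`, bias in row 1) and `W2` (`(n_hidden+1) x p`).
#' @export
bpnn_new <- function(m, n_hidden = 5L, p = 3L, seed = NULL,
                     init_range = 0.5) {
  m <- check_count(m, "m"); n_hidden <- check_count(n_hidden, "n_hidden")
  p <- check_count(p, "p")
  with_seed(seed, {
    W1 <- matrix(stats::runif((m + 1L) * n_hidden, -init_range, init_range),
                 m + 1L, n_hidden)
    W2 <- matrix(stats::runif((n_hidden + 1L) * p, -init_range, init_range),
                 n_hidden + 1L, p)
    structure(list(m = m, n_hidden = n_hidden, p = p, W1 = W1, W2 = W2,
                   training_meta = list(seed = seed)),
              class = "bpnn")
  })
}

#' @export
print.bpnn <- function(x, ...) {
  cat(sprintf("<bpnn> %d-%d-%d (input-hidden-output), sigmoid activations\n",
              x$m, x$n_hidden, x$p))
  tm <- x$training_meta
  if (!is.null(tm$epochs_run))
    cat(sprintf("  trained: %d epochs, train MSE %.5f, validation MSE %.5f\n",
                tm$epochs_run, tm$final_train_mse, tm$final_val_mse))
  invisible(x)
}

#' Feed-forward evaluation of the network
#'
#' The recall phase: a single forward pass, never mutating the model.
#'
#' @param model a [bpnn_new()] model.
#' @param x input vector of length `m` (finite values).
#' @return Output vector of length `p`, each component in (0, 1), named
#'   by motion mode when `p = 3`.
#' @export
bpnn_forward <- function(model, x) {
  if (length(x) != model$m)
    stop(sprintf("input has length %d, expected m = %d",
                 length(x), model$m), call. = FALSE)
  if (!all(is.finite(x)))
    stop("input contains non-finite values", call. = FALSE)
  h <- sigmoid(drop(crossprod(model$W1, c(1, x))))
  o <- sigmoid(drop(crossprod(model$W2, c(1, h))))
  if (model$p == 3L) names(o) <- MODE_LEVELS
  o
}

# Vectorized forward pass over rows of X; returns an n x p matrix.
bpnn_forward_batch <- function(model, X) {
  H <- sigmoid(cbind(1, X) %*% model$W1)
  sigmoid(cbind(1, H) %*% model$W2)
}

#' Per-pattern system error
#'
#' `E = 0.5 * sum_k (O_k - T_k)^2` between network output and target.
#'
#' @param O output vector.
#' @param Target target vector of equal length.
#' @export
bpnn_error <- function(O, Target) {
  if (length(O) != length(Target))
    stop("output and target lengths differ", call. = FALSE)
  0.5 * sum((O - Target)^2)
}

#' Mean squared error of a network over a pattern set (Eq.-style MSE)
#'
#' `MSE = 1/(n*p) * sum_l sum_k (T_lk - O_lk)^2` over the `n` patterns.
#'
#' @param model a `bpnn` model.
#' @param set a training set as returned by [build_training_data()]
#'   (list with `inputs` and `targets` matrices).
#' @export
bpnn_mse <- function(model, set) {
  O <- bpnn_forward_batch(model, set$inputs)
  mean((set$targets - O)^2)
}

# Analytic gradients of E = 0.5*sum((o-T)^2) w.r.t. W1, W2 for one pattern.
bpnn_gradients <- function(model, x, target) {
  a1 <- c(1, x)
  h <- sigmoid(drop(crossprod(model$W1, a1)))
  a2 <- c(1, h)
  o <- sigmoid(drop(crossprod(model$W2, a2)))
  delta_o <- (o - target) * o * (1 - o)
  gW2 <- tcrossprod(a2, delta_o)
  delta_h <- drop(model$W2[-1L, , drop = FALSE] %*% delta_o) * h * (1 - h)
  gW1 <- tcrossprod(a1, delta_h)
  list(gW1 = gW1, gW2 = gW2, E = 0.5 * sum((o - target)^2))
}

#' One momentum gradient-descent update on a single pattern
#'
#' Back-propagates the per-pattern error through both sigmoid layers and
#' applies the momentum update `dW(t+1) = -eta * dE/dW + alpha * dW(t)`.
#'
#' @param model a `bpnn` model.
#' @param x input vector (length `m`).
#' @param target target vector (length `p`).
#' @param eta learning rate (> 0).
#' @param alpha momentum coefficient in `[0, 1)`.
#' @param prev_deltas previous weight increments, a list with `dW1`,
#'   `dW2` (zeros when omitted).
#' @return List with the updated `model`, the applied `deltas`, and the
#'   pre-update pattern error `E`.
#' @export
bpnn_train_step <- function(model, x, target, eta, alpha = 0.9,
                            prev_deltas = NULL) {
  check_nonnegative(eta, "eta")
  if (!(alpha >= 0 && alpha < 1))
    stop("`alpha` must be in [0, 1)", call. = FALSE)
  if (is.null(prev_deltas))
    prev_deltas <- list(dW1 = model$W1 * 0, dW2 = model$W2 * 0)
  g <- bpnn_gradients(model, x, target)
  if (!all(is.finite(g$gW1)) || !all(is.finite(g$gW2)))
    stop("non-finite gradients: training diverged", call. = FALSE)
  dW1 <- -eta * g$gW1 + alpha * prev_deltas$dW1
  dW2 <- -eta * g$gW2 + alpha * prev_deltas$dW2
  model$W1 <- model$W1 + dW1
  model$W2 <- model$W2 + dW2
  list(model = model, deltas = list(dW1 = dW1, dW2 = dW2), E = g$E)
}

#' Build training and cross-validation sets of normalized MSD curves
#'
#' Simulates `n_per_mode` short trajectories per motion mode at the
#' training conditions (default: `D = 0.25` um^2/s, `tau = 0.1` s,
#' window of 31 frames; confinement diameter uniform in `[0.25, 2]` um;
#' drift speed uniform in `[0.5, 1.5]` um/s), computes each window's
#' normalized MSD curve (all `window - 2` lags) and one-hot targets, and
#' splits each mode 70/30 into training and cross-validation sets.
#'
#' @param n_per_mode trajectories per mode (default 1000).
#' @param window window length in frames (default 31).
#' @param D,tau diffusion coefficient and frame interval.
#' @param L_range,V_range uniform sampling ranges for the confinement
#'   diameter (um) and drift speed (um/s).
#' @param train_fraction fraction of each mode assigned to the training
#'   set (default 0.7).
#' @param seed RNG seed.
#' @return List with elements `train` and `validation`, each a list with
#'   `inputs` (n x m matrix, rows in `[0, 1]` with max 1), `targets`
#'   (n x 3 one-hot matrix) and `modes` (character).
#' @export
build_training_data <- function(n_per_mode = 1000L, window = 31L,
                                D = 0.25, tau = 0.1,
                                L_range = c(0.25, 2),
                                V_range = c(0.5, 1.5),
                                train_fraction = 0.7, seed = NULL) {
  n_per_mode <- check_count(n_per_mode, "n_per_mode")
  window <- check_count(window, "window", min = 4L)
  m <- window - 2L
  with_seed(seed, {
    sim_one <- function(mode) {
      traj <- switch(mode,
        Brownian = simulate_brownian(window, D, tau),
        confined = simulate_confined(window, D, tau,
                                     L = stats::runif(1L, L_range[1L], L_range[2L])),
        directed = simulate_directed(window, D, tau,
                                     V = stats::runif(1L, V_range[1L], V_range[2L])))
      normalize_msd(compute_msd(traj, n_max = m))
    }
    inputs <- vector("list", 3L * n_per_mode)
    modes <- character(3L * n_per_mode)
    i <- 0L
    for (mode in MODE_LEVELS) {
      for (r in seq_len(n_per_mode)) {
        i <- i + 1L
        inputs[[i]] <- sim_one(mode)
        modes[i] <- mode
      }
    }
    X <- do.call(rbind, inputs)
    Tmat <- outer(modes, MODE_LEVELS, "==") * 1
    colnames(Tmat) <- MODE_LEVELS
    # per-mode 70/30 split; trajectories are iid so a block split suffices
    n_train <- round(train_fraction * n_per_mode)
    take <- unlist(lapply(0:2, function(b)
      b * n_per_mode + seq_len(n_train)))
    mk <- function(idx) list(inputs = X[idx, , drop = FALSE],
                             targets = Tmat[idx, , drop = FALSE],
                             modes = modes[idx])
    list(train = mk(take), validation = mk(setdiff(seq_len(3L * n_per_mode), take)))
  })
}

#' Train a BPNN with per-pattern momentum updates and early stopping
#'
#' Runs epochs of stochastic (per-pattern, shuffled order) momentum
#' gradient descent. After each epoch the MSE on both sets is recorded;
#' training stops when the cross-validation MSE has not improved for
#' `patience` consecutive epochs (overfitting onset) or at `max_epochs`,
#' and the weights from the best-validation epoch are returned.
#'
#' @param model initial model from [bpnn_new()].
#' @param train,validation pattern sets from [build_training_data()].
#' @param eta learning rate (default 0.1).
#' @param alpha momentum (default 0.9).
#' @param max_epochs epoch cap (default 2000).
#' @param patience epochs without validation improvement before stopping
#'   (default 20).
#' @param seed RNG seed for the shuffling.
#' @return The trained `bpnn` with `training_meta` filled in and an
#'   `mse_history` data frame (epoch, train_mse, val_mse) attached.
#' @export
bpnn_train <- function(model, train, validation, eta = 0.1, alpha = 0.9,
                       max_epochs = 2000L, patience = 20L, seed = NULL) {
  check_positive(eta, "eta")
  patience <- check_count(patience, "patience")
  max_epochs <- check_count(max_epochs, "max_epochs")
  n_pat <- nrow(train$inputs)
  if (n_pat == 0L || nrow(validation$inputs) == 0L)
    stop("empty training or validation set", call. = FALSE)
  with_seed(seed, {
    deltas <- list(dW1 = model$W1 * 0, dW2 = model$W2 * 0)
    best <- list(val = Inf, W1 = model$W1, W2 = model$W2, epoch = 0L)
    hist_train <- hist_val <- numeric(0)
    stall <- 0L
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n_pat)
      for (l in ord) {
        g <- bpnn_gradients(model, train$inputs[l, ], train$targets[l, ])
        dW1 <- -eta * g$gW1 + alpha * deltas$dW1
        dW2 <- -eta * g$gW2 + alpha * deltas$dW2
        model$W1 <- model$W1 + dW1
        model$W2 <- model$W2 + dW2
        deltas <- list(dW1 = dW1, dW2 = dW2)
      }
      tm <- bpnn_mse(model, train)
      vm <- bpnn_mse(model, validation)
      if (!is.finite(tm) || !is.finite(vm))
        stop("training diverged: non-finite MSE", call. = FALSE)
      hist_train <- c(hist_train, tm)
      hist_val <- c(hist_val, vm)
      if (vm < best$val - 1e-12) {
        best <- list(val = vm, W1 = model$W1, W2 = model$W2, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
    model$W1 <- best$W1
    model$W2 <- best$W2
    model$training_meta <- utils::modifyList(model$training_meta %||% list(), list(
      eta = eta, alpha = alpha, epochs_run = length(hist_val),
      best_epoch = best$epoch,
      final_train_mse = hist_train[best$epoch],
      final_val_mse = best$val, train_seed = seed))
    attr(model, "mse_history") <- data.frame(
      epoch = seq_along(hist_train),
      train_mse = hist_train, val_mse = hist_val)
    model
  })
}

#' Classify pattern inputs by the argmax output rule
#'
#' @param model trained `bpnn`.
#' @param X matrix of input rows (or a single vector).
#' @return Character vector of predicted modes.
#' @export
bpnn_classify <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  O <- bpnn_forward_batch(model, X)
  MODE_LEVELS[max.col(O)]
}

#' Choose the hidden-layer size by cross-validation MSE
#'
#' Trains one network per candidate size on the same data and returns the
#' size attaining the lowest cross-validation MSE (ties broken in favour
#' of the smallest network).
#'
#' @param sizes integer vector of candidate hidden-node counts.
#' @param train,validation pattern sets.
#' @param ... passed to [bpnn_train()] (eta, alpha, max_epochs, patience).
#' @param seed base RNG seed; candidate i uses `seed + i` for its
#'   initialization and shuffling.
#' @return List with `best_size`, the named vector `val_mse`, and the
#'   winning `model`.
#' @export
select_hidden_size <- function(sizes, train, validation, ..., seed = NULL) {
  if (length(sizes) < 1L) stop("need at least one candidate size",
                               call. = FALSE)
  sizes <- sort(unique(as.integer(sizes)))
  m <- ncol(train$inputs)
  val <- numeric(length(sizes))
  models <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    si <- if (is.null(seed)) NULL else seed + i
    net <- bpnn_new(m, n_hidden = sizes[i], p = ncol(train$targets), seed = si)
    net <- bpnn_train(net, train, validation, ..., seed = si)
    val[i] <- net$training_meta$final_val_mse
    models[[i]] <- net
  }
  names(val) <- sizes
  best <- which.min(val)   # first minimum = smallest size on ties
  list(best_size = sizes[best], val_mse = val, model = models[[best]])
}
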