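# One fully trained pipeline (training-protocol conditions: 3 x 1000
# windows of 31 frames, D = 0.25 um^2/s, dt = 0.1 s; thresholds from 100
# Brownian nulls of 1000 frames) shared across the test files that need
# it. Trained lazily and cached for the whole run.

.pipeline_cache <- new.env(parent = emptyenv())

get_pipeline <- function() {
  if (is.null(.pipeline_cache$pl)) {
    dat <- build_training_data(1000, 31, seed = 101)
    net <- bpnn_new(29, n_hidden = 5, p = 3, seed = 102)
    net <- bpnn_train(net, dat$train, dat$validation, eta = 0.1,
                      alpha = 0.9, max_epochs = 2000, patience = 20,
                      seed = 103)
    th <- calibrate_thresholds(net, seed = 104)
    .pipeline_cache$pl <- list(net = net, th = th, data = dat)
  }
  .pipeline_cache$pl
}

# Reference two-segment composite recipe: 400 frames with a 50-frame confined
# segment (frames 100-149, L = 1 um) and a 50-frame directed segment
# (frames 300-349, V = 1.2 um/s).
two_segment_recipe <- function(L = 1, V = 1.2) {
  list(list(mode = "Brownian", length = 100L),
       list(mode = "confined", length = 50L, L = L),
       list(mode = "Brownian", length = 150L),
       list(mode = "directed", length = 50L, V = V),
       list(mode = "Brownian", length = 50L))
}

# Frames flagged with `mode` by a segmentation, as a logical vector.
flagged_frames <- function(result, mode) {
  v <- logical(result$n_frames)
  s <- result$segments[result$segments$mode == mode, , drop = FALSE]
  for (i in seq_len(nrow(s)))
    v[(s$start_frame[i]:s$end_frame[i]) + 1L] <- TRUE
  v
}
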