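# File round-tripping: trajectories and segment tables as CSV, models and
# threshold curves as JSON. Coordinates are micrometres, times seconds,
# frames 0-based. CSV dialect: comma-separated, mandatory header, UTF-8,
# '.' decimal separator.

SCHEMA_VERSION <- 1L

#' Write trajectories to a CSV file
#'
#' Columns: `track_id`, `frame` (0-based), `t` (s), `x`, `y` (um), and
#' `label` when any trajectory carries ground-truth labels.
#'
#' @param trajs a single trajectory or a (optionally named) list of them.
#' @param path output path.
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "spt_traj")) trajs <- list(trajs)
  ids <- names(trajs) %||% as.character(seq_along(trajs))
  if (is.null(names(trajs))) ids <- as.character(seq_along(trajs))
  rows <- lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    df <- data.frame(track_id = ids[i], frame = tr$frame, t = tr$t,
                     x = tr$x, y = tr$y)
    df$label <- if (!is.null(tr$label)) tr$label else NA_character_
    df
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$label))) out$label <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read trajectories from a CSV file
#'
#' Expects the column layout written by [write_trajectories()]. Frames
#' must be consecutive and times uniformly spaced within each track;
#' violations are reported with the offending data line.
#'
#' @param path CSV file path.
#' @return Named list of trajectories.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("track_id", "frame", "t", "x", "y")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  unknown <- setdiff(names(df), c(required, "label"))
  if (length(unknown))
    stop(sprintf("unknown column(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  for (col in c("frame", "t", "x", "y"))
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1L]
      stop(sprintf("malformed value in column '%s' at data line %d",
                   col, if (is.na(bad)) 1L else bad), call. = FALSE)
    }
  df$.line <- seq_len(nrow(df))
  out <- lapply(split(df, df$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2L)
      stop(sprintf("track '%s' has fewer than 2 frames", tr$track_id[1L]),
           call. = FALSE)
    if (any(diff(tr$frame) != 1L)) {
      bad <- which(diff(tr$frame) != 1L)[1L]
      stop(sprintf(
        "track '%s': gap in frame numbers after frame %d (data line %d)",
        tr$track_id[1L], tr$frame[bad], tr$.line[bad]), call. = FALSE)
    }
    dt <- stats::median(diff(tr$t))
    tryCatch(
      new_trajectory(tr$x, tr$y, dt, t = tr$t,
                     label = if ("label" %in% names(tr)) tr$label else NULL),
      error = function(e)
        stop(sprintf("track '%s' (starting at data line %d): %s",
                     tr$track_id[1L], tr$.line[1L], conditionMessage(e)),
             call. = FALSE))
  })
  out[unique(df$track_id)]
}

#' Write a segmentation's segment table to CSV
#'
#' Columns: `mode`, `start_frame`, `end_frame`, `duration_s`, `D`, `L`,
#' `V` (and `track_id` when a list of results is given).
#'
#' @param results an `spt_segmentation` or list of them.
#' @param path output path.
#' @export
write_segments <- function(results, path) {
  if (inherits(results, "spt_segmentation")) results <- list(results)
  ids <- names(results) %||% as.character(seq_along(results))
  rows <- lapply(seq_along(results), function(i) {
    s <- results[[i]]$segments
    for (col in c("D", "L", "V")) if (is.null(s[[col]])) s[[col]] <- NA_real_
    data.frame(track_id = ids[i],
               mode = s$mode, start_frame = s$start_frame,
               end_frame = s$end_frame, duration_s = s$duration_s,
               D = s$D, L = s$L, V = s$V)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Save / load a BPNN model as JSON
#'
#' The JSON carries a schema version, the layer sizes, row-major weight
#' lists and the training metadata, at full double precision so that a
#' round-trip reproduces forward outputs exactly.
#'
#' @param model a `bpnn`.
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  obj <- list(schema_version = SCHEMA_VERSION,
              type = "bpnn",
              m = model$m, n_hidden = model$n_hidden, p = model$p,
              W1 = as.vector(t(model$W1)),   # row-major
              W2 = as.vector(t(model$W2)),
              training_meta = model$training_meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "bpnn"))
    stop("not a bpnn model file", call. = FALSE)
  m <- as.integer(obj$m); nh <- as.integer(obj$n_hidden)
  p <- as.integer(obj$p)
  structure(list(
    m = m, n_hidden = nh, p = p,
    W1 = matrix(obj$W1, m + 1L, nh, byrow = TRUE),
    W2 = matrix(obj$W2, nh + 1L, p, byrow = TRUE),
    training_meta = as.list(obj$training_meta)),
    class = "bpnn")
}

#' Save / load calibrated threshold curves as JSON
#'
#' @param thresholds an `spt_thresholds`.
#' @param path JSON file path.
#' @export
write_thresholds <- function(thresholds, path) {
  obj <- list(schema_version = SCHEMA_VERSION,
              type = "spt_thresholds",
              k = thresholds$k, Y_C = thresholds$Y_C, Y_D = thresholds$Y_D,
              meta = thresholds$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "spt_thresholds"))
    stop("not a thresholds file", call. = FALSE)
  structure(list(k = as.integer(obj$k), Y_C = as.numeric(obj$Y_C),
                 Y_D = as.numeric(obj$Y_D), meta = as.list(obj$meta)),
            class = "spt_thresholds")
}

#' Packaged default model and thresholds
#'
#' A small pre-trained network (standard training-protocol conditions, seed
#' recorded in its metadata) and matching threshold curves shipped with
#' the package so that segmentation works out of the box. Retrain with
#' [build_training_data()] + [bpnn_train()] for production use.
#'
#' @return A `bpnn` / `spt_thresholds` object.
#' @export
default_model <- function() {
  read_model(system.file("extdata", "bpnn_default.json", package = "sptseg",
                         mustWork = TRUE))
}

#' @rdname default_model
#' @export
default_thresholds <- function() {
  read_thresholds(system.file("extdata", "thresholds_default.json",
                              package = "sptseg", mustWork = TRUE))
}
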