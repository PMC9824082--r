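# Frame equalization and vectorization into 40x64 spatiotemporal maps.
#
# Records of varying duration are brought to a common length of 40 frames:
# long records are thinned at regular index intervals (endpoints kept),
# short records grow by inserting neighbor-mean frames at the widest gaps.
# Each equalized record is then flattened, frame by frame, into a 40x64
# real-valued map (rows = time, columns = row-major pixels) that the
# denoising and feature-extraction stages treat as an image.

#' Construct a spatiotemporal map
#'
#' @param values 40x64 numeric matrix (or `target x 64`), rows in time order.
#' @param label,subjects,layout,sensor_id metadata carried through the pipeline.
#' @return a matrix of class `st_map` with metadata attributes.
#' @export
st_map <- function(values, label = NA_character_, subjects = NA,
                   layout = NA_character_, sensor_id = NA_character_) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("spatiotemporal map must be finite")
  structure(values, class = c("st_map", "matrix"),
            label = label, subjects = subjects, layout = layout,
            sensor_id = sensor_id)
}

#' Equalize a frame stream to a fixed number of frames
#'
#' Streams longer than `target_len` are thinned by keeping `target_len`
#' evenly spaced frame indices including both endpoints (index
#' `ceiling(i*(L-1)/(T-1) - 0.5) + 1`, ties broken toward the earlier
#' frame). Shorter streams are grown by repeatedly inserting, at the widest
#' remaining inter-frame gap (leftmost on ties), a new frame equal to the
#' element-wise mean of its two neighbors; original first and last frames
#' are always retained.
#'
#' @param stream a [frame_stream()] with at least 2 frames.
#' @param target_len desired number of frames (default 40).
#' @return a [frame_stream()] of exactly `target_len` frames.
#' @export
equalize_frames <- function(stream, target_len = 40L) {
  if (!inherits(stream, "frame_stream")) stop("not a frame_stream")
  L <- n_frames(stream)
  if (L < 2) stop("equalization needs at least 2 frames, got ", L)
  target_len <- as.integer(target_len)
  if (target_len < 2) stop("target_len must be >= 2")
  if (L == target_len) return(stream)
  if (L > target_len) {
    pos <- (0:(target_len - 1)) * (L - 1) / (target_len - 1)
    idx <- ceiling(pos - 0.5) + 1L  # half-integers round toward the earlier index
    idx[1] <- 1L; idx[target_len] <- L
    return(frame_stream(stream$pixels[idx, , drop = FALSE],
                        stream$timestamps[idx],
                        sensor_id = stream$sensor_id, fps = stream$fps))
  }
  px <- stream$pixels
  ts <- stream$timestamps
  pos <- as.numeric(seq_len(L))  # positions on the original index axis
  while (length(pos) < target_len) {
    g <- which.max(diff(pos))    # leftmost widest gap
    new_px <- (px[g, ] + px[g + 1, ]) / 2
    new_ts <- (ts[g] + ts[g + 1]) / 2
    px <- rbind(px[1:g, , drop = FALSE], new_px, px[(g + 1):nrow(px), , drop = FALSE])
    ts <- c(ts[1:g], new_ts, ts[(g + 1):length(ts)])
    pos <- c(pos[1:g], (pos[g] + pos[g + 1]) / 2, pos[(g + 1):length(pos)])
  }
  frame_stream(px, ts, sensor_id = stream$sensor_id, fps = stream$fps)
}

#' Vectorize an equalized stream into a spatiotemporal map
#'
#' Row `t` of the map is frame `t` flattened row-major:
#' `map[t, 8*(r-1)+c] == frame_t[r, c]`.
#'
#' @param stream a [frame_stream()] with exactly `target_len` frames.
#' @param target_len expected frame count (default 40).
#' @return an [st_map()] of size `target_len` x 64.
#' @export
vectorize_stream <- function(stream, target_len = 40L) {
  if (n_frames(stream) != target_len)
    stop("stream has ", n_frames(stream), " frames; equalize to ",
         target_len, " first (see equalize_frames)")
  st_map(stream$pixels, sensor_id = stream$sensor_id)
}

#' Recover the 8x8 frames from a spatiotemporal map
#'
#' Inverse of [vectorize_stream()]: each map row becomes an 8x8 frame.
#'
#' @param map an [st_map()] (or plain matrix with 64 columns).
#' @return list of 8x8 matrices, one per map row.
#' @export
devectorize_map <- function(map) {
  lapply(seq_len(nrow(map)), function(t) vector_to_frame(map[t, ]))
}

#' Construct a dataset tensor
#'
#' @param maps numeric array `Z x 40 x 64` of stacked spatiotemporal maps.
#' @param labels activity code per map.
#' @param subjects,layout optional per-map metadata vectors.
#' @param sensor_id the channel the maps were built from.
#' @return an object of class `dataset_tensor`.
#' @export
dataset_tensor <- function(maps, labels, subjects = NULL, layout = NULL,
                           sensor_id = NA_character_) {
  stopifnot(length(dim(maps)) == 3)
  Z <- dim(maps)[1]
  if (length(labels) != Z) stop("one label per map required")
  structure(list(maps = maps, labels = as.character(labels),
                 subjects = subjects %||% rep(NA, Z),
                 layout = layout %||% rep(NA_character_, Z),
                 sensor_id = sensor_id),
            class = "dataset_tensor")
}

#' @export
print.dataset_tensor <- function(x, ...) {
  cat("<dataset_tensor>", dim(x$maps)[1], "maps of",
      dim(x$maps)[2], "x", dim(x$maps)[3], "|",
      length(unique(x$labels)), "classes | sensor", x$sensor_id, "\n")
  invisible(x)
}

#' Number of samples in a dataset tensor
#' @param data a [dataset_tensor()].
#' @return integer sample count.
#' @export
n_samples <- function(data) dim(data$maps)[1]

# Z x 2560 matrix of flattened maps (row t of the map placed before row t+1).
flatten_maps <- function(data) {
  Z <- n_samples(data)
  out <- matrix(0, Z, prod(dim(data$maps)[2:3]))
  for (i in seq_len(Z)) out[i, ] <- as.vector(t(data$maps[i, , ]))
  out
}

# Inverse of flatten_maps for a single row.
unflatten_map <- function(v, M = 40L, N = 64L) matrix(v, M, N, byrow = TRUE)

#' Extract one map from a dataset tensor
#' @param data a [dataset_tensor()].
#' @param i sample index.
#' @return an [st_map()].
#' @export
get_map <- function(data, i) {
  st_map(data$maps[i, , ], label = data$labels[i],
         subjects = data$subjects[[i]], layout = data$layout[i],
         sensor_id = data$sensor_id)
}

#' Build a dataset tensor from activity records
#'
#' Equalizes and vectorizes the requested sensor's stream of every record
#' and stacks the resulting maps.
#'
#' @param records list of [activity_record()] objects.
#' @param sensor_id which sensor channel to use.
#' @param target_len equalized frame count (default 40).
#' @return a [dataset_tensor()] with `Z = length(records)` maps.
#' @export
build_dataset <- function(records, sensor_id = "S1", target_len = 40L) {
  Z <- length(records)
  maps <- array(0, c(Z, target_len, 64))
  labels <- character(Z)
  subjects <- vector("list", Z)
  layout <- character(Z)
  for (i in seq_len(Z)) {
    r <- records[[i]]
    if (!sensor_id %in% names(r$streams))
      stop("record ", i, " (", r$label, "): no stream for sensor ", sensor_id)
    eq <- equalize_frames(r$streams[[sensor_id]], target_len)
    maps[i, , ] <- eq$pixels
    labels[i] <- r$label
    subjects[[i]] <- r$subjects
    layout[i] <- r$layout
  }
  if (Z == 0) labels <- character(0)
  dataset_tensor(maps, labels, subjects = subjects, layout = layout,
                 sensor_id = sensor_id)
}

#' Subset a dataset tensor
#' @param data a [dataset_tensor()].
#' @param idx sample indices to keep.
#' @return a [dataset_tensor()].
#' @export
subset_tensor <- function(data, idx) {
  dataset_tensor(data$maps[idx, , , drop = FALSE], data$labels[idx],
                 subjects = data$subjects[idx], layout = data$layout[idx],
                 sensor_id = data$sensor_id)
}

#' Concatenate dataset tensors sample-wise
#' @param ... dataset tensors with identical map dimensions.
#' @return a combined [dataset_tensor()].
#' @export
bind_tensors <- function(...) {
  parts <- list(...)
  maps <- do.call(abind3, lapply(parts, `[[`, "maps"))
  dataset_tensor(maps,
                 unlist(lapply(parts, `[[`, "labels")),
                 subjects = do.call(c, lapply(parts, `[[`, "subjects")),
                 layout = unlist(lapply(parts, `[[`, "layout")),
                 sensor_id = parts[[1]]$sensor_id)
}

# rbind for 3D arrays along the first dimension.
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  Z <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(0, c(Z, d[2], d[3]))
  at <- 1L
  for (p in parts) {
    n <- dim(p)[1]
    if (n > 0) out[at:(at + n - 1), , ] <- p
    at <- at + n
  }
  out
}
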