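# Reading, writing and validating LRIR frame streams and dataset manifests.
#
# Pixel serialization convention (fixed and relied upon throughout the
# package): the 8x8 thermal frame is flattened row-major, pixel column
# p = 8*(r-1)+c for grid row r and column c, both 1-based. CSV rows are
# "timestamp,p01,...,p64".

#' Activity label vocabulary
#'
#' The activity codes recognised by the package: 8 single-subject activities
#' in the small layout (AS1-AS8), the same 8 in the large layout (AL1-AL8),
#' 7 double-subject activities (B1-B7), and 9 single-subject codes (I1-I9)
#' for the second, single-layout dataset design.
#'
#' @return character vector of valid activity codes.
#' @export
activity_vocabulary <- function() {
  c(paste0("AS", 1:8), paste0("AL", 1:8), paste0("B", 1:7), paste0("I", 1:9))
}

#' Construct a frame stream
#'
#' A frame stream holds the ordered 8x8 thermal frames of one sensor channel
#' for one activity record. Frames are stored pre-vectorized as an n x 64
#' matrix in the package's row-major pixel order.
#'
#' @param pixels numeric matrix with one row per frame and 64 columns
#'   (temperatures in degrees Celsius, row-major pixel order).
#' @param timestamps numeric vector of seconds since record start, strictly
#'   increasing.
#' @param sensor_id channel label, e.g. "S1".
#' @param fps nominal acquisition rate in frames per second (> 0).
#' @param temp_band plausibility band for temperatures; values outside it
#'   trigger a warning, not an error, to tolerate sensor artifacts.
#' @return an object of class `frame_stream`.
#' @export
frame_stream <- function(pixels, timestamps, sensor_id = "S1", fps = 10,
                         temp_band = c(0, 60)) {
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != 64L)
    stop("a frame must have exactly 64 pixel values, got ", ncol(pixels))
  if (nrow(pixels) != length(timestamps))
    stop("number of frames (", nrow(pixels), ") and timestamps (",
         length(timestamps), ") differ")
  if (!all(is.finite(pixels))) stop("non-finite pixel values in frame stream")
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive")
  if (any(pixels < temp_band[1] | pixels > temp_band[2]))
    warning("pixel temperatures outside the plausibility band [",
            temp_band[1], ", ", temp_band[2], "] degC")
  structure(list(pixels = unname(pixels), timestamps = as.numeric(timestamps),
                 sensor_id = sensor_id, fps = fps),
            class = "frame_stream")
}

#' @export
print.frame_stream <- function(x, ...) {
  cat("<frame_stream> sensor", x$sensor_id, "-", nrow(x$pixels), "frames @",
      x$fps, "fps,", sprintf("%.1f s\n", utils::tail(x$timestamps, 1)))
  invisible(x)
}

#' Number of frames in a stream
#' @param stream a `frame_stream`.
#' @return integer frame count.
#' @export
n_frames <- function(stream) nrow(stream$pixels)

#' Reshape one vectorized frame to its 8x8 grid
#' @param v numeric vector of length 64 in row-major pixel order.
#' @return an 8x8 matrix.
#' @export
vector_to_frame <- function(v) matrix(v, 8, 8, byrow = TRUE)

#' Flatten an 8x8 frame to the package's row-major pixel order
#' @param f an 8x8 matrix.
#' @return numeric vector of length 64.
#' @export
frame_to_vector <- function(f) as.vector(t(f))

#' Read a frame stream from CSV
#'
#' Expects one data row per frame: a timestamp followed by 64 pixel values
#' (65 comma-separated fields), with a header line. Rows must be in strictly
#' increasing timestamp order.
#'
#' @param path CSV file path.
#' @param sensor_id channel label to attach to the stream.
#' @param fps nominal frame rate recorded in the stream object.
#' @param temp_band plausibility band passed to [frame_stream()].
#' @return a [frame_stream()].
#' @export
read_frame_stream <- function(path, sensor_id = "S1", fps = 10,
                              temp_band = c(0, 60)) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = ",")
  bad <- which(nf != 65L)
  if (length(bad) > 0)
    stop("malformed row ", bad[1] - 1L, " in ", path, ": expected 65 fields, got ",
         nf[bad[1]], " (row index counts data rows, header excluded)")
  df <- utils::read.csv(path, header = TRUE)
  if (ncol(df) != 65L) stop("expected 65 columns in ", path)
  num <- as.matrix(df)
  if (!is.numeric(num) || anyNA(num)) {
    bad_row <- which(apply(is.na(suppressWarnings(
      matrix(as.numeric(as.matrix(df)), nrow(df)))), 1, any))[1]
    stop("non-numeric value in data row ", bad_row, " of ", path)
  }
  frame_stream(num[, -1, drop = FALSE], num[, 1], sensor_id = sensor_id,
               fps = fps, temp_band = temp_band)
}

#' Write a frame stream to CSV
#'
#' One row per frame: timestamp then 64 pixel values in row-major pixel
#' order, with header `timestamp,p01..p64`.
#'
#' @param stream a [frame_stream()]; must be non-empty.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_frame_stream <- function(stream, path) {
  if (!inherits(stream, "frame_stream")) stop("not a frame_stream")
  if (n_frames(stream) == 0) stop("cannot write an empty frame stream")
  df <- data.frame(timestamp = stream$timestamps, stream$pixels)
  names(df) <- c("timestamp", sprintf("p%02d", 1:64))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an activity record
#'
#' Bundles the per-sensor frame streams of one activity repetition with its
#' metadata.
#'
#' @param streams named list of [frame_stream()] objects, one per sensor.
#' @param label activity code drawn from the configured vocabulary.
#' @param subjects participant identifier(s).
#' @param layout `"small"` or `"large"`.
#' @param n_subjects number of subjects in the scene (1, 2, or 3).
#' @param vocab permitted activity codes (default [activity_vocabulary()]).
#' @return an object of class `activity_record`.
#' @export
activity_record <- function(streams, label, subjects, layout = "large",
                            n_subjects = length(subjects),
                            vocab = activity_vocabulary()) {
  if (!label %in% vocab)
    stop("unknown activity label '", label, "'")
  if (!layout %in% c("small", "large")) stop("layout must be 'small' or 'large'")
  if (!n_subjects %in% 1:3) stop("n_subjects must be 1, 2 or 3")
  if (is.null(names(streams)) || any(names(streams) == ""))
    names(streams) <- vapply(streams, function(s) s$sensor_id, character(1))
  structure(list(streams = streams, label = label, subjects = subjects,
                 layout = layout, n_subjects = n_subjects),
            class = "activity_record")
}

#' @export
print.activity_record <- function(x, ...) {
  cat("<activity_record>", x$label, "| subjects:", paste(x$subjects, collapse = "+"),
      "| layout:", x$layout, "| sensors:", paste(names(x$streams), collapse = ","), "\n")
  invisible(x)
}

#' Load a dataset of activity records from a manifest
#'
#' The manifest (JSON or YAML, chosen by file extension) lists one entry per
#' record with fields `label`, `subjects`, `layout`, and `streams`, the
#' latter a mapping from sensor id to a CSV path (relative paths resolve
#' against the manifest's directory).
#'
#' @param manifest path to the manifest file.
#' @param vocab permitted activity codes.
#' @return list of [activity_record()] objects, one per manifest entry.
#' @export
load_dataset <- function(manifest, vocab = activity_vocabulary()) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  ext <- tolower(tools::file_ext(manifest))
  spec <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(manifest)
          else jsonlite::read_json(manifest, simplifyVector = FALSE)
  entries <- if (!is.null(spec$records)) spec$records else spec
  base <- dirname(manifest)
  lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    if (is.null(e$label) || !e$label %in% vocab)
      stop("record ", i, ": unknown or missing label '", e$label %||% "<missing>", "'")
    streams <- lapply(names(e$streams), function(sid) {
      p <- e$streams[[sid]]
      if (!file.exists(p)) p <- file.path(base, p)
      if (!file.exists(p)) stop("record ", i, " (", e$label, "): missing stream file for sensor ", sid)
      read_frame_stream(p, sensor_id = sid)
    })
    names(streams) <- names(e$streams)
    activity_record(streams, label = e$label,
                    subjects = unlist(e$subjects),
                    layout = e$layout %||% "large",
                    vocab = vocab)
  })
}

#' Write a dataset of activity records as CSV streams plus a manifest
#'
#' @param records list of [activity_record()] objects.
#' @param dir output directory (created if needed).
#' @param format `"json"` or `"yaml"` manifest format.
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(records, dir, format = c("json", "yaml")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    paths <- lapply(names(r$streams), function(sid) {
      fn <- sprintf("rec%04d_%s.csv", i, sid)
      write_frame_stream(r$streams[[sid]], file.path(dir, fn))
      fn
    })
    names(paths) <- names(r$streams)
    list(label = r$label, subjects = r$subjects, layout = r$layout,
         streams = paths)
  })
  manifest <- file.path(dir, paste0("manifest.", ifelse(format == "json", "json", "yaml")))
  if (format == "json") {
    jsonlite::write_json(list(records = entries), manifest, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(list(records = entries), manifest)
  }
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
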