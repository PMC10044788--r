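# Readers/writers for frames, YOLO-style label files, track CSVs, and the
# flat YAML run configuration; plus a small level-filtered logger.

.log_state <- new.env(parent = emptyenv())
.log_state$level <- "info"
.log_state$file <- NULL
.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Configure package logging
#'
#' Messages at or above \code{level} go to stderr, and additionally to
#' \code{file} when set.
#'
#' @param level one of "debug", "info", "warn", "error".
#' @param file optional path of a log file (appended).
#' @return invisibly, the previous settings.
#' @export
setLogging <- function(level = "info", file = NULL) {
  level <- match.arg(level, names(.log_levels))
  old <- list(level = .log_state$level, file = .log_state$file)
  .log_state$level <- level
  .log_state$file <- file
  invisible(old)
}

logMsg <- function(level, fmt, ...) {
  if (.log_levels[[level]] < .log_levels[[.log_state$level]]) return(invisible())
  line <- sprintf("[%s] %s mrtrack: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), sprintf(fmt, ...))
  message(line)
  if (!is.null(.log_state$file))
    cat(line, "\n", file = .log_state$file, append = TRUE, sep = "")
  invisible()
}

#' Read video frames from a directory of images
#'
#' Reads every \code{stride}-th frame, in lexicographic order of the numbered
#' file names, from a directory of PNG/JPEG/TIFF images (one image per frame).
#' The recorded frame rate is \code{frameRate / stride}: subsampling a 60 fps
#' clip with stride 3 yields an effective rate of 20 frames per second.
#'
#' @param path directory containing image files, or a single image file.
#' @param stride keep every stride-th frame (>= 1).
#' @param frameRate nominal frame rate of the source, frames/second.
#' @return A \linkS4class{FrameSequence}.
#' @export
readFrames <- function(path, stride = 1L, frameRate = 25) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1) stop("stride must be a positive integer")
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                    ignore.case = TRUE, full.names = TRUE))
  } else path
  if (length(files) == 0) stop("no image files found in ", path)
  keep <- files[seq(1, length(files), by = stride)]
  frames <- lapply(keep, function(f) {
    img <- tryCatch(EBImage::readImage(f),
                    error = function(e) stop("unreadable image file: ", f,
                                             " (", conditionMessage(e), ")"))
    a <- EBImage::imageData(img)
    if (length(dim(a)) == 3) a <- apply(a, c(1, 2), mean)
    # EBImage stores (x, y) in [0,1]; convert to (y, x) rows-first, 0-255
    t(a) * 255
  })
  dims <- vapply(frames, dim, integer(2))
  if (!all(dims[1, ] == dims[1, 1]) || !all(dims[2, ] == dims[2, 1]))
    stop("inconsistent frame sizes across the sequence")
  FrameSequence(frames, frameRate = frameRate / stride)
}

#' Write frames as numbered PNG files
#'
#' @param seq a \linkS4class{FrameSequence}.
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
writeFrames <- function(seq, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nFrames(seq))
  for (i in seq_len(nFrames(seq))) {
    paths[i] <- file.path(dir, sprintf("frame_%06d.png", i - 1))
    png::writePNG(pmin(pmax(getFrame(seq, i) / 255, 0), 1), paths[i])
  }
  invisible(paths)
}

#' Write and read track files
#'
#' Tracks are stored as CSV with header \code{frame,id,x,y,conf}; frame
#' indices are 0-based and coordinates are pixels (centroid). At most one row
#' per (frame, id) pair is allowed, and rows must be sorted by (frame, id).
#'
#' @param tracks data.frame with columns frame, id, x, y and optionally conf
#'   (defaulting to 1).
#' @param path output (or input) CSV path.
#' @return \code{writeTracks} invisibly returns \code{path};
#'   \code{readTracks} returns the track data.frame.
#' @export
writeTracks <- function(tracks, path) {
  tracks <- as.data.frame(tracks)
  if (nrow(tracks) > 0) {
    if (is.null(tracks$conf)) tracks$conf <- 1
    tracks <- tracks[, c("frame", "id", "x", "y", "conf")]
    if (anyDuplicated(tracks[, c("frame", "id")]))
      stop("duplicate (frame, identity) records")
    if (is.unsorted(order(tracks$frame, tracks$id)) ||
        any(diff(order(tracks$frame, tracks$id)) < 0))
      tracks <- tracks[order(tracks$frame, tracks$id), ]
  } else {
    tracks <- data.frame(frame = integer(), id = integer(), x = numeric(),
                         y = numeric(), conf = numeric())
  }
  write.csv(tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTracks
#' @export
readTracks <- function(path) {
  if (!file.exists(path)) stop("track file does not exist: ", path)
  tr <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed track file: ",
                                          conditionMessage(e)))
  need <- c("frame", "id", "x", "y", "conf")
  if (!all(need %in% names(tr)))
    stop("track file missing columns: ",
         paste(setdiff(need, names(tr)), collapse = ", "))
  bad <- which(!is.finite(tr$frame) | !is.finite(tr$id))
  if (length(bad) > 0)
    stop("malformed row at line ", bad[1] + 1L, " of ", path)
  if (anyDuplicated(tr[, c("frame", "id")]))
    stop("duplicate (frame, identity) records in ", path)
  tr
}

#' Write and read YOLO-style label files
#'
#' One text file per frame named \code{frame_<index>.txt}; each row is
#' \code{class cx cy w h [id]} with centre and size normalized to [0, 1] by
#' the frame dimensions. Class 0 denotes an ear.
#'
#' @param labels data.frame with columns frame, class, x0, y0, x1, y1 (pixel
#'   box corners, half-open) and optionally id.
#' @param dir label directory.
#' @param width,height frame dimensions in pixels used for normalization.
#' @return \code{writeLabels} invisibly returns \code{dir}();
#'   \code{readLabels} returns the label data.frame in pixel coordinates.
#' @export
writeLabels <- function(labels, dir, width, height) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fr in unique(labels$frame)) {
    sub <- labels[labels$frame == fr, , drop = FALSE]
    rows <- sprintf("%d %.6f %.6f %.6f %.6f%s", sub$class,
                    (sub$x0 + sub$x1) / 2 / width,
                    (sub$y0 + sub$y1) / 2 / height,
                    (sub$x1 - sub$x0) / width, (sub$y1 - sub$y0) / height,
                    ifelse(is.na(sub$id), "", paste0(" ", sub$id)))
    writeLines(rows, file.path(dir, sprintf("frame_%06d.txt", fr)))
  }
  invisible(dir)
}

#' @rdname writeLabels
#' @export
readLabels <- function(dir, width, height) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.txt$",
                           full.names = TRUE))
  out <- lapply(files, function(f) {
    fr <- as.integer(sub("^frame_(\\d+)\\.txt$", "\\1", basename(f)))
    lines <- readLines(f)
    if (length(lines) == 0) return(NULL)
    parts <- strsplit(trimws(lines), "\\s+")
    do.call(rbind, lapply(seq_along(parts), function(i) {
      p <- suppressWarnings(as.numeric(parts[[i]]))
      if (length(p) < 5 || anyNA(p[1:5]))
        stop("malformed label row ", i, " in ", f)
      data.frame(frame = fr, class = as.integer(p[1]),
                 x0 = (p[2] - p[4] / 2) * width, y0 = (p[3] - p[5] / 2) * height,
                 x1 = (p[2] + p[4] / 2) * width, y1 = (p[3] + p[5] / 2) * height,
                 id = if (length(p) >= 6) as.integer(p[6]) else NA_integer_)
    }))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(), class = integer(), x0 = numeric(),
                      y0 = numeric(), x1 = numeric(), y1 = numeric(),
                      id = integer())
  out
}

# Default configuration. Detector training defaults follow the published
# hyper-parameter table of the ear-detection network: SGD, batch size 8,
# 50 epochs, initial learning rate 0.01, one-cycle final factor 0.2,
# momentum 0.937.
defaultConfig <- function() {
  list(
    seed = 1L,
    n_subjects = 2L,
    frame_rate = 25,
    # synthetic arena (study conditions of the bundled generator)
    arena_frames = 300L,
    train_frames = 200L,
    speed_scale = 1,
    train_speed_scale = 2,
    body_major = 9,
    body_minor = 4.5,
    ear_radius = 2.8,
    noise_sd = 2,
    # preprocessing
    reference_mean = 128,
    blob_threshold = 35,
    min_blob_area = 50,
    background_samples = 40L,
    background_stat = "median",
    ear_threshold = 0.5,
    # detector
    img_size = 64L,
    improved_neck = TRUE,
    base_width = 8L,
    confidence_threshold = 0.5,
    track_confidence = 0.1,
    nms_iou = 0.45,
    epochs = 50L,
    batch_size = 8L,
    learning_rate = 0.01,
    final_lr_factor = 0.2,
    momentum = 0.937,
    # siamese
    siamese_epochs = 8L,
    siamese_pairs = 200L,
    crop_size = 32L,
    embed_dim = 16L,
    margin = 1.0,
    min_score = 0.2,
    neg_gap_seconds = 60,
    # evaluation / behaviour
    match_radius = 20,
    drift_radius = 6,
    mapping_window = 30L,
    px_per_cm = 10,
    block_seconds = 300
  )
}

#' Load a run configuration
#'
#' Reads a flat YAML key/value file and merges it over the documented
#' defaults. Missing keys take their defaults (detector training defaults:
#' batch size 8, 50 epochs, initial learning rate 0.01, SGD momentum 0.937,
#' one-cycle final learning-rate factor 0.2); unknown keys raise a warning; a
#' value whose type does not match its default raises an error naming the key.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return named list of configuration values.
#' @examples
#' cfg <- loadConfig(NULL)
#' cfg$momentum   # 0.937
#' @export
loadConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file does not exist: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  if (!is.list(user)) stop("config must be a flat key/value mapping")
  for (key in names(user)) {
    if (!key %in% names(cfg)) {
      warning("unknown config key: ", key)
      next
    }
    val <- user[[key]]
    if (!is.numeric(val) && is.numeric(cfg[[key]]))
      stop("type mismatch for config key '", key, "': expected numeric")
    if (!is.logical(val) && is.logical(cfg[[key]]))
      stop("type mismatch for config key '", key, "': expected logical")
    cfg[[key]] <- if (is.integer(cfg[[key]])) as.integer(val) else val
  }
  cfg
}
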