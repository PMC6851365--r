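#' In-memory video source
#'
#' Wraps a sequence of frames with its native frame rate so it can be fed to
#' [extract_frames()]. This is the entry point for synthetic videos and for
#' frames decoded by any external tool.
#'
#' @param frames either a list of `H x W x 3` arrays or a 4-D array
#'   `H x W x 3 x T`, in temporal order; values on `[0,1]` or 0-255.
#' @param fps native frame rate (frames per second).
#' @return An `array_video` object.
#' @export
array_video <- function(frames, fps = 30) {
  if (is.array(frames) && length(dim(frames)) == 4L)
    frames <- lapply(seq_len(dim(frames)[4]), function(i) frames[, , , i])
  if (!is.list(frames))
    stop("frames must be a list of H x W x 3 arrays or a 4-D array",
         call. = FALSE)
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  structure(list(frames = frames, fps = fps), class = "array_video")
}

#' Sample, resize and normalize frames from a video source
#'
#' Downsamples a video source to `rate_fps` (1 FPS by default — the sampling
#' rate at which per-frame phase recognition operates), resizes each sampled
#' frame to the classifier's input resolution with bilinear interpolation
#' (aspect distortion accepted; 1920:1080 is within a percent of 299:168),
#' and scales pixel values to `[0,1]`. The frame sampled for output second
#' `t` is the native frame whose timestamp is closest to the window center
#' `t + 0.5` s.
#'
#' Supported sources: an [array_video()]; a directory of pre-extracted
#' PNG/JPEG frames named `<t>.png` (read via EBImage, treated as a native
#' stream at `dir_fps`). Video container files must be pre-extracted to
#' frames by an external decoder; passing one raises an input error.
#'
#' @param video an [array_video()] or a frame-directory path.
#' @param rate_fps output sampling rate, at most the native rate; default 1.
#' @param resolution `(width, height)` target, default `c(299, 168)` — the
#'   recognizer's input grid.
#' @param dir_fps native rate assumed for directory sources (default 1,
#'   i.e. already-downsampled frames).
#' @return A `frame_stream`: list of frame records with `time_s` (0-based
#'   integer sample index), `image` (H x W x 3 in `[0,1]`), `source_id`.
#' @export
extract_frames <- function(video, rate_fps = 1, resolution = c(299L, 168L),
                           dir_fps = 1) {
  stopifnot(length(resolution) == 2L, rate_fps > 0)
  if (is.character(video)) {
    if (dir.exists(video)) {
      video <- video_from_dir(video, dir_fps)
    } else if (file.exists(video)) {
      stop("input error: '", video, "' is not a frame directory; decode ",
           "video containers to per-frame images first", call. = FALSE)
    } else stop("input error: cannot open '", video, "'", call. = FALSE)
  }
  if (!inherits(video, "array_video"))
    stop("input error: unsupported video source", call. = FALSE)
  n_native <- length(video$frames)
  if (n_native == 0L) stop("empty stream: video has no frames", call. = FALSE)
  if (rate_fps > video$fps)
    stop("rate_fps (", rate_fps, ") exceeds native rate (", video$fps, ")",
         call. = FALSE)
  duration_s <- n_native / video$fps
  n_out <- max(1L, floor(duration_s * rate_fps))
  sid <- video$source_id %||% "video"
  records <- vector("list", n_out)
  for (j in seq_len(n_out)) {
    t_center <- (j - 1L) / rate_fps + 0.5 / rate_fps
    k <- round(t_center * video$fps + 0.5)  # native frames are 1-based
    k <- max(1L, min(n_native, as.integer(k)))
    img <- normalize_frame(resize_frame(video$frames[[k]], resolution))
    records[[j]] <- list(time_s = j - 1L, image = img, source_id = sid)
  }
  structure(records, class = "frame_stream", source_id = sid)
}

video_from_dir <- function(path, fps) {
  files <- list.files(path, pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L)
    stop("input error: no frame images in '", path, "'", call. = FALSE)
  key <- suppressWarnings(as.numeric(sub("\\.[^.]*$", "", basename(files))))
  files <- files[order(key, basename(files))]
  frames <- lapply(files, function(f) {
    img <- EBImage::readImage(f)
    a <- EBImage::imageData(img)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
    if (dim(a)[3] > 3L) a <- a[, , 1:3]          # drop alpha
    aperm(a, c(2L, 1L, 3L))                      # EBImage is W x H -> H x W
  })
  v <- array_video(frames, fps = fps)
  v$source_id <- basename(path)
  v
}

# bilinear resize to (width, height); input H x W x 3
resize_frame <- function(img, resolution) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  w <- as.integer(resolution[1]); h <- as.integer(resolution[2])
  if (dim(img)[1] == h && dim(img)[2] == w) return(img)
  e <- EBImage::Image(aperm(img, c(2L, 1L, 3L)), colormode = "Color")
  out <- EBImage::resize(e, w = w, h = h)       # bilinear by default
  aperm(EBImage::imageData(out), c(2L, 1L, 3L))
}

# scale pixel values to [0,1]; idempotent on already-normalized input
normalize_frame <- function(img) {
  if (max(img) > 1 + 1e-9) img <- img / 255
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' @export
print.frame_stream <- function(x, ...) {
  d <- if (length(x) > 0L) paste(dim(x[[1]]$image), collapse = "x") else "-"
  cat("Frame stream:", length(x), "frames,", d, "(HxWxC),",
      "source:", attr(x, "source_id") %||% "<unnamed>", "\n")
  invisible(x)
}

#' Per-frame true labels for a frame stream
#'
#' @param frames a `frame_stream`.
#' @param timeline a [phase_timeline()]; when `NULL`, labels already carried
#'   by the frames are returned.
#' @return Character vector of labels aligned with the stream.
#' @export
frame_labels <- function(frames, timeline = NULL) {
  if (is.null(timeline)) {
    lab <- vapply(frames, function(f) f$label %||% NA_character_, character(1))
    if (anyNA(lab)) stop("frames carry no labels; supply a timeline",
                         call. = FALSE)
    return(lab)
  }
  t <- vapply(frames, function(f) f$time_s, integer(1))
  labels_from_timeline(timeline, max(t) + 1L)[t + 1L]
}
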