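#' Frame sequences
#'
#' A `frame_sequence` is the package's uniform in-memory representation of
#' video data: a list of `T` grayscale frames (H x W matrices with
#' intensities in \[0,1\]) plus a frame rate in Hz and a provenance string.
#'
#' @param frames list of numeric H x W matrices with values in \[0,1\],
#'   or a single matrix, or an H x W x T array.
#' @param fps frame rate in Hz (> 0).
#' @param source_path provenance string recorded with the sequence.
#' @return An object of class `frame_sequence` with elements `frames`
#'   (list of matrices), `fps` and `source`.
#' @examples
#' fs <- frame_sequence(list(matrix(0.5, 4, 4), matrix(0.6, 4, 4)), fps = 30)
#' length(fs$frames)
#' @export
frame_sequence <- function(frames, fps, source_path = "<memory>") {
  if (is.matrix(frames)) frames <- list(frames)
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (!is.list(frames) || length(frames) < 1L)
    stop("`frames` must hold at least one frame", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share the same height and width", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("`fps` must be a single positive number", call. = FALSE)
  rng <- range(vapply(frames, range, numeric(2)))
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("frame intensities must lie in [0, 1]", call. = FALSE)
  structure(list(frames = frames, fps = as.numeric(fps),
                 source = source_path),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %d frames, %d x %d px, %.3g fps (%s)\n",
              length(x$frames), d[1], d[2], x$fps, x$source))
  invisible(x)
}

# natural sort: "f2.png" before "f10.png"
natural_sort <- function(paths) {
  base <- basename(paths)
  keys <- lapply(base, function(s) {
    parts <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
    parts
  })
  maxlen <- max(vapply(keys, length, integer(1)))
  ord <- do.call(order, lapply(seq_len(maxlen), function(i) {
    piece <- vapply(keys, function(k) if (i <= length(k)) k[i] else "",
                    character(1))
    num <- suppressWarnings(as.numeric(piece))
    if (all(!is.na(num) | piece == "")) {
      num[is.na(num)] <- -Inf
      num
    } else piece
  }))
  paths[ord]
}

# one file -> list of grayscale [0,1] matrices (multi-page TIFF -> several)
read_gray_frames <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  cm <- EBImage::colorMode(img)
  if (cm == EBImage::Color) {
    dat <- EBImage::imageData(EBImage::channel(img, "luminance"))
  }
  nd <- length(dim(dat))
  if (nd == 2L) {
    list(t(dat))                       # EBImage is x,y; we store y,x
  } else {
    lapply(seq_len(dim(dat)[3]), function(i) t(dat[, , i]))
  }
}

#' Load a video frame sequence from image files
#'
#' Reads single images, lexicographically ordered image series (PNG, TIFF,
#' JPEG) and multi-page TIFF stacks into a [frame_sequence]. Color input is
#' converted to grayscale by luminance weighting and intensities are
#' normalized to \[0,1\] regardless of the source bit depth, so downstream
#' thresholds are bit-depth independent. Files are put in temporal order by
#' natural sort of their names.
#'
#' @param path a file, a directory, a glob pattern (e.g. `"frames/*.png"`),
#'   or a character vector of files.
#' @param fps_override frame rate in Hz. Required for image sequences,
#'   which carry no timing metadata.
#' @return A [frame_sequence].
#' @export
open_frames <- function(path, fps_override = NULL) {
  files <- character(0)
  for (p in path) {
    if (dir.exists(p)) {
      files <- c(files, list.files(p, full.names = TRUE,
                                   pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                                   ignore.case = TRUE))
    } else if (grepl("[*?]", p)) {
      files <- c(files, Sys.glob(p))
    } else if (file.exists(p)) {
      files <- c(files, p)
    }
  }
  if (length(files) == 0L)
    stop("input error: no readable image files at ", paste(path, collapse = ", "),
         call. = FALSE)
  files <- natural_sort(files)
  frames <- do.call(c, lapply(files, read_gray_frames))
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("format error: frames have mixed sizes", call. = FALSE)
  if (is.null(fps_override))
    stop(paste("configuration error: image sequences carry no frame rate;",
               "supply fps_override"), call. = FALSE)
  frame_sequence(frames, fps = fps_override,
                 source_path = paste(files[1], "(+", length(files) - 1,
                                     "more)"))
}

#' Compute an animal-free background by temporal projection
#'
#' Exploits per-pixel intensity variation over time: as long as the animal
#' keeps moving, a maximum-intensity projection removes a dark animal from
#' a bright background, a minimum projection removes a bright animal from a
#' dark background, and a mean projection suits mildly varying illumination.
#'
#' @param seq a [frame_sequence].
#' @param mode one of `"max"`, `"min"`, `"mean"`.
#' @param stride use every `stride`-th frame (default 1 = all frames) to
#'   bound memory/time on long recordings.
#' @return A `background_image`: list with `image` (H x W matrix), `mode`
#'   and `n_frames_used`.
#' @export
compute_background <- function(seq, mode = c("max", "min", "mean"),
                               stride = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(seq, "frame_sequence"), stride >= 1)
  idx <- seq(1L, length(seq$frames), by = as.integer(stride))
  stack <- simplify2array(seq$frames[idx])   # H x W x T
  img <- switch(mode,
    max  = apply(stack, c(1, 2), max),
    min  = apply(stack, c(1, 2), min),
    mean = apply(stack, c(1, 2), mean))
  structure(list(image = img, mode = mode, n_frames_used = length(idx),
                 source = seq$source),
            class = "background_image")
}

#' Write a background image plus JSON sidecar
#'
#' Stores the background as a 16-bit TIFF (or an 8-bit PNG, the PNG
#' writer's depth limit) and a `.json` sidecar with the projection mode,
#' frame count and provenance.
#'
#' @param bg a `background_image` from [compute_background()].
#' @param path output image path (`.tif` for full 16-bit depth, or `.png`).
#' @return `path`, invisibly.
#' @export
write_background <- function(bg, path) {
  stopifnot(inherits(bg, "background_image"))
  EBImage::writeImage(EBImage::Image(t(bg$image)), path, bits.per.sample = 16L)
  sidecar <- sub("\\.[A-Za-z]+$", ".json", path)
  jsonlite::write_json(list(mode = bg$mode, n_frames_used = bg$n_frames_used,
                            source_path = bg$source),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
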