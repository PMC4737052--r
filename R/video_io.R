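# Frame I/O.  Image sequences are read and written as portable graymaps
# (PGM, ASCII "P2" or binary "P5"), a plain grayscale format that needs no
# external imaging library; intensities are rescaled to [0, 1] by the file's
# maxval.  Raw matrices are always accepted programmatically.

#' Read a PGM image
#'
#' Supports ASCII (`P2`) and binary (`P5`) portable graymaps with 8- or
#' 16-bit samples; values are rescaled to `[0, 1]`.
#'
#' @param path file path.
#' @return numeric matrix `img[y, x]` in `[0, 1]`.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header: magic, width, height, maxval, with '#' comments allowed
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || ch == "") stop("unexpected end of PGM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else {
        tok <- paste0(tok, ch)
      }
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop("not a PGM (P2/P5) file: ", path)
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  n <- w * h
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    if (maxval < 256) {
      vals <- as.integer(readBin(con, "integer", n = n, size = 1,
                                 signed = FALSE))
    } else {
      vals <- as.integer(readBin(con, "integer", n = n, size = 2,
                                 signed = FALSE, endian = "big"))
    }
  }
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a PGM image
#'
#' Writes an ASCII (`P2`) portable graymap.  Intensities are clipped to
#' `[0, 1]` and quantized to `maxval` levels.
#'
#' @param img numeric matrix `img[y, x]`.
#' @param path output path.
#' @param maxval maximum sample value (default 65535, 16-bit).
#' @return invisibly, `path`.
#' @export
write_pgm <- function(img, path, maxval = 65535) {
  q <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)),
               sprintf("%d", maxval)), con)
  apply(q, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Read a video from a directory of PGM frames
#'
#' Frames are read in lexicographic filename order.
#'
#' @param dir directory containing `.pgm` files.
#' @param frame_rate frames per second.
#' @param pattern filename filter.
#' @return a [video_stream()].
#' @export
read_video_dir <- function(dir, frame_rate = 50, pattern = "\\.pgm$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L) stop("no frames found in ", dir, call. = FALSE)
  video_stream(lapply(files, read_pgm), frame_rate)
}

#' Write a video as a directory of PGM frames
#'
#' @param video a [video_stream()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return invisibly, the vector of file paths.
#' @export
write_video_dir <- function(video, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(video$frames), function(t) {
    p <- file.path(dir, sprintf("%s_%05d.pgm", prefix, t))
    write_pgm(video$frames[[t]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Serialize detection results as JSON
#'
#' Writes, per frame, the list of detected blocks with their indices, PMI
#' and direction.
#'
#' @param detection a [detect_motion()] result.
#' @param path output file.
#' @param detected_only drop undetected blocks (default `TRUE`).
#' @return invisibly, `path`.
#' @export
write_detection_json <- function(detection, path, detected_only = TRUE) {
  frames <- lapply(detection$maps, function(m) {
    if (detected_only) m <- m[m$detected, , drop = FALSE]
    m[, c("k", "l", "pmi", "theta_hat")]
  })
  jsonlite::write_json(
    list(threshold = detection$threshold, eps = detection$eps,
         frames = frames),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
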