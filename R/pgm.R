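#' Read and write binary PGM (P5) frames
#'
#' Frames are exchanged as binary PGM, magic `P5`, maxval 255, one file per
#' frame, pixel rows stored top to bottom. `read_pgm()` validates the header
#' (magic, dimensions, maxval, payload size) and signals a format error
#' naming the file on any violation; a written frame re-reads byte-exact.
#'
#' @param path file path.
#' @param frame an integer matrix with values in `[0, 255]`.
#' @param config optional [detector_config()]; if given, the file dimensions
#'   must match it.
#' @return `read_pgm()` returns an integer matrix (rows x cols);
#'   `write_pgm()` returns `path` invisibly.
#' @examples
#' f <- matrix(sample(0:255, 12), 3, 4)
#' p <- tempfile(fileext = ".pgm")
#' write_pgm(f, p)
#' identical(read_pgm(p), f + 0L)
#' @export
write_pgm <- function(frame, path) {
  if (!is.matrix(frame) || any(frame < 0) || any(frame > 255))
    stop("invalid-input: frame must be a matrix with values in [0, 255]",
         call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(frame), nrow(frame)), "255"), con, sep = "\n")
  writeBin(as.raw(t(frame)), con)  # row-major payload
  invisible(path)
}

pgm_error <- function(path, why) {
  stop(sprintf("format error in PGM file '%s': %s", path, why), call. = FALSE)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path, config = NULL) {
  if (!file.exists(path)) pgm_error(path, "file does not exist")
  raw <- readBin(path, "raw", n = file.size(path))
  # header: magic, width, height, maxval as whitespace/comment-separated
  # tokens, then a single whitespace byte before the payload
  pos <- 1L; tokens <- character(0)
  n <- length(raw)
  is_space <- function(b) b %in% as.raw(c(0x20, 0x09, 0x0a, 0x0d, 0x0b, 0x0c))
  while (length(tokens) < 4L) {
    while (pos <= n && is_space(raw[pos])) pos <- pos + 1L
    if (pos <= n && raw[pos] == as.raw(0x23)) {   # '#' comment to end of line
      while (pos <= n && raw[pos] != as.raw(0x0a)) pos <- pos + 1L
      next
    }
    start <- pos
    while (pos <= n && !is_space(raw[pos])) pos <- pos + 1L
    if (pos == start) pgm_error(path, "truncated header")
    tokens <- c(tokens, rawToChar(raw[start:(pos - 1L)]))
  }
  if (tokens[1] != "P5")
    pgm_error(path, paste0("unsupported magic '", tokens[1],
                           "' (only binary P5 is supported)"))
  width <- suppressWarnings(as.integer(tokens[2]))
  height <- suppressWarnings(as.integer(tokens[3]))
  maxval <- suppressWarnings(as.integer(tokens[4]))
  if (is.na(width) || is.na(height) || width <= 0L || height <= 0L)
    pgm_error(path, "invalid dimensions")
  if (is.na(maxval) || maxval != 255L)
    pgm_error(path, paste0("maxval ", tokens[4], " unsupported (must be 255)"))
  pos <- pos + 1L  # single whitespace after maxval
  npx <- width * height
  if (n - pos + 1L < npx) pgm_error(path, "truncated pixel data")
  vals <- as.integer(raw[pos:(pos + npx - 1L)])
  frame <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  if (!is.null(config) &&
      (height != config$height_px || width != config$width_px))
    pgm_error(path, sprintf("dimensions %d x %d do not match config %d x %d",
                            height, width, config$height_px, config$width_px))
  frame
}

#' Read and write hot-pixel masks
#'
#' A hot-pixel mask travels either as a PGM of the sensor dimensions
#' (255 = hot, 0 = normal) or as a two-column 1-based `(row, col)` CSV.
#'
#' @param mask a logical hot-pixel matrix.
#' @param path file path.
#' @param config a [detector_config()] (required to size a mask read from
#'   CSV; optional dimension check for PGM).
#' @return readers return a logical matrix; writers return `path` invisibly.
#' @export
write_mask_pgm <- function(mask, path) {
  write_pgm(matrix(ifelse(mask, 255L, 0L), nrow = nrow(mask)), path)
}

#' @rdname write_mask_pgm
#' @export
read_mask_pgm <- function(path, config = NULL) {
  read_pgm(path, config) > 0L
}

#' @rdname write_mask_pgm
#' @export
write_mask_csv <- function(mask, path) {
  write.csv(mask_positions(mask), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mask_pgm
#' @export
read_mask_csv <- function(path, config) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("row", "col") %in% names(df)))
    stop("format error: mask CSV ", path, " must have columns row, col",
         call. = FALSE)
  hot_mask(df, config)
}

#' List the PGM frames of a directory in sequence order
#'
#' Frame order is defined by the zero-padded numeric part of the file names.
#'
#' @param dir directory containing `*.pgm` frames.
#' @return character vector of paths in frame order.
#' @export
list_frames <- function(dir) {
  if (!dir.exists(dir))
    stop("invalid-input: no such frames directory: ", dir, call. = FALSE)
  paths <- list.files(dir, pattern = "\\.pgm$", full.names = TRUE)
  if (length(paths) == 0L)
    stop("invalid-input: no PGM frames found in ", dir, call. = FALSE)
  num <- suppressWarnings(
    as.integer(sub("^.*?(\\d+)\\.pgm$", "\\1", basename(paths))))
  paths[order(num, basename(paths), na.last = TRUE)]
}

#' Run the streaming detector over a directory of PGM frames
#'
#' Reads each frame in sequence order, applies [stream_detect()] and returns
#' the detection record stream (`frame_index`, `row`, `col`); the sentinel
#' `(0,0)` is preserved.
#'
#' @param dir directory of PGM frames (see [list_frames()]).
#' @param mask logical hot-pixel matrix or `NULL`.
#' @param config a [detector_config()].
#' @return data frame with columns `frame_index` (0-based), `row`, `col`.
#' @export
detect_frames <- function(dir, mask = NULL, config) {
  paths <- list_frames(dir)
  n <- length(paths)
  rows <- integer(n); cols <- integer(n)
  for (k in seq_len(n)) {
    pos <- stream_detect(read_pgm(paths[k], config), mask, config)
    rows[k] <- pos[["row"]]; cols[k] <- pos[["col"]]
  }
  data.frame(frame_index = seq_len(n) - 1L, row = rows, col = cols)
}
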