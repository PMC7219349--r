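#' Read a raster image into feature form
#'
#' Decodes PNG, TIFF or PGM files into a [feature_image()].  Grayscale files
#' give one feature channel; RGB files give three.  Values are returned in
#' the file's native intensity units (0--255 for 8-bit storage); an alpha
#' channel, if present, is dropped.
#'
#' @param path path to a PNG, TIFF or PGM file; format detected from the
#'   file extension (`.png`, `.tif`/`.tiff`, `.pgm`).
#' @param as_gray collapse RGB input to a single luminance channel
#'   (unweighted channel mean)?
#' @return a `feature_image`.
#' @export
read_image <- function(path, as_gray = FALSE) {
  if (!file.exists(path))
    stop(sprintf("cannot read image '%s': no such file", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = tryCatch(png::readPNG(path) * 255,
                    error = function(e) stop(sprintf(
                      "cannot decode PNG '%s': %s", path, conditionMessage(e)),
                      call. = FALSE)),
    tif  = ,
    tiff = tryCatch(tiff::readTIFF(path) * 255,
                    error = function(e) stop(sprintf(
                      "cannot decode TIFF '%s': %s", path,
                      conditionMessage(e)), call. = FALSE)),
    pgm  = read_pgm(path),
    stop(sprintf("unsupported image format '%s' for '%s'", ext, path),
         call. = FALSE))
  plane <- function(a, l) matrix(a[, , l], dim(a)[1L], dim(a)[2L])
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3L] == 4L) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(arr)[3L] == 2L) arr <- plane(arr, 1L)              # gray+alpha
  }
  if (length(dim(arr)) == 3L && isTRUE(as_gray)) {
    arr <- (plane(arr, 1L) + plane(arr, 2L) + plane(arr, 3L)) / 3
  }
  if (length(dim(arr)) == 3L && dim(arr)[3L] == 1L) arr <- plane(arr, 1L)
  if (is.null(dim(arr)) || prod(dim(arr)[1:2]) == 0L)
    stop(sprintf("zero-area image '%s'", path), call. = FALSE)
  feature_image(snap_int(arr))
}

# 8-bit decoders hand back k/255 floats; snap values that are integers up to
# float error so 8-bit round-trips are value-exact (16-bit data unaffected)
snap_int <- function(v) {
  r <- round(v)
  ifelse(abs(v - r) < 1e-6, r, v)
}

#' Write a feature image to disk
#'
#' Single-channel images may be written as PNG or PGM; three-channel images
#' as PNG.  Values are clipped to the intensity range and rounded to the
#' 8-bit grid by the encoder.
#'
#' @param image a [feature_image()] (or coercible).
#' @param path output path; format from extension.
#' @return `invisible(path)`.
#' @export
write_image <- function(image, path) {
  image <- as.feature_image(image)
  rng <- image$intensity_range
  v <- pmin(pmax(image$values, rng[1L]), rng[2L])
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    if (image$channels != 1L) stop("PGM supports one channel", call. = FALSE)
    write_pgm(vec_to_grid(round(v[, 1L]), image$height, image$width), path)
  } else if (ext == "png") {
    if (image$channels == 1L) {
      png::writePNG(vec_to_grid(v[, 1L], image$height, image$width) / 255,
                    path)
    } else {
      arr <- array(0, dim = c(image$height, image$width, image$channels))
      for (l in seq_len(image$channels))
        arr[, , l] <- vec_to_grid(v[, l], image$height, image$width)
      png::writePNG(arr / 255, path)
    }
  } else {
    stop(sprintf("unsupported output format '%s'", ext), call. = FALSE)
  }
  invisible(path)
}

#' Write a label map as an 8-bit image
#'
#' The default palette spreads the C classes evenly over the 0--255 gray
#' range: class j maps to `round(255 * j / (C - 1))` (0 when C = 1), so the
#' written image is directly viewable.
#'
#' @param labels a [label_map()].
#' @param path output path (`.png` or `.pgm`).
#' @param palette optional numeric vector of length C giving the gray value
#'   for each class (class 0 first).
#' @return `invisible(path)`.
#' @export
write_label_map <- function(labels, path, palette = NULL) {
  C <- labels$C
  if (is.null(palette)) {
    palette <- if (C == 1L) 0 else round(255 * (seq_len(C) - 1) / (C - 1))
  }
  if (length(palette) != C) stop("palette length must equal C", call. = FALSE)
  img <- feature_image(matrix(palette[labels$labels + 1L], ncol = 1L),
                       height = labels$height, width = labels$width)
  write_image(img, path)
}

#' Read a label map back from an 8-bit image
#'
#' Inverts the default [write_label_map()] palette: the distinct gray values
#' present are ranked and mapped to classes 0..C-1 in increasing order.
#'
#' @param path image path.
#' @param C optional class count (defaults to the number of distinct values).
#' @return a `label_map`.
#' @export
read_label_map <- function(path, C = NULL) {
  img <- read_image(path, as_gray = TRUE)
  vals <- img$values[, 1L]
  lev <- sort(unique(vals))
  lab <- match(vals, lev) - 1L
  label_map(lab, height = img$height, width = img$width,
            C = if (is.null(C)) length(lev) else C)
}

# Minimal PGM (P2 ascii / P5 binary, maxval <= 255) reader and writer.  PGM
# is the plain-text fixture format of the test suite; no installed package
# decodes it.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- pgm_tokenizer(con)
  magic <- tok()
  if (!magic %in% c("P2", "P5"))
    stop(sprintf("cannot decode PGM '%s': bad magic '%s'", path, magic),
         call. = FALSE)
  w <- suppressWarnings(as.integer(tok()))
  h <- suppressWarnings(as.integer(tok()))
  maxval <- suppressWarnings(as.integer(tok()))
  if (anyNA(c(w, h, maxval)) || w < 1L || h < 1L || maxval < 1L)
    stop(sprintf("cannot decode PGM '%s': bad header", path), call. = FALSE)
  n <- w * h
  if (magic == "P5") {
    raw <- readBin(con, "raw", n = n)
    if (length(raw) < n)
      stop(sprintf("cannot decode PGM '%s': truncated data", path),
           call. = FALSE)
    px <- as.integer(raw)
  } else {
    px <- integer(0)
    while (length(px) < n) {
      t <- tok()
      if (!nzchar(t))
        stop(sprintf("cannot decode PGM '%s': truncated data", path),
             call. = FALSE)
      px <- c(px, suppressWarnings(as.integer(t)))
    }
    if (anyNA(px))
      stop(sprintf("cannot decode PGM '%s': non-numeric data", path),
           call. = FALSE)
  }
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}

# whitespace/comment-aware token reader over a binary connection
pgm_tokenizer <- function(con) {
  function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) return("")
      if (ch == "#") {  # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
      } else if (!grepl("[[:space:]]", ch)) {
        tokchars <- ch
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || grepl("[[:space:]]", ch)) break
          tokchars <- c(tokchars, ch)
        }
        return(paste(tokchars, collapse = ""))
      }
    }
  }
}

write_pgm <- function(m, path, ascii = TRUE) {
  m <- pmin(pmax(round(m), 0), 255)
  if (ascii) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
    writeLines(apply(m, 1L, paste, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(ncol(m), nrow(m)), "255"), con)
    writeBin(as.raw(grid_to_vec(m)), con)
  }
  invisible(path)
}
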