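# Minimal multi-page TIFF I/O.
#
# No TIFF package is available in the supported dependency set, so the
# subset of baseline TIFF needed for grayscale 2D+T movies is implemented
# here directly: uncompressed, single-sample-per-pixel pages of 8/16-bit
# unsigned integers or 32-bit IEEE floats, both byte orders on read,
# little-endian single-strip pages on write.

TIFF_TYPE_SIZES <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)

read_tiff_pages <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  rd_int <- function(off, size, n = 1, signed = size >= 4) {
    # size-4 reads are signed (readBin limitation); offsets < 2^31 in
    # practice for the movie sizes this package handles.
    readBin(raw[(off + 1):(off + size * n)], what = "integer", n = n,
            size = size, signed = signed || size >= 4, endian = endian)
  }
  rd_dbl <- function(off, n = 1) {
    readBin(raw[(off + 1):(off + 4 * n)], what = "numeric", n = n,
            size = 4, endian = endian)
  }
  if (rd_int(2, 2) != 42) stop("not a TIFF file: ", path)
  ifd_off <- rd_int(4, 4)
  pages <- list()
  while (ifd_off != 0) {
    n_entries <- rd_int(ifd_off, 2)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e_off <- ifd_off + 2 + (i - 1) * 12
      tag <- rd_int(e_off, 2)
      type <- rd_int(e_off + 2, 2)
      count <- rd_int(e_off + 4, 4)
      tsz <- TIFF_TYPE_SIZES[type]
      val_off <- if (tsz * count <= 4) e_off + 8 else rd_int(e_off + 8, 4)
      val <- switch(as.character(type),
                    `3` = rd_int(val_off, 2, count),
                    `4` = rd_int(val_off, 4, count),
                    `1` = rd_int(val_off, 1, count),
                    NULL)
      tags[[as.character(tag)]] <- val
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    width <- g(256); height <- g(257)
    if (is.null(width) || is.null(height))
      stop("TIFF page without dimensions")
    bits <- g(258, 1L)[1]
    if (g(259, 1L) != 1) stop("compressed TIFF not supported")
    if (g(277, 1L) != 1) stop("only single-sample grayscale TIFF supported")
    fmt <- g(339, 1L)[1]
    strip_off <- g(273); strip_cnt <- g(279)
    rows_per_strip <- g(278, height)
    if (is.null(strip_off)) stop("TIFF page without strip offsets")
    if (is.null(strip_cnt))
      strip_cnt <- pmin(rows_per_strip,
                        height - (seq_along(strip_off) - 1) * rows_per_strip) *
        width * bits / 8
    npix <- width * height
    vals <- numeric(npix)
    at <- 0
    for (s in seq_along(strip_off)) {
      nb <- strip_cnt[s]
      nv <- nb * 8 / bits
      v <- if (fmt == 3) {
        if (bits != 32) stop("only 32-bit float TIFF supported")
        rd_dbl(strip_off[s], nv)
      } else {
        if (!bits %in% c(8, 16, 32)) stop("unsupported TIFF bit depth")
        if (bits == 32) rd_int(strip_off[s], 4, nv, signed = TRUE)
        else rd_int(strip_off[s], bits / 8, nv, signed = (fmt == 2))
      }
      vals[(at + 1):(at + nv)] <- v
      at <- at + nv
    }
    # TIFF data are row-major; R matrices are column-major.
    pages[[length(pages) + 1]] <-
      t(matrix(vals, nrow = width, ncol = height))
    ifd_off <- rd_int(ifd_off + 2 + n_entries * 12, 4)
  }
  pages
}

write_tiff_pages <- function(pages, path, bits, sample_format) {
  con <- file(path, "wb")
  on.exit(close(con))
  heights <- vapply(pages, nrow, integer(1))
  widths <- vapply(pages, ncol, integer(1))
  page_bytes <- heights * widths * bits / 8
  data_off <- 8 + c(0, cumsum(page_bytes))[seq_along(pages)]
  n <- length(pages)
  w_int <- function(x, size) {
    x <- as.integer(x)
    if (size == 2) x <- ifelse(x > 32767L, x - 65536L, x)
    writeBin(x, con, size = size, endian = "little")
  }
  writeChar("II", con, eos = NULL)
  w_int(42, 2)
  first_ifd <- 8 + sum(page_bytes)
  w_int(first_ifd, 4)
  for (p in pages) {
    v <- as.vector(t(p)) # row-major
    if (sample_format == 3) {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      w_int(v, bits / 8)
    }
  }
  entry <- function(tag, type, count, value) {
    w_int(tag, 2); w_int(type, 2); w_int(count, 4)
    if (type == 3) { w_int(value, 2); w_int(0, 2) } else w_int(value, 4)
  }
  ifd_size <- 2 + 10 * 12 + 4
  for (i in seq_len(n)) {
    ifd_off <- first_ifd + (i - 1) * ifd_size
    w_int(10, 2)
    entry(256, 4, 1, widths[i])
    entry(257, 4, 1, heights[i])
    entry(258, 3, 1, bits)
    entry(259, 3, 1, 1)            # no compression
    entry(262, 3, 1, 1)            # BlackIsZero
    entry(273, 4, 1, data_off[i])
    entry(277, 3, 1, 1)            # one sample per pixel
    entry(278, 4, 1, heights[i])
    entry(279, 4, 1, page_bytes[i])
    entry(339, 3, 1, sample_format)
    w_int(if (i < n) ifd_off + ifd_size else 0, 4)
  }
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' Frames are ordered by page index. Values are preserved as stored, with
#' one declared exception: integer-typed probability maps are normalised by
#' the maximum value of their integer type so that `kind = "probability"`
#' movies always hold values in \[0, 1\].
#'
#' @param path path to a grayscale multi-page TIFF.
#' @param calibration a [calibration()] object.
#' @param kind interpretation of pixel values, see [movie()].
#' @return A [movie()] object.
#' @export
read_movie <- function(path, calibration,
                       kind = c("probability", "intensity", "binary",
                                "labels")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- read_tiff_pages(path)
  if (!length(pages)) stop("TIFF contains no pages: ", path)
  shapes <- vapply(pages, dim, integer(2))
  if (any(shapes != shapes[, 1]))
    stop("TIFF pages have inconsistent shapes")
  if (kind == "probability") {
    mx <- max(vapply(pages, max, numeric(1)), 0)
    if (mx > 1 + 1e-9) {
      denom <- if (mx <= 255) 255 else if (mx <= 65535) 65535 else mx
      pages <- lapply(pages, function(p) p / denom)
      md_log("io", "normalised integer probability map by 1/%g", denom)
    }
  }
  movie(pages, calibration, kind = kind)
}

#' Write a movie as a multi-page TIFF
#'
#' Probability and intensity movies are written as 32-bit float pages;
#' binary and label movies as 16-bit unsigned integers.
#'
#' @param m a [movie()] object.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_movie <- function(m, path) {
  stopifnot(inherits(m, "morphodyn_movie"))
  kind <- attr(m, "kind")
  pages <- lapply(seq_len(n_frames(m)), function(t) get_frame(m, t))
  if (kind %in% c("binary", "labels")) {
    if (max(vapply(pages, max, numeric(1))) > 65535)
      stop("label values exceed 16-bit range")
    write_tiff_pages(pages, path, bits = 16, sample_format = 1)
  } else {
    write_tiff_pages(pages, path, bits = 32, sample_format = 3)
  }
  invisible(path)
}

#' Write a table of results as CSV
#'
#' Columns keep their order; floats are serialised at full precision.
#'
#' @param rows a data.frame (possibly with zero rows; the header is still
#'   written).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  data.table::fwrite(rows, path)
  invisible(path)
}

#' Read a CSV table written by [write_table()]
#' @param path path to a CSV file.
#' @return A `data.table`.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  data.table::fread(path)
}
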