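# Minimal baseline TIFF codec: single-channel, uncompressed, little-endian,
# 8/16-bit unsigned or 32-bit float, single- or multi-page.  No R TIFF
# bindings are assumed to be installed; this covers exactly the grayscale
# images the pipeline exchanges and nothing more.

.tiff_tag <- function(id, type, count, value) {
  list(id = id, type = type, count = count, value = value)
}

#' Write a grayscale matrix as an uncompressed TIFF
#'
#' @param m numeric matrix (rows = image rows).
#' @param path output file.
#' @param bits 8 or 16 for unsigned integer data, 32 for IEEE float.
#' @return `path`, invisibly.
#' @keywords internal
write_tiff_gray <- function(m, path, bits = 16L) {
  stopifnot(is.matrix(m), bits %in% c(8L, 16L, 32L))
  nr <- nrow(m); nc <- ncol(m)
  if (bits < 32L) {
    v <- as.integer(round(as.vector(t(m))))
    if (any(v < 0L) || any(v > 2^bits - 1))
      stop("pixel values out of range for ", bits, "-bit unsigned TIFF")
    sample_format <- 1L
  } else {
    v <- as.numeric(as.vector(t(m)))
    sample_format <- 3L
  }
  bytes_px <- bits %/% 8L
  n_tags <- 10L
  ifd_offset <- 8L
  data_offset <- ifd_offset + 2L + n_tags * 12L + 4L
  tags <- list(
    .tiff_tag(256L, 3L, 1L, nc),                 # ImageWidth
    .tiff_tag(257L, 3L, 1L, nr),                 # ImageLength
    .tiff_tag(258L, 3L, 1L, bits),               # BitsPerSample
    .tiff_tag(259L, 3L, 1L, 1L),                 # Compression: none
    .tiff_tag(262L, 3L, 1L, 1L),                 # Photometric: BlackIsZero
    .tiff_tag(273L, 4L, 1L, data_offset),        # StripOffsets
    .tiff_tag(277L, 3L, 1L, 1L),                 # SamplesPerPixel
    .tiff_tag(278L, 3L, 1L, nr),                 # RowsPerStrip
    .tiff_tag(279L, 4L, 1L, nr * nc * bytes_px), # StripByteCounts
    .tiff_tag(339L, 3L, 1L, sample_format)       # SampleFormat
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  writeBin(n_tags, con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(tg$id, con, size = 2, endian = "little")
    writeBin(tg$type, con, size = 2, endian = "little")
    writeBin(tg$count, con, size = 4, endian = "little")
    if (tg$type == 3L) {  # SHORT: left-justified in the 4-byte slot
      writeBin(as.integer(tg$value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(tg$value), con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  if (bits == 8L) {
    writeBin(v, con, size = 1, endian = "little")
  } else if (bits == 16L) {
    writeBin(v, con, size = 2, endian = "little")
  } else {
    writeBin(v, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Write a 3-D array as a multi-page grayscale TIFF
#'
#' Pages are taken along the third dimension; each page is written as an
#' uncompressed 32-bit float IFD chained to the next.
#'
#' @param a numeric 3-D array `[row, col, page]`.
#' @param path output file.
#' @keywords internal
write_tiff_stack <- function(a, path) {
  stopifnot(length(dim(a)) == 3L)
  nr <- dim(a)[1]; nc <- dim(a)[2]; np <- dim(a)[3]
  n_tags <- 10L
  ifd_size <- 2L + n_tags * 12L + 4L
  page_bytes <- nr * nc * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")   # first IFD at 8
  for (p in seq_len(np)) {
    ifd_off <- 8L + (p - 1L) * (ifd_size + page_bytes)
    data_off <- ifd_off + ifd_size
    next_off <- if (p < np) data_off + page_bytes else 0L
    tags <- list(
      .tiff_tag(256L, 3L, 1L, nc), .tiff_tag(257L, 3L, 1L, nr),
      .tiff_tag(258L, 3L, 1L, 32L), .tiff_tag(259L, 3L, 1L, 1L),
      .tiff_tag(262L, 3L, 1L, 1L), .tiff_tag(273L, 4L, 1L, data_off),
      .tiff_tag(277L, 3L, 1L, 1L), .tiff_tag(278L, 3L, 1L, nr),
      .tiff_tag(279L, 4L, 1L, page_bytes), .tiff_tag(339L, 3L, 1L, 3L))
    writeBin(n_tags, con, size = 2, endian = "little")
    for (tg in tags) {
      writeBin(tg$id, con, size = 2, endian = "little")
      writeBin(tg$type, con, size = 2, endian = "little")
      writeBin(tg$count, con, size = 4, endian = "little")
      if (tg$type == 3L) {
        writeBin(as.integer(tg$value), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(tg$value), con, size = 4, endian = "little")
      }
    }
    writeBin(next_off, con, size = 4, endian = "little")
    writeBin(as.numeric(as.vector(t(a[, , p]))), con, size = 4,
             endian = "little")
  }
  invisible(path)
}

.read_ushort <- function(raw, off, endian) {
  readBin(raw[(off + 1):(off + 2)], "integer", size = 2, signed = FALSE,
          endian = endian)
}
.read_uint <- function(raw, off, endian) {
  x <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = endian)
  if (x < 0) x <- x + 2^32
  x
}

.tiff_read_ifd <- function(raw, off, endian) {
  n <- .read_ushort(raw, off, endian)
  tags <- list()
  for (k in seq_len(n)) {
    base <- off + 2L + (k - 1L) * 12L
    id <- .read_ushort(raw, base, endian)
    type <- .read_ushort(raw, base + 2L, endian)
    count <- .read_uint(raw, base + 4L, endian)
    val <- if (type == 3L && count == 1L) {
      .read_ushort(raw, base + 8L, endian)
    } else if (type %in% c(3L, 4L) && count > 1L) {
      ptr <- .read_uint(raw, base + 8L, endian)
      sz <- if (type == 3L) 2L else 4L
      vapply(seq_len(count), function(i) {
        if (sz == 2L) .read_ushort(raw, ptr + (i - 1L) * sz, endian)
        else .read_uint(raw, ptr + (i - 1L) * sz, endian)
      }, numeric(1))
    } else {
      .read_uint(raw, base + 8L, endian)
    }
    tags[[as.character(id)]] <- val
  }
  nxt <- .read_uint(raw, off + 2L + n * 12L, endian)
  list(tags = tags, next_offset = nxt)
}

#' Read an uncompressed grayscale TIFF
#'
#' Returns a numeric matrix, or a 3-D array (pages stacked along the third
#' dimension) when the file holds multiple pages.  RGB or compressed input
#' is rejected with an explicit error.
#'
#' @param path TIFF file.
#' @keywords internal
read_tiff_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  magic <- rawToChar(raw[1:2])
  endian <- if (magic == "II") "little" else if (magic == "MM") "big" else
    stop("not a TIFF file: ", path)
  off <- .read_uint(raw, 4L, endian)
  pages <- list()
  while (off != 0) {
    ifd <- .tiff_read_ifd(raw, off, endian)
    tg <- ifd$tags
    width <- tg[["256"]]; height <- tg[["257"]]
    bits <- if (is.null(tg[["258"]])) 1L else tg[["258"]][1]
    comp <- if (is.null(tg[["259"]])) 1L else tg[["259"]]
    photo <- if (is.null(tg[["262"]])) 1L else tg[["262"]]
    spp <- if (is.null(tg[["277"]])) 1L else tg[["277"]]
    fmt <- if (is.null(tg[["339"]])) 1L else tg[["339"]][1]
    if (spp != 1L || photo >= 2L)
      stop("multi-channel/RGB TIFF not supported; extract a single channel ",
           "before loading: ", path)
    if (comp != 1L)
      stop("compressed TIFF not supported: ", path)
    offsets <- tg[["273"]]; counts <- tg[["279"]]
    buf <- raw[unlist(lapply(seq_along(offsets), function(i) {
      (offsets[i] + 1):(offsets[i] + counts[i])
    }))]
    n_px <- width * height
    v <- if (fmt == 3L) {
      readBin(buf, "numeric", n = n_px, size = bits %/% 8L, endian = endian)
    } else if (bits == 8L) {
      as.numeric(readBin(buf, "integer", n = n_px, size = 1, signed = FALSE,
                         endian = endian))
    } else if (bits == 16L) {
      as.numeric(readBin(buf, "integer", n = n_px, size = 2, signed = FALSE,
                         endian = endian))
    } else if (bits == 32L) {
      as.numeric(readBin(buf, "integer", n = n_px, size = 4, endian = endian))
    } else stop("unsupported bit depth: ", bits)
    pages[[length(pages) + 1L]] <- matrix(v, nrow = height, ncol = width,
                                          byrow = TRUE)
    off <- ifd$next_offset
  }
  if (length(pages) == 1L) pages[[1L]]
  else array(unlist(pages), dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                                    length(pages)))
}
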