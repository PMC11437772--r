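#' Speckle video frame stack
#'
#' Container for a timed sequence of 2-D grayscale speckle images, the raw
#' unit of laser speckle imaging measurement. Frames are stored as a 3-D
#' integer-valued array indexed `(time, row, col)`.
#'
#' @param frames 3-D numeric array, dimensions `(n_frames, height, width)`,
#'   integer-valued grayscale intensities in `[0, 2^bit_depth - 1]`.
#' @param fps Frame rate in Hz (> 0). Nominal acquisition is 30 fps.
#' @param bit_depth Camera bit depth (bits per pixel); 8 or 16 supported by
#'   the TIFF writer, any positive integer accepted by the container.
#' @param source_id Free-text provenance label.
#'
#' @return An object of class `frame_stack`: a list with elements `frames`,
#'   `fps`, `bit_depth`, `source_id`.
#' @examples
#' st <- frame_stack(array(rep(1:4, 2), c(2, 2, 2)), fps = 30)
#' n_frames(st)
#' @export
frame_stack <- function(frames, fps, bit_depth = 8L, source_id = "") {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array (time, row, col)")
  storage.mode(frames) <- "double"
  x <- structure(
    list(frames = frames, fps = as.numeric(fps),
         bit_depth = as.integer(bit_depth), source_id = as.character(source_id)),
    class = "frame_stack")
  validate_frame_stack(x)
  x
}

#' Validate a frame stack's invariants
#'
#' Checks frame count, intensity range against bit depth, and frame rate.
#' Called by the constructor; exported so readers can re-validate.
#'
#' @param x A `frame_stack`.
#' @return `x`, invisibly. Errors on violation.
#' @export
validate_frame_stack <- function(x) {
  stopifnot(inherits(x, "frame_stack"))
  d <- dim(x$frames)
  if (d[1L] < 2L) stop("frame stack needs at least 2 frames")
  if (!is.finite(x$fps) || x$fps <= 0) stop("fps must be > 0")
  if (x$bit_depth < 1L) stop("bit_depth must be a positive integer")
  rng <- range(x$frames)
  if (rng[1L] < 0 || rng[2L] > 2^x$bit_depth - 1)
    stop(sprintf("intensities outside [0, %d] for bit_depth %d",
                 2^x$bit_depth - 1L, x$bit_depth))
  invisible(x)
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %dx%d px, %g fps, %d-bit%s\n",
              d[1L], d[2L], d[3L], x$fps, x$bit_depth,
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A `frame_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[1L]

# Flatten to an (n_frames x n_pixels) matrix; pixel order is column-major
# within each frame, fixed so all estimators and oracles agree.
stack_matrix <- function(stack) {
  d <- dim(stack$frames)
  matrix(stack$frames, nrow = d[1L], ncol = d[2L] * d[3L])
}

# ---- raw binary + JSON sidecar -------------------------------------------

#' Write a frame stack as raw binary plus JSON sidecar header
#'
#' The binary file holds little-endian unsigned 8- or 16-bit pixels in
#' frame-major, column-major-within-frame order; `<path>.json` records
#' `{shape, dtype, fps, bit_depth, source_id}`.
#'
#' @param stack A `frame_stack`.
#' @param path Output path for the binary payload (sidecar is `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_stack_raw <- function(stack, path) {
  validate_frame_stack(stack)
  d <- dim(stack$frames)
  bytes <- if (stack$bit_depth > 8L) 2L else 1L
  v <- as.integer(round(as.vector(stack$frames)))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(int_to_le_raw(v, bytes), con)
  header <- list(shape = d, dtype = if (bytes == 2L) "uint16" else "uint8",
                 fps = stack$fps, bit_depth = stack$bit_depth,
                 source_id = stack$source_id)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a frame stack from raw binary plus JSON sidecar
#'
#' @param path Path to the binary payload written by [write_stack_raw()].
#' @return A `frame_stack`.
#' @export
read_stack_raw <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(header$shape)
  bytes <- if (identical(header$dtype, "uint16")) 2L else 1L
  n <- prod(d)
  con <- file(path, "rb"); on.exit(close(con))
  v <- readBin(con, "integer", n = n, size = bytes, signed = FALSE,
               endian = "little")
  if (length(v) != n) stop("raw stack truncated: expected ", n, " pixels")
  frame_stack(array(as.double(v), d), fps = header$fps,
              bit_depth = as.integer(header$bit_depth),
              source_id = header$source_id %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# integers -> little-endian raw, 1 or 2 bytes per value (unsigned)
int_to_le_raw <- function(v, bytes) {
  if (bytes == 1L) return(as.raw(v))
  lo <- as.raw(v %% 256L); hi <- as.raw(v %/% 256L)
  out <- raw(2L * length(v))
  out[seq(1L, by = 2L, length.out = length(v))] <- lo
  out[seq(2L, by = 2L, length.out = length(v))] <- hi
  out
}

# ---- minimal baseline TIFF (uncompressed grayscale, multi-page) ----------
#
# No TIFF package ships with the supported toolchain, so a minimal baseline
# codec lives here: little-endian, one strip per page, Compression=1,
# Photometric=BlackIsZero, 8- or 16-bit. Acquisition metadata (fps,
# bit_depth, source_id) rides in the first page's ImageDescription as JSON.

tiff_tag_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L)

le <- function(x, bytes) {
  # unsigned integer -> little-endian raw of fixed width
  out <- raw(bytes)
  for (i in seq_len(bytes)) { out[i] <- as.raw(x %% 256); x <- x %/% 256 }
  out
}

tiff_entry <- function(tag, type, count, value_raw) {
  pad <- raw(4L - length(value_raw))
  c(le(tag, 2L), le(type, 2L), le(count, 4L), value_raw, pad)
}

#' Write a frame stack as a multi-page grayscale TIFF
#'
#' Baseline TIFF: little-endian, uncompressed, one strip per page,
#' photometric BlackIsZero; 8-bit or 16-bit per sample depending on the
#' stack's `bit_depth`. The first page's ImageDescription tag carries a JSON
#' record of `fps`, `bit_depth` and `source_id` so [read_stack_tiff()] can
#' restore the full object.
#'
#' @param stack A `frame_stack`.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  validate_frame_stack(stack)
  d <- dim(stack$frames); nf <- d[1L]; h <- d[2L]; w <- d[3L]
  bytes <- if (stack$bit_depth > 8L) 2L else 1L
  desc <- jsonlite::toJSON(list(fps = stack$fps, bit_depth = stack$bit_depth,
                                source_id = stack$source_id),
                           auto_unbox = TRUE)
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0L))

  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(charToRaw("II"), le(42L, 2L), le(0L, 4L)), con)  # patched below
  pos <- 8L

  strip_off <- integer(nf); strip_len <- h * w * bytes
  for (t in seq_len(nf)) {
    strip_off[t] <- pos
    # TIFF pages are row-major; transpose each frame
    fr <- as.integer(round(t(stack$frames[t, , ])))
    writeBin(int_to_le_raw(fr, bytes), con)
    pos <- pos + strip_len
  }
  desc_off <- 0L
  if (length(desc_raw) > 4L) {        # inline only if it fits the value slot
    desc_off <- pos
    writeBin(desc_raw, con)
    pos <- pos + length(desc_raw)
    if (pos %% 2L == 1L) { writeBin(raw(1L), con); pos <- pos + 1L }
  }

  ifd_off <- integer(nf)
  for (t in seq_len(nf)) {
    entries <- list(
      tiff_entry(256L, 3L, 1L, le(w, 2L)),             # ImageWidth
      tiff_entry(257L, 3L, 1L, le(h, 2L)),             # ImageLength
      tiff_entry(258L, 3L, 1L, le(8L * bytes, 2L)),    # BitsPerSample
      tiff_entry(259L, 3L, 1L, le(1L, 2L)),            # Compression: none
      tiff_entry(262L, 3L, 1L, le(1L, 2L)))            # BlackIsZero
    if (t == 1L)
      entries <- c(entries, list(
        tiff_entry(270L, 2L, length(desc_raw),
                   if (length(desc_raw) > 4L) le(desc_off, 4L) else desc_raw)))
    entries <- c(entries, list(
      tiff_entry(273L, 4L, 1L, le(strip_off[t], 4L)),  # StripOffsets
      tiff_entry(277L, 3L, 1L, le(1L, 2L)),            # SamplesPerPixel
      tiff_entry(278L, 3L, 1L, le(h, 2L)),             # RowsPerStrip
      tiff_entry(279L, 4L, 1L, le(strip_len, 4L))))    # StripByteCounts
    entries <- entries[order(vapply(entries, function(e)
      as.integer(e[1L]) + 256L * as.integer(e[2L]), 1L))]
    ifd_off[t] <- pos
    next_off <- 0L  # patched for all but last
    ifd <- c(le(length(entries), 2L), do.call(c, entries), le(next_off, 4L))
    writeBin(ifd, con)
    pos <- pos + length(ifd)
  }
  # patch IFD chain: header -> ifd1 -> ifd2 -> ... -> 0
  seek(con, 4L, rw = "write"); writeBin(le(ifd_off[1L], 4L), con)
  if (nf > 1L) {
    n_entries <- c(10L, rep(9L, nf - 1L))  # page 1 has ImageDescription
    for (t in seq_len(nf - 1L)) {
      link_pos <- ifd_off[t] + 2L + 12L * n_entries[t]
      seek(con, link_pos, rw = "write")
      writeBin(le(ifd_off[t + 1L], 4L), con)
    }
  }
  invisible(path)
}

read_le <- function(raw, off, bytes) {
  # off is 0-based file offset
  sum(as.integer(raw[off + seq_len(bytes)]) * 256^(0:(bytes - 1L)))
}

#' Read a multi-page grayscale TIFF as a frame stack
#'
#' Supports the baseline subset written by [write_stack_tiff()]:
#' little-endian or big-endian byte order, uncompressed, single-sample
#' grayscale, 8- or 16-bit, any strip layout. Frame-rate metadata is taken
#' from the JSON ImageDescription if present, else from `fps`.
#'
#' @param path `.tif` path.
#' @param fps Fallback frame rate when the file carries no metadata.
#' @return A `frame_stack`.
#' @export
read_stack_tiff <- function(path, fps = NULL) {
  raw <- readBin(path, "raw", n = file.size(path))
  big <- FALSE
  if (identical(rawToChar(raw[1:2]), "MM")) big <- TRUE
  else if (!identical(rawToChar(raw[1:2]), "II")) stop("not a TIFF file: ", path)
  rd <- function(off, bytes) {
    v <- as.integer(raw[off + seq_len(bytes)])
    if (big) sum(v * 256^((bytes - 1L):0)) else sum(v * 256^(0:(bytes - 1L)))
  }
  if (rd(2L, 2L) != 42L) stop("bad TIFF magic in ", path)

  pages <- list(); desc <- NULL
  ifd <- rd(4L, 4L)
  # sizes of TIFF types 1..12 (BYTE..DOUBLE); only integer/ASCII consumed
  type_size <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)
  needed <- c(256L, 257L, 258L, 259L, 262L, 270L, 273L, 278L, 279L)
  while (ifd != 0L) {
    n <- rd(ifd, 2L)
    tags <- list()
    for (i in seq_len(n) - 1L) {
      e <- ifd + 2L + 12L * i
      tag <- rd(e, 2L); type <- rd(e + 2L, 2L); count <- rd(e + 4L, 4L)
      if (!tag %in% needed || type > 4L) next
      sz <- type_size[type]
      nbytes <- sz * count
      voff <- if (nbytes > 4L) rd(e + 8L, 4L) else e + 8L
      vals <- if (type == 2L) {
        rawToChar(raw[voff + seq_len(max(count - 1L, 0L))])
      } else {
        vapply(seq_len(count) - 1L, function(k) rd(voff + k * sz, sz), 1)
      }
      tags[[as.character(tag)]] <- vals
    }
    pages[[length(pages) + 1L]] <- tags
    if (!is.null(tags[["270"]]) && is.null(desc)) desc <- tags[["270"]]
    ifd <- rd(ifd + 2L + 12L * n, 4L)
  }
  if (!length(pages)) stop("TIFF has no pages: ", path)

  p1 <- pages[[1L]]
  w <- p1[["256"]]; h <- p1[["257"]]
  bits <- (p1[["258"]] %||% 8)[1L]
  if (!bits %in% c(8, 16)) stop("unsupported BitsPerSample: ", bits)
  if (!is.null(p1[["259"]]) && p1[["259"]] != 1)
    stop("compressed TIFF not supported")
  bytes <- bits / 8L

  frames <- array(0, c(length(pages), h, w))
  for (t in seq_along(pages)) {
    pg <- pages[[t]]
    offs <- pg[["273"]]; lens <- pg[["279"]]
    px <- unlist(lapply(seq_along(offs), function(s) {
      nv <- lens[s] / bytes
      vapply(seq_len(nv) - 1L, function(k) rd(offs[s] + k * bytes, bytes), 1)
    }))
    frames[t, , ] <- matrix(px, h, w, byrow = TRUE)
  }
  meta <- NULL
  if (!is.null(desc))
    meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
  fps_use <- meta$fps %||% fps
  if (is.null(fps_use))
    stop("TIFF carries no fps metadata; pass `fps` explicitly")
  frame_stack(frames, fps = fps_use,
              bit_depth = as.integer(meta$bit_depth %||% bits),
              source_id = meta$source_id %||% basename(path))
}
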