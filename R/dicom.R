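# Minimal DICOM support for uncompressed 8-bit secondary-capture ultrasound
# images: explicit/implicit VR little endian, RGB / YBR_FULL / MONOCHROME2,
# both planar configurations. Compressed transfer syntaxes, sequences with
# undefined length and multi-frame clips are out of scope.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_SC_STORAGE  <- "1.2.840.10008.5.1.4.1.1.7"

u16le <- function(raw, at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
u32le <- function(raw, at) {
  as.numeric(raw[at]) + 256 * as.numeric(raw[at + 1L]) +
    65536 * as.numeric(raw[at + 2L]) + 16777216 * as.numeric(raw[at + 3L])
}

# VRs whose explicit-VR header carries a 4-byte length after 2 reserved bytes
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# DICOM strings are padded to even length with NUL (UI) or space
raw_string <- function(body) trimws(rawToChar(body[body != as.raw(0L)]))

#' Read a DICOM secondary-capture image
#'
#' Supports uncompressed 8-bit images in explicit or implicit VR little
#' endian, with photometric interpretation `RGB`, `YBR_FULL` (converted to
#' RGB) or `MONOCHROME2` (replicated across channels). Pixel spacing
#' (0028,0030) is propagated when present.
#'
#' @param path DICOM file.
#' @return a [rgb_image()] with `metadata$photometric`, `metadata$source`.
#' @export
read_dicom_image <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 132L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file (missing DICM magic): ", path)

  wanted <- c("0002,0010", "0028,0002", "0028,0004", "0028,0006",
              "0028,0010", "0028,0011", "0028,0030", "0028,0100",
              "7fe0,0010")
  vals <- list()
  pos <- 133L
  explicit <- TRUE  # file meta group is always explicit VR LE
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- u16le(raw, pos); elem <- u16le(raw, pos + 2L)
    if (group > 2L && is.null(vals[["parsed_meta"]])) {
      # end of the meta group: switch to the declared transfer syntax
      ts <- vals[["0002,0010"]]
      if (is.null(ts)) stop("DICOM file has no transfer syntax UID")
      if (ts == UID_EXPLICIT_LE) explicit <- TRUE
      else if (ts == UID_IMPLICIT_LE) explicit <- FALSE
      else stop("unsupported DICOM transfer syntax: ", ts)
      vals[["parsed_meta"]] <- TRUE
    }
    if (explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% LONG_VRS) {
        len <- u32le(raw, pos + 8L); hdr <- 12L
      } else {
        len <- u16le(raw, pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- u32le(raw, pos + 4L); hdr <- 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements are not supported")
    tag <- sprintf("%04x,%04x", group, elem)
    if (tag %in% wanted) {
      body <- if (len > 0) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
      vals[[tag]] <- body
      if (tag == "0002,0010")
        vals[[tag]] <- raw_string(body)
    }
    pos <- pos + hdr + len
    if (tag == "7fe0,0010") break
  }

  str_of <- function(tag) raw_string(vals[[tag]])
  int_of <- function(tag, default = NULL) {
    if (is.null(vals[[tag]])) return(default)
    u16le(vals[[tag]], 1L)
  }
  rows <- int_of("0028,0010"); cols <- int_of("0028,0011")
  if (is.null(rows) || is.null(cols) || is.null(vals[["7fe0,0010"]]))
    stop("DICOM file lacks image dimensions or pixel data")
  if (!identical(int_of("0028,0100", 8L), 8L))
    stop("only 8-bit DICOM images are supported")
  samples <- int_of("0028,0002", 1L)
  planar <- int_of("0028,0006", 0L)
  photometric <- if (is.null(vals[["0028,0004"]])) {
    if (samples == 3L) "RGB" else "MONOCHROME2"
  } else str_of("0028,0004")
  spacing <- NULL
  if (!is.null(vals[["0028,0030"]])) {
    spacing <- as.numeric(strsplit(str_of("0028,0030"), "\\\\")[[1]])
    if (any(!is.finite(spacing)) || any(spacing <= 0)) spacing <- NULL
  }

  v <- as.integer(vals[["7fe0,0010"]])
  npx <- rows * cols
  if (length(v) < npx * samples)
    stop("DICOM pixel data shorter than Rows*Columns*SamplesPerPixel")
  v <- v[seq_len(npx * samples)]  # drop trailing pad byte
  px <- if (samples == 1L) {
    array(rep(matrix(v, rows, cols, byrow = TRUE), 3L), c(rows, cols, 3L))
  } else {
    chan <- if (planar == 0L)
      lapply(1:3, function(c) v[seq(c, by = 3L, length.out = npx)])
    else
      lapply(1:3, function(c) v[((c - 1L) * npx + 1L):(c * npx)])
    array(unlist(lapply(chan, function(x) matrix(x, rows, cols, byrow = TRUE))),
          c(rows, cols, 3L))
  }
  if (photometric == "YBR_FULL") px <- ybr_full_to_rgb(px)
  else if (!photometric %in% c("RGB", "MONOCHROME2"))
    stop("unsupported photometric interpretation: ", photometric)
  rgb_image(px, pixel_spacing = spacing,
            metadata = list(source = path, photometric = photometric))
}

# full-range YCbCr -> RGB (the JPEG convention DICOM YBR_FULL uses)
ybr_full_to_rgb <- function(px) {
  y <- px[, , 1]; cb <- px[, , 2] - 128; cr <- px[, , 3] - 128
  out <- array(0, dim(px))
  out[, , 1] <- y + 1.402 * cr
  out[, , 2] <- y - 0.344136 * cb - 0.714136 * cr
  out[, , 3] <- y + 1.772 * cb
  pmin(pmax(round(out), 0), 255)
}

#' Write an image as a DICOM secondary capture
#'
#' Writes an explicit-VR little-endian part-10 file. An [rgb_image()] is
#' stored as interleaved `RGB`; a [flow_image()] as `MONOCHROME2`. Instance
#' UIDs are derived deterministically from the pixel content so identical
#' inputs produce identical files.
#'
#' @param image a [rgb_image()] or [flow_image()].
#' @param path output file.
#' @export
write_dicom <- function(image, path) {
  if (inherits(image, "microv_flow")) {
    px <- image$pixels
    data <- as.raw(as.integer(t(px)))
    samples <- 1L; photometric <- "MONOCHROME2"
    rows <- nrow(px); cols <- ncol(px)
  } else if (inherits(image, "microv_rgb")) {
    px <- image$pixels
    rows <- dim(px)[1]; cols <- dim(px)[2]
    inter <- integer(rows * cols * 3L)
    for (ch in 1:3) inter[seq(ch, by = 3L, length.out = rows * cols)] <-
      as.integer(t(px[, , ch]))
    data <- as.raw(inter)
    samples <- 3L; photometric <- "RGB"
  } else stop("'image' must be a microv_rgb or microv_flow")

  uid <- sprintf("1.2.826.0.1.3680043.9.7432.%d.%d.%.0f",
                 rows, cols, sum(as.numeric(data)) %% 1e8)

  enc_str <- function(group, el, vr, s, nul_pad = FALSE) {
    b <- charToRaw(s)
    if (length(b) %% 2L == 1L)
      b <- c(b, if (nul_pad) as.raw(0) else charToRaw(" "))
    list(group, el, vr, b)
  }
  enc_us <- function(group, el, x)
    list(group, el, "US", writeBin(as.integer(x), raw(), size = 2, endian = "little"))
  enc_raw <- function(group, el, vr, b) {
    if (length(b) %% 2L == 1L) b <- c(b, as.raw(0))
    list(group, el, vr, b)
  }

  meta <- list(
    enc_raw(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    enc_str(0x0002, 0x0002, "UI", UID_SC_STORAGE, nul_pad = TRUE),
    enc_str(0x0002, 0x0003, "UI", uid, nul_pad = TRUE),
    enc_str(0x0002, 0x0010, "UI", UID_EXPLICIT_LE, nul_pad = TRUE),
    enc_str(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9.7432.1", nul_pad = TRUE))
  body <- list(
    enc_str(0x0008, 0x0016, "UI", UID_SC_STORAGE, nul_pad = TRUE),
    enc_str(0x0008, 0x0018, "UI", uid, nul_pad = TRUE),
    enc_str(0x0008, 0x0060, "CS", "US"),
    enc_us(0x0028, 0x0002, samples),
    enc_str(0x0028, 0x0004, "CS", photometric))
  if (samples == 3L) body <- c(body, list(enc_us(0x0028, 0x0006, 0L)))
  body <- c(body, list(
    enc_us(0x0028, 0x0010, rows),
    enc_us(0x0028, 0x0011, cols)))
  if (!is.null(image$pixel_spacing)) {
    sp <- rep(image$pixel_spacing, length.out = 2L)
    body <- c(body, list(enc_str(0x0028, 0x0030, "DS",
                                 sprintf("%g\\%g", sp[1], sp[2]))))
  }
  body <- c(body, list(
    enc_us(0x0028, 0x0100, 8L),
    enc_us(0x0028, 0x0101, 8L),
    enc_us(0x0028, 0x0102, 7L),
    enc_us(0x0028, 0x0103, 0L),
    enc_raw(0x7FE0, 0x0010, "OB", data)))

  elem_bytes <- function(e) {
    tag <- writeBin(as.integer(c(e[[1]], e[[2]])), raw(), size = 2,
                    endian = "little")
    vr <- e[[3]]; val <- e[[4]]
    if (vr %in% LONG_VRS) {
      c(tag, charToRaw(vr), as.raw(c(0, 0)),
        writeBin(length(val), raw(), size = 4, endian = "little"), val)
    } else {
      c(tag, charToRaw(vr),
        writeBin(length(val), raw(), size = 2, endian = "little"), val)
    }
  }
  meta_bytes <- do.call(c, lapply(meta, elem_bytes))
  group_len <- elem_bytes(enc_raw(0x0002, 0x0000, "UL",
    writeBin(length(meta_bytes), raw(), size = 4, endian = "little")))
  out <- c(raw(128L), charToRaw("DICM"), group_len, meta_bytes,
           do.call(c, lapply(body, elem_bytes)))
  writeBin(out, path)
  invisible(path)
}
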