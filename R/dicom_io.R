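# Slice I/O: DICOM reading (minimal, uncompressed little-endian), a
# plain-text HU grid format for fixtures, and lossless PNG output.

#' Read a single-frame CT DICOM slice
#'
#' Minimal DICOM reader for uncompressed single-frame CT objects
#' (implicit or explicit VR little endian). Pixel values are converted to
#' Hounsfield units via the mandatory rescale tags:
#' \code{HU = stored * RescaleSlope + RescaleIntercept}. Photometric
#' interpretation (MONOCHROME1/2) does not affect HU and both are
#' accepted. Non-CT modalities, multi-frame objects, compressed transfer
#' syntaxes and missing rescale tags are rejected with informative
#' errors.
#'
#' @param path Path to a DICOM file.
#' @return An object of class \code{"slice_record"}: list with \code{hu}
#'   (HU matrix), \code{source_id}, \code{rescale_slope},
#'   \code{rescale_intercept}.
#' @seealso \code{\link{write_synthetic_dicom}} for generating test
#'   fixtures.
#' @export
read_dicom_slice <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 132L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path, call. = FALSE)
  el <- parse_dicom_elements(raw)
  ts <- el$string("0002,0010")
  if (is.null(ts)) ts <- "1.2.840.10008.1.2.1"
  if (!ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
    stop("unsupported (compressed?) transfer syntax: ", ts, call. = FALSE)

  modality <- el$string("0008,0060")
  if (is.null(modality) || modality != "CT")
    stop("not a CT object (Modality = ", modality %||% "absent", ")",
         call. = FALSE)
  nframes <- el$string("0028,0008")
  if (!is.null(nframes) && as.integer(nframes) > 1L)
    stop("multi-frame objects are unsupported", call. = FALSE)

  rows <- el$uint16("0028,0010")
  cols <- el$uint16("0028,0011")
  if (is.null(rows) || is.null(cols))
    stop("missing (0028,0010) Rows / (0028,0011) Columns", call. = FALSE)
  slope <- el$string("0028,1053")
  intercept <- el$string("0028,1052")
  if (is.null(slope))
    stop("missing tag (0028,1053) RescaleSlope", call. = FALSE)
  if (is.null(intercept))
    stop("missing tag (0028,1052) RescaleIntercept", call. = FALSE)
  slope <- as.numeric(slope); intercept <- as.numeric(intercept)

  bits <- el$uint16("0028,0100") %||% 16L
  signed <- (el$uint16("0028,0103") %||% 0L) == 1L
  px <- el$bytes("7FE0,0010")
  if (is.null(px)) stop("missing (7FE0,0010) PixelData", call. = FALSE)
  n <- as.integer(rows) * as.integer(cols)
  stored <- if (bits == 16L) {
    readBin(px, "integer", n = n, size = 2L, signed = signed,
            endian = "little")
  } else if (bits == 8L) {
    readBin(px, "integer", n = n, size = 1L, signed = signed)
  } else stop("unsupported BitsAllocated: ", bits, call. = FALSE)
  if (length(stored) < n)
    stop("PixelData shorter than Rows * Columns", call. = FALSE)
  # DICOM pixel order is row-major
  hu <- hu_image(matrix(stored * slope + intercept,
                        nrow = rows, ncol = cols, byrow = TRUE))
  structure(list(hu = hu,
                 source_id = el$string("0008,0018") %||% basename(path),
                 rescale_slope = slope,
                 rescale_intercept = intercept),
            class = "slice_record")
}

# DICOM strings may be NUL- or space-padded
raw_to_string <- function(v) trimws(rawToChar(v[v != as.raw(0L)]))

# element walker over the byte stream; returns accessors keyed by
# "GGGG,EEEE" (upper-case hex). File meta (group 0002) is always explicit
# VR; the dataset follows the transfer syntax.
parse_dicom_elements <- function(raw) {
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  store <- new.env(parent = emptyenv())
  pos <- 133L
  explicit_dataset <- TRUE
  meta_end <- .Machine$integer.max
  repeat {
    if (pos + 7L > length(raw)) break
    grp <- u16(pos); ele <- u16(pos + 2L)
    in_meta <- grp == 2L
    explicit <- in_meta || explicit_dataset
    if (explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_; len <- u32(pos + 4L); hdr <- 8L
    }
    if (len == 4294967295)
      stop("undefined-length element unsupported (tag ",
           sprintf("%04X,%04X", grp, ele), ")", call. = FALSE)
    key <- sprintf("%04X,%04X", grp, ele)
    if (len > 0L && pos + hdr + len - 1L <= length(raw))
      assign(key, raw[(pos + hdr):(pos + hdr + len - 1L)], envir = store)
    else if (len == 0L)
      assign(key, raw(0), envir = store)
    if (in_meta && key == "0002,0000")
      meta_end <- pos + hdr + len +
        u32(pos + hdr) # group length counts bytes after this element
    pos <- pos + hdr + len
    if (grp == 2L && pos >= meta_end) {
      # switch the dataset VR mode once the meta group ends
      ts_raw <- get0("0002,0010", envir = store)
      ts <- if (is.null(ts_raw)) "" else raw_to_string(ts_raw)
      explicit_dataset <- !identical(ts, "1.2.840.10008.1.2")
    }
  }
  list(
    string = function(key) {
      v <- get0(key, envir = store)
      if (is.null(v)) NULL else raw_to_string(v)
    },
    uint16 = function(key) {
      v <- get0(key, envir = store)
      if (is.null(v) || length(v) < 2L) NULL
      else as.integer(v[1L]) + 256L * as.integer(v[2L])
    },
    bytes = function(key) get0(key, envir = store)
  )
}

#' Write a synthetic single-frame CT DICOM file
#'
#' Emits a minimal, valid explicit-VR little-endian DICOM object carrying
#' the given stored pixel values and rescale parameters. This exists so
#' that DICOM-reading code can be exercised against fixtures generated in
#' code; the files are synthetic and carry no patient data.
#'
#' @param path Output path.
#' @param stored Integer matrix of stored pixel values (16-bit range).
#' @param slope,intercept Rescale slope and intercept written to the
#'   (0028,1053) / (0028,1052) tags. Either may be \code{NULL} to omit
#'   the tag (for negative testing).
#' @param modality Modality string, default \code{"CT"}.
#' @param photometric \code{"MONOCHROME2"} (default) or
#'   \code{"MONOCHROME1"}.
#' @param signed Write signed (\code{1}) or unsigned (\code{0}) pixel
#'   representation.
#' @param n_frames If not \code{NULL}, writes a NumberOfFrames tag.
#' @return \code{path}, invisibly.
#' @export
write_synthetic_dicom <- function(path, stored, slope = 1,
                                  intercept = -1024, modality = "CT",
                                  photometric = "MONOCHROME2",
                                  signed = TRUE, n_frames = NULL) {
  stopifnot(is.matrix(stored))
  pad_even <- function(s) if (nchar(s) %% 2 == 1) paste0(s, " ") else s
  el_str <- function(grp, ele, vr, value) {
    value <- pad_even(value)
    c(writeBin(c(grp, ele), raw(), size = 2, endian = "little"),
      charToRaw(vr),
      writeBin(nchar(value), raw(), size = 2, endian = "little"),
      charToRaw(value))
  }
  el_us <- function(grp, ele, value) {
    c(writeBin(c(grp, ele), raw(), size = 2, endian = "little"),
      charToRaw("US"),
      writeBin(2L, raw(), size = 2, endian = "little"),
      writeBin(as.integer(value), raw(), size = 2, endian = "little"))
  }
  el_ow <- function(grp, ele, bytes) {
    c(writeBin(c(grp, ele), raw(), size = 2, endian = "little"),
      charToRaw("OW"), as.raw(c(0, 0)),
      writeBin(length(bytes), raw(), size = 4, endian = "little"),
      bytes)
  }
  ts <- "1.2.840.10008.1.2.1"
  sop_class <- "1.2.840.10008.5.1.4.1.1.2"      # CT Image Storage
  sop_inst <- "1.2.826.0.1.3680043.9999.1"
  meta_body <- c(
    el_str(2L, 2L, "UI", sop_class),
    el_str(2L, 3L, "UI", sop_inst),
    el_str(2L, 16L, "UI", ts))
  meta <- c(
    c(writeBin(c(2L, 0L), raw(), size = 2, endian = "little"),
      charToRaw("UL"),
      writeBin(4L, raw(), size = 2, endian = "little"),
      writeBin(length(meta_body), raw(), size = 4, endian = "little")),
    meta_body)

  # pixel data in DICOM row-major order
  vals <- as.integer(t(stored))
  px <- writeBin(vals, raw(), size = 2, endian = "little")

  ds <- c(el_str(8L, 24L, "UI", sop_inst),       # SOPInstanceUID
          el_str(8L, 96L, "CS", modality))
  if (!is.null(n_frames))
    ds <- c(ds, el_str(40L, 8L, "IS", as.character(n_frames)))
  ds <- c(ds,
          el_str(40L, 4L, "CS", photometric),
          el_us(40L, 16L, nrow(stored)),          # Rows
          el_us(40L, 17L, ncol(stored)),          # Columns
          el_us(40L, 256L, 16L),                  # BitsAllocated
          el_us(40L, 257L, 16L),                  # BitsStored
          el_us(40L, 259L, if (signed) 1L else 0L))
  if (!is.null(intercept))
    ds <- c(ds, el_str(40L, 4178L, "DS", format(intercept)))
  if (!is.null(slope))
    ds <- c(ds, el_str(40L, 4179L, "DS", format(slope)))
  ds <- c(ds, el_ow(32736L, 16L, px))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, ds), con)
  invisible(path)
}

#' Read a plain-text HU grid
#'
#' Parses a whitespace-delimited rectangular numeric grid into an HU
#' matrix. Ragged rows and non-numeric tokens are rejected with the
#' offending row/column in the message.
#'
#' @param path Path to the text file.
#' @return HU matrix (validated with \code{\link{hu_image}}).
#' @export
read_hu_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty HU grid: ", path, call. = FALSE)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  width <- length(toks[[1L]])
  rows <- lapply(seq_along(toks), function(i) {
    tk <- toks[[i]]
    if (length(tk) != width)
      stop(sprintf("ragged HU grid: row %d has %d values, expected %d",
                   i, length(tk), width), call. = FALSE)
    v <- suppressWarnings(as.numeric(tk))
    if (anyNA(v))
      stop(sprintf("non-numeric token at row %d, col %d: '%s'",
                   i, which(is.na(v))[1L], tk[which(is.na(v))[1L]]),
           call. = FALSE)
    v
  })
  hu_image(do.call(rbind, rows))
}

#' Write a plain-text HU grid
#'
#' @param hu HU matrix.
#' @param path Output path.
#' @return \code{path}, invisibly. Round-trips exactly through
#'   \code{\link{read_hu_grid}}.
#' @export
write_hu_grid <- function(hu, path) {
  stopifnot(is.matrix(hu))
  lines <- apply(hu, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Write an 8-bit image as lossless PNG
#'
#' Grayscale matrices are saved single-channel; \code{(rows, cols, 3)}
#' arrays as RGB. Values must already be integers in \eqn{[0, 255]};
#' the round trip through \code{png::readPNG} is exact.
#'
#' @param img Matrix (gray) or 3-channel array (RGB) of values in
#'   \eqn{[0, 255]}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_png <- function(img, path) {
  if (any(img < 0 | img > 255))
    stop("image values must lie in [0, 255]", call. = FALSE)
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' Read an 8-bit PNG back to integer values
#'
#' @param path PNG path.
#' @return Matrix or 3-channel array of integers in \eqn{[0, 255]}.
#' @export
read_png <- function(path) {
  x <- png::readPNG(path)
  v <- round(x * 255)
  storage.mode(v) <- "integer"
  v
}
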