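# Minimal DICOM support for classic uncompressed single-frame CT images.
#
# No DICOM package is available in this environment, so the package carries a
# small reader/writer pair covering exactly what the pipeline needs: little
# endian transfer syntaxes (explicit 1.2.840.10008.1.2.1 and implicit
# 1.2.840.10008.1.2), single-frame 16-bit grayscale pixel data, and the
# geometry/dose attributes the ROI extractor consumes. The writer always emits
# explicit VR little endian. It is not a general DICOM implementation.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_CT_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"
UID_ROOT <- "2.25"   # UUID-derived UID root

# VRs using the 4-byte length form in explicit VR
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_uid <- function() {
  # derive a numeric UID from random digits under the UUID root
  paste0(UID_ROOT, ".", paste(sample(0:9, 30, replace = TRUE), collapse = ""))
}

int16_to_raw <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
uint_to_raw <- function(x, size) writeBin(as.integer(x), raw(), size = size, endian = "little")

pad_even <- function(bytes, pad = as.raw(0L)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

dcm_element <- function(group, element, vr, value_bytes) {
  pad <- if (vr %in% c("UI", "OB", "OW", "UN")) as.raw(0L) else charToRaw(" ")
  value_bytes <- pad_even(value_bytes, pad)
  hdr <- c(uint_to_raw(group, 2L), uint_to_raw(element, 2L), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(hdr, as.raw(c(0L, 0L)), uint_to_raw(length(value_bytes), 4L), value_bytes)
  } else {
    if (length(value_bytes) > 65534L) stop("value too long for short VR form")
    c(hdr, uint_to_raw(length(value_bytes), 2L), value_bytes)
  }
}

dcm_str <- function(group, element, vr, x) {
  dcm_element(group, element, vr, charToRaw(paste(x, collapse = "\\")))
}
dcm_us <- function(group, element, x) dcm_element(group, element, "US", uint_to_raw(x, 2L))

# decimal-string formatting, one clean token per value (no format() padding)
dcm_ds <- function(x) vapply(x, function(v) format(v, digits = 10, trim = TRUE),
                             character(1))

#' Write one ROI/slice as a classic CT DICOM file
#'
#' Emits an uncompressed explicit-VR little-endian single-frame CT image.
#' Pixels are quantised to integer HU and stored as signed 16-bit values with
#' rescale slope 1 and intercept -1024 (so stored = HU + 1024); the round trip
#' is exact for integer-valued HU images in `[-1024, 31743]`.
#'
#' @param pixels numeric matrix of HU values (rows x cols).
#' @param path output file path.
#' @param pixel_spacing_mm pixel pitch in mm (scalar, or c(row, col)).
#' @param image_position_mm patient-coordinate position of the first pixel
#'   centre, c(x, y, z) in mm.
#' @param slice_thickness_mm nominal slice thickness (mm).
#' @param kvp tube voltage (kV).
#' @param ctdi_vol_mgy displayed CTDIvol (mGy), written to tag (0018,9345).
#' @param scanner_model manufacturer's model name.
#' @param series_uid,instance_number series grouping attributes.
#' @return `path`, invisibly.
#' @export
write_dicom_slice <- function(pixels, path, pixel_spacing_mm,
                              image_position_mm = c(0, 0, 0),
                              slice_thickness_mm = 1, kvp = 120,
                              ctdi_vol_mgy = NA, scanner_model = "synthetic",
                              series_uid = dcm_uid(), instance_number = 1L) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)))
  if (length(pixel_spacing_mm) == 1L)
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  stored <- round(pixels) + 1024
  if (any(stored < -32768 | stored > 32767))
    stop("pixel values out of the signed 16-bit stored range", call. = FALSE)
  # DICOM PixelData is row-major (all columns of row 1, then row 2, ...)
  stored_rm <- as.integer(t(stored))
  ds <- c(
    dcm_str(0x0008, 0x0016, "UI", UID_CT_STORAGE),
    dcm_str(0x0008, 0x0018, "UI", dcm_uid()),
    dcm_str(0x0008, 0x0060, "CS", "CT"),
    dcm_str(0x0008, 0x1090, "LO", scanner_model),
    dcm_str(0x0018, 0x0050, "DS", dcm_ds(slice_thickness_mm)),
    dcm_str(0x0018, 0x0060, "DS", dcm_ds(kvp)),
    if (is.finite(ctdi_vol_mgy))
      dcm_element(0x0018, 0x9345, "FD",
                  writeBin(as.numeric(ctdi_vol_mgy), raw(), size = 8L,
                           endian = "little")),
    dcm_str(0x0020, 0x000E, "UI", series_uid),
    dcm_str(0x0020, 0x0013, "IS", as.character(instance_number)),
    dcm_str(0x0020, 0x0032, "DS", dcm_ds(image_position_mm)),
    dcm_str(0x0020, 0x0037, "DS", dcm_ds(c(1, 0, 0, 0, 1, 0))),
    dcm_us(0x0028, 0x0002, 1L),                       # samples per pixel
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_us(0x0028, 0x0010, nrow(pixels)),             # Rows
    dcm_us(0x0028, 0x0011, ncol(pixels)),             # Columns
    dcm_str(0x0028, 0x0030, "DS",
            dcm_ds(pixel_spacing_mm)),   # row\col spacing
    dcm_us(0x0028, 0x0100, 16L),                      # BitsAllocated
    dcm_us(0x0028, 0x0101, 16L),                      # BitsStored
    dcm_us(0x0028, 0x0102, 15L),                      # HighBit
    dcm_us(0x0028, 0x0103, 1L),                       # signed
    dcm_str(0x0028, 0x1052, "DS", "-1024"),           # RescaleIntercept
    dcm_str(0x0028, 0x1053, "DS", "1"),               # RescaleSlope
    dcm_element(0x7FE0, 0x0010, "OW", int16_to_raw(stored_rm))
  )
  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_str(0x0002, 0x0002, "UI", UID_CT_STORAGE),
    dcm_str(0x0002, 0x0003, "UI", dcm_uid()),
    dcm_str(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    dcm_str(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".1"))
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", uint_to_raw(length(meta_body), 4L)),
            meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

# --- reader -----------------------------------------------------------------

is_dicom_file <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 133) return(FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  seek(con, 128L)
  identical(rawToChar(readBin(con, raw(), 4L)), "DICM")
}

read_u <- function(bytes, pos, size) {
  v <- readBin(bytes[pos:(pos + size - 1L)], "integer", size = size,
               endian = "little", signed = size > 2L)
  if (size < 4L && v < 0) v <- v + 2^(8 * size)
  # 4-byte unsigned lengths can exceed .Machine$integer.max only for huge
  # elements; not supported here
  v
}

# Parse one dataset (after preamble/meta) into a named list keyed "gggg,eeee".
parse_dicom_dataset <- function(bytes, pos, explicit, file) {
  out <- list()
  n <- length(bytes)
  while (pos <= n - 7L) {
    group <- read_u(bytes, pos, 2L); element <- read_u(bytes, pos + 2L, 2L)
    pos <- pos + 4L
    if (explicit) {
      vr <- rawToChar(bytes[pos:(pos + 1L)])
      if (vr %in% LONG_VRS) {
        len <- read_u(bytes, pos + 4L, 4L); pos <- pos + 8L
      } else {
        len <- read_u(bytes, pos + 2L, 2L); pos <- pos + 4L
      }
    } else {
      vr <- "UN"
      len <- read_u(bytes, pos, 4L); pos <- pos + 4L
    }
    if (is.na(len) || len < 0 || vr == "SQ")
      stop(sprintf("unsupported DICOM element (sequence/undefined length) in %s",
                   file), call. = FALSE)
    key <- sprintf("%04x,%04x", group, element)
    out[[key]] <- list(vr = vr, bytes = if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0))
    pos <- pos + len
  }
  out
}

dcm_get_str <- function(ds, key) {
  el <- ds[[key]]
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$bytes[el$bytes != as.raw(0L)]))
}
dcm_get_num <- function(ds, key) {
  s <- dcm_get_str(ds, key)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dcm_get_us <- function(ds, key) {
  el <- ds[[key]]
  if (is.null(el)) return(NULL)
  read_u(el$bytes, 1L, 2L)
}

#' Read one classic CT DICOM file
#'
#' Supports uncompressed little-endian (explicit or implicit VR) single-frame
#' grayscale images. Stored values are converted to HU via
#' `HU = stored * RescaleSlope + RescaleIntercept`.
#'
#' @param path DICOM file path.
#' @return a list: `pixels` (HU matrix, rows x cols), `pixel_spacing_mm`
#'   c(row, col), `image_position_mm`, `orientation` (6 direction cosines),
#'   `instance_number`, and `meta` (scanner model, kVp, slice thickness,
#'   CTDIvol, transfer syntax; missing attributes are NA).
#' @export
read_dicom_slice <- function(path) {
  bytes <- readBin(path, raw(), file.size(path))
  if (length(bytes) < 140L)
    stop(sprintf("%s: too short to be a DICOM file", path), call. = FALSE)
  if (rawToChar(bytes[129:132]) != "DICM")
    stop(sprintf("%s: missing DICM magic", path), call. = FALSE)
  # file meta is always explicit VR little endian
  pos <- 133L
  # read just the meta group to find the transfer syntax and its extent
  grp_len_el <- parse_meta_group <- NULL
  meta <- list(); ts <- UID_EXPLICIT_LE
  # group length element (0002,0000)
  g <- read_u(bytes, pos, 2L)
  if (g != 2L) stop(sprintf("%s: missing file meta group", path), call. = FALSE)
  vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
  len <- read_u(bytes, pos + 6L, 2L)
  meta_len <- read_u(bytes, pos + 8L, 4L)
  meta_start <- pos + 12L
  meta_ds <- parse_dicom_dataset(bytes[meta_start:(meta_start + meta_len - 1L)],
                                 1L, explicit = TRUE, file = path)
  ts_found <- dcm_get_str(meta_ds, "0002,0010")
  if (!is.null(ts_found)) ts <- ts_found
  if (!ts %in% c(UID_EXPLICIT_LE, UID_IMPLICIT_LE))
    stop(sprintf("%s: unsupported transfer syntax %s", path, ts), call. = FALSE)
  ds <- parse_dicom_dataset(bytes, meta_start + meta_len,
                            explicit = ts == UID_EXPLICIT_LE, file = path)
  rows <- dcm_get_us(ds, "0028,0010"); cols <- dcm_get_us(ds, "0028,0011")
  if (is.null(rows) || is.null(cols))
    stop(sprintf("%s: missing Rows/Columns", path), call. = FALSE)
  spacing <- dcm_get_num(ds, "0028,0030")
  if (is.null(spacing))
    stop(sprintf("%s: missing PixelSpacing", path), call. = FALSE)
  bits <- dcm_get_us(ds, "0028,0100"); if (is.null(bits)) bits <- 16L
  signed <- identical(dcm_get_us(ds, "0028,0103"), 1L)
  px <- ds[["7fe0,0010"]]
  if (is.null(px)) stop(sprintf("%s: missing PixelData", path), call. = FALSE)
  stored <- readBin(px$bytes, "integer", n = rows * cols,
                    size = bits / 8L, endian = "little", signed = signed)
  slope <- dcm_get_num(ds, "0028,1053"); if (is.null(slope)) slope <- 1
  icept <- dcm_get_num(ds, "0028,1052"); if (is.null(icept)) icept <- 0
  hu <- matrix(stored * slope + icept, rows, cols, byrow = TRUE)
  ctdi <- if (!is.null(ds[["0018,9345"]])) {
    el <- ds[["0018,9345"]]
    if (el$vr %in% c("FD", "UN") && length(el$bytes) == 8L)
      readBin(el$bytes, "double", size = 8L, endian = "little")
    else as.numeric(dcm_get_str(ds, "0018,9345"))
  } else NA_real_
  num_or_na <- function(key) { v <- dcm_get_num(ds, key); if (is.null(v)) NA_real_ else v }
  str_or_na <- function(key) { v <- dcm_get_str(ds, key); if (is.null(v)) NA_character_ else v }
  list(pixels = hu,
       pixel_spacing_mm = spacing,
       image_position_mm = { v <- dcm_get_num(ds, "0020,0032"); if (is.null(v)) c(0, 0, 0) else v },
       orientation = { v <- dcm_get_num(ds, "0020,0037"); if (is.null(v)) c(1, 0, 0, 0, 1, 0) else v },
       instance_number = { v <- dcm_get_num(ds, "0020,0013"); if (is.null(v)) NA_integer_ else as.integer(v) },
       meta = list(scanner_model = str_or_na("0008,1090"),
                   kvp = num_or_na("0018,0060"),
                   slice_thickness_mm = num_or_na("0018,0050"),
                   ctdi_vol_mgy = ctdi,
                   transfer_syntax = ts))
}
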