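#' Load a CT DICOM series as a volume
#'
#' Reads every DICOM file in a directory, checks that the files form one
#' consistent series (identical matrix size and pixel spacing), converts
#' stored values to HU via the rescale equation, and stacks the slices sorted
#' by axial (z) position.
#'
#' @param path directory containing one DICOM series.
#' @return an object of class `series_volume`: `voxels` (slices x rows x
#'   cols array, HU), `pixel_spacing_mm` c(row, col),
#'   `slice_positions_mm`, `origin_mm` / `orientation` of the first slice,
#'   and `meta` (scanner model, kVp, slice thickness, CTDIvol; `NA` when the
#'   file does not carry the attribute).
#' @export
load_series <- function(path) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  files <- files[vapply(files, is_dicom_file, logical(1))]
  if (length(files) == 0L)
    stop(sprintf("no DICOM files found under %s", path), call. = FALSE)
  slices <- lapply(files, function(f) {
    tryCatch(read_dicom_slice(f),
             error = function(e) stop(sprintf("%s: %s", f, conditionMessage(e)),
                                      call. = FALSE))
  })
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (length(unique(dims[1, ])) > 1L || length(unique(dims[2, ])) > 1L)
    stop(sprintf("inconsistent matrix sizes in series (first offender: %s)",
                 files[which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]]),
         call. = FALSE)
  sp <- vapply(slices, function(s) s$pixel_spacing_mm, numeric(2))
  if (any(abs(sp - sp[, 1]) > 1e-9))
    stop(sprintf("inconsistent pixel spacing in series (first offender: %s)",
                 files[which(colSums(abs(sp - sp[, 1])) > 1e-9)[1]]), call. = FALSE)
  z <- vapply(slices, function(s) s$image_position_mm[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  vox <- array(0, dim = c(length(slices), dims[1, 1], dims[2, 1]))
  for (i in seq_along(slices)) vox[i, , ] <- slices[[i]]$pixels
  structure(list(voxels = vox,
                 pixel_spacing_mm = slices[[1]]$pixel_spacing_mm,
                 slice_positions_mm = z,
                 origin_mm = slices[[1]]$image_position_mm,
                 orientation = slices[[1]]$orientation,
                 meta = slices[[1]]$meta),
            class = "series_volume")
}

#' @export
print.series_volume <- function(x, ...) {
  cat(sprintf("<series_volume %d slices of %dx%d @ %.4f/%.4f mm, CTDIvol %s mGy>\n",
              dim(x$voxels)[1], dim(x$voxels)[2], dim(x$voxels)[3],
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              format(x$meta$ctdi_vol_mgy)))
  invisible(x)
}

#' Lesion/background layout for ROI extraction
#'
#' Physical positions (DICOM patient coordinates, mm) of the lesion centres
#' and of the noise-only background ROI centres for one phantom size. The
#' standard low-contrast module carries four spheres per diameter; only the
#' 5-mm spheres feed the observer analysis.
#'
#' @param phantom_size `"S"`, `"M"` or `"L"`.
#' @param lesion_centres_mm n x 3 matrix of (x, y, z) lesion centres.
#' @param lesion_diameters_mm length-n vector of sphere diameters (mm).
#' @param background_centres_mm m x 3 matrix of background ROI centres.
#' @return an object of class `lesion_layout`.
#' @export
lesion_layout <- function(phantom_size, lesion_centres_mm, lesion_diameters_mm,
                          background_centres_mm) {
  if (!phantom_size %in% c("S", "M", "L"))
    stop("`phantom_size` must be S, M or L", call. = FALSE)
  lc <- as.matrix(lesion_centres_mm); bc <- as.matrix(background_centres_mm)
  if (nrow(lc) == 0L && nrow(bc) == 0L)
    stop("layout must contain at least one centre", call. = FALSE)
  if (ncol(lc) != 3L || ncol(bc) != 3L)
    stop("centres must be (x, y, z) triples", call. = FALSE)
  if (length(lesion_diameters_mm) != nrow(lc))
    stop("every lesion centre needs a diameter", call. = FALSE)
  if (any(lesion_diameters_mm <= 0))
    stop("lesion diameters must be positive", call. = FALSE)
  structure(list(phantom_size = phantom_size,
                 lesion_centres_mm = lc,
                 lesion_diameters_mm = as.numeric(lesion_diameters_mm),
                 background_centres_mm = bc),
            class = "lesion_layout")
}

#' Read a lesion layout from a JSON or YAML config
#'
#' The config carries `phantom_size`, `lesion_centres_mm` (list of [x, y, z]),
#' `lesion_diameters_mm`, and `background_centres_mm`. JSON is read with
#' jsonlite; `.yml`/`.yaml` files use the yaml package when installed.
#'
#' @param path config file path.
#' @return a [lesion_layout()].
#' @export
read_lesion_layout <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML layouts requires the `yaml` package; use JSON instead",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  to_mat <- function(x) {
    if (is.null(x) || length(x) == 0L) return(matrix(numeric(0), 0, 3))
    if (is.list(x)) x <- do.call(rbind, lapply(x, as.numeric))
    matrix(as.numeric(x), ncol = 3)
  }
  lesion_layout(cfg$phantom_size, to_mat(cfg$lesion_centres_mm),
                as.numeric(cfg$lesion_diameters_mm %||% numeric(0)),
                to_mat(cfg$background_centres_mm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Map a physical patient coordinate to 0-based (row, col) indices on a slice
# using the image position and the row/column direction cosines; snapped to
# the nearest voxel (no sub-pixel interpolation).
physical_to_index <- function(volume, xyz) {
  rel <- as.numeric(xyz) - volume$origin_mm
  row_dir <- volume$orientation[4:6]   # direction of increasing row index
  col_dir <- volume$orientation[1:3]   # direction of increasing column index
  r <- sum(rel * row_dir) / volume$pixel_spacing_mm[1]
  c <- sum(rel * col_dir) / volume$pixel_spacing_mm[2]
  c(row = round(r), col = round(c))
}

#' Extract labelled ROIs from a series volume
#'
#' For every configured centre, takes the slice nearest the centre's z
#' coordinate and cuts the half-open square window `[c - N/2, c + N/2)` (in
#' 0-based pixel indices) around the centre voxel. Lesion centres yield
#' `signal_present` ROIs tagged with their diameter; background centres yield
#' `signal_absent` ROIs. With the standard 10-scan protocol this produces the
#' 40/90 design: 4 signal + 9 background ROIs per scan.
#'
#' @param volume a [load_series()] result.
#' @param layout a [lesion_layout()].
#' @param roi_size_px ROI side length N in pixels.
#' @param only_diameter_mm optionally restrict lesion ROIs to one sphere
#'   diameter (e.g. 5); `NULL` keeps all.
#' @param source_id provenance tag prefix for the ROIs.
#' @return a list of [roi_image()].
#' @export
extract_rois <- function(volume, layout, roi_size_px = 64L,
                         only_diameter_mm = NULL, source_id = "series") {
  stopifnot(inherits(volume, "series_volume"), inherits(layout, "lesion_layout"))
  stopifnot_scalar_num(roi_size_px, "roi_size_px", positive = TRUE, integer = TRUE)
  n <- as.integer(roi_size_px)
  keep <- seq_len(nrow(layout$lesion_centres_mm))
  if (!is.null(only_diameter_mm))
    keep <- which(abs(layout$lesion_diameters_mm - only_diameter_mm) < 1e-9)
  centres <- rbind(layout$lesion_centres_mm[keep, , drop = FALSE],
                   layout$background_centres_mm)
  if (nrow(centres) == 0L)
    stop("layout contains no centres to extract", call. = FALSE)
  diam <- c(layout$lesion_diameters_mm[keep],
            rep(NA_real_, nrow(layout$background_centres_mm)))
  lab <- rep(c("signal_present", "signal_absent"),
             c(length(keep), nrow(layout$background_centres_mm)))
  dims <- dim(volume$voxels)
  half_lo <- floor(n / 2); half_hi <- n - half_lo  # [c-N/2, c+N/2)
  out <- vector("list", nrow(centres))
  for (i in seq_len(nrow(centres))) {
    slice <- which.min(abs(volume$slice_positions_mm - centres[i, 3]))
    rc <- physical_to_index(volume, centres[i, ])
    r0 <- rc["row"] - half_lo; r1 <- rc["row"] + half_hi - 1L
    c0 <- rc["col"] - half_lo; c1 <- rc["col"] + half_hi - 1L
    if (r0 < 0 || c0 < 0 || r1 >= dims[2] || c1 >= dims[3])
      stop(sprintf("centre (%g, %g, %g) too close to the volume border for a %dx%d ROI",
                   centres[i, 1], centres[i, 2], centres[i, 3], n, n),
           call. = FALSE)
    px <- volume$voxels[slice, (r0:r1) + 1L, (c0:c1) + 1L]
    out[[i]] <- roi_image(px, mean(volume$pixel_spacing_mm),
                          label = lab[i],
                          lesion_diameter_mm = if (lab[i] == "signal_present") diam[i] else NULL,
                          source_id = sprintf("%s:roi%02d", source_id, i))
  }
  out
}

# --- portable ROI dataset container ----------------------------------------

#' Write and read ROI datasets as plain text
#'
#' The portable dataset container: one CSV of pixel values per ROI (no
#' header, one image row per line) plus a `manifest.csv` with columns
#' filename, label, pixel_spacing_mm, lesion_diameter_mm, source_id. The
#' round trip preserves pixel values to full double precision.
#'
#' @param rois list of [roi_image()].
#' @param dir dataset directory (created if needed).
#' @return `write_roi_dataset` returns `dir` invisibly; `read_roi_dataset`
#'   returns the list of `roi_image`s.
#' @export
write_roi_dataset <- function(rois, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(
    filename = sprintf("roi_%04d.csv", seq_along(rois)),
    label = vapply(rois, `[[`, "", "label"),
    pixel_spacing_mm = vapply(rois, `[[`, 0, "pixel_spacing_mm"),
    lesion_diameter_mm = vapply(rois, function(r)
      r$lesion_diameter_mm %||% NA_real_, 0),
    source_id = vapply(rois, `[[`, "", "source_id"),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(rois)) {
    write.table(format(rois[[i]]$pixels, digits = 17, trim = TRUE),
                file.path(dir, manifest$filename[i]),
                sep = ",", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_roi_dataset
#' @export
read_roi_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf))
    stop(sprintf("no manifest.csv under %s", dir), call. = FALSE)
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    px <- as.matrix(read.csv(file.path(dir, manifest$filename[i]),
                             header = FALSE))
    dimnames(px) <- NULL
    d <- manifest$lesion_diameter_mm[i]
    roi_image(px, manifest$pixel_spacing_mm[i], manifest$label[i],
              lesion_diameter_mm = if (is.finite(d)) d else NULL,
              source_id = manifest$source_id[i])
  })
}

#' Export a synthetic ROI dataset as DICOM files
#'
#' Writes each ROI as one classic CT DICOM file (integer-HU quantisation, see
#' [write_dicom_slice()]) plus the same manifest as [write_roi_dataset()] —
#' the round-trip fixture for the DICOM reader.
#'
#' @param rois list of [roi_image()].
#' @param dir output directory.
#' @param spacing_z_mm spacing between consecutive ROI "slices" (mm).
#' @return `dir`, invisibly.
#' @export
export_dicom_dataset <- function(rois, dir, spacing_z_mm = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  uid <- dcm_uid()
  manifest <- data.frame(
    filename = sprintf("roi_%04d.dcm", seq_along(rois)),
    label = vapply(rois, `[[`, "", "label"),
    pixel_spacing_mm = vapply(rois, `[[`, 0, "pixel_spacing_mm"),
    lesion_diameter_mm = vapply(rois, function(r)
      r$lesion_diameter_mm %||% NA_real_, 0),
    source_id = vapply(rois, `[[`, "", "source_id"),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(rois)) {
    write_dicom_slice(rois[[i]]$pixels, file.path(dir, manifest$filename[i]),
                      pixel_spacing_mm = rois[[i]]$pixel_spacing_mm,
                      image_position_mm = c(0, 0, (i - 1) * spacing_z_mm),
                      series_uid = uid, instance_number = i)
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
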