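#' Rectangular region-of-interest specification
#'
#' Coordinates are 0-based and half-open: the ROI covers columns
#' `[x0, x1)` and rows `[y0, y1)`, with `x` indexing columns and `y`
#' indexing rows. This convention is stated explicitly so that ROI tables
#' are portable across tools.
#'
#' @param image_id Image file name (used as the record key together with
#'   the rectangle).
#' @param x0,y0,x1,y1 Integers with `0 <= x0 < x1`, `0 <= y0 < y1`.
#' @param plane Optional scan-plane tag (`"sagittal"` or `"transverse"`).
#' @param side Optional side tag (`"left"` or `"right"`).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(image_id, x0, y0, x1, y1, plane = NA_character_,
                     side = NA_character_) {
  x0 <- as.integer(x0); y0 <- as.integer(y0)
  x1 <- as.integer(x1); y1 <- as.integer(y1)
  if (x0 < 0L || y0 < 0L || x0 >= x1 || y0 >= y1)
    stop(sprintf("invalid ROI rectangle [%d,%d)x[%d,%d)", x0, x1, y0, y1),
         call. = FALSE)
  if (!is.na(plane) && !plane %in% c("sagittal", "transverse"))
    stop("plane must be 'sagittal' or 'transverse'", call. = FALSE)
  if (!is.na(side) && !side %in% c("left", "right"))
    stop("side must be 'left' or 'right'", call. = FALSE)
  structure(list(image_id = as.character(image_id), x0 = x0, y0 = y0,
                 x1 = x1, y1 = y1, plane = as.character(plane),
                 side = as.character(side)),
            class = "roi_spec")
}

#' Load a grayscale image from PNG or TIFF
#'
#' Reads an image file into a [gray_image()]. PNG input must be 8-bit;
#' grayscale or channel-equal RGB is used as-is, and true-color RGB is
#' collapsed with the Rec. 709 luminance formula
#' `0.2126 R + 0.7152 G + 0.0722 B` before rounding. TIFF input may be
#' 8- or 16-bit; 16-bit values are rescaled by the fixed-range map
#' `v * (levels - 1) / (2^16 - 1)` with half-toward-zero rounding, so the
#' full 16-bit range maps onto the full 8-bit range irrespective of image
#' content. Unsupported bit depths raise an error rather than silently
#' truncating.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param levels Gray levels of the result (default 256).
#' @return A [gray_image()].
#' @export
load_grayscale_image <- function(path, levels = 256L) {
  if (!file.exists(path))
    stop(sprintf("cannot read image file '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  levels <- as.integer(levels)
  if (ext == "png") {
    bit_depth <- png_bit_depth(path)
    if (bit_depth != 8L)
      stop(sprintf("unsupported bit depth %d in '%s' (PNG must be 8-bit)",
                   bit_depth, path), call. = FALSE)
    arr <- png::readPNG(path)
    gray <- collapse_channels(arr, path) * 255
    px <- round_half_to_zero(gray * (levels - 1L) / 255)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bit_depth <- attr(arr, "bits.per.sample")
    if (is.null(bit_depth) || !bit_depth %in% c(8L, 16L))
      stop(sprintf("unsupported bit depth %s in '%s' (TIFF must be 8- or 16-bit)",
                   paste(bit_depth, collapse = "/"), path), call. = FALSE)
    gray <- collapse_channels(arr, path)
    px <- round_half_to_zero(gray * (levels - 1L) / (2^bit_depth - 1))
  } else {
    stop(sprintf("cannot read image file '%s' (supported: PNG, TIFF)", path),
         call. = FALSE)
  }
  gray_image(px, levels = levels)
}

# PNG IHDR: 8-byte signature, 4-byte length, "IHDR", 4+4 byte dimensions,
# then one bit-depth byte at offset 24 (0-based)
png_bit_depth <- function(path) {
  header <- readBin(path, "raw", n = 26L)
  if (length(header) < 26L ||
      !identical(header[1:8],
                 as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))))
    stop(sprintf("cannot read image file '%s' (not a PNG)", path),
         call. = FALSE)
  as.integer(header[25])
}

collapse_channels <- function(arr, path) {
  if (length(dim(arr)) == 2L) return(arr)
  nch <- dim(arr)[3]
  if (nch == 2L) return(arr[, , 1])            # gray + alpha
  if (nch %in% c(3L, 4L)) {
    r <- arr[, , 1]; g <- arr[, , 2]; b <- arr[, , 3]
    if (identical(r, g) && identical(g, b)) return(r)
    return(0.2126 * r + 0.7152 * g + 0.0722 * b)
  }
  stop(sprintf("cannot read image file '%s' (%d channels)", path, nch),
       call. = FALSE)
}

#' Crop a rectangular ROI out of an image
#'
#' Output pixel `(r, c)` equals input pixel `(y0 + r, x0 + c)` (0-based);
#' the result is `(y1 - y0)` rows by `(x1 - x0)` columns.
#'
#' @param image A [gray_image()].
#' @param roi A [roi_spec()] whose rectangle lies within the image.
#' @return A [gray_image()] of the cropped region.
#' @export
crop_roi <- function(image, roi) {
  image <- as_gray_image(image)
  if (!inherits(roi, "roi_spec")) stop("roi must be a roi_spec()")
  if (roi$x1 > image$width || roi$y1 > image$height)
    stop(sprintf(
      "ROI [%d,%d)x[%d,%d) out of bounds for %d x %d image",
      roi$x0, roi$x1, roi$y0, roi$y1, image$height, image$width),
      call. = FALSE)
  px <- image$pixels[(roi$y0 + 1L):roi$y1, (roi$x0 + 1L):roi$x1,
                     drop = FALSE]
  gray_image(px, levels = image$levels)
}

#' Extract one labeled feature record from an image ROI
#'
#' Crops the ROI, computes its GLCM and texture features, and attaches the
#' lesion labels. `lesion_label = "microlith"` requires the mineralization
#' flag and `"other"` requires the nodule flag, matching the reading-room
#' convention that a label implies the corresponding finding was recorded.
#'
#' @param image A [gray_image()].
#' @param roi A [roi_spec()].
#' @param params A [glcm_params()].
#' @param mineralization,nodule Logical finding flags.
#' @param lesion_label One of `"normal"`, `"microlith"`, `"other"`.
#' @param metadata Optional named list of extra per-record columns
#'   (e.g. age group, treatment flags, body condition score).
#' @return A one-row [tibble::tibble()] in the feature-table schema.
#' @export
extract_record <- function(image, roi, params = glcm_params(),
                           mineralization = FALSE, nodule = FALSE,
                           lesion_label = c("normal", "microlith", "other"),
                           metadata = NULL) {
  lesion_label <- match.arg(lesion_label)
  if (lesion_label == "microlith" && !isTRUE(mineralization))
    stop("lesion_label 'microlith' requires mineralization = TRUE",
         call. = FALSE)
  if (lesion_label == "other" && !isTRUE(nodule))
    stop("lesion_label 'other' requires nodule = TRUE", call. = FALSE)
  crop <- crop_roi(image, roi)
  feats <- tryCatch(
    image_features(crop, params),
    error = function(e) {
      stop(sprintf("%s (image '%s', ROI [%d,%d)x[%d,%d))",
                   conditionMessage(e), roi$image_id,
                   roi$x0, roi$x1, roi$y0, roi$y1), call. = FALSE)
    })
  rec <- tibble::tibble(
    image_id = roi$image_id, x0 = roi$x0, y0 = roi$y0,
    x1 = roi$x1, y1 = roi$y1, plane = roi$plane, side = roi$side,
    mineralization = isTRUE(mineralization), nodule = isTRUE(nodule),
    lesion_label = lesion_label)
  for (nm in feature_names()) rec[[nm]] <- unname(feats[nm])
  if (!is.null(metadata)) for (nm in names(metadata)) rec[[nm]] <- metadata[[nm]]
  rec
}

#' Batch feature extraction over a ROI table
#'
#' Runs [extract_record()] for every row of a ROI/label table. Each output
#' record depends only on its own input row, so extraction order does not
#' matter.
#'
#' @param image_dir Directory containing the image files named in
#'   `rois$image_id`.
#' @param rois A data frame with columns `image_id, x0, y0, x1, y1` and
#'   optionally `plane, side, mineralization, nodule, lesion_label` plus
#'   metadata columns, e.g. as written by [make_cohort()].
#' @param params A [glcm_params()].
#' @return A feature table ([tibble::tibble()]), one row per ROI.
#' @export
extract_features <- function(image_dir, rois, params = glcm_params()) {
  required <- c("image_id", "x0", "y0", "x1", "y1")
  missing_cols <- setdiff(required, names(rois))
  if (length(missing_cols) > 0L)
    stop(sprintf("ROI table is missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  meta_cols <- setdiff(names(rois),
                       c(required, "plane", "side", "mineralization",
                         "nodule", "lesion_label"))
  rows <- lapply(seq_len(nrow(rois)), function(k) {
    r <- rois[k, ]
    img <- load_grayscale_image(file.path(image_dir, r$image_id),
                                levels = params$levels)
    roi <- roi_spec(r$image_id, r$x0, r$y0, r$x1, r$y1,
                    plane = if ("plane" %in% names(r)) r$plane else NA,
                    side = if ("side" %in% names(r)) r$side else NA)
    md <- if (length(meta_cols)) as.list(r[meta_cols]) else NULL
    extract_record(
      img, roi, params,
      mineralization = isTRUE(r$mineralization),
      nodule = isTRUE(r$nodule),
      lesion_label = if ("lesion_label" %in% names(r)) r$lesion_label
                     else "normal",
      metadata = md)
  })
  tbl <- do.call(rbind, rows)
  validate_feature_table(tbl)
  tbl
}

feature_csv_schema <- function() {
  c("image_id", "x0", "y0", "x1", "y1", "plane", "side",
    "mineralization", "nodule", "lesion_label", feature_names())
}

validate_feature_table <- function(tbl) {
  schema <- feature_csv_schema()
  if (nrow(tbl) == 0L) stop("feature table is empty", call. = FALSE)
  if (length(names(tbl)) < length(schema) ||
      !identical(names(tbl)[seq_along(schema)], schema))
    stop(sprintf(
      "feature table schema mismatch: expected columns %s",
      paste(schema, collapse = ", ")), call. = FALSE)
  key <- paste(tbl$image_id, tbl$x0, tbl$y0, tbl$x1, tbl$y1)
  if (anyDuplicated(key)) {
    first <- which(duplicated(key))[1]
    stop(sprintf("duplicate (image_id, ROI) key at row %d: %s",
                 first, key[first]), call. = FALSE)
  }
  invisible(tbl)
}

#' Write / read a feature table as CSV
#'
#' The schema is fixed (column order is part of the contract):
#' `image_id, x0, y0, x1, y1, plane, side, mineralization, nodule,
#' lesion_label`, the seven texture features in canonical order, then any
#' extra metadata columns. UTF-8, comma delimiter, `.` decimal separator,
#' header row required. Feature values round-trip losslessly (written with
#' full double precision).
#'
#' @param table Feature table as produced by [extract_features()].
#' @param path Output / input CSV path.
#' @return `write_feature_csv()` returns `path` invisibly;
#'   `read_feature_csv()` returns the feature table.
#' @export
write_feature_csv <- function(table, path) {
  validate_feature_table(table)
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read feature CSV '%s'", path), call. = FALSE)
  spec <- readr::cols(
    image_id = readr::col_character(),
    x0 = readr::col_integer(), y0 = readr::col_integer(),
    x1 = readr::col_integer(), y1 = readr::col_integer(),
    plane = readr::col_character(), side = readr::col_character(),
    mineralization = readr::col_logical(), nodule = readr::col_logical(),
    lesion_label = readr::col_character(),
    .default = readr::col_guess())
  for (nm in feature_names()) spec$cols[[nm]] <- readr::col_double()
  # a wrong-schema file is reported by validate_feature_table below, not
  # by readr's unmatched-parser warning
  tbl <- suppressWarnings(
    readr::read_csv(path, col_types = spec, progress = FALSE))
  validate_feature_table(tbl)
  tbl
}
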