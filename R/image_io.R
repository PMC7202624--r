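# Image and manifest I/O, physical pixel spacing, circular FOV masks.
#
# Every metric downstream is reported in micrometres, so the micron-per-
# pixel spacing is a required, explicit input everywhere an image enters
# the package: there is no default.

#' Largest centered inscribed disk mask
#'
#' Builds the default circular field-of-view mask: the largest disk,
#' centered on the image, that fits inside the pixel grid. A pixel belongs
#' to the disk when its center lies within the disk radius.
#'
#' @param nrow,ncol image dimensions in pixels.
#' @return logical matrix, `TRUE` inside the field of view.
#' @export
inscribed_disk_mask <- function(nrow, ncol) {
  r <- min(nrow, ncol) / 2
  ci <- (nrow + 1) / 2
  cj <- (ncol + 1) / 2
  di <- (seq_len(nrow) - ci)^2
  dj <- (seq_len(ncol) - cj)^2
  outer(di, dj, "+") <= r^2
}

#' pCLE image container
#'
#' A grayscale pixel grid together with its physical pixel spacing and a
#' circular field-of-view (FOV) mask. The spacing anchors every metric in
#' micrometres; the FOV mask marks the instrument's circular fiber-bundle
#' field (600 um diameter on the clinical probe).
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param spacing_um micrometres per pixel (isotropic, > 0).
#' @param fov_mask optional logical matrix; defaults to the largest
#'   centered inscribed disk.
#' @param source_id opaque snapshot identifier.
#' @return an object of class `pcle_image`.
#' @export
pcle_image <- function(pixels, spacing_um, fov_mask = NULL, source_id = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (!is.numeric(spacing_um) || length(spacing_um) != 1 ||
      is.na(spacing_um) || spacing_um <= 0)
    stop("`spacing_um` must be a positive scalar")
  if (any(pixels < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  if (is.null(fov_mask)) {
    fov_mask <- inscribed_disk_mask(nrow(pixels), ncol(pixels))
  } else {
    fov_mask <- fov_mask != 0
    if (!identical(dim(fov_mask), dim(pixels)))
      stop("`fov_mask` dimensions must match `pixels`")
  }
  structure(
    list(pixels = pixels, spacing_um = spacing_um, fov_mask = fov_mask,
         source_id = as.character(source_id)),
    class = "pcle_image")
}

#' @export
print.pcle_image <- function(x, ...) {
  cat(sprintf("pcle_image '%s': %d x %d px, %.4g um/px (FOV %d px across)\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels), x$spacing_um,
              min(dim(x$pixels))))
  invisible(x)
}

# ---- minimal uncompressed grayscale TIFF codec -------------------------
# No TIFF package is available in the target environment, so the package
# carries a deliberately small baseline codec: single strip, uncompressed,
# one sample per pixel, 8/16-bit unsigned or 32-bit float, either byte
# order on read, little-endian on write.

read_tiff_gray <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  endian <- if (identical(magic[1:2], charToRaw("II"))) "little"
            else if (identical(magic[1:2], charToRaw("MM"))) "big"
            else stop("not a TIFF file: ", path)
  u16 <- function() readBin(con, "integer", 1, size = 2, signed = FALSE,
                            endian = endian)
  u32 <- function() readBin(con, "integer", 1, size = 4, endian = endian)
  ifd_off <- u32()
  seek(con, ifd_off)
  n_entries <- u16()
  tags <- list()
  for (k in seq_len(n_entries)) {
    tag <- u16(); typ <- u16(); cnt <- u32()
    pos <- seek(con)
    val <- if (typ == 3 && cnt == 1) { v <- u16(); u16(); v } else u32()
    seek(con, pos + 4)
    tags[[as.character(tag)]] <- list(type = typ, count = cnt, value = val)
  }
  gt <- function(tag, default = NULL) {
    t <- tags[[as.character(tag)]]
    if (is.null(t)) default else t$value
  }
  width <- gt(256); height <- gt(257)
  if (is.null(width) || is.null(height)) stop("TIFF missing dimensions")
  bits <- gt(258, 8)
  if (gt(259, 1) != 1) stop("only uncompressed TIFF is supported")
  spp <- gt(277, 1)
  if (spp != 1)
    stop(sprintf("multi-channel image (%d samples/pixel); expected grayscale",
                 spp))
  fmt <- gt(339, 1)
  strip_off <- gt(273)
  if (is.null(strip_off)) stop("TIFF missing strip offset")
  # multiple strips: offsets stored out of line; require a single strip
  if (tags[["273"]]$count != 1) stop("only single-strip TIFF is supported")
  seek(con, strip_off)
  n <- width * height
  px <- if (fmt == 3 && bits == 32) {
    readBin(con, "double", n, size = 4, endian = endian)
  } else if (bits == 8) {
    as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE,
                       endian = endian))
  } else if (bits == 16) {
    as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                       endian = endian))
  } else stop("unsupported TIFF bit depth: ", bits)
  # TIFF stores rows first (row-major); R matrices are column-major
  t(matrix(px, nrow = width, ncol = height))
}

write_tiff_gray <- function(pixels, path, bits = NULL) {
  if (is.null(bits)) {
    mx <- suppressWarnings(max(pixels))
    intish <- all(pixels == round(pixels)) && mx <= 65535 && min(pixels) >= 0
    bits <- if (!intish) 32L else if (mx <= 255) 8L else 16L
  }
  height <- nrow(pixels); width <- ncol(pixels)
  data <- as.vector(t(pixels)) # row-major
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, typ, cnt, val) {
    w16(tag); w16(typ); w32(cnt)
    if (typ == 3) { w16(val); w16(0) } else w32(val)
  }
  writeBin(charToRaw("II"), con); w16(42L); w32(8L)
  n_entries <- 10L
  data_off <- 8L + 2L + n_entries * 12L + 4L
  bytes <- width * height * (bits %/% 8L)
  fmt <- if (bits == 32L) 3L else 1L
  w16(n_entries)
  entry(256, 3, 1, width)
  entry(257, 3, 1, height)
  entry(258, 3, 1, bits)
  entry(259, 3, 1, 1)        # no compression
  entry(262, 3, 1, 1)        # black is zero
  entry(273, 4, 1, data_off)
  entry(277, 3, 1, 1)
  entry(278, 3, 1, height)
  entry(279, 4, 1, bytes)
  entry(339, 3, 1, fmt)      # sample format (uint / IEEE float)
  w32(0L)                    # next IFD
  if (bits == 32L) {
    writeBin(as.numeric(data), con, size = 4, endian = "little")
  } else if (bits == 16L) {
    writeBin(as.integer(data), con, size = 2, endian = "little")
  } else {
    writeBin(as.raw(as.integer(data)), con)
  }
  invisible(path)
}

# ---- user-facing load/save ---------------------------------------------

#' Load a snapshot image
#'
#' Reads a single-channel TIFF or PNG image into a [pcle_image]. PNG
#' intensities are scaled to the 0-255 range (the `png` reader normalises
#' to 0-1); TIFF intensities are read verbatim.
#'
#' @param path image file (`.tif`, `.tiff` or `.png`).
#' @param spacing_um micrometres per pixel; required, no default.
#' @param fov_mask optional explicit FOV mask (logical matrix or path to a
#'   mask image where nonzero means inside); defaults to the inscribed
#'   centered disk.
#' @param source_id snapshot identifier; defaults to the file name.
#' @return a [pcle_image].
#' @export
load_image <- function(path, spacing_um, fov_mask = NULL,
                       source_id = basename(path)) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("tif", "tiff")) {
    read_tiff_gray(path)
  } else if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) {
      if (dim(a)[3] > 1)
        stop(sprintf("multi-channel image (%d channels); expected grayscale",
                     dim(a)[3]))
      a <- a[, , 1]
    }
    round(a * 255)
  } else stop("unsupported image format: .", ext)
  if (is.character(fov_mask)) {
    fov_mask <- load_image(fov_mask, spacing_um)$pixels > 0
  }
  pcle_image(px, spacing_um, fov_mask = fov_mask, source_id = source_id)
}

#' Save an image
#'
#' Writes a numeric matrix or [pcle_image] as single-channel TIFF
#' (verbatim intensities, bit depth chosen from the value range) or PNG
#' (values scaled from 0-255).
#'
#' @param image numeric matrix or [pcle_image].
#' @param path output file; format from extension.
#' @export
save_image <- function(image, path) {
  px <- if (inherits(image, "pcle_image")) image$pixels else image
  if (is.logical(px)) px <- px * 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_tiff_gray(px, path)
  } else if (ext == "png") {
    png::writePNG(pmin(pmax(px / 255, 0), 1), path)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

# ---- cohort manifest ---------------------------------------------------

.group_levels <- c("Normal", "COP", "HP", "NSIP", "IPF")

#' Read a cohort manifest
#'
#' A manifest maps snapshot image files to patients and diagnosis groups.
#' Required columns: `patient_id`, `group` (one of Normal, COP, HP, NSIP,
#' IPF), `snapshot_index` (1-based acquisition order) and `path`. An
#' optional `spacing_um` column overrides the pipeline-level spacing, and
#' an optional `role` column (train/test) marks classifier splits.
#'
#' @param path CSV file with a header.
#' @return data frame of validated manifest rows, in file order.
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "group", "snapshot_index", "path")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$group), .group_levels)
  if (length(bad))
    stop("unknown group label(s): ", paste(sQuote(bad), collapse = ", "),
         " (expected one of ", paste(.group_levels, collapse = ", "), ")")
  df$snapshot_index <- as.integer(df$snapshot_index)
  key <- paste(df$patient_id, df$snapshot_index)
  if (anyDuplicated(key))
    stop("duplicate (patient_id, snapshot_index) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  df
}

.metric_cols <- c("patient_id", "group", "snapshot_index", "T_med_um",
                  "sigma_T_um", "C_s_per_mm", "n_holes",
                  "skeleton_length_um")

#' Write per-snapshot metrics to CSV
#'
#' Deterministic column order (`patient_id`, `group`, `snapshot_index`,
#' `T_med_um`, `sigma_T_um`, `C_s_per_mm`, `n_holes`,
#' `skeleton_length_um`, plus exclusion bookkeeping) and input row order.
#'
#' @param records data frame of cohort records (see [quantify_snapshot]).
#' @param path output CSV path.
#' @export
write_metrics <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) {
    records <- as.data.frame(
      setNames(rep(list(numeric(0)), length(.metric_cols)), .metric_cols))
    records$excluded <- logical(0)
    records$exclusion_reason <- character(0)
  }
  if (is.null(records$excluded)) records$excluded <- FALSE
  if (is.null(records$exclusion_reason)) records$exclusion_reason <- ""
  out <- records[, c(.metric_cols, "excluded", "exclusion_reason")]
  for (cn in c("T_med_um", "sigma_T_um", "C_s_per_mm", "skeleton_length_um"))
    out[[cn]] <- signif(out[[cn]], 6)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a metrics CSV written by [write_metrics]
#' @param path CSV file.
#' @return data frame of cohort records.
#' @export
read_metrics <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(df$excluded)) df$excluded <- FALSE
  df$excluded <- as.logical(df$excluded)
  if (is.null(df$exclusion_reason)) df$exclusion_reason <- ""
  df$exclusion_reason[is.na(df$exclusion_reason)] <- ""
  df
}
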