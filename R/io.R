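#' Grayscale electron micrograph with physical pixel size
#'
#' A `gray_image` couples an 8-bit intensity raster with the physical edge
#' length of one pixel in nanometres. The pixel size is always supplied by
#' the user or the run configuration — EM vendors store it inconsistently in
#' TIFF tags, so it is never inferred from file metadata.
#'
#' @param pixels Integer matrix of intensities in `[0, 255]`, at least
#'   32 x 32 (rows are image rows).
#' @param pixel_size_nm Positive physical pixel size, nm per pixel edge.
#' @return An object of class `gray_image`: a list with elements `pixels`
#'   and `pixel_size_nm`.
#' @export
gray_image <- function(pixels, pixel_size_nm) {
  if (!is.matrix(pixels)) abort("`pixels` must be a matrix")
  if (nrow(pixels) < 32 || ncol(pixels) < 32) {
    abort("image must be at least 32 x 32 pixels")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    abort("intensities must lie in [0, 255]")
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 ||
      is.na(pixel_size_nm) || pixel_size_nm <= 0) {
    abort("`pixel_size_nm` must be a single positive number")
  }
  pixels <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  structure(list(pixels = pixels, pixel_size_nm = as.numeric(pixel_size_nm)),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.3g nm/px, gray range [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

# Accept either a gray_image or a bare matrix; return the integer raster.
as_pixels <- function(img) {
  if (inherits(img, "gray_image")) return(img$pixels)
  if (is.matrix(img)) {
    m <- img
    storage.mode(m) <- "integer"
    return(m)
  }
  abort("expected a `gray_image` or an intensity matrix")
}

png_header_info <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 26)
  list(bit_depth = as.integer(hdr[25]), color_type = as.integer(hdr[26]))
}

#' Read an 8-bit grayscale micrograph
#'
#' Reads a single-channel 8-bit TIFF or PNG. Multi-channel and non-8-bit
#' rasters are rejected rather than silently converted.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size_nm Physical pixel size in nm (user-supplied; never read
#'   from file metadata).
#' @return A [gray_image].
#' @export
read_image <- function(path, pixel_size_nm) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(px, "bits.per.sample")
    if (!is.null(bits) && any(bits != 8L)) abort("TIFF is not 8-bit")
  } else if (ext == "png") {
    info <- png_header_info(path)
    if (info$bit_depth != 8L) abort("PNG is not 8-bit")
    if (!info$color_type %in% c(0L, 4L)) abort("PNG is not single-channel grayscale")
    if (info$color_type == 4L) abort("PNG has an alpha channel")
    px <- round(png::readPNG(path) * 255)
  } else {
    abort("unsupported raster format (use TIFF or PNG)")
  }
  if (length(dim(px)) != 2) abort("raster is multi-channel; expected one channel")
  gray_image(px, pixel_size_nm)
}

#' Write an 8-bit grayscale micrograph
#'
#' @param img A [gray_image] or integer matrix in `[0, 255]`.
#' @param path Destination `.tif`/`.tiff` or `.png` path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  px <- as_pixels(img)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px / 255, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(px / 255, path)
  } else {
    abort("unsupported raster format (use TIFF or PNG)")
  }
  invisible(path)
}

#' Read or write a granule instance label map
#'
#' Instance maps (0 = background, k >= 1 = granule k) are stored as 16-bit
#' grayscale TIFF.
#'
#' @param imap Integer label matrix with values in `[0, 65535]`.
#' @param path TIFF path.
#' @return `read_instance_map()` returns an integer matrix of class
#'   `instance_map`; `write_instance_map()` returns `path` invisibly.
#' @export
write_instance_map <- function(imap, path) {
  m <- unclass(imap)
  if (min(m) < 0 || max(m) > 65535) abort("labels must fit 16 bits")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_instance_map
#' @export
read_instance_map <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) != 2) abort("instance map must be single-channel")
  m <- matrix(as.integer(m), nrow(m), ncol(m))
  structure(m, class = c("instance_map", "matrix", "array"))
}

granule_table_columns <- c(
  "id", "centroid_x_px", "centroid_y_px", "area_nm2", "perimeter_nm",
  "equiv_radius_nm", "core_radius_nm", "round_coefficient", "mean_gray",
  "membrane_distance_nm"
)

#' Write the per-granule measurement table
#'
#' One CSV row per granule. Centroids are exported as 0-based pixel
#' coordinates with `centroid_x_px` = column and `centroid_y_px` = row, so
#' the CSV plots directly in image coordinates. The optional columns
#' `core_radius_nm` and `membrane_distance_nm` appear only when present in
#' `records`. Granule boundary polygons are not stuffed into CSV cells; use
#' [write_boundaries()] for a JSON sidecar.
#'
#' @param records Tibble of granule measurements from [measure_granules()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_granule_table <- function(records, path) {
  df <- as.data.frame(records)
  if (nrow(df) > 0) {
    df$centroid_x_px <- df$centroid_col - 1
    df$centroid_y_px <- df$centroid_row - 1
  } else {
    df$centroid_x_px <- numeric(0)
    df$centroid_y_px <- numeric(0)
  }
  keep <- intersect(granule_table_columns, names(df))
  utils::write.csv(df[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read back a granule measurement table
#'
#' @param path CSV path written by [write_granule_table()].
#' @return A tibble with internal 1-based `centroid_row`/`centroid_col`
#'   columns reconstructed from the exported 0-based coordinates.
#' @export
read_granule_table <- function(path) {
  df <- utils::read.csv(path)
  if ("centroid_x_px" %in% names(df)) {
    df$centroid_col <- df$centroid_x_px + 1
    df$centroid_row <- df$centroid_y_px + 1
  }
  as_tibble(df)
}

#' Write granule boundary polygons as JSON
#'
#' One polygon per granule id, each a list of 0-based `[row, col]` vertices.
#'
#' @param records Tibble from [measure_granules()] with a `boundary`
#'   list-column of n x 2 matrices (1-based row, col pixel centres).
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(records, path) {
  polys <- lapply(seq_len(nrow(records)), function(i) {
    b <- records$boundary[[i]]
    list(id = records$id[i], vertices = unname(b - 1))
  })
  jsonlite::write_json(polys, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
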