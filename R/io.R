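#' Write or read a grayscale image as 16-bit TIFF
#'
#' Single-channel, uncompressed 16-bit grayscale; intensities are clipped to
#' `[0, 1]` on write and returned in `[0, 1]` on read.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param path Output path (`.tif`).
#' @return `read_image_tiff` returns the image matrix.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(is.matrix(image))
  tiff::writeTIFF(pmin(pmax(image, 0), 1), path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

# Strict CSV reading: the named columns must be present, in order first.
read_csv_schema <- function(path, columns) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(columns, names(df))
  if (length(missing)) {
    stop(basename(path), " is missing columns: ", paste(missing, collapse = ", "))
  }
  df[columns]
}

#' Read tables written by the analysis pipeline
#'
#' Schema-validated readers for the standard pipeline outputs: droplet
#' detections (`droplet_id, center_x_px, center_y_px, diameter_um`) and
#' crystal measurements (`droplet_id, crystal_id, length_um, width_um,
#' orientation_deg`). Column names carry units; a file without the expected
#' header is rejected.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_droplets_csv <- function(path) {
  read_csv_schema(path, c("droplet_id", "center_x_px", "center_y_px",
                          "diameter_um"))
}

#' @rdname read_droplets_csv
#' @export
read_crystals_csv <- function(path) {
  read_csv_schema(path, c("droplet_id", "crystal_id", "length_um", "width_um",
                          "orientation_deg"))
}

#' Write a CV trace as CSV
#'
#' Columns `t_ms,cv`.
#'
#' @param trace A [cv_trace()].
#' @param path Output path.
#' @export
write_cv_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "cv_trace"))
  utils::write.csv(data.frame(t_ms = trace$times_ms, cv = trace$cv), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_cv_trace_csv
#' @param threshold Mixing threshold applied on read.
#' @export
read_cv_trace_csv <- function(path, threshold = 0.05) {
  df <- read_csv_schema(path, c("t_ms", "cv"))
  cv_trace(df$t_ms, df$cv, threshold = threshold)
}
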