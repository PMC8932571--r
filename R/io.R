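# Plain-text / standard-format serialization of the package's objects.

#' Write and read contrast images (16-bit TIFF + JSON sidecar)
#'
#' Images are stored as single-channel 16-bit TIFF files, with a JSON
#' sidecar per directory recording the pixel pitch and the linear
#' contrast-to-intensity scaling so the round trip is exact to 16-bit
#' quantization. Requires the `tiff` package.
#'
#' @param images list of [contrast_image]s.
#' @param dir output directory (created if needed).
#' @return `write_images`: invisibly, the file names. `read_images`: a
#'   list of [contrast_image]s.
#' @export
write_images <- function(images, dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the `tiff` package is required for TIFF export", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lo <- min(vapply(images, min, numeric(1)))
  hi <- max(vapply(images, max, numeric(1)))
  if (hi <= lo) hi <- lo + 1
  files <- sprintf("image_%04d.tif", seq_along(images))
  for (i in seq_along(images)) {
    z <- (unclass(images[[i]]) - lo) / (hi - lo)
    tiff::writeTIFF(z, file.path(dir, files[i]), bits.per.sample = 16)
  }
  meta <- list(pixel_pitch = pixel_pitch(images[[1]]),
               contrast_min = lo, contrast_max = hi, files = files)
  jsonlite::write_json(meta, file.path(dir, "images.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' @rdname write_images
#' @export
read_images <- function(dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the `tiff` package is required for TIFF import", call. = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "images.json"),
                              simplifyVector = TRUE)
  lapply(meta$files, function(f) {
    z <- tiff::readTIFF(file.path(dir, f))
    contrast_image(z * (meta$contrast_max - meta$contrast_min) +
                     meta$contrast_min,
                   pixel_pitch = meta$pixel_pitch)
  })
}

#' Write and read spike-count tables as CSV
#'
#' Long format: `cell_id, image_id, trial, count` plus the counting
#' window in a header comment-free companion of the same name with
#' extension `.json`.
#'
#' @param table a [response_table].
#' @param path CSV file path.
#' @param cell_id identifier written with every row.
#' @return `write_counts`: invisibly, `path`. `read_counts`: a
#'   [response_table].
#' @export
write_counts <- function(table, path, cell_id = "cell1") {
  long <- data.frame(
    cell_id = cell_id,
    image_id = rep(seq_len(nrow(table)), times = ncol(table)),
    trial = rep(seq_len(ncol(table)), each = nrow(table)),
    count = as.vector(unclass(table)))
  write.csv(long, path, row.names = FALSE)
  jsonlite::write_json(list(count_window = attr(table, "count_window")),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  long <- read.csv(path)
  counts <- matrix(0L, max(long$image_id), max(long$trial))
  counts[cbind(long$image_id, long$trial)] <- long$count
  window <- c(0, 300)
  side <- paste0(path, ".json")
  if (file.exists(side))
    window <- unlist(jsonlite::read_json(side, simplifyVector = TRUE))
  response_table(counts, count_window = window)
}

#' Serialize a fitted encoding model to JSON
#'
#' @param model an `ln_model` or `sc_model`.
#' @param path JSON file path.
#' @return `write_model`: invisibly, `path`. `read_model`: the model.
#' @export
write_model <- function(model, path) {
  x <- unclass(model)
  x$class <- class(model)[1]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- x$class
  x$class <- NULL
  if (length(x$flags) == 0) x$flags <- character()
  structure(x, class = c(cls, "encoding_model"))
}

#' Export a Gaussian RF fit as a one-row data.frame / CSV
#'
#' Columns: `cell_id, mu_x, mu_y, s_xx, s_xy, s_yy, pixel_pitch,
#' diameter_um`.
#'
#' @param rf a [gaussian_rf].
#' @param path optional CSV path; when `NULL` the data.frame is returned
#'   only.
#' @param cell_id identifier.
#' @return The one-row data.frame, invisibly when writing.
#' @export
export_rf <- function(rf, path = NULL, cell_id = "cell1") {
  df <- data.frame(cell_id = cell_id,
                   mu_x = rf$mu[1], mu_y = rf$mu[2],
                   s_xx = rf$sigma[1, 1], s_xy = rf$sigma[1, 2],
                   s_yy = rf$sigma[2, 2],
                   pixel_pitch = rf$pixel_pitch,
                   diameter_um = effective_diameter(rf))
  if (!is.null(path)) {
    write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
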