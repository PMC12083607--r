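# Thermal image I/O.
#
# A thermal image is a plain numeric matrix of temperatures in degrees
# Celsius (rows x cols). Two on-disk dialects are supported: a headerless
# CSV of Celsius values, and a 16-bit single-band TIFF of centi-Kelvin
# (pixel value = Kelvin * 100), a common radiometric export format.

CENTIKELVIN_OFFSET <- 273.15

#' Read a thermal image from a CSV of Celsius values
#'
#' @param path Headerless CSV, one image row per line.
#' @return Numeric matrix of temperatures in degrees Celsius.
#' @export
read_thermal_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

#' Write a thermal image to a CSV of Celsius values
#' @param thermal Numeric matrix, degrees Celsius.
#' @param path Output path.
#' @export
write_thermal_csv <- function(thermal, path) {
  utils::write.table(thermal, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a centi-Kelvin 16-bit TIFF thermal image
#'
#' @param path Single-band TIFF whose integer pixel values are Kelvin x 100.
#' @return Numeric matrix of temperatures in degrees Celsius.
#' @export
read_thermal_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img / 100 - CENTIKELVIN_OFFSET
}

#' Write a thermal image as a centi-Kelvin 16-bit TIFF
#'
#' @inheritParams write_thermal_csv
#' @export
write_thermal_tiff <- function(thermal, path) {
  ck <- round((thermal + CENTIKELVIN_OFFSET) * 100)
  if (any(ck < 0 | ck > 65535)) {
    abort("Temperatures outside the representable centi-Kelvin range.",
          class = "thermoroi_io_error")
  }
  tiff::writeTIFF(ck / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
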