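#' Waveband table of the 18-channel multispectral instrument
#'
#' The instrument acquires reflectance at 18 fixed wavelengths between
#' 405 and 970 nm.  Bands are referred to throughout the package by their
#' 1-based index; this table is the (index, wavelength) bijection.
#'
#' @return A data frame with columns `index` (integer, 1-18) and
#'   `wavelength_nm` (numeric).
#' @examples
#' msi_wavebands()
#' @export
msi_wavebands <- function() {
  data.frame(
    index = 1:18,
    wavelength_nm = c(405, 435, 450, 470, 505, 525, 570, 590, 630,
                      645, 660, 700, 850, 870, 890, 910, 940, 970)
  )
}

#' Wavelength (nm) of a waveband index
#'
#' @param index integer vector of band indices in 1..18.
#' @return Numeric vector of wavelengths in nanometres.
#' @examples
#' waveband_nm(c(1, 12, 18))
#' @export
waveband_nm <- function(index) {
  index <- as.integer(index)
  if (any(is.na(index)) || any(index < 1L) || any(index > 18L)) {
    stop("waveband index must be an integer in 1..18", call. = FALSE)
  }
  msi_wavebands()$wavelength_nm[index]
}

# Column labels used in dataset files: Mean.01..Mean.18 / StdDev.01..StdDev.18.
feature_cols <- function(block = c("mean", "sd")) {
  block <- match.arg(block)
  prefix <- if (block == "mean") "Mean" else "StdDev"
  sprintf("%s.%02d", prefix, 1:18)
}
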