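#' Tumour / spheroid volume from calliper measurements
#'
#' Implements the printed quantification formula verbatim:
#' `volume = (length x width)^2 x 0.526`. Note this differs from the common
#' ellipsoid proxy `(width^2 x length)/2`; the published form is kept for
#' fidelity and is, like the printed formula, symmetric in length and
#' width.
#'
#' @param length,width Strictly positive measurements (mm).
#' @return Volume on the printed scale; vectorised.
#' @examples
#' tumour_volume(1, 1)   # 0.526
#' @export
tumour_volume <- function(length, width) {
  if (any(length <= 0) || any(width <= 0))
    stop("length and width must be strictly positive")
  (length * width)^2 * 0.526
}

#' DAB optical density from mean 8-bit intensity
#'
#' `OD = log10(max_intensity / mean_intensity)`, the optical-density
#' convention for immunohistochemistry densitometry on 8-bit images
#' (max intensity 255).
#'
#' @param mean_intensity Mean DAB-channel intensity, in `(0, max_intensity]`.
#' @param max_intensity Saturation value (default 255 for 8-bit images).
#' @return Optical density; vectorised.
#' @examples
#' dab_od(25.5)   # 1
#' @export
dab_od <- function(mean_intensity, max_intensity = 255) {
  if (any(mean_intensity <= 0))
    stop("mean intensity must be positive (saturated/empty field)")
  if (any(mean_intensity > max_intensity))
    stop("mean intensity exceeds the maximum intensity")
  log10(max_intensity / mean_intensity)
}
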