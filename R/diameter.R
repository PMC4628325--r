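#' Effective diameter of a lesion from its volume
#'
#' The effective diameter is the diameter of the sphere whose volume equals
#' the measured nodule volume: `d = 2 * (3 V / (4 pi))^(1/3)`.
#'
#' @param volume_cm3 Lesion volume(s) in cm^3 (> 0).
#' @return Effective diameter(s) in mm.
#' @examples
#' effective_diameter(4 * pi / 3) # unit-radius sphere: 20 mm
#' @export
effective_diameter <- function(volume_cm3) {
  abort_if(any(volume_cm3 <= 0), "`volume_cm3` must be positive")
  # cm -> mm
  10 * 2 * (3 * volume_cm3 / (4 * pi))^(1 / 3)
}

#' Volume of the sphere with a given effective diameter
#'
#' Inverse of [effective_diameter()].
#'
#' @param diameter_mm Effective diameter(s) in mm (> 0).
#' @return Volume(s) in cm^3.
#' @examples
#' volume_from_diameter(10)
#' @export
volume_from_diameter <- function(diameter_mm) {
  abort_if(any(diameter_mm <= 0), "`diameter_mm` must be positive")
  d_cm <- diameter_mm / 10
  (4 / 3) * pi * (d_cm / 2)^3
}

#' Convert a volume ratio to the equivalent effective-diameter ratio
#'
#' For spheres of equal shape, diameter scales as the cube root of volume, so
#' a volume ratio `v` corresponds to a diameter ratio `v^(1/3)`.
#'
#' @param v_ratio Volume ratio(s) (> 0).
#' @return Diameter ratio(s).
#' @examples
#' volume_ratio_to_diameter_ratio(0.65) # ~0.866, a 13 % diameter decrease
#' @export
volume_ratio_to_diameter_ratio <- function(v_ratio) {
  abort_if(any(v_ratio <= 0), "`v_ratio` must be positive")
  v_ratio^(1 / 3)
}

#' Convert an effective-diameter ratio to the equivalent volume ratio
#'
#' Inverse of [volume_ratio_to_diameter_ratio()]: `v = d^3`. Applying it to
#' the RECIST diameter thresholds (-30 %, +20 %) gives volume changes of
#' about -66 % and +73 %.
#'
#' @param d_ratio Diameter ratio(s) (> 0).
#' @return Volume ratio(s).
#' @examples
#' diameter_ratio_to_volume_ratio(c(0.7, 1.2))
#' @export
diameter_ratio_to_volume_ratio <- function(d_ratio) {
  abort_if(any(d_ratio <= 0), "`d_ratio` must be positive")
  d_ratio^3
}

#' Effective-diameter response thresholds from volume thresholds
#'
#' Maps a volumetric threshold set to the effective-diameter scale (cube
#' roots of the unrounded critical ratios, then integer percent rounding),
#' for comparison with RECIST's one-dimensional -30 %/+20 % thresholds. At
#' the default volume thresholds the stable region on the diameter scale is
#' about (-14 %, +16 %), strictly inside RECIST's.
#'
#' @param thresholds A [response_thresholds()] object (default: the package
#'   default thresholds).
#' @return A tibble with one row per boundary: `boundary`, `volume_ratio`,
#'   `diameter_ratio`, `volume_pct`, `diameter_pct` (integer percent, rounded
#'   half away from zero).
#' @examples
#' diameter_thresholds()
#' @export
diameter_thresholds <- function(thresholds = response_thresholds()) {
  th <- as_thresholds(thresholds)
  v <- c(th$lower_ratio, th$upper_ratio)
  d <- volume_ratio_to_diameter_ratio(v)
  tibble::tibble(
    boundary = c("lower", "upper"),
    volume_ratio = v,
    diameter_ratio = d,
    volume_pct = as.integer(round_half_out(100 * (v - 1))),
    diameter_pct = as.integer(round_half_out(100 * (d - 1)))
  )
}
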