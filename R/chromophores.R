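#' Wavelength grid used by the packaged chromophore compilation
#'
#' The seven-point grid spanning the diagnostic window, 450-1050 nm in
#' 100 nm steps.
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
dpf_wavelengths <- function() seq(450, 1050, by = 100)

#' Chromophore absorption library
#'
#' Absorption coefficients (1/mm) of the tissue chromophores used to build
#' layer absorption spectra: water, deoxyhemoglobin and oxyhemoglobin (whole
#' blood at 150 g hemoglobin / L), and a flat residual "baseline" absorber
#' standing in for everything not modelled explicitly.  Values are a
#' literature-standard compilation at the seven grid wavelengths (water after
#' the Segelstein-type tabulations; hemoglobin from Prahl-type molar
#' extinction converted at 2.33 mM heme protein).  Every column can be
#' overridden, so alternative compilations can be swapped in without touching
#' the transport code.
#'
#' @param wavelengths Wavelength grid in nm. Only the default seven-point
#'   grid has packaged values; supplying a different grid requires supplying
#'   every spectrum explicitly.
#' @param mua_water,mua_hb,mua_hbo2,mua_other Optional replacement spectra
#'   (1/mm, one value per wavelength).
#' @return A `data.frame` of class `chromophore_library` with columns
#'   `wavelength`, `mua_water`, `mua_hb`, `mua_hbo2`, `mua_other`.
#' @examples
#' lib <- chromophore_library()
#' lib[lib$wavelength == 850, ]
#' @export
chromophore_library <- function(wavelengths = dpf_wavelengths(),
                                mua_water = NULL, mua_hb = NULL,
                                mua_hbo2 = NULL, mua_other = NULL) {
  grid <- dpf_wavelengths()
  if (is.null(mua_water) || is.null(mua_hb) || is.null(mua_hbo2) ||
      is.null(mua_other)) {
    if (!identical(as.numeric(wavelengths), as.numeric(grid)))
      stop("packaged spectra exist only on the 450-1050 nm / 100 nm grid; ",
           "supply all four spectra for a custom grid", call. = FALSE)
  }
  # whole blood, 150 g Hb/L: mua [1/mm] = ln(10) * eps [1/cm/M] * 2.3256e-3 / 10
  eps_to_mua <- log(10) * 150 / 64500 / 10
  eps_hbo2 <- c(62816, 43016, 368, 562, 1058, 1204, 1080)
  eps_hb   <- c(100000, 53412, 3750, 1405, 691, 502, 380)
  defaults <- list(
    mua_water = c(9.22e-6, 5.65e-5, 3.40e-4, 2.60e-3, 4.30e-3, 3.88e-2, 1.70e-2),
    mua_hb    = eps_hb * eps_to_mua,
    mua_hbo2  = eps_hbo2 * eps_to_mua,
    mua_other = rep(0.01, 7)
  )
  pick <- function(user, name) {
    v <- if (is.null(user)) defaults[[name]] else as.numeric(user)
    if (length(v) != length(wavelengths))
      stop(sprintf("'%s' must have one value per wavelength", name),
           call. = FALSE)
    if (any(!is.finite(v)) || any(v < 0))
      stop(sprintf("'%s' must be finite and non-negative", name),
           call. = FALSE)
    v
  }
  out <- data.frame(
    wavelength = as.numeric(wavelengths),
    mua_water = pick(mua_water, "mua_water"),
    mua_hb = pick(mua_hb, "mua_hb"),
    mua_hbo2 = pick(mua_hbo2, "mua_hbo2"),
    mua_other = pick(mua_other, "mua_other")
  )
  class(out) <- c("chromophore_library", "data.frame")
  out
}

lib_row <- function(lib, wavelength) {
  i <- which(abs(lib$wavelength - wavelength) < 1e-9)
  if (length(i) != 1)
    stop(sprintf("wavelength %g nm is not on the library grid (%s); ",
                 wavelength, paste(lib$wavelength, collapse = ", ")),
         "no interpolation is performed", call. = FALSE)
  lib[i, ]
}

#' Melanin absorption coefficient
#'
#' Power-law melanin absorption, `C_mel * lambda^exponent` with the packaged
#' constants `C_mel = 6.6e10` and exponent `-3.33` (lambda in nm, result in
#' 1/mm).  Published versions of this law differ in the leading constant by
#' an order of magnitude depending on the units convention, so the constant
#' is exposed as an argument.
#'
#' @param wavelength Wavelength in nm, within 450-1050.
#' @param c_mel Leading constant of the power law.
#' @param exponent Power-law exponent.
#' @return Absorption coefficient in 1/mm.
#' @examples
#' melanin_mua(450)   # about 97 / mm
#' @export
melanin_mua <- function(wavelength, c_mel = 6.6e10, exponent = -3.33) {
  if (any(wavelength < 450 | wavelength > 1050))
    stop("wavelength must lie within the supported 450-1050 nm range",
         call. = FALSE)
  c_mel * wavelength^exponent
}

#' Epidermis absorption coefficient
#'
#' Volume-fraction mixture for the melanin-bearing epidermis:
#' `v_mel * mua_mel + v_water * mua_mid + (1 - v_mel - v_water) * mua_other`.
#' The spectrum multiplying the water fraction is selectable: `"water"`
#' (the physically sensible choice, default) or `"hbo2"` (oxyhemoglobin,
#' reproducing the source model's printed mixture verbatim).  Both are kept
#' because the printed formula pairs the water volume fraction with an
#' oxyhemoglobin spectrum, which is almost certainly a misprint.
#'
#' @param wavelength Wavelength in nm (library grid point).
#' @param v_mel Melanin volume fraction in `[0, 1]`.
#' @param v_water Water volume fraction in `[0, 1]`; `v_mel + v_water <= 1`.
#' @param lib A [chromophore_library()].
#' @param middle_term Spectrum paired with `v_water`: `"water"` or `"hbo2"`.
#' @param c_mel,exponent Passed to [melanin_mua()].
#' @return Absorption coefficient in 1/mm.
#' @export
epidermis_mua <- function(wavelength, v_mel, v_water,
                          lib = chromophore_library(),
                          middle_term = c("water", "hbo2"),
                          c_mel = 6.6e10, exponent = -3.33) {
  middle_term <- match.arg(middle_term)
  check_fraction(v_mel, "v_mel")
  check_fraction(v_water, "v_water")
  if (v_mel + v_water > 1 + 1e-12)
    stop("v_mel + v_water must not exceed 1", call. = FALSE)
  row <- lib_row(lib, wavelength)
  mid <- if (middle_term == "water") row$mua_water else row$mua_hbo2
  v_mel * melanin_mua(wavelength, c_mel, exponent) +
    v_water * mid +
    (1 - (v_mel + v_water)) * row$mua_other
}

#' Layer absorption coefficient
#'
#' Absorption of a skin layer from its blood, water and melanin volume
#' fractions.  Melanin-bearing layers (`v_mel > 0`) use the epidermis
#' mixture; all other layers use the standard blend
#' `v_blood * (S * mua_HbO2 + (1 - S) * mua_Hb) + v_water * mua_water +
#' remainder * mua_other`, with `S` the blood oxygen saturation carried by
#' the layer (default 0.75).
#'
#' @param layer A [layer_spec()].
#' @param wavelength Wavelength in nm (library grid point).
#' @param lib A [chromophore_library()].
#' @param middle_term Epidermis option, see [epidermis_mua()].
#' @return Absorption coefficient in 1/mm.
#' @export
layer_mua <- function(layer, wavelength, lib = chromophore_library(),
                      middle_term = c("water", "hbo2")) {
  stopifnot(inherits(layer, "layer_spec"))
  middle_term <- match.arg(middle_term)
  if (layer$v_mel > 0)
    return(epidermis_mua(wavelength, layer$v_mel, layer$v_water, lib,
                         middle_term))
  row <- lib_row(lib, wavelength)
  s <- layer$oxygen_saturation
  mua_blood <- s * row$mua_hbo2 + (1 - s) * row$mua_hb
  layer$v_blood * mua_blood +
    layer$v_water * row$mua_water +
    (1 - (layer$v_blood + layer$v_water)) * row$mua_other
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single fraction in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}
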