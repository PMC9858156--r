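#' Specify one tissue layer
#'
#' @param name Layer name.
#' @param thickness Layer thickness in mm, strictly positive.  The bottom
#'   layer may additionally be extended to a semi-infinite half-space at
#'   simulation time (see [run_transport()]).
#' @param mus Scattering coefficient spectrum, 1/mm, one value per library
#'   grid wavelength.
#' @param g Henyey-Greenstein anisotropy factor, `|g| < 1`.
#' @param n Refractive index, `>= 1`.
#' @param v_blood,v_water,v_mel Volume fractions in `[0, 1]`,
#'   `v_blood + v_water + v_mel <= 1`.  `v_mel` should be non-zero only for
#'   the epidermis.
#' @param oxygen_saturation Blood oxygen saturation fraction `S` in `[0, 1]`.
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(name, thickness, mus, g = 0.9, n = 1.37,
                       v_blood = 0, v_water = 0, v_mel = 0,
                       oxygen_saturation = 0.75) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop("layer 'name' must be a non-empty string", call. = FALSE)
  if (!is.numeric(thickness) || length(thickness) != 1 || thickness <= 0)
    stop(sprintf("layer '%s': thickness must be strictly positive", name),
         call. = FALSE)
  if (any(!is.finite(mus)) || any(mus < 0))
    stop(sprintf("layer '%s': mus must be finite and non-negative", name),
         call. = FALSE)
  if (abs(g) >= 1)
    stop(sprintf("layer '%s': anisotropy |g| must be < 1", name),
         call. = FALSE)
  if (n < 1)
    stop(sprintf("layer '%s': refractive index must be >= 1", name),
         call. = FALSE)
  check_fraction(v_blood, "v_blood")
  check_fraction(v_water, "v_water")
  check_fraction(v_mel, "v_mel")
  check_fraction(oxygen_saturation, "oxygen_saturation")
  if (v_blood + v_water + v_mel > 1 + 1e-12)
    stop(sprintf("layer '%s': v_blood + v_water + v_mel must not exceed 1",
                 name), call. = FALSE)
  structure(list(name = name, thickness = thickness, mus = as.numeric(mus),
                 g = g, n = n, v_blood = v_blood, v_water = v_water,
                 v_mel = v_mel, oxygen_saturation = oxygen_saturation),
            class = "layer_spec")
}

#' Assemble a layered skin model
#'
#' @param layers List of [layer_spec()] objects, top layer first.
#' @param n_ambient Refractive index of the medium above the surface
#'   (default air, 1.0).
#' @param wavelengths Wavelength grid (nm) on which the layer `mus` spectra
#'   are tabulated.
#' @return An object of class `skin_model`.
#' @export
skin_model <- function(layers, n_ambient = 1.0,
                       wavelengths = dpf_wavelengths()) {
  if (!length(layers) || !all(vapply(layers, inherits, TRUE, "layer_spec")))
    stop("'layers' must be a non-empty list of layer_spec objects",
         call. = FALSE)
  nw <- length(wavelengths)
  for (l in layers)
    if (length(l$mus) != nw)
      stop(sprintf("layer '%s': mus has %d values but the grid has %d",
                   l$name, length(l$mus), nw), call. = FALSE)
  if (n_ambient < 1) stop("n_ambient must be >= 1", call. = FALSE)
  m <- structure(list(layers = layers, n_ambient = n_ambient,
                      wavelengths = as.numeric(wavelengths)),
                 class = "skin_model")
  stopifnot(all(diff(layer_depths(m)) > 0))   # strictly increasing interfaces
  m
}

#' @export
print.skin_model <- function(x, ...) {
  cat(sprintf("<skin_model> %d layers, n_ambient = %g\n",
              length(x$layers), x$n_ambient))
  d <- layer_depths(x)
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  %-22s z = %-6.4g-%-7.4g mm  g=%.2f n=%.2f Vb=%.2g Vw=%.2g Vmel=%.2g\n",
                l$name, d[i], d[i + 1], l$g, l$n, l$v_blood, l$v_water,
                l$v_mel))
  }
  invisible(x)
}

#' Depths of the layer interfaces
#'
#' @param model A [skin_model()].
#' @return Numeric vector of interface depths (mm), starting at 0.
#' @export
layer_depths <- function(model) {
  cumsum(c(0, vapply(model$layers, `[[`, 0, "thickness")))
}

#' Layer names of a model
#' @param model A [skin_model()].
#' @return Character vector.
#' @export
layer_names <- function(model) {
  vapply(model$layers, `[[`, "", "name")
}

#' The default seven-layer skin model
#'
#' The packaged stack: stratum corneum, epidermis, papillary dermis, upper
#' blood net dermis, reticular dermis, deep blood net dermis and subcutaneous
#' tissue, with the standard thicknesses (0.02, 0.25, 0.1, 0.08, 0.2, 0.3,
#' 2 mm), a shared scattering spectrum (60.61, 41.74, 22.33, 15.05, 13.32,
#' 9.5, 7.52 1/mm at 450-1050 nm) and the blood/water volume fractions of the
#' source compilation.  Only the epidermis carries melanin; its volume
#' fraction is the argument (0.02 for light and 0.20 for dark skin in the
#' replication setting).
#'
#' @param melanin_fraction Epidermal melanin volume fraction in `[0, 1]`.
#' @param g Anisotropy applied to every layer.
#' @param n Refractive index applied to every layer.
#' @param oxygen_saturation Blood oxygen saturation for all perfused layers.
#' @param n_ambient Ambient refractive index.
#' @return A [skin_model()] with seven layers.
#' @examples
#' m <- build_default_model(0.02)
#' layer_names(m)
#' @export
build_default_model <- function(melanin_fraction = 0.02, g = 0.9, n = 1.37,
                                oxygen_saturation = 0.75, n_ambient = 1.0) {
  check_fraction(melanin_fraction, "melanin_fraction")
  mus <- c(60.61, 41.74, 22.33, 15.05, 13.32, 9.5, 7.52)
  tab <- data.frame(
    name = c("stratum_corneum", "epidermis", "papillary_dermis",
             "upper_blood_net_dermis", "reticular_dermis",
             "deep_blood_net_dermis", "subcutaneous_tissue"),
    thickness = c(0.02, 0.25, 0.1, 0.08, 0.2, 0.3, 2),
    v_blood = c(0, 0, 0.04, 0.3, 0.04, 0.1, 0.05),
    v_water = c(0.05, 0.2, 0.5, 0.6, 0.7, 0.7, 0.7),
    stringsAsFactors = FALSE
  )
  layers <- lapply(seq_len(nrow(tab)), function(i) {
    layer_spec(tab$name[i], tab$thickness[i], mus = mus, g = g, n = n,
               v_blood = tab$v_blood[i], v_water = tab$v_water[i],
               v_mel = if (tab$name[i] == "epidermis") melanin_fraction else 0,
               oxygen_saturation = oxygen_saturation)
  })
  skin_model(layers, n_ambient = n_ambient)
}

#' Wavelength-resolved optical properties of a model
#'
#' Evaluates absorption from the chromophore mixtures and looks up the
#' scattering spectrum for every layer at one grid wavelength.
#'
#' @param model A [skin_model()].
#' @param wavelength Wavelength in nm (library grid point).
#' @param lib A [chromophore_library()].
#' @param middle_term Epidermis mixture option, see [epidermis_mua()].
#' @return `data.frame` with columns `layer`, `thickness`, `mua`, `mus`,
#'   `g`, `n`.
#' @export
model_optical_properties <- function(model, wavelength,
                                     lib = chromophore_library(),
                                     middle_term = c("water", "hbo2")) {
  stopifnot(inherits(model, "skin_model"))
  middle_term <- match.arg(middle_term)
  iw <- which(abs(model$wavelengths - wavelength) < 1e-9)
  if (length(iw) != 1)
    stop(sprintf("wavelength %g nm is not on the model grid", wavelength),
         call. = FALSE)
  data.frame(
    layer = layer_names(model),
    thickness = vapply(model$layers, `[[`, 0, "thickness"),
    mua = vapply(model$layers, layer_mua, 0, wavelength = wavelength,
                 lib = lib, middle_term = middle_term),
    mus = vapply(model$layers, function(l) l$mus[iw], 0),
    g = vapply(model$layers, `[[`, 0, "g"),
    n = vapply(model$layers, `[[`, 0, "n"),
    stringsAsFactors = FALSE
  )
}
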