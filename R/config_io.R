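#' Read a skin model from a YAML/JSON configuration
#'
#' The schema mirrors [skin_model()]: top-level `n_ambient`, `wavelengths`,
#' and an ordered `layers` list in which each entry carries every
#' [layer_spec()] field; an optional `chromophores` block (wavelength-keyed
#' columns) overrides the packaged [chromophore_library()].  Validation is
#' strict and error messages name the offending field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `model` (a [skin_model()]) and `lib`
#'   (a [chromophore_library()], packaged defaults if not overridden).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$layers) || !length(cfg$layers))
    stop("config field 'layers' is missing or empty", call. = FALSE)
  wl <- if (is.null(cfg$wavelengths)) dpf_wavelengths()
        else as.numeric(cfg$wavelengths)
  need <- function(lyr, field, i) {
    if (is.null(lyr[[field]]))
      stop(sprintf("layer %d ('%s'): required field '%s' is missing",
                   i, if (is.null(lyr$name)) "?" else lyr$name, field),
           call. = FALSE)
    lyr[[field]]
  }
  layers <- lapply(seq_along(cfg$layers), function(i) {
    ly <- cfg$layers[[i]]
    layer_spec(
      name = need(ly, "name", i),
      thickness = need(ly, "thickness", i),
      mus = as.numeric(need(ly, "mus", i)),
      g = if (is.null(ly$g)) 0.9 else ly$g,
      n = if (is.null(ly$n)) 1.37 else ly$n,
      v_blood = if (is.null(ly$v_blood)) 0 else ly$v_blood,
      v_water = if (is.null(ly$v_water)) 0 else ly$v_water,
      v_mel = if (is.null(ly$v_mel)) 0 else ly$v_mel,
      oxygen_saturation =
        if (is.null(ly$oxygen_saturation)) 0.75 else ly$oxygen_saturation)
  })
  model <- skin_model(layers,
                      n_ambient = if (is.null(cfg$n_ambient)) 1.0
                                  else cfg$n_ambient,
                      wavelengths = wl)
  lib <- if (is.null(cfg$chromophores)) chromophore_library()
  else {
    ch <- cfg$chromophores
    for (f in c("wavelength", "mua_water", "mua_hb", "mua_hbo2", "mua_other"))
      if (is.null(ch[[f]]))
        stop(sprintf("chromophores block: required column '%s' is missing", f),
             call. = FALSE)
    chromophore_library(as.numeric(ch$wavelength),
                        mua_water = as.numeric(ch$mua_water),
                        mua_hb = as.numeric(ch$mua_hb),
                        mua_hbo2 = as.numeric(ch$mua_hbo2),
                        mua_other = as.numeric(ch$mua_other))
  }
  list(model = model, lib = lib)
}

#' Write a skin model to a YAML configuration
#'
#' @param model A [skin_model()].
#' @param path Output path.
#' @param lib Optional [chromophore_library()] to embed.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path, lib = NULL) {
  stopifnot(inherits(model, "skin_model"))
  cfg <- list(
    n_ambient = model$n_ambient,
    wavelengths = model$wavelengths,
    layers = lapply(model$layers, function(l) l[c(
      "name", "thickness", "mus", "g", "n", "v_blood", "v_water", "v_mel",
      "oxygen_saturation")])
  )
  if (!is.null(lib))
    cfg$chromophores <- as.list(as.data.frame(lib))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Path to a packaged model fixture
#'
#' `skin_2pct.yaml` and `skin_20pct.yaml` hold the default seven-layer stack
#' with 2% and 20% epidermal melanin.
#'
#' @param name Fixture file name.
#' @return Full path to the installed fixture.
#' @export
model_fixture <- function(name = c("skin_2pct.yaml", "skin_20pct.yaml")) {
  name <- match.arg(name)
  system.file("extdata", name, package = "skindpf", mustWork = TRUE)
}
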