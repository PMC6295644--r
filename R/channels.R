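#' Predictor channel vocabulary
#'
#' The prediction models draw on 18 non-invasive channels measured at
#' 0.1 Hz: 10 non-insulated skin temperatures, 4 insulated skin
#' temperatures (scapula, sternum, rib, radial artery), 3 skin heat
#' fluxes (scapula, rib, sternum) and heart rate. Rectal temperature is
#' the invasive reference channel. Channels are named
#' `<modality>_<site>`; heart rate and rectal temperature carry no site.
#'
#' @param modality One of `"skin_temp"`, `"insulated_skin_temp"`,
#'   `"heat_flux"`, `"heart_rate"`, `"rectal_temp"`.
#' @param site Body-site label (e.g. `"scapula"`), or `NA` for heart
#'   rate / rectal temperature.
#' @return `channel_spec()` returns a `"channel_spec"` object with
#'   fields `modality`, `site`, `units` and `name`.
#' @examples
#' channel_spec("heat_flux", "sternum")
#' predictor_channels()
#' @export
channel_spec <- function(modality, site = NA_character_) {
  modality <- match.arg(modality, c("skin_temp", "insulated_skin_temp",
                                    "heat_flux", "heart_rate", "rectal_temp"))
  if (modality %in% c("heart_rate", "rectal_temp")) site <- NA_character_
  units <- switch(modality,
                  heat_flux = "W/m2",
                  heart_rate = "beats/min",
                  "degC")
  structure(list(modality = modality, site = site, units = units,
                 name = channel_name(modality, site)),
            class = "channel_spec")
}

channel_name <- function(modality, site) {
  if (is.na(site) || !nzchar(site)) modality else paste(modality, site, sep = "_")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("<channel %s [%s]>\n", x$name, x$units))
  invisible(x)
}

#' @rdname channel_spec
#' @return `predictor_channels()` returns the character vector of the 18
#'   predictor channel names, in the canonical table order.
#' @export
predictor_channels <- function() {
  c("skin_temp_scapula", "skin_temp_forearm", "skin_temp_radial",
    "skin_temp_thigh", "skin_temp_calf", "skin_temp_hand",
    "skin_temp_arm", "skin_temp_sternum", "skin_temp_rib",
    "insulated_skin_temp_rib", "skin_temp_forehead",
    "insulated_skin_temp_radial", "insulated_skin_temp_scapula",
    "insulated_skin_temp_sternum",
    "heart_rate",
    "heat_flux_scapula", "heat_flux_rib", "heat_flux_sternum")
}

#' @rdname channel_spec
#' @return `all_channels()` returns the 18 predictors plus `rectal_temp`.
#' @export
all_channels <- function() c(predictor_channels(), "rectal_temp")

#' @param name A channel name of the form `<modality>_<site>`.
#' @rdname channel_spec
#' @export
parse_channel_name <- function(name) {
  modalities <- c("insulated_skin_temp", "skin_temp", "heat_flux",
                  "heart_rate", "rectal_temp")
  for (m in modalities) {
    if (name == m) return(channel_spec(m))
    if (startsWith(name, paste0(m, "_"))) {
      return(channel_spec(m, substring(name, nchar(m) + 2L)))
    }
  }
  stop("not a recognised channel name: ", name, call. = FALSE)
}

is_heat_flux <- function(name) startsWith(name, "heat_flux")
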