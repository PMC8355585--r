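#' Reducing-end derivatization presets and custom tags
#'
#' A derivatization describes what is added to a glycan's residue (dehydro)
#' sum to obtain the neutral analyte, per labeling channel. For duplex
#' stable-isotope labeling the light and heavy channels differ by a fixed
#' delta mass (e.g. d0/d2 tags at about 2 Da, or combined
#' \eqn{^{18}}O + deuterium labels at about 3 Da).
#'
#' Presets:
#' \describe{
#'   \item{`"free end"`}{underivatized released glycan; light = H2O, no
#'     heavy channel.}
#'   \item{`"reduced end"`}{borohydride-reduced alditol; light = H2O + H2.}
#'   \item{`"2-AB"`}{2-aminobenzamide by reductive amination; light =
#'     H2O + C7H8N2 (net +120.0687 over the free glycan).}
#'   \item{`"PFBHA"`}{pentafluorobenzyl-hydroxylamine oxime tag; light
#'     adds C7H4F5NO, heavy is the d2 form (delta 2.0126 Da).}
#'   \item{`"GREDIL"`}{reduction-based label incorporating one
#'     \eqn{^{18}}O and one deuterium (delta 3.0105 Da over the alditol).}
#' }
#'
#' @param name Preset name (case-insensitive) or a label for a custom tag.
#' @param light,heavy For a custom tag: element map (formula string or
#'   named count vector) of the net addition per channel. `D` and `O18`
#'   denote the label isotopes.
#' @param light_mass,heavy_mass Alternative bare mass deltas in Da for
#'   custom tags defined without an element map.
#' @return An object of class `glyq_derivatization` with fields `name`,
#'   `light`, `heavy` (element maps or `NULL`), `light_mass`, `heavy_mass`
#'   and `delta_mass` (heavy minus light; `NA` if no heavy channel).
#' @examples
#' derivatization("PFBHA")$delta_mass
#' derivatization("custom d0/d2", light = "H2O", heavy = "OD2")$delta_mass
#' @export
derivatization <- function(name, light = NULL, heavy = NULL,
                           light_mass = NULL, heavy_mass = NULL) {
  presets <- list(
    "free end"    = list(light = "H2O", heavy = NULL),
    "reduced end" = list(light = "H4O", heavy = NULL),
    "2-ab"        = list(light = "C7H10N2O", heavy = NULL),
    "pfbha"       = list(light = "C7H4F5NO", heavy = "C7H2D2F5NO"),
    "gredil"      = list(light = "H4O", heavy = "H3DO18")
  )
  key <- tolower(name)
  if (is.null(light) && is.null(light_mass)) {
    if (!key %in% names(presets)) {
      stop("unknown derivatization preset '", name, "'; presets: ",
           paste(c("free end", "reduced end", "2-AB", "PFBHA", "GREDIL"),
                 collapse = ", "), call. = FALSE)
    }
    light <- presets[[key]]$light
    heavy <- presets[[key]]$heavy
  }
  if (!is.null(light)) {
    light <- as_elements(light)
    light_mass <- element_mass(light)
  }
  if (!is.null(heavy)) {
    heavy <- as_elements(heavy)
    heavy_mass <- element_mass(heavy)
  }
  stopifnot(is.numeric(light_mass))
  delta <- if (is.null(heavy_mass)) NA_real_ else heavy_mass - light_mass
  structure(
    list(name = name, light = light, heavy = heavy,
         light_mass = light_mass, heavy_mass = heavy_mass,
         delta_mass = delta),
    class = "glyq_derivatization"
  )
}

#' @export
print.glyq_derivatization <- function(x, ...) {
  cat("<derivatization> ", x$name, "\n", sep = "")
  cat("  light: +", format(x$light_mass, nsmall = 6), " Da",
      if (!is.null(x$light)) paste0(" (", format_formula(x$light), ")"), "\n",
      sep = "")
  if (!is.null(x$heavy_mass)) {
    cat("  heavy: +", format(x$heavy_mass, nsmall = 6), " Da",
        if (!is.null(x$heavy)) paste0(" (", format_formula(x$heavy), ")"),
        "  delta ", format(x$delta_mass, digits = 7), " Da\n", sep = "")
  }
  invisible(x)
}

deriv_channel_mass <- function(deriv, channel = c("light", "heavy")) {
  channel <- match.arg(channel)
  m <- if (channel == "light") deriv$light_mass else deriv$heavy_mass
  if (is.null(m)) {
    stop("derivatization '", deriv$name, "' has no heavy channel",
         call. = FALSE)
  }
  m
}
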