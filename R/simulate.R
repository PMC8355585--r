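#' Specify a synthetic labeled glycan mixture
#'
#' Describes a duplex (or light-only) mixture of glycans for spectrum
#' synthesis, emulating MALDI-MS stable-isotope-labeling experiments:
#' each member is a composition with an adduct and a heavy:light mixing
#' ratio; the derivatization supplies the light/heavy label chemistry and
#' the exact label delta mass.
#'
#' @param members Tibble/data frame with columns `composition`, `adduct`
#'   (preset name), optional `ratio_hl` (heavy:light, default 1; 0 means
#'   light only) and optional `scale` (light-channel base intensity,
#'   default 100).
#' @param deriv A [derivatization()] object; needs a heavy channel when
#'   any `ratio_hl > 0`.
#' @param charge Charge state of all rendered ions (default 1).
#' @param fwhm Profile peak full width at half maximum at `mz_ref`, Th
#'   (default 0.1, a typical reflectron MALDI-TOF at m/z 1000); scales
#'   linearly with m/z.
#' @param mz_ref Reference m/z for `fwhm` (default 1000).
#' @param noise_sd Additive Gaussian intensity noise (profile rendering),
#'   standard deviation in intensity units.
#' @param baseline Constant baseline intensity (profile rendering).
#' @param seed RNG seed; a fixed seed makes rendering bit-identical.
#' @return List of class `glyq_mixture`.
#' @export
mixture_spec <- function(members, deriv = derivatization("PFBHA"),
                         charge = 1, fwhm = 0.1, mz_ref = 1000,
                         noise_sd = 0, baseline = 0, seed = 1L) {
  members <- tibble::as_tibble(members)
  if (!"ratio_hl" %in% names(members)) members$ratio_hl <- 1
  if (!"scale" %in% names(members)) members$scale <- 100
  stopifnot(all(members$ratio_hl >= 0), all(members$scale > 0),
            charge >= 1, fwhm > 0)
  if (any(members$ratio_hl > 0) && is.na(deriv$delta_mass)) {
    stop("derivatization '", deriv$name,
         "' has no heavy channel; heavy:light ratios must be 0",
         call. = FALSE)
  }
  structure(list(members = members, deriv = deriv, charge = charge,
                 fwhm = fwhm, mz_ref = mz_ref, noise_sd = noise_sd,
                 baseline = baseline, seed = as.integer(seed)),
            class = "glyq_mixture")
}

#' Render a mixture as a centroid (stick) spectrum
#'
#' Places each member's theoretical isotope pattern at its exact
#' theoretical m/z offsets (spacing 1.0033548/z). Heavy-channel sticks
#' sit at the light m/z plus the exact label delta over charge -- not the
#' rounded delta -- reproducing the true mass relationship of deuterium /
#' \eqn{^{18}}O labels. Sticks coinciding within 1e-4 Th are summed.
#' Deterministic (no noise in stick mode).
#'
#' @param mix A [mixture_spec()].
#' @return Centroid `glyq_spectrum` tibble (`mz`, `intensity`).
#' @export
render_sticks <- function(mix) {
  z <- mix$charge
  sticks <- purrr::pmap_dfr(mix$members,
    function(...) {
      row <- list(...)
      composition <- row$composition
      ratio_hl <- row$ratio_hl
      scale <- row$scale
      add <- adduct(row$adduct)
      ## the ion pattern includes the charge-carrier atoms (41K matters)
      el <- ion_elements(residue_elements(composition), mix$deriv, add, z)
      pat <- as.numeric(isotope_pattern(el))
      neutral <- residue_mass(composition) + mix$deriv$light_mass
      mono <- theoretical_mz(neutral, add, z)
      offs <- (seq_along(pat) - 1) * ISOTOPE_SPACING / z
      light <- tibble::tibble(mz = mono + offs, intensity = scale * pat)
      if (ratio_hl > 0) {
        heavy_mono <- mono + mix$deriv$delta_mass / z
        heavy <- tibble::tibble(mz = heavy_mono + offs,
                                intensity = scale * ratio_hl * pat)
        dplyr::bind_rows(light, heavy)
      } else light
    })
  sticks <- dplyr::arrange(sticks, .data$mz)
  ## sum sticks coincident within 1e-4 Th
  grp <- cumsum(c(TRUE, diff(sticks$mz) > 1e-4))
  merged <- sticks |>
    dplyr::group_by(grp = grp) |>
    dplyr::summarise(mz = sum(.data$mz * .data$intensity) /
                       sum(.data$intensity),
                     intensity = sum(.data$intensity), .groups = "drop") |>
    dplyr::select("mz", "intensity")
  new_spectrum(merged$mz, merged$intensity, mode = "centroid",
               source = "synthetic sticks")
}

#' Render a mixture as a profile spectrum
#'
#' Each stick becomes a Gaussian of the same height, with sigma derived
#' from the FWHM at the reference m/z and scaled linearly with m/z,
#' sampled on a uniform grid; a constant baseline and seeded Gaussian
#' noise (clipped at zero) are added.
#'
#' @param mix A [mixture_spec()].
#' @param grid_step Sampling step in Th; must be smaller than the
#'   narrowest peak sigma (error otherwise: undersampled).
#' @param pad m/z margin around the outermost sticks (default 3 Th).
#' @return Profile `glyq_spectrum`.
#' @export
render_profile <- function(mix, grid_step = 0.01, pad = 3) {
  sticks <- render_sticks(mix)
  sigma <- (mix$fwhm / (2 * sqrt(2 * log(2)))) * sticks$mz / mix$mz_ref
  if (grid_step >= min(sigma)) {
    stop("grid_step ", grid_step, " >= minimum peak sigma ",
         signif(min(sigma), 4), ": undersampled", call. = FALSE)
  }
  grid <- seq(min(sticks$mz) - pad, max(sticks$mz) + pad, by = grid_step)
  y <- rep(mix$baseline, length(grid))
  for (i in seq_len(nrow(sticks))) {
    lo <- findInterval(sticks$mz[i] - 6 * sigma[i], grid) + 1L
    hi <- findInterval(sticks$mz[i] + 6 * sigma[i], grid)
    if (hi < lo) next
    idx <- lo:hi
    y[idx] <- y[idx] + sticks$intensity[i] *
      exp(-(grid[idx] - sticks$mz[i])^2 / (2 * sigma[i]^2))
  }
  if (mix$noise_sd > 0) {
    y <- withr::with_seed(mix$seed,
                          y + stats::rnorm(length(y), sd = mix$noise_sd))
    y <- pmax(y, 0)
  }
  new_spectrum(grid, y, mode = "profile", source = "synthetic profile")
}

#' Write a spectrum in the ASCII two-column format the reader consumes
#'
#' @param spectrum A `glyq_spectrum`.
#' @param path Output file.
#' @param digits Significant digits for m/z and intensity (default 10).
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(spectrum, path, digits = 10) {
  writeLines(paste(format(spectrum$mz, digits = digits, trim = TRUE,
                          scientific = FALSE),
                   format(spectrum$intensity, digits = digits,
                          trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}
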