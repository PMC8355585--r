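#' Run the full quantitation pipeline on one spectrum
#'
#' Chains every stage: read (if given a path), noise estimation,
#' centroiding (profile mode), mass calibration, envelope detection,
#' exhaustive glycan matching and -- when a label delta is set --
#' light/heavy pairing with overlap-calibrated ratios.
#'
#' @param x A `glyq_spectrum` or a path to an ASCII peak list.
#' @param config A [search_config()].
#' @return List of class `glyq_run` with elements `spectrum`, `peaks`,
#'   `envelopes`, `matches`, `pairs` (or `NULL` when `delta_mass = 0`),
#'   `noise`, `config`, `source`.
#' @examples
#' db <- glycan_db("human", bounds = c(hex = 5, hexnac = 4, dhex = 1, sialic = 0))
#' mix <- mixture_spec(tibble::tibble(composition = "Hex3HexNAc2",
#'                                    adduct = "Na+", ratio_hl = 5))
#' cfg <- search_config(db = db, deriv = derivatization("PFBHA"),
#'                      noise_level = 0)
#' run <- run_pipeline(render_sticks(mix), cfg)
#' run$pairs[, c("composition", "ratio_HL", "flag")]
#' @export
run_pipeline <- function(x, config = search_config()) {
  src <- if (is.character(x)) x else attr(x, "source") %||% "spectrum"
  spectrum <- if (is.character(x)) read_peaklist(x, mode = config$mode) else x
  noise <- config$noise_level %||%
    estimate_noise(spectrum, method = config$noise_method,
                   coefficient = config$noise_coefficient)
  peaks <- if (spectrum_mode(spectrum) == "profile") {
    pick_peaks(spectrum, noise = noise, min_points = config$min_points)
  } else {
    dplyr::mutate(tibble::as_tibble(spectrum),
                  snr = if (noise > 0) .data$intensity / noise else Inf)
  }
  envelopes <- detect_envelopes(peaks, max_charge = config$max_charge,
                                spacing_tol = config$spacing_tol,
                                min_isotopes = config$min_isotopes,
                                snr_min = config$snr_min) |>
    apply_mass_calibration(config$calibration_offset)
  matches <- match_glycans(envelopes, config)
  pairs <- if (config$delta_mass > 0 && nrow(matches)) {
    pair_light_heavy(matches, envelopes, config)
  } else NULL
  structure(list(spectrum = spectrum, peaks = peaks,
                 envelopes = envelopes, matches = matches, pairs = pairs,
                 noise = noise, config = config, source = src),
            class = "glyq_run")
}

#' @export
print.glyq_run <- function(x, ...) {
  cat("<glyquant run> ", x$source, "\n", sep = "")
  cat("  ", nrow(x$peaks), " peaks, ", nrow(x$envelopes), " envelopes, ",
      nrow(x$matches), " matches",
      if (!is.null(x$pairs)) paste0(", ",
                                    sum(x$pairs$flag == "ok"), " pairs"),
      "\n", sep = "")
  invisible(x)
}

#' One-row summary of a pipeline run
#' @param x A `glyq_run`.
#' @param ... Unused.
#' @return Tibble with peak/envelope/match/pair counts and the noise
#'   level.
#' @exportS3Method generics::glance
glance.glyq_run <- function(x, ...) {
  tibble::tibble(
    source = x$source, n_peaks = nrow(x$peaks),
    n_envelopes = nrow(x$envelopes), n_matches = nrow(x$matches),
    n_pairs = if (is.null(x$pairs)) NA_integer_ else
      sum(x$pairs$flag == "ok"),
    noise = x$noise
  )
}

#' Tidy the quantitation result of a run
#'
#' @param x A `glyq_run`.
#' @param ... Unused.
#' @return The pair table when the run had a label delta, otherwise the
#'   match table.
#' @exportS3Method generics::tidy
tidy.glyq_run <- function(x, ...) {
  if (!is.null(x$pairs)) x$pairs else x$matches
}
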