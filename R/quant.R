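#' Pair light and heavy channel matches and compute calibrated ratios
#'
#' Matches with identical (composition, adduct, charge) and opposite
#' channel tags are paired when their observed monoisotopic separation
#' equals `delta_mass / charge` within the ppm tolerance. When the label
#' delta is small, the light channel's +round(delta) isotopologue sits
#' under the heavy channel's quantitation peak; the ratio is therefore
#' calibrated by subtracting that theoretical contribution (see
#' [calibrated_ratio()]).
#'
#' When no standalone heavy envelope was detected -- the usual situation
#' in profile data, where the overlapped heavy monoisotopic peak merges
#' with the light isotopologue into one centroid consumed by the light
#' envelope -- the heavy partner is recovered from the light envelope's
#' own intensity ladder at offset `quant_offset + round(delta)`, provided
#' that intensity exceeds the light channel's predicted contribution by
#' more than 2% (otherwise the match is reported unpaired, as for a
#' light-only sample).
#'
#' @param matches Match tibble from [match_glycans()].
#' @param envelopes The envelope tibble the matches refer to.
#' @param config The [search_config()] used (needs `delta_mass > 0`).
#' @return Pair tibble: one row per light match, with `intensity_light`,
#'   `intensity_heavy`, `calibr_ratio`, `ratio_raw`, `ratio_LH`,
#'   `ratio_HL`, `paired_mz` (observed heavy mono m/z), and `flag`
#'   (`"ok"`, `"unpaired"`, or `"overlap_dominated"`).
#' @export
pair_light_heavy <- function(matches, envelopes, config) {
  if (config$delta_mass <= 0) {
    stop("pairing requires delta_mass > 0", call. = FALSE)
  }
  lights <- dplyr::filter(matches, .data$channel == "L")
  heavies <- dplyr::filter(matches, .data$channel == "H")
  d_off <- round_half_away(config$delta_mass)
  env_by_id <- split(envelopes, envelopes$envelope)

  purrr::map_dfr(seq_len(nrow(lights)), function(i) {
    L <- lights[i, ]
    base <- dplyr::select(L, "envelope", "composition", "formula",
                          "free_mass", "adduct", "charge", "channel",
                          "theoretical_mz", "observed_mz", "error_ppm",
                          "quant_isotope")
    pat <- ion_pattern(L$formula, L$adduct, L$charge, config)
    calibr <- if (L$quant_offset + 1L <= length(pat)) {
      overlap_fraction(pat, L$quant_offset, d_off)
    } else 0

    tol_da <- config$tolerance_ppm * 1e-6 * L$observed_mz
    sep <- config$delta_mass / L$charge
    H <- dplyr::filter(heavies,
                       .data$composition == L$composition,
                       .data$adduct == L$adduct,
                       .data$charge == L$charge,
                       abs((.data$observed_mz - L$observed_mz) - sep) <=
                         tol_da)
    i_light <- L$quant_intensity
    if (nrow(H) >= 1) {
      H <- H[1, ]
      i_heavy <- H$quant_intensity
      paired_mz <- H$observed_mz
    } else {
      ## overlap-derived heavy: read the light envelope ladder
      env <- env_by_id[[as.character(L$envelope)]]
      idx <- L$quant_offset + d_off + 1L
      ladder <- env$intensity[[1]]
      expected_light <- i_light * calibr
      if (idx <= length(ladder) && ladder[idx] > expected_light * 1.02) {
        i_heavy <- ladder[idx]
        paired_mz <- env$peak_mz[[1]][idx]
        theo_h <- L$theoretical_mz + sep
        if (is.na(paired_mz) ||
            abs(paired_mz - theo_h) > config$tolerance_ppm * 1e-6 * theo_h) {
          return(dplyr::mutate(base, intensity_light = i_light,
                               intensity_heavy = NA_real_,
                               calibr_ratio = calibr,
                               ratio_raw = NA_real_, ratio_LH = NA_real_,
                               ratio_HL = NA_real_, paired_mz = NA_real_,
                               flag = "unpaired"))
        }
      } else {
        return(dplyr::mutate(base, intensity_light = i_light,
                             intensity_heavy = NA_real_,
                             calibr_ratio = calibr, ratio_raw = NA_real_,
                             ratio_LH = NA_real_, ratio_HL = NA_real_,
                             paired_mz = NA_real_, flag = "unpaired"))
      }
    }
    r <- calibrated_ratio(i_light, i_heavy, pat, L$quant_offset,
                          config$delta_mass)
    dplyr::mutate(base, intensity_light = i_light,
                  intensity_heavy = i_heavy, calibr_ratio = r$calibr_ratio,
                  ratio_raw = r$ratio_raw, ratio_LH = r$ratio_LH,
                  ratio_HL = r$ratio_HL, paired_mz = paired_mz,
                  flag = r$flag)
  })
}

round_half_away <- function(x) {
  s <- sign(x)
  s * floor(abs(x) + 0.5)
}

#' Overlap-calibrated light/heavy abundance ratio
#'
#' With a label spacing of `delta_mass` Da, the heavy channel's
#' quantitation peak carries, in addition to the heavy analyte, the light
#' analyte's isotopologue `round(delta_mass)` bins above its own
#' quantitation isotopologue. The calibrated ratio removes that
#' theoretical contribution:
#' \deqn{Ratio_{calibr} = \frac{I_{light}}{I_{heavy} - I_{light} \cdot
#'   calibr_{ratio}}}
#' \deqn{calibr_{ratio} = \frac{A[q + round(\Delta)]}{A[q]}}
#' where `A` is the light channel's theoretical isotope pattern and `q`
#' its quantitation offset. For noise-free data the correction is exact:
#' the measured heavy intensity is `r_H A[q] + r_L A[q + round(delta)]`,
#' and the subtracted term cancels the second summand exactly.
#'
#' @param intensity_light,intensity_heavy Measured channel intensities at
#'   the quantitation isotopologue (> 0).
#' @param pattern Light-channel theoretical isotope pattern of the full
#'   ion.
#' @param quant_offset 0-based quantitation isotopologue offset.
#' @param delta_mass Label spacing, Da (rounded half-away-from-zero to
#'   unit-mass bins).
#' @return List with `calibr_ratio`, `ratio_raw` (uncalibrated L/H),
#'   `ratio_LH` (calibrated light/heavy), `ratio_HL` (its reciprocal) and
#'   `flag` (`"ok"` or `"overlap_dominated"` when the corrected heavy
#'   intensity is not positive, in which case the ratios are `NA`).
#' @examples
#' calibrated_ratio(100, 120, c(1, 0.5, 0.2), 0, 2)$ratio_LH  # 1.0
#' @export
calibrated_ratio <- function(intensity_light, intensity_heavy, pattern,
                             quant_offset, delta_mass) {
  if (!isTRUE(intensity_light > 0) || !isTRUE(intensity_heavy > 0)) {
    return(list(calibr_ratio = NA_real_, ratio_raw = NA_real_,
                ratio_LH = NA_real_, ratio_HL = NA_real_,
                flag = "zero_intensity"))
  }
  d_off <- round_half_away(delta_mass)
  calibr <- overlap_fraction(pattern, quant_offset, d_off)
  denom <- intensity_heavy - intensity_light * calibr
  raw <- intensity_light / intensity_heavy
  if (denom <= 0) {
    return(list(calibr_ratio = calibr, ratio_raw = raw,
                ratio_LH = NA_real_, ratio_HL = NA_real_,
                flag = "overlap_dominated"))
  }
  lh <- intensity_light / denom
  list(calibr_ratio = calibr, ratio_raw = raw, ratio_LH = lh,
       ratio_HL = 1 / lh, flag = "ok")
}

#' Write the per-spectrum quantitation report
#'
#' Tab-separated table, one row per match, preceded by a `#`-prefixed
#' header block echoing every configuration value (reproducibility
#' contract). In identification-only runs (`delta_mass = 0`) the pairing
#' and ratio columns are left empty.
#'
#' @param matches Match tibble from [match_glycans()].
#' @param pairs Pair tibble from [pair_light_heavy()], or `NULL` for
#'   identification-only runs.
#' @param config The [search_config()] used.
#' @param path Output file path.
#' @param source_file Input file identity recorded in the first column.
#' @return `path`, invisibly.
#' @export
write_report <- function(matches, pairs, config, path,
                         source_file = NA_character_) {
  cols <- c("source_file", "composition", "derivatization", "adduct",
            "charge", "channel", "theoretical_mz", "observed_mz",
            "error_ppm", "quant_isotope", "intensity", "paired_mz",
            "intensity_light", "intensity_heavy", "calibr_ratio",
            "ratio_LH", "ratio_HL", "flag")
  tab <- dplyr::mutate(matches,
                       source_file = source_file,
                       derivatization = config$deriv$name,
                       intensity = .data$quant_intensity,
                       paired_mz = NA_real_, intensity_light = NA_real_,
                       intensity_heavy = NA_real_, calibr_ratio = NA_real_,
                       ratio_LH = NA_real_, ratio_HL = NA_real_,
                       flag = NA_character_)
  if (!is.null(pairs) && nrow(pairs) && config$delta_mass > 0) {
    key <- c("envelope", "composition", "adduct", "charge", "channel")
    tab <- dplyr::rows_update(
      tab,
      dplyr::select(pairs, dplyr::all_of(key), "paired_mz",
                    "intensity_light", "intensity_heavy", "calibr_ratio",
                    "ratio_LH", "ratio_HL", "flag"),
      by = key, unmatched = "ignore")
  }
  tab <- dplyr::select(tab, dplyr::all_of(cols))

  header <- c(
    paste0("# glyquant report"),
    paste0("# source_file = ", source_file),
    paste0("# tolerance_ppm = ", config$tolerance_ppm),
    paste0("# polarity = ", config$polarity),
    paste0("# adducts = ", paste(vapply(config$adducts, `[[`, "", "name"),
                                 collapse = ",")),
    paste0("# max_charge = ", config$max_charge),
    paste0("# derivatization = ", config$deriv$name),
    paste0("# delta_mass = ", config$delta_mass),
    paste0("# calibration_offset = ", config$calibration_offset),
    paste0("# snr_min = ", config$snr_min),
    paste0("# min_isotopes = ", config$min_isotopes),
    paste0("# spacing_tol = ", config$spacing_tol),
    paste0("# noise_method = ", config$noise_method),
    paste0("# noise_coefficient = ", config$noise_coefficient),
    paste0("# noise_level = ", config$noise_level %||% "estimated"),
    paste0("# min_points = ", config$min_points),
    paste0("# mode = ", config$mode),
    paste0("# database = ", paste(unique(config$db$source_db),
                                  collapse = ","),
           " (", nrow(config$db), " records)")
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(tab)) {
    cells <- vapply(tab, function(col) {
      out <- if (is.numeric(col)) {
        format(col, digits = 10, trim = TRUE, scientific = FALSE)
      } else as.character(col)
      ifelse(is.na(col), "", out)
    }, character(nrow(tab)))
    if (nrow(tab) == 1L) cells <- matrix(cells, nrow = 1)
    writeLines(apply(cells, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}
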