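#' Search configuration for glycan matching and quantitation
#'
#' Bundles the database and all matching parameters. Defaults are the
#' standard MALDI-TOF settings: 50 ppm tolerance, H+/Na+/K+ adducts,
#' positive mode, maximum charge 3, S/N 10, at least 3 isotopes per
#' envelope, no labeling delta (identification-only).
#'
#' @param db Glycan record tibble ([glycan_db()], [read_glycan_db()]).
#' @param tolerance_ppm Matching tolerance in ppm (> 0).
#' @param adducts List of [adduct()] objects; all must match `polarity`.
#' @param polarity `"positive"` or `"negative"`.
#' @param max_charge Maximum charge state searched.
#' @param deriv A [derivatization()] object.
#' @param delta_mass Light/heavy label spacing in Da; 0 means
#'   identification-only (no heavy channel search, no ratios). Defaults to
#'   the derivatization's own delta when it has a heavy channel.
#' @param calibration_offset Constant mass offset subtracted from observed
#'   m/z before matching (Da).
#' @param snr_min,min_isotopes,spacing_tol Envelope detection settings
#'   (see [detect_envelopes()]).
#' @param noise_method,noise_coefficient Noise estimation settings (see
#'   [estimate_noise()]); `noise_level` overrides estimation with a fixed
#'   value (use 0 for noise-free synthetic data).
#' @param noise_level Optional fixed noise level (`NULL` = estimate).
#' @param min_points Minimum profile points for Gaussian fitting.
#' @param mode Spectrum mode passed to [read_peaklist()].
#' @return A list of class `glyq_config`.
#' @export
search_config <- function(db = glycan_db(),
                          tolerance_ppm = 50,
                          adducts = default_adducts("positive"),
                          polarity = c("positive", "negative"),
                          max_charge = 3,
                          deriv = derivatization("free end"),
                          delta_mass = NULL,
                          calibration_offset = 0,
                          snr_min = 10, min_isotopes = 3,
                          spacing_tol = 0.05,
                          noise_method = "median", noise_coefficient = 2,
                          noise_level = NULL, min_points = 4,
                          mode = "auto") {
  polarity <- match.arg(polarity)
  stopifnot(tolerance_ppm > 0, max_charge >= 1)
  if (inherits(adducts, "glyq_adduct")) adducts <- list(adducts)
  pol <- vapply(adducts, function(a) a$polarity, character(1))
  if (any(pol != polarity)) {
    stop("adduct polarity mismatch with run polarity '", polarity, "'",
         call. = FALSE)
  }
  if (is.null(delta_mass)) {
    delta_mass <- if (is.na(deriv$delta_mass)) 0 else deriv$delta_mass
  }
  if (delta_mass < 0) stop("delta_mass must be >= 0", call. = FALSE)
  structure(
    list(db = db, tolerance_ppm = tolerance_ppm, adducts = adducts,
         polarity = polarity, max_charge = max_charge, deriv = deriv,
         delta_mass = delta_mass, calibration_offset = calibration_offset,
         snr_min = snr_min, min_isotopes = min_isotopes,
         spacing_tol = spacing_tol, noise_method = noise_method,
         noise_coefficient = noise_coefficient, noise_level = noise_level,
         min_points = min_points, mode = mode,
         cache = new.env(parent = emptyenv())),
    class = "glyq_config"
  )
}

## Candidate table: theoretical mono m/z for every (record, adduct,
## channel, charge). Heavy channel uses neutral light mass + delta_mass.
candidate_table <- function(config) {
  db <- config$db
  if (!nrow(db)) stop("empty glycan database", call. = FALSE)
  if (!is.null(config$cache$candidates)) return(config$cache$candidates)
  channels <- if (config$delta_mass > 0) c("L", "H") else "L"
  light_neutral <- db$residue_mass + config$deriv$light_mass
  cand <- purrr::map_dfr(config$adducts, function(add) {
    purrr::map_dfr(seq_len(config$max_charge), function(z) {
      purrr::map_dfr(channels, function(ch) {
        neutral <- light_neutral +
          if (ch == "H") config$delta_mass else 0
        tibble::tibble(
          composition = db$composition, formula = db$formula,
          free_mass = db$free_mass, residue_mass = db$residue_mass,
          adduct = add$name, charge = z, channel = ch,
          theoretical_mz = theoretical_mz(neutral, add, z)
        )
      })
    })
  })
  config$cache$candidates <- cand
  cand
}

#' Exhaustively match isotope envelopes against glycan candidates
#'
#' For each envelope's monoisotopic m/z, reports all (composition, adduct,
#' channel) combinations whose theoretical monoisotopic m/z lies within
#' the ppm tolerance -- all matches, not best-only; ambiguity is left to
#' downstream inspection. The heavy channel is searched only when
#' `delta_mass > 0`. Per envelope, matches are ranked by absolute ppm
#' error (ties toward lower free mass).
#'
#' The quantitation isotopologue of each match is the apex of the
#' theoretical pattern of the full ion (residues + light-channel tag +
#' adduct atoms); `quant_intensity` is the envelope's summed intensity at
#' that offset, falling back to the monoisotopic offset when the apex
#' peak is beyond the detected envelope.
#'
#' @param envelopes Envelope tibble from [detect_envelopes()] (after
#'   [apply_mass_calibration()] if used).
#' @param config A [search_config()].
#' @return Match tibble: `envelope`, `composition`, `free_mass`, `adduct`,
#'   `charge`, `channel` ("L"/"H"), `theoretical_mz`, `observed_mz`,
#'   `error_ppm`, `quant_offset` (0-based), `quant_isotope` (1-based),
#'   `quant_intensity`, `mono_intensity`, `rank`.
#' @export
match_glycans <- function(envelopes, config) {
  cand <- candidate_table(config)
  if (!nrow(envelopes)) return(empty_matches())
  hits <- purrr::map_dfr(seq_len(nrow(envelopes)), function(i) {
    env <- envelopes[i, ]
    sel <- cand$charge == env$charge &
      abs(cand$theoretical_mz - env$mono_mz) <=
        config$tolerance_ppm * 1e-6 * cand$theoretical_mz
    if (!any(sel)) return(NULL)
    dplyr::mutate(cand[sel, ],
                  envelope = env$envelope,
                  observed_mz = env$mono_mz,
                  error_ppm = (env$mono_mz - .data$theoretical_mz) /
                    .data$theoretical_mz * 1e6)
  })
  if (is.null(hits) || !nrow(hits)) return(empty_matches())

  ## quantitation offset/intensity from the light-channel ion pattern
  hits <- dplyr::mutate(
    hits,
    quant_offset = purrr::pmap_int(
      list(.data$formula, .data$adduct, .data$charge),
      function(f, a, z) ion_apex(f, a, z, config)),
    .row = dplyr::row_number())
  env_int <- stats::setNames(envelopes$intensity, envelopes$envelope)
  hits <- hits |>
    dplyr::mutate(
      quant_offset = purrr::map2_int(.data$quant_offset, .data$envelope,
        function(q, e) {
          if (q + 1L > length(env_int[[as.character(e)]])) 0L else q
        }),
      quant_intensity = purrr::map2_dbl(.data$quant_offset, .data$envelope,
        function(q, e) env_int[[as.character(e)]][q + 1L]),
      quant_isotope = .data$quant_offset + 1L,
      mono_intensity = purrr::map_dbl(.data$envelope,
        function(e) env_int[[as.character(e)]][1L])
    ) |>
    dplyr::arrange(.data$envelope, abs(.data$error_ppm), .data$free_mass) |>
    dplyr::group_by(.data$envelope) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select(-".row")
  dplyr::select(hits, "envelope", "composition", "formula", "free_mass",
                "residue_mass", "adduct", "charge", "channel",
                "theoretical_mz", "observed_mz", "error_ppm",
                "quant_offset", "quant_isotope", "quant_intensity",
                "mono_intensity", "rank")
}

empty_matches <- function() {
  tibble::tibble(envelope = integer(), composition = character(),
                 formula = character(), free_mass = numeric(),
                 residue_mass = numeric(), adduct = character(),
                 charge = integer(), channel = character(),
                 theoretical_mz = numeric(), observed_mz = numeric(),
                 error_ppm = numeric(), quant_offset = integer(),
                 quant_isotope = integer(), quant_intensity = numeric(),
                 mono_intensity = numeric(), rank = integer())
}

## Apex offset of the full-ion isotope pattern (light channel), cached
## per element signature within a session.
ion_apex <- function(formula, adduct_name, z, config) {
  attr(ion_pattern(formula, adduct_name, z, config), "apex")
}

## Elemental composition of the full light-channel ion: glycan residues +
## light tag + signed adduct atoms.
ion_elements <- function(residue_el, deriv, add, z) {
  el <- el_add(residue_el,
               if (!is.null(deriv$light)) deriv$light else numeric())
  sa <- scale_adduct(add, z)
  pos <- sa$elements[sa$elements > 0]
  if (length(pos)) el <- el_add(el, pos)
  neg <- sa$elements[sa$elements < 0]
  if (length(neg)) el <- el_subtract(el, -neg)
  el
}

ion_pattern <- function(formula, adduct_name, z, config) {
  add <- config$adducts[[match(adduct_name,
                               vapply(config$adducts, `[[`, "", "name"))]]
  el <- ion_elements(parse_formula(formula), config$deriv, add, z)
  key <- paste0(format_formula(el), "|", config$deriv$name)
  cached <- pattern_cache[[key]]
  if (!is.null(cached)) return(cached)
  p <- isotope_pattern(el)
  pattern_cache[[key]] <- p
  p
}

pattern_cache <- new.env(parent = emptyenv())
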