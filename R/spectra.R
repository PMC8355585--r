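#' Read an ASCII two-column peak list
#'
#' Parses the plain-text "m/z intensity" format that vendor software
#' exports (one pair per line; tab, space or comma separated; decimal
#' point only). Non-numeric lines (headers) and `#` comment lines are
#' skipped and counted; points are sorted by m/z; duplicate identical m/z
#' values are collapsed by summing intensities with a warning.
#'
#' @param path Path to the peak list file.
#' @param mode `"profile"`, `"centroid"` or `"auto"`. Auto classifies the
#'   file as profile when the median point spacing is below 0.1 Th and
#'   there are more than 5,000 points.
#' @return A tibble of class `glyq_spectrum` with columns `mz`,
#'   `intensity`, and attributes `mode`, `source` (file path) and
#'   `skipped` (count of skipped lines).
#' @export
read_peaklist <- function(path, mode = c("auto", "profile", "centroid")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_comment <- grepl("^\\s*#", lines)
  fields <- stringr::str_split(trimws(lines[!is_comment]), "[\\s,;]+")
  mz <- suppressWarnings(as.numeric(purrr::map_chr(fields, 1,
                                                   .default = NA)))
  ity <- suppressWarnings(as.numeric(purrr::map_chr(fields, 2,
                                                    .default = NA)))
  ok <- !is.na(mz) & !is.na(ity)
  skipped <- sum(is_comment) + sum(!ok)
  if (!any(ok)) stop("no numeric m/z-intensity rows in ", path,
                     call. = FALSE)
  new_spectrum(mz[ok], ity[ok], mode = mode, source = path,
               skipped = skipped)
}

new_spectrum <- function(mz, intensity, mode = "centroid", source = NA_character_,
                         skipped = 0L) {
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    warning("collapsed duplicate m/z values by summing intensities",
            call. = FALSE)
    intensity <- as.numeric(tapply(intensity, match(mz, unique(mz)), sum))
    mz <- unique(mz)
  }
  if (any(intensity < 0)) stop("negative intensities", call. = FALSE)
  if (mode == "auto") {
    spacing <- stats::median(diff(mz))
    mode <- if (length(mz) > 5000 && isTRUE(spacing < 0.1)) "profile" else
      "centroid"
  }
  structure(tibble::tibble(mz = mz, intensity = intensity),
            mode = mode, source = source, skipped = skipped,
            class = c("glyq_spectrum", class(tibble::tibble())))
}

spectrum_mode <- function(spectrum) attr(spectrum, "mode") %||% "centroid"

#' Estimate the spectrum noise level
#'
#' Noise is the median (or mean) of all nonzero intensities multiplied by
#' a predefined coefficient; peaks are later filtered on
#' signal-to-noise = intensity / noise.
#'
#' @param spectrum A `glyq_spectrum` (or any data frame with `intensity`).
#' @param method `"median"` (robust, default) or `"mean"`.
#' @param coefficient Positive multiplier (default 2).
#' @return Noise level (0 with a warning if all intensities are zero).
#' @export
estimate_noise <- function(spectrum, method = c("median", "mean"),
                           coefficient = 2) {
  method <- match.arg(method)
  stopifnot(coefficient > 0, nrow(spectrum) > 0)
  v <- spectrum$intensity[spectrum$intensity > 0]
  if (!length(v)) {
    warning("all intensities are zero; noise level 0", call. = FALSE)
    return(0)
  }
  coefficient * if (method == "median") stats::median(v) else mean(v)
}

#' Centroid a profile spectrum by Gaussian fitting
#'
#' Local maxima above the noise level seed peak windows that extend while
#' intensity decreases on either side. Each window with at least
#' `min_points` points is fitted with a Gaussian by a log-parabola least
#' squares on the upper part of the peak (exact for a noise-free
#' Gaussian); the fitted mean and height become the centroid m/z and
#' intensity. If the fit fails or the window is too small, an
#' intensity-weighted centroid is used instead.
#'
#' @param spectrum Profile-mode `glyq_spectrum`.
#' @param noise Noise level used both as the detection floor and as the
#'   reference for `snr`.
#' @param min_points Minimum points in a window for Gaussian fitting
#'   (default 4).
#' @return Centroid peak tibble with `mz`, `intensity`, `snr` (intensity /
#'   noise; `Inf` when `noise` is 0), sorted by m/z.
#' @export
pick_peaks <- function(spectrum, noise = estimate_noise(spectrum),
                       min_points = 4) {
  if (spectrum_mode(spectrum) != "profile") {
    stop("pick_peaks() expects a profile-mode spectrum", call. = FALSE)
  }
  mz <- spectrum$mz; y <- spectrum$intensity
  n <- length(y)
  if (n < 3) return(tibble::tibble(mz = numeric(), intensity = numeric(),
                                   snr = numeric()))
  apex <- which(y > noise & y > 0)
  apex <- apex[apex > 1 & apex < n]
  apex <- apex[y[apex] >= y[apex - 1] & y[apex] > y[apex + 1]]
  ## split suppression: adjacent maxima separated only by a shallow valley
  ## (noise ripple on one physical peak) collapse onto the taller one
  repeat {
    if (length(apex) < 2) break
    valley <- vapply(seq_len(length(apex) - 1), function(k) {
      min(y[apex[k]:apex[k + 1]])
    }, numeric(1))
    shallow <- which(valley >= 0.8 * pmin(y[apex[-length(apex)]],
                                          y[apex[-1]]))
    if (!length(shallow)) break
    k <- shallow[1]
    drop <- if (y[apex[k]] >= y[apex[k + 1]]) k + 1 else k
    apex <- apex[-drop]
  }
  out <- purrr::map_dfr(apex, function(i) {
    lo <- i
    while (lo > 1 && y[lo - 1] < y[lo]) lo <- lo - 1
    hi <- i
    while (hi < n && y[hi + 1] < y[hi]) hi <- hi + 1
    fit_gaussian_window(mz[lo:hi], y[lo:hi], min_points)
  })
  if (!nrow(out)) return(tibble::tibble(mz = numeric(),
                                        intensity = numeric(),
                                        snr = numeric()))
  out |>
    dplyr::mutate(snr = if (noise > 0) .data$intensity / noise else Inf) |>
    dplyr::arrange(.data$mz)
}

fit_gaussian_window <- function(x, y, min_points) {
  centroid <- function() {
    tibble::tibble(mz = sum(x * y) / sum(y), intensity = max(y))
  }
  if (length(x) < min_points) return(centroid())
  ## log-parabola fit on the top of the peak: for y = h*exp(-(x-m)^2/2s^2),
  ## log y is an exact quadratic in x
  top <- y >= 0.2 * max(y) & y > 0
  if (sum(top) < 3) return(centroid())
  fit <- tryCatch(stats::lm(log(y[top]) ~ x[top] + I(x[top]^2)),
                  error = function(e) NULL)
  if (is.null(fit)) return(centroid())
  b <- stats::coef(fit)
  if (any(!is.finite(b)) || b[3] >= 0) return(centroid())
  mu <- -b[2] / (2 * b[3])
  h <- exp(b[1] - b[2]^2 / (4 * b[3]))
  if (!is.finite(mu) || mu < min(x) || mu > max(x) || !is.finite(h)) {
    return(centroid())
  }
  tibble::tibble(mz = unname(mu), intensity = unname(h))
}

#' Group centroid peaks into charge-assigned isotope envelopes
#'
#' Greedy left-to-right deisotoping after signal filtration: peaks below
#' `snr_min` are discarded up front (they would otherwise bridge bogus
#' chains at fractional spacings). Each surviving unconsumed peak seeds
#' candidate chains at spacings 1.0033548/z for z = 1..`max_charge`; at
#' each step the peak closest to the expected grid position (within
#' `spacing_tol`) continues the chain. The longest chain wins (ties
#' toward lower charge); chains shorter than `min_isotopes` are
#' discarded; member peaks are consumed and cannot seed further
#' envelopes, but envelope intensities are read from all surviving peaks
#' near the grid, so overlapping envelopes share intensity.
#'
#' The per-offset intensity (`intensity` list column) is the sum of all
#' peak intensities within `spacing_tol` of the envelope grid position --
#' this is what a quantitation step should read, since co-eluting species
#' closer than the tolerance are indistinguishable at MALDI-TOF
#' resolution.
#'
#' @param peaks Centroid peak tibble (`mz`, `intensity`, optionally `snr`;
#'   sorted by m/z).
#' @param max_charge Maximum charge state to consider (default 3).
#' @param spacing_tol Allowed deviation from the theoretical isotope
#'   spacing, Th (default 0.05).
#' @param min_isotopes Minimum peaks per envelope (default 3).
#' @param snr_min Signal-to-noise threshold; peaks below it are removed
#'   before deisotoping (default 10).
#' @return Envelope tibble with `envelope` (id), `charge`, `mono_mz`,
#'   `mono_intensity`, `n_peaks`, and list columns `peak_mz` (member
#'   centroid m/z per offset) and `intensity` (per-offset summed
#'   intensity, offset 0 first).
#' @export
detect_envelopes <- function(peaks, max_charge = 3, spacing_tol = 0.05,
                             min_isotopes = 3, snr_min = 10) {
  stopifnot(max_charge >= 1, spacing_tol > 0, min_isotopes >= 1)
  if (is.unsorted(peaks$mz)) stop("peaks must be sorted by m/z",
                                  call. = FALSE)
  ## signal filtration: sub-S/N peaks take no part in deisotoping (they
  ## would otherwise bridge bogus chains at fractional spacings)
  snr <- if ("snr" %in% names(peaks)) peaks$snr else rep(Inf, nrow(peaks))
  keep <- snr >= snr_min
  mz <- peaks$mz[keep]; ity <- peaks$intensity[keep]; snr <- snr[keep]
  n <- length(mz)
  consumed <- rep(FALSE, n)
  envs <- list()
  for (i in seq_len(n)) {
    if (consumed[i]) next
    best <- NULL
    for (z in seq_len(max_charge)) {
      members <- i
      k <- 1L
      repeat {
        expected <- mz[i] + k * ISOTOPE_SPACING / z
        j <- nearest_peak(mz, expected, spacing_tol)
        if (is.na(j)) break
        members <- c(members, j)
        k <- k + 1L
      }
      if (is.null(best) || length(members) > length(best$members)) {
        best <- list(z = z, members = members)
      }
    }
    if (length(best$members) < min_isotopes) next
    consumed[best$members] <- TRUE
    grid <- mz[i] + (seq_along(best$members) - 1L) * ISOTOPE_SPACING / best$z
    by_offset <- vapply(grid, function(g) {
      sum(ity[abs(mz - g) <= spacing_tol])
    }, numeric(1))
    envs[[length(envs) + 1L]] <- tibble::tibble(
      charge = best$z, mono_mz = mz[i], mono_intensity = by_offset[1],
      mono_snr = snr[i], n_peaks = length(best$members),
      peak_mz = list(mz[best$members]), intensity = list(by_offset)
    )
  }
  out <- dplyr::bind_rows(envs)
  if (!nrow(out)) {
    return(tibble::tibble(envelope = integer(), charge = integer(),
                          mono_mz = numeric(), mono_intensity = numeric(),
                          mono_snr = numeric(), n_peaks = integer(),
                          peak_mz = list(), intensity = list()))
  }
  dplyr::mutate(out, envelope = dplyr::row_number(), .before = 1)
}

nearest_peak <- function(mz, expected, tol) {
  lo <- findInterval(expected - tol, mz) + 1L
  hi <- findInterval(expected + tol, mz)
  if (hi < lo) return(NA_integer_)
  cand <- lo:hi
  cand[which.min(abs(mz[cand] - expected))]
}

#' Shift envelope m/z values by a fixed calibration offset
#'
#' Corrects a constant instrumental mass offset before matching: every
#' m/z is shifted by `-offset` (a spectrum reading 0.05 Th high is fixed
#' with `offset = 0.05`).
#'
#' @param envelopes Envelope tibble from [detect_envelopes()].
#' @param offset Calibration offset in Da (default 0).
#' @return Envelope tibble with shifted `mono_mz` and `peak_mz`.
#' @export
apply_mass_calibration <- function(envelopes, offset = 0) {
  stopifnot(is.finite(offset))
  if (offset == 0) return(envelopes)
  dplyr::mutate(envelopes,
                mono_mz = .data$mono_mz - offset,
                peak_mz = purrr::map(.data$peak_mz, ~ .x - offset))
}
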