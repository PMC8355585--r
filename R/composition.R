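#' Parse a glycan composition string
#'
#' Reads the canonical composition notation
#' `HexAHexNAcBdHexCNeuAcDNeuGcE` (zero-count classes omitted) into
#' monosaccharide counts. The five classes are hexose (Hex),
#' N-acetylhexosamine (HexNAc), deoxyhexose/fucose (dHex),
#' N-acetylneuraminic acid (NeuAc) and N-glycolylneuraminic acid (NeuGc).
#'
#' @param x Character vector of composition strings, e.g. `"Hex3HexNAc2"`.
#' @return A tibble with one row per input and integer columns
#'   `hex`, `hexnac`, `dhex`, `neuac`, `neugc`.
#' @examples
#' parse_composition(c("Hex3HexNAc2", "Hex5HexNAc4NeuAc2"))
#' @export
parse_composition <- function(x) {
  stopifnot(is.character(x))
  pat <- "(HexNAc|NeuAc|NeuGc|dHex|Hex)([0-9]+)"
  rows <- lapply(x, function(s) {
    m <- stringr::str_match_all(s, pat)[[1]]
    if (nrow(m) == 0 || sum(nchar(m[, 1])) != nchar(s) ||
        anyDuplicated(m[, 2])) {
      stop("cannot parse composition '", s, "'", call. = FALSE)
    }
    counts <- stats::setNames(rep(0L, 5), names(MONO_NAMES))
    key <- names(MONO_NAMES)[match(m[, 2], MONO_NAMES)]
    counts[key] <- as.integer(m[, 3])
    tibble::as_tibble_row(as.list(counts))
  })
  dplyr::bind_rows(rows)
}

#' Format monosaccharide counts as a canonical composition string
#'
#' Classes appear in the fixed order Hex, HexNAc, dHex, NeuAc, NeuGc and
#' zero-count classes are omitted, so formatting round-trips through
#' [parse_composition()].
#'
#' @param hex,hexnac,dhex,neuac,neugc Non-negative integer count vectors
#'   (recycled to a common length).
#' @return Character vector of composition strings.
#' @export
format_composition <- function(hex = 0, hexnac = 0, dhex = 0,
                               neuac = 0, neugc = 0) {
  len <- max(length(hex), length(hexnac), length(dhex),
             length(neuac), length(neugc))
  counts <- lapply(list(hex, hexnac, dhex, neuac, neugc), rep_len, len)
  if (any(unlist(counts) < 0)) stop("negative monosaccharide count", call. = FALSE)
  purrr::pmap_chr(counts, function(...) {
    n <- c(...)
    if (all(n == 0)) stop("empty composition", call. = FALSE)
    paste0(MONO_NAMES[n > 0], n[n > 0], collapse = "")
  })
}

#' Elemental composition of a glycan residue sum
#'
#' Element-wise sum of the dehydro residue formulas
#' Hex = C6H10O5, HexNAc = C8H13NO5, dHex = C6H10O4, NeuAc = C11H17NO8,
#' NeuGc = C11H17NO9.
#'
#' @param composition A composition string or a one-row data frame / named
#'   list with counts `hex`, `hexnac`, `dhex`, `neuac`, `neugc`.
#' @return Named element-count vector.
#' @examples
#' residue_elements("Hex3HexNAc2")
#' @export
residue_elements <- function(composition) {
  cc <- composition_counts(composition)
  el <- numeric(0)
  for (k in names(RESIDUE_FORMULA)) {
    if (cc[[k]] > 0) el <- el_add(el, RESIDUE_FORMULA[[k]] * cc[[k]])
  }
  el
}

#' Monoisotopic residue (dehydro) mass of a glycan composition
#' @inheritParams residue_elements
#' @return Mass in Da.
#' @export
residue_mass <- function(composition) {
  cc <- composition_counts(composition)
  sum(vapply(names(RESIDUE_FORMULA),
             function(k) cc[[k]] * element_mass(RESIDUE_FORMULA[[k]]),
             numeric(1)))
}

composition_counts <- function(composition) {
  if (is.character(composition)) {
    composition <- parse_composition(composition)
  }
  composition <- as.list(composition)
  cc <- stats::setNames(as.list(rep(0L, 5)), names(MONO_NAMES))
  for (k in intersect(names(composition), names(cc))) {
    v <- composition[[k]]
    stopifnot(length(v) == 1, v >= 0)
    cc[[k]] <- as.integer(v)
  }
  cc
}
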