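#' Theoretical isotope pattern of an elemental composition
#'
#' Computes the aggregated (unit-mass-binned) isotopologue distribution by
#' per-element binomial/multinomial expansion convolved across elements.
#' Offset 0 is the monoisotopic species; successive offsets are spaced at
#' 1.0033548 Da (the 13C-12C difference) per charge when placed on the m/z
#' axis. The label pseudo-elements `D` and `O18` are treated as
#' isotopically pure and contribute no spread.
#'
#' Entries at kept offsets are exact: truncating the tail of a
#' convolution of non-negative series never changes lower-offset terms.
#'
#' @param elements Element-count vector or formula string (a glycan
#'   composition string such as `"Hex3HexNAc2"` is also accepted and is
#'   interpreted as the residue-sum elements plus H2O, i.e. the free
#'   glycan).
#' @param max_offsets Maximum number of isotopologue bins to compute
#'   (default 15).
#' @param normalize `"max"` (most abundant isotopologue = 1, default) or
#'   `"sum"` (abundances sum to 1).
#' @param trim Relative abundance below which trailing offsets are dropped
#'   (default 1e-6 of the maximum).
#' @return Object of class `glyq_pattern`: a numeric abundance vector
#'   indexed by offset 0, 1, 2, ... with attributes `apex` (0-based offset
#'   of the most abundant isotopologue, ties toward lower offset) and
#'   `normalize`.
#' @examples
#' p <- isotope_pattern("C6H12O6")
#' apex_isotope(p)
#' @export
isotope_pattern <- function(elements, max_offsets = 15,
                            normalize = c("max", "sum"), trim = 1e-6) {
  normalize <- match.arg(normalize)
  stopifnot(max_offsets >= 1)
  el <- pattern_elements(elements)
  if (!length(el)) stop("empty elemental composition", call. = FALSE)
  if (any(el < 0)) stop("negative element counts", call. = FALSE)

  acc <- 1
  for (sym in names(el)) {
    p1 <- ISOTOPE_ABUNDANCE[[sym]]
    if (is.null(p1)) stop("unknown element symbol: ", sym, call. = FALSE)
    if (length(p1) > 1L && el[[sym]] > 0) {
      acc <- convolve_trunc(acc, vec_power(p1, el[[sym]], max_offsets),
                            max_offsets)
    }
  }
  acc <- as.numeric(acc)
  mx <- max(acc)
  keep <- max(which(acc >= trim * mx))
  acc <- acc[seq_len(keep)]
  ab <- if (normalize == "max") acc / mx else acc / sum(acc)
  structure(ab, apex = which.max(acc) - 1L, normalize = normalize,
            class = "glyq_pattern")
}

pattern_elements <- function(elements) {
  if (is.character(elements) && length(elements) == 1 &&
      grepl("(HexNAc|NeuAc|NeuGc|dHex|Hex)[0-9]+", elements)) {
    return(el_add(residue_elements(elements), "H2O"))
  }
  as_elements(elements)
}

## Truncated linear convolution of two abundance vectors.
convolve_trunc <- function(a, b, L) {
  n <- min(L, length(a) + length(b) - 1L)
  out <- numeric(n)
  for (i in seq_along(a)) {
    jmax <- min(length(b), n - i + 1L)
    if (jmax < 1L) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

## Distribution of n i.i.d. atoms: p convolved with itself n times,
## by exponentiation-by-squaring with tail truncation at L offsets.
vec_power <- function(p, n, L) {
  result <- 1
  base <- p
  while (n > 0) {
    if (n %% 2 == 1) result <- convolve_trunc(result, base, L)
    n <- n %/% 2
    if (n > 0) base <- convolve_trunc(base, base, L)
  }
  result
}

#' @export
print.glyq_pattern <- function(x, ...) {
  cat("<isotope pattern> ", length(x), " offsets, apex at offset ",
      attr(x, "apex"), " (isotope ", attr(x, "apex") + 1L, ")\n", sep = "")
  print(round(as.numeric(x), 6))
  invisible(x)
}

#' Most abundant isotopologue offset
#'
#' @param pattern A `glyq_pattern` or bare abundance vector (offset 0
#'   first).
#' @return 0-based offset of the maximum abundance; ties broken toward the
#'   lower offset.
#' @examples
#' apex_isotope(c(0.5, 1, 1))  # 1
#' @export
apex_isotope <- function(pattern) {
  stopifnot(length(pattern) >= 1)
  which.max(as.numeric(pattern)) - 1L
}

#' Isotopic overlap fraction used in ratio calibration
#'
#' Fraction of the light channel's theoretical abundance that falls on the
#' heavy channel's quantitation peak when the two channels are
#' `delta_offsets` unit-mass bins apart:
#' `abundance[quant_offset + delta_offsets] / abundance[quant_offset]`.
#' Returns 0 when the numerator offset lies beyond the pattern.
#'
#' @param pattern Isotope pattern (offset 0 first).
#' @param quant_offset 0-based offset of the quantitation isotopologue.
#' @param delta_offsets Rounded label delta mass in unit-mass bins (>= 1).
#' @return Overlap fraction (in `[0, 1]` when quantifying at the apex).
#' @export
overlap_fraction <- function(pattern, quant_offset, delta_offsets) {
  ab <- as.numeric(pattern)
  stopifnot(delta_offsets >= 1, quant_offset >= 0,
            quant_offset < length(ab))
  denom <- ab[quant_offset + 1L]
  if (denom == 0) stop("zero abundance at the quantitation offset",
                       call. = FALSE)
  i <- quant_offset + delta_offsets + 1L
  if (i > length(ab)) return(0)
  ab[i] / denom
}

#' Tabulate isotope patterns for a set of glycan records
#'
#' Convenience dump of unit-mass-binned patterns as a tidy table, one row
#' per (composition, offset).
#'
#' @param db Glycan record tibble (needs `composition` and `formula`).
#' @param ... Passed to [isotope_pattern()].
#' @return Tibble with `composition`, `isotope` (1-based), `offset`
#'   (0-based) and `abundance`.
#' @export
pattern_table <- function(db, ...) {
  purrr::map2_dfr(db$composition, db$formula, function(comp, f) {
    p <- isotope_pattern(f, ...)
    tibble::tibble(composition = comp, isotope = seq_along(p),
                   offset = seq_along(p) - 1L, abundance = as.numeric(p))
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an isotope pattern into a tibble
#' @param x A `glyq_pattern`.
#' @param ... Unused.
#' @return Tibble with `isotope` (1-based), `offset` (0-based),
#'   `abundance`, and logical `apex`.
#' @exportS3Method generics::tidy
tidy.glyq_pattern <- function(x, ...) {
  tibble::tibble(isotope = seq_along(x), offset = seq_along(x) - 1L,
                 abundance = as.numeric(x),
                 apex = (seq_along(x) - 1L) == attr(x, "apex"))
}
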