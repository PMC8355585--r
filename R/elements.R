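#' Parse a molecular formula string
#'
#' Converts a Hill-style formula such as `"C6H10O5"` into a named integer
#' vector of atom counts. The label pseudo-elements `D` (deuterium) and
#' `O18` (oxygen-18) are recognised alongside C, H, N, O, F, Na and K, so
#' heavy-channel label chemistry can be written directly
#' (e.g. `"C7H2D2F5NO"` for a d2 tag).
#'
#' @param formula Formula string. An omitted count means 1 (`"NO"` is one
#'   nitrogen and one oxygen).
#' @return Named numeric vector of atom counts (elements with count 0
#'   dropped).
#' @examples
#' parse_formula("C6H10O5")
#' parse_formula("C7H2D2F5NO")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  s <- gsub("\\s", "", formula)
  if (s == "") return(element_counts())
  ## longest symbols first so "O18" beats "O", "Na" beats "N"
  pat <- "(O18|Na|D|C|H|N|O|F|K)([0-9]*)"
  m <- stringr::str_match_all(s, pat)[[1]]
  if (sum(nchar(m[, 1])) != nchar(s)) {
    stop("cannot parse formula '", formula, "': unknown element symbol",
         call. = FALSE)
  }
  n <- ifelse(m[, 3] == "", 1L, suppressWarnings(as.integer(m[, 3])))
  element_counts(stats::setNames(as.numeric(n), m[, 2]))
}

#' Construct an element-count vector
#'
#' @param x Named numeric vector (element symbol -> atom count). Repeated
#'   symbols are summed; zero counts are dropped.
#' @return Named numeric vector in a canonical element order.
#' @export
element_counts <- function(x = numeric()) {
  if (length(x) == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  bad <- setdiff(names(x), SUPPORTED_ELEMENTS)
  if (length(bad)) {
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- tapply(unname(x), names(x), sum)
  out <- out[order(match(names(out), SUPPORTED_ELEMENTS))]
  out <- out[out != 0]
  stats::setNames(as.numeric(out), names(out))
}

#' Add element-count vectors
#' @param ... Named element-count vectors (or formula strings).
#' @return Combined element-count vector.
#' @export
el_add <- function(...) {
  parts <- lapply(list(...), as_elements)
  element_counts(unlist(parts))
}

#' Subtract element counts (`a - b`)
#'
#' Errors if any resulting count would be negative.
#' @param a,b Element-count vectors or formula strings.
#' @export
el_subtract <- function(a, b) {
  b <- as_elements(b)
  out <- el_add(a, stats::setNames(-unname(b), names(b)))
  if (any(out < 0)) {
    stop("element subtraction yields negative count(s): ",
         paste(names(out)[out < 0], collapse = ", "), call. = FALSE)
  }
  out
}

as_elements <- function(x) {
  if (is.character(x)) parse_formula(x) else element_counts(x)
}

#' Monoisotopic mass of an elemental composition
#'
#' Count-weighted sum of principal-isotope masses; `D` and `O18` contribute
#' their exact heavy-isotope masses.
#'
#' @param elements Named element-count vector or formula string.
#' @return Mass in Da.
#' @examples
#' element_mass("H2O")
#' @export
element_mass <- function(elements) {
  el <- as_elements(elements)
  if (any(el < 0)) stop("negative element counts", call. = FALSE)
  sum(ATOMIC_MASS[names(el)] * el)
}

#' Format an element-count vector as a formula string
#' @param elements Named element-count vector.
#' @return Formula string such as `"C34H56N2O25"`.
#' @export
format_formula <- function(elements) {
  el <- as_elements(elements)
  if (!length(el)) return("")
  paste0(names(el), ifelse(el == 1, "", format(el, trim = TRUE, scientific = FALSE)),
         collapse = "")
}
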