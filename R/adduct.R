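#' Charge-carrier (adduct) presets
#'
#' An adduct describes the ion-forming change relative to the neutral
#' molecule: a signed element delta and a signed charge. The m/z
#' contribution accounts for the electron mass:
#' \deqn{m/z = (M + mass(\Delta elements) - z \cdot m_e) / |z|}
#'
#' Positive-mode presets: `"H+"`, `"Na+"`, `"K+"`; negative-mode presets:
#' `"-H"`, `"Na-2H"`, `"K-2H"`.
#'
#' @param name Preset name, or a label for a custom adduct.
#' @param elements Signed element changes for a custom adduct (named
#'   vector; negative counts mean loss).
#' @param charge Signed integer charge for a custom adduct.
#' @return Object of class `glyq_adduct` with fields `name`, `elements`,
#'   `charge`, `polarity`.
#' @examples
#' adduct("Na+")
#' theoretical_mz(1000, adduct("H+"))
#' @export
adduct <- function(name, elements = NULL, charge = NULL) {
  presets <- list(
    "H+"    = list(elements = c(H = 1), charge = 1L),
    "Na+"   = list(elements = c(Na = 1), charge = 1L),
    "K+"    = list(elements = c(K = 1), charge = 1L),
    "-H"    = list(elements = c(H = -1), charge = -1L),
    "Na-2H" = list(elements = c(Na = 1, H = -2), charge = -1L),
    "K-2H"  = list(elements = c(K = 1, H = -2), charge = -1L)
  )
  if (is.null(elements)) {
    if (!name %in% names(presets)) {
      stop("unknown adduct '", name, "'; presets: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    }
    elements <- presets[[name]]$elements
    charge <- presets[[name]]$charge
  }
  stopifnot(is.numeric(charge), length(charge) == 1, charge != 0)
  structure(
    list(name = name, elements = elements, charge = as.integer(charge),
         polarity = if (charge > 0) "positive" else "negative"),
    class = "glyq_adduct"
  )
}

#' @export
print.glyq_adduct <- function(x, ...) {
  cat("<adduct> ", x$name, "  charge ", x$charge, " (", x$polarity, ")\n",
      sep = "")
  invisible(x)
}

#' Default adduct sets by polarity
#' @param polarity `"positive"` or `"negative"`.
#' @return List of `glyq_adduct` objects (H+/Na+/K+ or -H/Na-2H/K-2H).
#' @export
default_adducts <- function(polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  nm <- if (polarity == "positive") c("H+", "Na+", "K+") else
    c("-H", "Na-2H", "K-2H")
  lapply(nm, adduct)
}

## Apply an adduct k times (multiple charging with the same carrier).
scale_adduct <- function(add, k) {
  stopifnot(k >= 1)
  structure(
    list(name = if (k == 1) add$name else paste0(k, "(", add$name, ")"),
         elements = add$elements * k, charge = add$charge * as.integer(k),
         polarity = add$polarity),
    class = "glyq_adduct"
  )
}

#' Theoretical m/z of a neutral mass under an adduct
#'
#' @param neutral Neutral monoisotopic mass(es) in Da.
#' @param add A [adduct()] object.
#' @param k Number of adduct units (multiplies elements and charge), for
#'   multiply charged ions.
#' @return m/z value(s).
#' @examples
#' theoretical_mz(1000, adduct("H+"))   # 1001.007276
#' @export
theoretical_mz <- function(neutral, add, k = 1) {
  add <- scale_adduct(add, k)
  ## element delta may be net-negative (e.g. -H); compute signed mass sum
  dm <- sum(ATOMIC_MASS[names(add$elements)] * add$elements)
  (neutral + dm - add$charge * ELECTRON_MASS) / abs(add$charge)
}
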