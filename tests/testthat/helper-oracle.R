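## Independent isotope-pattern oracles, kept deliberately separate from the
## package's convolution path.

iso_table <- function() glyquant:::ISOTOPE_ABUNDANCE

## Exact per-element distribution by explicit multinomial enumeration.
oracle_element_dist <- function(p, n) {
  k <- length(p)
  if (k == 1 || n == 0) return(1)
  grids <- do.call(expand.grid, rep(list(0:n), k - 1))
  grids <- grids[rowSums(grids) <= n, , drop = FALSE]
  out <- numeric(n * (k - 1) + 1)
  for (r in seq_len(nrow(grids))) {
    heavy <- as.numeric(grids[r, ])
    off <- sum(heavy * seq_len(k - 1))
    out[off + 1] <- out[off + 1] +
      stats::dmultinom(c(n - sum(heavy), heavy), prob = p)
  }
  out
}

## Full-length polynomial product across elements (no truncation).
oracle_pattern <- function(formula, normalize = c("max", "sum")) {
  normalize <- match.arg(normalize)
  el <- if (is.character(formula)) parse_formula(formula) else formula
  acc <- 1
  for (sym in names(el)) {
    d <- oracle_element_dist(iso_table()[[sym]], el[[sym]])
    new <- numeric(length(acc) + length(d) - 1)
    for (i in seq_along(acc)) {
      for (j in seq_along(d)) new[i + j - 1] <- new[i + j - 1] + acc[i] * d[j]
    }
    acc <- new
  }
  if (normalize == "max") acc / max(acc) else acc / sum(acc)
}

## Atom-by-atom brute force (every isotopologue combination), for tiny
## molecules only.
oracle_pattern_atoms <- function(formula) {
  el <- parse_formula(formula)
  syms <- rep(names(el), times = el)
  stopifnot(sum(el) <= 12)
  choices <- lapply(syms, function(s) seq_along(iso_table()[[s]]) - 1L)
  grid <- as.matrix(do.call(expand.grid, choices))
  prob <- apply(grid, 1, function(row) {
    prod(mapply(function(ch, s) iso_table()[[s]][ch + 1], row, syms))
  })
  off <- rowSums(grid)
  agg <- tapply(prob, off, sum)
  full <- numeric(max(off) + 1)
  full[as.integer(names(agg)) + 1] <- agg
  full / max(full)
}
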