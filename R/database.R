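#' Build a combinatorial glycan composition database
#'
#' Enumerates every nonredundant monosaccharide composition within the
#' count bounds and below a free-mass limit. The default bounds follow the
#' common N-glycan count envelope (Hex <= 12, HexNAc <= 7, dHex <= 5,
#' NeuAc + NeuGc <= 4) with a 4,500 Da mass ceiling. The `"human"` variant
#' excludes NeuGc-containing compositions, the `"mammalian"` variant allows
#' both sialic acids, so the human database is exactly the NeuGc-free
#' subset of the mammalian one under identical bounds.
#'
#' @param variant `"mammalian"` (NeuAc and NeuGc) or `"human"` (no NeuGc).
#' @param bounds Named list/vector of per-class maxima: `hex`, `hexnac`,
#'   `dhex`, `sialic` (joint NeuAc + NeuGc maximum).
#' @param mass_limit Maximum free (released-glycan) monoisotopic mass, Da.
#' @return A tibble of glycan records ordered by `free_mass` then
#'   composition string, with columns `composition`, `hex`, `hexnac`,
#'   `dhex`, `neuac`, `neugc`, `formula` (residue-sum elements),
#'   `residue_mass`, `free_mass` (= residue mass + H2O) and `source_db`.
#' @examples
#' db <- glycan_db("human", bounds = c(hex = 2, hexnac = 1, dhex = 0, sialic = 0))
#' db$composition
#' @export
glycan_db <- function(variant = c("mammalian", "human"),
                      bounds = c(hex = 12, hexnac = 7, dhex = 5, sialic = 4),
                      mass_limit = 4500) {
  variant <- match.arg(variant)
  bounds <- as.list(bounds)
  for (k in c("hex", "hexnac", "dhex", "sialic")) {
    if (is.null(bounds[[k]])) bounds[[k]] <- 0
    if (bounds[[k]] < 0) stop("negative bound for ", k, call. = FALSE)
  }
  if (mass_limit <= 0) stop("mass_limit must be positive", call. = FALSE)

  grid <- tidyr::expand_grid(
    hex = 0:bounds$hex, hexnac = 0:bounds$hexnac, dhex = 0:bounds$dhex,
    neuac = 0:bounds$sialic, neugc = 0:bounds$sialic
  ) |>
    dplyr::filter(.data$neuac + .data$neugc <= bounds$sialic,
                  .data$hex + .data$hexnac + .data$dhex +
                    .data$neuac + .data$neugc > 0)
  if (variant == "human") grid <- dplyr::filter(grid, .data$neugc == 0)

  rm_unit <- vapply(RESIDUE_FORMULA, element_mass, numeric(1))
  grid <- grid |>
    dplyr::mutate(
      residue_mass = .data$hex * rm_unit[["hex"]] +
        .data$hexnac * rm_unit[["hexnac"]] + .data$dhex * rm_unit[["dhex"]] +
        .data$neuac * rm_unit[["neuac"]] + .data$neugc * rm_unit[["neugc"]],
      free_mass = .data$residue_mass + MASS_H2O
    ) |>
    dplyr::filter(.data$free_mass <= mass_limit)

  finish_db(grid, source_db = variant)
}

finish_db <- function(grid, source_db) {
  grid |>
    dplyr::mutate(
      composition = format_composition(.data$hex, .data$hexnac, .data$dhex,
                                       .data$neuac, .data$neugc),
      formula = purrr::pmap_chr(
        list(.data$hex, .data$hexnac, .data$dhex, .data$neuac, .data$neugc),
        function(hex, hexnac, dhex, neuac, neugc) {
          format_formula(residue_elements(
            list(hex = hex, hexnac = hexnac, dhex = dhex,
                 neuac = neuac, neugc = neugc)))
        }),
      source_db = source_db
    ) |>
    dplyr::arrange(.data$free_mass, .data$composition) |>
    dplyr::select("composition", "hex", "hexnac", "dhex", "neuac", "neugc",
                  "formula", "residue_mass", "free_mass", "source_db")
}

#' Load a user glycan composition table
#'
#' Reads a comma- or tab-separated table with a header row containing at
#' least one of the columns `Hex`, `HexNAc`, `dHex`, `NeuAc`, `NeuGc`
#' (case-insensitive) and an optional `Name` column. Lines starting with
#' `#` are ignored. Duplicate compositions are collapsed with a warning;
#' masses and element maps are recomputed from the counts.
#'
#' @param path Path to the table file.
#' @return A glycan record tibble as from [glycan_db()], `source_db =
#'   "custom"`.
#' @export
read_glycan_db <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (!length(keep)) {
    warning("empty database file: ", path, call. = FALSE)
    return(finish_db(tibble::tibble(hex = integer(), hexnac = integer(),
                                    dhex = integer(), neuac = integer(),
                                    neugc = integer(),
                                    residue_mass = numeric(),
                                    free_mass = numeric()),
                     source_db = "custom"))
  }
  sep <- if (grepl("\t", lines[keep[1]])) "\t" else ","
  header <- trimws(strsplit(lines[keep[1]], sep)[[1]])
  canon <- c(hex = "hex", hexnac = "hexnac", dhex = "dhex",
             neuac = "neuac", neugc = "neugc", name = "name")
  idx <- canon[match(tolower(header), names(canon))]
  if (any(is.na(idx))) {
    stop("unknown column(s) in ", path, ": ",
         paste(header[is.na(idx)], collapse = ", "),
         "; expected Hex, HexNAc, dHex, NeuAc, NeuGc, Name", call. = FALSE)
  }
  rows <- lapply(keep[-1], function(i) {
    fields <- trimws(strsplit(lines[i], sep)[[1]])
    counts <- stats::setNames(as.list(rep(0L, 5)), names(MONO_NAMES))
    for (j in seq_along(idx)) {
      col <- idx[[j]]
      if (col == "name" || j > length(fields)) next
      v <- suppressWarnings(as.numeric(fields[j]))
      if (is.na(v) || v != round(v)) {
        stop("unparseable count '", fields[j], "' at line ", i, " of ",
             path, call. = FALSE)
      }
      if (v < 0) stop("negative count at line ", i, " of ", path, call. = FALSE)
      counts[[col]] <- as.integer(v)
    }
    if (sum(unlist(counts)) == 0) {
      stop("empty composition at line ", i, " of ", path, call. = FALSE)
    }
    tibble::as_tibble_row(counts)
  })
  grid <- dplyr::bind_rows(rows)
  ndup <- nrow(grid) - nrow(dplyr::distinct(grid))
  if (ndup > 0) {
    warning("collapsed ", ndup, " duplicate composition(s) in ", path,
            call. = FALSE)
    grid <- dplyr::distinct(grid)
  }
  grid <- dplyr::mutate(
    grid,
    residue_mass = purrr::pmap_dbl(grid, function(hex, hexnac, dhex, neuac,
                                                  neugc) {
      residue_mass(list(hex = hex, hexnac = hexnac, dhex = dhex,
                        neuac = neuac, neugc = neugc))
    }),
    free_mass = .data$residue_mass + MASS_H2O
  )
  finish_db(grid, source_db = "custom")
}

#' Neutral analyte mass of database records under a derivatization
#'
#' Adds the channel's net addition to each record's residue mass. With the
#' `"free end"` preset and the light channel this equals `free_mass`.
#'
#' @param db Glycan record tibble from [glycan_db()] / [read_glycan_db()].
#' @param deriv A [derivatization()] object.
#' @param channel `"light"` or `"heavy"`.
#' @return `db` with an added `neutral_mass` column (and `channel`).
#' @export
neutral_mass <- function(db, deriv = derivatization("free end"),
                         channel = c("light", "heavy")) {
  channel <- match.arg(channel)
  add <- deriv_channel_mass(deriv, channel)
  dplyr::mutate(db,
                channel = channel,
                neutral_mass = .data$residue_mass + add)
}
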