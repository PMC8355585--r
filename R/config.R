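#' Resolve a run configuration from defaults, a config file and overrides
#'
#' Precedence: explicit overrides > config-file values > defaults. The
#' defaults are the standard MALDI-TOF feasibility settings: 50 ppm
#' tolerance, H+/Na+/K+ adducts, positive mode, max charge 3, S/N 10.
#' The config file is a flat `key = value` text file (`#` comments
#' allowed); unknown keys are an error listing the valid keys.
#'
#' Keys: `inputs` (comma-separated files/globs), `output_dir`, `mode`,
#' `polarity`, `adducts` (comma-separated preset names), `max_charge`,
#' `tolerance_ppm`, `derivatization` (preset name), `delta_mass`,
#' `calibration_offset`, `db` (`human`, `mammalian` or a table path),
#' `mass_limit`, `noise_method`, `noise_coefficient`, `noise_level`,
#' `snr_min`, `min_isotopes`, `spacing_tol`, `min_points`.
#'
#' @param path Optional config file path.
#' @param overrides Named list of values taking precedence over the file
#'   (e.g. parsed command-line flags).
#' @return Named list of class `glyq_runconfig` of fully resolved values.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    inputs = character(), output_dir = ".", mode = "auto",
    polarity = "positive", adducts = c("H+", "Na+", "K+"),
    max_charge = 3, tolerance_ppm = 50, derivatization = "free end",
    delta_mass = 0, calibration_offset = 0, db = "mammalian",
    mass_limit = 4500, noise_method = "median", noise_coefficient = 2,
    noise_level = NA_real_, snr_min = 10, min_isotopes = 3,
    spacing_tol = 0.05, min_points = 4
  )
  numeric_keys <- c("max_charge", "tolerance_ppm", "delta_mass",
                    "calibration_offset", "mass_limit",
                    "noise_coefficient", "noise_level", "snr_min",
                    "min_isotopes", "spacing_tol", "min_points")
  from_file <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    for (ln in lines) {
      kv <- stringr::str_match(ln, "^\\s*([A-Za-z_]+)\\s*=\\s*(.*?)\\s*$")
      if (is.na(kv[1, 1])) stop("cannot parse config line: ", ln,
                                call. = FALSE)
      from_file[[kv[1, 2]]] <- kv[1, 3]
    }
  }
  merged <- defaults
  apply_layer <- function(merged, layer) {
    bad <- setdiff(names(layer), names(defaults))
    if (length(bad)) {
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           "; valid keys: ", paste(names(defaults), collapse = ", "),
           call. = FALSE)
    }
    for (k in names(layer)) {
      v <- layer[[k]]
      if (is.character(v) && k %in% c("inputs", "adducts") &&
          length(v) == 1) {
        v <- trimws(strsplit(v, ",")[[1]])
      }
      if (k %in% numeric_keys) v <- as.numeric(v)
      merged[[k]] <- v
    }
    merged
  }
  merged <- apply_layer(merged, from_file)
  merged <- apply_layer(merged, overrides)
  structure(merged, class = "glyq_runconfig")
}

as_search_config <- function(rc) {
  db <- if (rc$db %in% c("human", "mammalian")) {
    glycan_db(rc$db, mass_limit = rc$mass_limit)
  } else {
    read_glycan_db(rc$db)
  }
  search_config(
    db = db, tolerance_ppm = rc$tolerance_ppm,
    adducts = lapply(rc$adducts, adduct), polarity = rc$polarity,
    max_charge = rc$max_charge, deriv = derivatization(rc$derivatization),
    delta_mass = rc$delta_mass,
    calibration_offset = rc$calibration_offset, snr_min = rc$snr_min,
    min_isotopes = rc$min_isotopes, spacing_tol = rc$spacing_tol,
    noise_method = rc$noise_method,
    noise_coefficient = rc$noise_coefficient,
    noise_level = if (is.na(rc$noise_level)) NULL else rc$noise_level,
    min_points = rc$min_points, mode = rc$mode
  )
}

#' Process a batch of peak list files
#'
#' Runs the full pipeline independently on every input file, writes a
#' per-file TSV report (`<input>.glyquant.tsv`), a per-file run log, and
#' one `summary.tsv` with file, envelope, match and pair counts. A
#' failing file is marked in the summary but does not abort the
#' remaining files.
#'
#' @param runconfig A [load_config()] result (needs `inputs` and
#'   `output_dir`).
#' @return Summary tibble (`file`, `status`, `n_envelopes`, `n_matches`,
#'   `n_pairs`, `report`), with attribute `exit_status` (0 when all files
#'   succeeded, 1 otherwise), invisibly returned by the CLI.
#' @export
run_batch <- function(runconfig) {
  files <- unlist(lapply(runconfig$inputs, function(g) {
    hits <- Sys.glob(g)
    if (length(hits)) hits else g
  }))
  if (!length(files)) stop("no input files", call. = FALSE)
  config <- as_search_config(runconfig)
  if (!dir.exists(runconfig$output_dir)) {
    dir.create(runconfig$output_dir, recursive = TRUE)
  }
  rows <- lapply(files, function(f) {
    report <- file.path(runconfig$output_dir,
                        paste0(basename(f), ".glyquant.tsv"))
    res <- tryCatch({
      run <- run_pipeline(f, config)
      write_report(run$matches, run$pairs, config, report,
                   source_file = f)
      log_path <- file.path(runconfig$output_dir,
                            paste0(basename(f), ".log.txt"))
      writeLines(c(
        paste0("input: ", f),
        paste0("skipped_lines: ", attr(run$spectrum, "skipped") %||% 0),
        paste0("noise_level: ", run$noise),
        paste0("n_peaks: ", nrow(run$peaks)),
        paste0("n_envelopes: ", nrow(run$envelopes)),
        paste0("n_matches: ", nrow(run$matches)),
        paste0("n_pairs: ", if (is.null(run$pairs)) 0 else
          sum(run$pairs$flag == "ok"))
      ), log_path)
      tibble::tibble(file = f, status = "ok",
                     n_envelopes = nrow(run$envelopes),
                     n_matches = nrow(run$matches),
                     n_pairs = if (is.null(run$pairs)) NA_integer_ else
                       sum(run$pairs$flag == "ok"),
                     report = report)
    }, error = function(e) {
      tibble::tibble(file = f, status = paste0("error: ",
                                               conditionMessage(e)),
                     n_envelopes = NA_integer_, n_matches = NA_integer_,
                     n_pairs = NA_integer_, report = NA_character_)
    })
    res
  })
  summary <- dplyr::bind_rows(rows)
  utils::write.table(summary,
                     file.path(runconfig$output_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  attr(summary, "exit_status") <- if (all(summary$status == "ok")) 0L else 1L
  summary
}
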