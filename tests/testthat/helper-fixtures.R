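## Shared fixtures built in code.

## Small databases keep the matching tests fast; the default-bounds
## database is built once per test run where needed.
small_db <- function() {
  glycan_db("mammalian", bounds = c(hex = 6, hexnac = 5, dhex = 1, sialic = 0))
}

the_full_db <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- glycan_db("mammalian")
    cache
  }
})

## d0/d2-style duplex on the free glycan: heavy = light with 2 H -> 2 D.
d2_duplex <- function() derivatization("d0/d2", light = "H2O", heavy = "OD2")

duplex_run <- function(composition, ratio_hl, deriv = d2_duplex(),
                       adducts = "Na+", db = small_db(), profile = FALSE,
                       noise_sd = 0, seed = 1L, config_args = list()) {
  mix <- mixture_spec(
    tibble::tibble(composition = composition, adduct = adducts,
                   ratio_hl = ratio_hl),
    deriv = deriv, noise_sd = noise_sd, seed = seed)
  sp <- if (profile) render_profile(mix) else render_sticks(mix)
  cfg <- do.call(search_config, c(
    list(db = db, deriv = deriv,
         noise_level = if (noise_sd == 0) 0 else NULL),
    config_args))
  run_pipeline(sp, cfg)
}

pair_for <- function(run, composition, adduct = "Na+") {
  pr <- run$pairs
  pr[pr$composition == composition & pr$adduct == adduct, ]
}
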