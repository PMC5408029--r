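# Frozen encode/decode fixtures for regression testing: a few (bank, seed,
# stimulus) triples together with the spike counts they produce, serialized
# as JSON so an installed copy of the package can be checked against them.

utils::globalVariables(c("prior_mean", "fraction", "curve"))

#' Generate frozen population-response fixtures
#'
#' Encodes a small set of stimulus values on both default tuning banks under
#' fixed per-case seeds and writes the resulting spike counts, together with
#' the generating parameters, to a JSON file. Re-running with the same seed
#' reproduces the file exactly; tests compare freshly encoded responses
#' against a frozen copy to catch regressions in the encoder or in the RNG
#' plumbing.
#'
#' @param path Output JSON path.
#' @param seed Base integer seed; case seeds are derived as `seed + case - 1`.
#' @param cfg A [sim_config()] providing bank parameters and decision time.
#' @return The fixture list, invisibly (it is also written to `path`).
#' @export
make_fixtures <- function(path, seed = 2026L, cfg = sim_config()) {
  cfg <- validate_config(cfg)
  sim <- build_simulation(cfg)
  # stimuli: the worked example value on each bank plus one mid-range value
  cases <- list(
    list(variable = "gamma_dot", stimulus = 0.797),
    list(variable = "gamma_dot", stimulus = 1.15),
    list(variable = "gamma", stimulus = 0.1622),
    list(variable = "gamma", stimulus = 0.5)
  )
  fixtures <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    bank <- sim$banks[[cs$variable]]
    resp <- encode(bank, cs$stimulus, seed = seed + i - 1L)
    list(variable = cs$variable, stimulus = cs$stimulus,
         seed = seed + i - 1L,
         bank = list(range = bank$range, n_peaks = length(bank$centers),
                     sd = bank$sd, amplitude = bank$amplitude),
         counts = resp$counts,
         mle_estimate = mle_decode(bank, resp, cfg$grid_step))
  })
  jsonlite::write_json(fixtures, path, auto_unbox = TRUE, digits = NA)
  invisible(fixtures)
}
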