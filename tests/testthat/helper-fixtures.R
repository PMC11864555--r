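# shared fixtures, built in code

# scenario with every stochastic channel switched off: truth must be
# recovered exactly downstream
noise_free_preset <- function(name = "mixed-13yr", seed = 1L, ...) {
  make_scenario_preset(name, seed = seed, sst_noise_sd = 0,
                       catch_noise = FALSE, arrival_jitter_sd = 0,
                       residence_jitter_sd = 0, ...)
}

# flat scenario: no regime shifts, so arrival pulses sit at the default
# thermal positions in every year
flat_scenario <- function(seed = 1L, n_years = 13L, ...) {
  scenario(n_years = n_years, regime_sequence = rep("T1", n_years),
           early_shift = 0, late_shift = 0, ns_offset = 0, seed = seed, ...)
}

quiet_pipeline <- function(config) {
  suppressWarnings(suppressMessages(run_pipeline(config)))
}

quiet_compare_lme <- function(...) {
  suppressWarnings(suppressMessages(compare_lme(...)))
}

# independent brute-force oracles (deliberately naive)
oracle_first_below <- function(x, thr) {
  for (i in seq_along(x)) if (x[i] < thr) return(i - 1L)
  NA_integer_
}

oracle_mdmt <- function(counts) {
  total <- sum(counts)
  acc <- 0
  for (i in seq_along(counts)) {
    acc <- acc + counts[i]
    if (acc > total / 2) return(i - 1L)
  }
  NA_integer_
}

oracle_temp_bins <- function(catch, sst, width = 1) {
  acc <- new.env()
  for (i in seq_along(catch)) {
    key <- as.character(floor(sst[i] / width) * width)
    acc[[key]] <- (acc[[key]] %||% 0) + catch[i]
  }
  vals <- unlist(as.list(acc))
  vals[order(as.numeric(names(vals)))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
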