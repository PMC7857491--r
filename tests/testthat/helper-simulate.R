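# Shared builders for simulated fixtures. All fixtures are generated in
# code; noise-free configurations are the default because most checks are
# exact-inverse identities against the generator.

clean_config <- function(...) {
  simulation_config(noise_sd = 0, quench_efficiency = 1, ...)
}

# minimal plate: n sample wells (replicates) + the two control wells
triplet_design <- function(n_samples = 1, condition = "sample",
                           overrides = NULL) {
  wells <- sprintf("A%02d", seq_len(n_samples))
  design <- lapply(seq_len(n_samples), function(i) {
    d <- list(well = wells[i], role = "sample", condition = condition,
              replicate = i)
    if (!is.null(overrides)) d$config <- overrides
    d
  })
  c(design,
    list(list(well = "H01", role = "substrate_control"),
         list(well = "H02", role = "enzyme_control")))
}

# analytic initial rate of the generative model, mol/min per reaction
generative_rate <- function(cfg) {
  vmax_eff <- cfg$Vmax * modifier_factor(cfg$modifiers, cfg$substrate)
  cfg$volume * vmax_eff * cfg$S0 / (cfg$Km + cfg$S0)
}

# per-dose simulate + quantify for condition panels: returns one activity
# per element of `configs` (a named list of update_config override lists)
panel_activities <- function(configs, base = clean_config(), seed = 1L,
                             k = base$k_AU, window = 12L) {
  vapply(seq_along(configs), function(i) {
    cfg <- do.call(update_config, c(list(base), configs[[i]]))
    ds <- simulate_plate(triplet_design(1, overrides = NULL),
                         cfg, seed = seed + i)
    quantify_plate(ds, k, window = window)$A
  }, numeric(1))
}
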