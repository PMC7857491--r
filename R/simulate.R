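#' Simulate one EFQO well
#'
#' Forward-simulates the fluorescence time series of a single well from the
#' integrated Michaelis-Menten progress curve plus instrument terms.
#' With \eqn{S(t)} the remaining substrate ([integrated_mm_substrate()] under
#' the condition-scaled \eqn{V_{max}}), \eqn{q} the quench efficiency,
#' \eqn{k} the generative fluorescence coefficient and \eqn{V} the volume:
#' \itemize{
#'   \item sample: \eqn{I(t) = bg + (1-q) k S(t) V + k (S_0 - S(t)) V +
#'     (a_S + a_E) t + \epsilon(t)}
#'   \item substrate control: \eqn{I(t) = bg + (1-q) k S_0 V + a_S t + \epsilon}
#'   \item enzyme control: \eqn{I(t) = bg + a_E t + \epsilon}
#' }
#' \eqn{\epsilon} is i.i.d. Gaussian(0, noise_sd^2), reproducible from
#' \code{seed}. The reads are at 0, read_interval, ..., duration minutes,
#' t = 0 being the first read after preincubation.
#'
#' @param config a [simulation_config()].
#' @param role \code{"sample"}, \code{"substrate_control"} or
#'   \code{"enzyme_control"}.
#' @param seed integer; defaults to \code{config$seed}.
#' @return A [kinetic_trace()].
#' @export
simulate_trace <- function(config,
                           role = c("sample", "substrate_control",
                                    "enzyme_control"),
                           seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  role <- match.arg(role)
  times <- seq(0, config$duration, by = config$read_interval)
  q <- config$quench_efficiency
  kV <- config$k_AU * config$volume
  signal <- switch(role,
    sample = {
      vmax_eff <- config$Vmax * modifier_factor(config$modifiers,
                                                config$substrate)
      S <- integrated_mm_substrate(config$S0, config$Km, vmax_eff, times)
      config$background + (1 - q) * kV * S + kV * (config$S0 - S) +
        config$sample_drift * times
    },
    substrate_control = config$background + (1 - q) * kV * config$S0 +
      config$drift_substrate * times,
    enzyme_control = config$background + config$drift_enzyme * times)
  signal <- rep_len(signal, length(times))
  if (config$noise_sd > 0)
    signal <- signal + with_local_seed(seed,
      stats::rnorm(length(times), 0, config$noise_sd))
  kinetic_trace("A01", times, signal, role = role)
}

#' Simulate a full EFQO plate
#'
#' Batch wrapper over [simulate_trace()] producing a [plate_dataset()]: one
#' kinetic trace per well plus a plate layout recording every condition
#' field. Per-well seeds are derived deterministically from the master seed
#' and the well position, so a plate is reproducible as a whole while wells
#' remain independent.
#'
#' @param design a list of per-well specifications, each a list with
#'   elements \code{well} (id), \code{role}, optional \code{condition}
#'   (label, default the role), optional \code{replicate}, optional
#'   \code{enzyme} (source label), and optional \code{config} -- either a
#'   [simulation_config()] or a list of [update_config()] overrides applied
#'   to \code{base_config}.
#' @param base_config the default [simulation_config()] for wells without
#'   their own.
#' @param seed master integer seed.
#' @return A [plate_dataset()] whose provenance records the master seed.
#' @export
simulate_plate <- function(design, base_config = simulation_config(),
                           seed = 1L) {
  stopifnot(is.list(design), inherits(base_config, "simulation_config"))
  if (length(design) > 96L)
    stop("a plate holds at most 96 wells")
  if (length(design) == 0L)
    return(plate_dataset(list(), empty_layout(),
                         provenance = list(seed = as.integer(seed),
                                           source = "simulate_plate")))
  wells <- vapply(design, function(d) normalize_well_id(d$well), character(1))
  if (anyDuplicated(wells))
    stop("duplicate well id(s): ",
         paste(unique(wells[duplicated(wells)]), collapse = ", "))
  seed <- as.integer(seed)

  traces <- vector("list", length(design))
  layout_rows <- vector("list", length(design))
  for (i in seq_along(design)) {
    d <- design[[i]]
    cfg <- if (is.null(d$config)) base_config
           else if (inherits(d$config, "simulation_config")) d$config
           else do.call(update_config, c(list(base_config), d$config))
    well_seed <- derive_seed(seed, well_index(wells[i]))
    tr <- simulate_trace(cfg, role = d$role, seed = well_seed)
    tr$well_id <- wells[i]
    traces[[i]] <- tr
    mod <- cfg$modifiers
    layout_rows[[i]] <- data.frame(
      well = wells[i],
      role = d$role,
      condition = if (is.null(d$condition)) d$role else as.character(d$condition),
      enzyme = if (is.null(d$enzyme)) "lysate" else as.character(d$enzyme),
      protein_mg = cfg$protein_mass,
      substrate = cfg$substrate$sequence,
      substrate_conc_M = cfg$S0,
      inhibitor = mod$inhibitor_name,
      inhibitor_conc_M = mod$inhibitor_conc,
      pH = mod$pH,
      temp_C = mod$temperature,
      replicate = if (is.null(d$replicate)) 1L else as.integer(d$replicate),
      stringsAsFactors = FALSE)
  }
  layout <- do.call(rbind, layout_rows)
  layout <- layout[order(well_index(layout$well)), , drop = FALSE]
  rownames(layout) <- NULL
  plate_dataset(traces, layout,
                provenance = list(seed = seed, source = "simulate_plate"))
}

# deterministic per-well seed below 2^31
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + as.numeric(index) * 104729 + 13) %%
               2147483629)
}

# evaluate expr under a temporary RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

empty_layout <- function() {
  data.frame(well = character(), role = character(), condition = character(),
             enzyme = character(), protein_mg = numeric(),
             substrate = character(), substrate_conc_M = numeric(),
             inhibitor = character(), inhibitor_conc_M = numeric(),
             pH = numeric(), temp_C = numeric(), replicate = integer(),
             stringsAsFactors = FALSE)
}
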