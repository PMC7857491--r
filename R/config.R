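#' Simulation configuration for a synthetic EFQO reaction
#'
#' Full generative parameter set for one simulated well (and, with
#' [simulate_plate()], whole plates) of the EFQO 5'-exonuclease assay.
#' Defaults reproduce the standard assay conditions: 1 uM 30-nt
#' 5'-FAM/3'-quencher ssDNA substrate in a 100-ul reaction, 5 ng/ul lysate
#' protein (0.5 ug/well), 30-min preincubation, then reads every 5 min for
#' 12 h at 37 deg C, with a substrate-only and a lysate-only control well
#' carrying independent linear background drifts.
#'
#' \code{Km} and \code{Vmax} describe the uninhibited reference kinetics;
#' condition effects enter as a multiplicative factor on \code{Vmax} via
#' [modifier_factor()]. \code{k_AU} is the generative fluorescence
#' coefficient (AU per mole of released 5' nucleotide), the counterpart of
#' the calibration slope \eqn{k} estimated by [fit_calibration()].
#' \code{quench_efficiency} is the fraction of intact-substrate fluorophore
#' signal suppressed by the 3' quencher; values below 1 leak a constant
#' fraction of the intact-substrate signal into the baseline.
#'
#' @param S0 initial substrate concentration, mol/L.
#' @param volume reaction volume, L.
#' @param Km Michaelis constant, mol/L.
#' @param Vmax maximal hydrolysis rate of the reference condition, mol/(L min).
#' @param k_AU fluorescence units per mole of released 5' nucleotide.
#' @param quench_efficiency in (0, 1].
#' @param background constant instrument background, AU.
#' @param drift_substrate,drift_enzyme linear drift slopes of the
#'   substrate-only and enzyme-only control wells, AU/min.
#' @param sample_drift_policy \code{"sum_of_controls"} (sample-well drift is
#'   exactly \code{drift_substrate + drift_enzyme}, making the control-based
#'   correction unbiased) or \code{"custom"} (use \code{sample_drift}).
#' @param sample_drift sample-well drift, AU/min; only with policy
#'   \code{"custom"}.
#' @param noise_sd additive i.i.d. Gaussian read noise, AU.
#' @param read_interval read spacing, min.
#' @param duration total kinetic read length, min.
#' @param preincubation preincubation period before the first read, min
#'   (t = 0 is the first read after preincubation).
#' @param protein_mass protein per well, mg.
#' @param seed integer seed for the well's noise draws.
#' @param modifiers a [condition_modifier()].
#' @param substrate an [oligo_substrate()].
#' @return An object of class \code{simulation_config}.
#' @export
simulation_config <- function(S0 = 1e-6,
                              volume = 1e-4,
                              Km = 5e-6,
                              Vmax = 2e-9,
                              k_AU = 1e13,
                              quench_efficiency = 0.95,
                              background = 50,
                              drift_substrate = 0.05,
                              drift_enzyme = 0.02,
                              sample_drift_policy = c("sum_of_controls", "custom"),
                              sample_drift = NULL,
                              noise_sd = 2,
                              read_interval = 5,
                              duration = 720,
                              preincubation = 30,
                              protein_mass = 5e-4,
                              seed = 1L,
                              modifiers = condition_modifier(),
                              substrate = oligo_substrate()) {
  sample_drift_policy <- match.arg(sample_drift_policy)
  stopifnot(S0 >= 0, volume >= 0, Km >= 0, Vmax >= 0, k_AU >= 0,
            noise_sd >= 0, read_interval > 0, duration >= read_interval,
            preincubation >= 0, protein_mass >= 0,
            quench_efficiency > 0, quench_efficiency <= 1,
            inherits(modifiers, "condition_modifier"),
            inherits(substrate, "oligo_substrate"))
  if (sample_drift_policy == "custom" && is.null(sample_drift))
    stop("sample_drift must be supplied with sample_drift_policy = 'custom'")
  if (sample_drift_policy == "sum_of_controls")
    sample_drift <- drift_substrate + drift_enzyme
  structure(
    list(S0 = S0, volume = volume, Km = Km, Vmax = Vmax, k_AU = k_AU,
         quench_efficiency = quench_efficiency, background = background,
         drift_substrate = drift_substrate, drift_enzyme = drift_enzyme,
         sample_drift_policy = sample_drift_policy,
         sample_drift = sample_drift, noise_sd = noise_sd,
         read_interval = read_interval, duration = duration,
         preincubation = preincubation, protein_mass = protein_mass,
         seed = as.integer(seed), modifiers = modifiers,
         substrate = substrate),
    class = "simulation_config")
}

#' Modify a simulation configuration
#'
#' Returns a new, re-validated [simulation_config()] with the supplied
#' fields replaced. Nested \code{modifiers} / \code{substrate} overrides may
#' be given as plain lists of the corresponding constructor arguments.
#'
#' @param config a [simulation_config()].
#' @param ... fields to replace.
#' @return A new \code{simulation_config}.
#' @export
update_config <- function(config, ...) {
  stopifnot(inherits(config, "simulation_config"))
  dots <- list(...)
  args <- unclass(config)
  # re-derive sample_drift unless the caller pins it
  if (args$sample_drift_policy == "sum_of_controls" &&
      !("sample_drift" %in% names(dots)))
    args$sample_drift <- NULL
  for (nm in names(dots)) {
    if (nm %in% c("modifiers", "substrate") && is.list(dots[[nm]]) &&
        !inherits(dots[[nm]], c("condition_modifier", "oligo_substrate"))) {
      base <- unclass(args[[nm]])
      over <- dots[[nm]]
      ctor <- if (nm == "modifiers") condition_modifier else oligo_substrate
      keep <- base[intersect(names(base), names(formals(ctor)))]
      keep[names(over)] <- over
      args[[nm]] <- do.call(ctor, keep)
    } else {
      args[[nm]] <- dots[[nm]]
    }
  }
  do.call(simulation_config, args)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  S0 %.3g M in %.3g L | Km %.3g M, Vmax %.3g M/min | k_AU %.3g AU/mol\n",
              x$S0, x$volume, x$Km, x$Vmax, x$k_AU))
  cat(sprintf("  reads every %g min for %g min (preincubation %g min), noise sd %.3g AU\n",
              x$read_interval, x$duration, x$preincubation, x$noise_sd))
  cat(sprintf("  background %.3g AU; drifts S %.3g, E %.3g AU/min (sample: %s)\n",
              x$background, x$drift_substrate, x$drift_enzyme,
              x$sample_drift_policy))
  cat(sprintf("  quench efficiency %.3g | protein %.3g mg | seed %d\n",
              x$quench_efficiency, x$protein_mass, x$seed))
  invisible(x)
}
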