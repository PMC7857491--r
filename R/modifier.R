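#' Reaction-condition modifier
#'
#' Bundles the condition-dependent multiplicative effects acting on the
#' maximal hydrolysis rate of a simulated EFQO reaction: logistic inhibitor
#' dose response (or a fixed inhibition fraction), chelator/cation
#' activation, a Gaussian pH-activity profile, and a descending-logistic
#' thermal-stability profile.
#'
#' The neutral default (no inhibitor, activation 1, pH at its optimum,
#' temperature far below the thermal midpoint) has a combined factor of
#' essentially 1.
#'
#' @param inhibitor_name character(1) label, \code{"none"} if absent.
#' @param inhibitor_conc inhibitor concentration, mol/L (>= 0).
#' @param inhibitor_ic50 half-maximal inhibitory concentration, mol/L (> 0).
#' @param hill Hill coefficient of the inhibition curve (> 0).
#' @param fixed_inhibition_fraction optional value in [0, 1]; when set it
#'   overrides the logistic dose-response term with \code{1 - fraction}.
#' @param activation_factor dimensionless (> 1 = activator, e.g. EDTA on the
#'   recombinant enzyme).
#' @param pH,pH_optimum,pH_width reaction pH, the pH of maximal activity,
#'   and the Gaussian width of the pH-activity bell (pH units, width > 0).
#' @param temperature,thermal_midpoint,thermal_width reaction/preincubation
#'   temperature, the half-inactivation temperature, and the logistic width
#'   of the thermal decline (deg C, width > 0).
#' @return An object of class \code{condition_modifier}.
#' @seealso [modifier_factor()]
#' @export
condition_modifier <- function(inhibitor_name = "none",
                               inhibitor_conc = 0,
                               inhibitor_ic50 = 1e-5,
                               hill = 1,
                               fixed_inhibition_fraction = NULL,
                               activation_factor = 1,
                               pH = 6.0, pH_optimum = 6.0, pH_width = 0.8,
                               temperature = 37,
                               thermal_midpoint = 55, thermal_width = 2) {
  stopifnot(inhibitor_conc >= 0, inhibitor_ic50 > 0, hill > 0,
            pH_width > 0, thermal_width > 0, activation_factor >= 0)
  if (!is.null(fixed_inhibition_fraction)) {
    stopifnot(is.numeric(fixed_inhibition_fraction),
              fixed_inhibition_fraction >= 0, fixed_inhibition_fraction <= 1)
    fixed_inhibition_fraction <- as.numeric(fixed_inhibition_fraction)
  }
  structure(
    list(inhibitor_name = as.character(inhibitor_name),
         inhibitor_conc = as.numeric(inhibitor_conc),
         inhibitor_ic50 = as.numeric(inhibitor_ic50),
         hill = as.numeric(hill),
         fixed_inhibition_fraction = fixed_inhibition_fraction,
         activation_factor = as.numeric(activation_factor),
         pH = as.numeric(pH), pH_optimum = as.numeric(pH_optimum),
         pH_width = as.numeric(pH_width),
         temperature = as.numeric(temperature),
         thermal_midpoint = as.numeric(thermal_midpoint),
         thermal_width = as.numeric(thermal_width)),
    class = "condition_modifier")
}

#' Combined rate multiplier of a condition modifier
#'
#' Evaluates the dimensionless multiplier applied to the maximal hydrolysis
#' rate Vmax under a given set of reaction conditions:
#' \deqn{f = activation \times inhibition \times pH \times thermal
#'       \,[\times\, substrate\ terms]}
#' with \eqn{inhibition = 1/(1+(c/IC_{50})^{h})} (or
#' \eqn{1 - fixed\ fraction} when a fixed inhibition fraction is set),
#' \eqn{pH = \exp(-(pH-pH_{opt})^2 / (2\,w_{pH}^2))} and
#' \eqn{thermal = 1/(1+\exp((T-T_m)/w_T))}. When a substrate is supplied its
#' PTO and 5'-base rate factors are included.
#'
#' @param mod a [condition_modifier()].
#' @param substrate optional [oligo_substrate()] whose \code{pto_rate_factor}
#'   and \code{five_prime_base_factor} multiply into the result.
#' @return numeric(1) >= 0.
#' @examples
#' modifier_factor(condition_modifier())                         # ~1
#' modifier_factor(condition_modifier(inhibitor_conc = 1e-5))    # 0.5 at IC50
#' @export
modifier_factor <- function(mod, substrate = NULL) {
  stopifnot(inherits(mod, "condition_modifier"))
  inhibition <- if (!is.null(mod$fixed_inhibition_fraction)) {
    1 - mod$fixed_inhibition_fraction
  } else if (mod$inhibitor_conc > 0) {
    1 / (1 + (mod$inhibitor_conc / mod$inhibitor_ic50)^mod$hill)
  } else 1
  ph_term <- exp(-(mod$pH - mod$pH_optimum)^2 / (2 * mod$pH_width^2))
  thermal_term <- 1 / (1 + exp((mod$temperature - mod$thermal_midpoint) /
                                 mod$thermal_width))
  f <- mod$activation_factor * inhibition * ph_term * thermal_term
  if (!is.null(substrate)) {
    stopifnot(inherits(substrate, "oligo_substrate"))
    f <- f * substrate$pto_rate_factor * substrate$five_prime_base_factor
  }
  f
}

#' @export
print.condition_modifier <- function(x, ...) {
  cat("<condition_modifier>\n")
  if (x$inhibitor_conc > 0 || !is.null(x$fixed_inhibition_fraction))
    cat(sprintf("  inhibitor: %s (%.3g mol/L, IC50 %.3g, hill %.3g%s)\n",
                x$inhibitor_name, x$inhibitor_conc, x$inhibitor_ic50, x$hill,
                if (!is.null(x$fixed_inhibition_fraction))
                  sprintf(", fixed fraction %.3g", x$fixed_inhibition_fraction)
                else ""))
  cat(sprintf("  activation %.3g | pH %.2f (opt %.2f, width %.2f) | T %.1f C (midpoint %.1f, width %.1f)\n",
              x$activation_factor, x$pH, x$pH_optimum, x$pH_width,
              x$temperature, x$thermal_midpoint, x$thermal_width))
  cat(sprintf("  combined rate factor: %.4g\n", modifier_factor(x)))
  invisible(x)
}
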