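# Downstream model fits characterizing the 5' exonuclease: Michaelis-Menten
# substrate dependence, four-parameter-logistic inhibition (IC50), and
# pH-optimum / thermal-midpoint activity profiles.

# Shared Levenberg-Marquardt wrapper. fn(p) returns model predictions for
# named parameter vector p; standard errors from the Gauss-Newton
# covariance sigma^2 (J'J)^-1. nls.lm copes with zero-residual (noise-free)
# data, which stats::nls does not.
lm_least_squares <- function(fn, start, y, lower = NULL, upper = NULL,
                             label = "nonlinear") {
  out <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = function(p) y - fn(p),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 10000)),
    error = function(e) stop(label, " fit failed: ", conditionMessage(e)))
  if (out$info == 0 || out$info == 5)
    stop(label, " fit failed to converge: ", out$message)
  p <- out$par
  n <- length(y); np <- length(p)
  sigma2 <- out$deviance / max(n - np, 1L)
  covm <- tryCatch(sigma2 * solve(out$hessian),
                   error = function(e) matrix(NA_real_, np, np))
  se <- sqrt(pmax(diag(covm), 0))
  names(se) <- names(p)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) max(0, 1 - out$deviance / ss_tot) else 1
  list(par = p, se = se, r_squared = r2, deviance = out$deviance,
       fitted = fn(p), n = n)
}

#' Fit Michaelis-Menten substrate dependence
#'
#' Nonlinear least squares of measured rates against substrate
#' concentration, \eqn{v = V_{max} S / (K_m + S)} (Levenberg-Marquardt).
#' Initialization: \eqn{V_{max,0}} = maximal observed rate, \eqn{K_{m,0}} =
#' substrate concentration at half-maximal rate (linearly interpolated).
#'
#' @param S0_values substrate concentrations, mol/L; >= 4 distinct values
#'   spanning at least a 4-fold range.
#' @param rates observed rates (any consistent activity unit).
#' @return An object of class \code{mm_fit}: \code{Km}, \code{Vmax}, their
#'   standard errors, \code{r_squared}, \code{n_points}. Methods:
#'   \code{print}, \code{coef}, \code{predict}.
#' @examples
#' S <- c(0.25, 0.5, 1, 2, 5, 10) * 1e-6
#' fit_mm(S, 2 * S / (1e-6 + S))
#' @export
fit_mm <- function(S0_values, rates) {
  S <- as.numeric(S0_values); v <- as.numeric(rates)
  stopifnot(length(S) == length(v))
  su <- sort(unique(S[S > 0]))
  if (length(su) < 4L)
    stop("fit_mm requires >= 4 distinct positive substrate concentrations")
  if (max(su) / min(su) < 4)
    stop("substrate concentrations must span at least a 4-fold range")
  start <- c(Vmax = max(v), Km = half_max_x(S, v))
  fit <- lm_least_squares(function(p) p[["Vmax"]] * S / (p[["Km"]] + S),
                          start, v, lower = c(Vmax = 0, Km = 0),
                          label = "Michaelis-Menten")
  if (fit$par[["Km"]] <= 0 || fit$par[["Vmax"]] <= 0)
    stop("Michaelis-Menten fit degenerate: non-positive Km or Vmax")
  structure(list(Km = fit$par[["Km"]], Vmax = fit$par[["Vmax"]],
                 Km_se = fit$se[["Km"]], Vmax_se = fit$se[["Vmax"]],
                 r_squared = fit$r_squared, n_points = length(v),
                 S = S, rates = v),
            class = "mm_fit")
}

half_max_x <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  half <- max(y) / 2
  above <- which(y >= half)[1]
  if (is.na(above) || above == 1L) return(x[max(above, 1L, na.rm = TRUE)])
  x0 <- x[above - 1L]; x1 <- x[above]
  y0 <- y[above - 1L]; y1 <- y[above]
  if (y1 == y0) return(x1)
  x0 + (half - y0) * (x1 - x0) / (y1 - y0)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> Km = %.4g +/- %.2g mol/L, Vmax = %.4g +/- %.2g, R^2 = %.5f (n = %d)\n",
              x$Km, x$Km_se, x$Vmax, x$Vmax_se, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) c(Km = object$Km, Vmax = object$Vmax)

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$S
       else if (is.data.frame(newdata)) newdata$S else as.numeric(newdata)
  object$Vmax * S / (object$Km + S)
}

#' @export
plot.mm_fit <- function(x, ...) {
  graphics::plot(x$S, x$rates, xlab = "substrate (mol/L)", ylab = "rate",
                 main = sprintf("Km = %.3g mol/L, Vmax = %.3g", x$Km, x$Vmax),
                 ...)
  grid <- seq(0, max(x$S), length.out = 200)
  graphics::lines(grid, predict(x, grid))
  invisible(x)
}

#' Fit a four-parameter-logistic inhibition curve (IC50)
#'
#' Least-squares fit of
#' \deqn{a(d) = bottom + \frac{top - bottom}{1 + (d/IC_{50})^{h}}}
#' to activities measured over an inhibitor dose series, with the Hill
#' slope \eqn{h} free within \code{hill_bounds} and \eqn{IC_{50}} fitted on
#' the log scale. Zero-dose points are kept as top anchors by placing them
#' two decades below the smallest nonzero dose on the log axis (recorded in
#' the returned object).
#'
#' @param doses inhibitor concentrations, mol/L; >= 5 doses spanning from
#'   near-zero to near-full inhibition.
#' @param activities measured activities, same length.
#' @param hill_bounds allowed Hill-slope interval.
#' @return An object of class \code{dose_response_fit}: \code{ic50},
#'   \code{hill}, \code{top}, \code{bottom}, standard errors,
#'   \code{r_squared}, \code{n_doses}. Methods: \code{print}, \code{coef},
#'   \code{predict}, \code{plot}.
#' @export
fit_4pl <- function(doses, activities, hill_bounds = c(0.2, 5)) {
  doses <- as.numeric(doses); a <- as.numeric(activities)
  stopifnot(length(doses) == length(a), all(doses >= 0))
  if (length(doses) < 5L) stop("fit_4pl requires >= 5 doses")
  rng <- diff(range(a))
  if (rng <= 1e-9 * max(abs(a), 1e-300))
    stop("undefined IC50: flat dose response (top - bottom below noise floor)")
  zero_anchor <- NULL
  if (any(doses == 0)) {
    zero_anchor <- min(doses[doses > 0]) / 100
    doses[doses == 0] <- zero_anchor
  }
  ld <- log(doses)
  start <- c(top = max(a), bottom = min(a),
             lic = log(half_inhibition_dose(doses, a)), hill = 1)
  fit <- lm_least_squares(
    function(p) p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
      (1 + exp(p[["hill"]] * (ld - p[["lic"]]))),
    start, a,
    lower = c(top = -Inf, bottom = -Inf, lic = -Inf, hill = hill_bounds[1]),
    upper = c(top = Inf, bottom = Inf, lic = Inf, hill = hill_bounds[2]),
    label = "4PL")
  top <- fit$par[["top"]]; bottom <- fit$par[["bottom"]]
  if (top < bottom)
    stop("4PL fit inverted: activity increases with dose")
  if (top - bottom <= 1e-9 * max(abs(a)))
    stop("undefined IC50: fitted top - bottom below noise floor")
  ic50 <- exp(fit$par[["lic"]])
  structure(list(ic50 = ic50, hill = fit$par[["hill"]],
                 top = top, bottom = bottom,
                 ic50_se = ic50 * fit$se[["lic"]],
                 hill_se = fit$se[["hill"]],
                 top_se = fit$se[["top"]], bottom_se = fit$se[["bottom"]],
                 r_squared = fit$r_squared, n_doses = length(doses),
                 zero_dose_anchor = zero_anchor,
                 doses = doses, activities = a),
            class = "dose_response_fit")
}

half_inhibition_dose <- function(d, a) {
  o <- order(d)
  d <- d[o]; a <- a[o]
  half <- (max(a) + min(a)) / 2
  below <- which(a <= half)[1]
  if (is.na(below) || below == 1L) return(stats::median(d))
  x0 <- log(d[below - 1L]); x1 <- log(d[below])
  y0 <- a[below - 1L]; y1 <- a[below]
  if (y1 == y0) return(exp(x1))
  exp(x0 + (half - y0) * (x1 - x0) / (y1 - y0))
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> IC50 = %.4g mol/L (se %.2g), hill = %.3g, top = %.4g, bottom = %.4g, R^2 = %.5f (n = %d doses)\n",
              x$ic50, x$ic50_se, x$hill, x$top, x$bottom, x$r_squared,
              x$n_doses))
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(ic50 = object$ic50, hill = object$hill, top = object$top,
    bottom = object$bottom)
}

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$doses
       else if (is.data.frame(newdata)) newdata$dose else as.numeric(newdata)
  object$bottom + (object$top - object$bottom) /
    (1 + (d / object$ic50)^object$hill)
}

#' @export
plot.dose_response_fit <- function(x, ...) {
  grid <- exp(seq(log(min(x$doses)), log(max(x$doses)), length.out = 200))
  graphics::plot(x$doses, x$activities, log = "x",
                 xlab = "dose (mol/L)", ylab = "activity",
                 main = sprintf("IC50 = %.3g mol/L", x$ic50), ...)
  graphics::lines(grid, predict(x, grid))
  graphics::abline(v = x$ic50, lty = 2)
  invisible(x)
}

#' Percent inhibition and inhibition relative to a reference inhibitor
#'
#' For each condition \eqn{c} with activity \eqn{a_c},
#' \eqn{inhibition(c) = 100 (1 - a_c / a_{control})} and
#' \eqn{relative(c) = 100\, inhibition(c) / inhibition(reference)}.
#'
#' @param activities named numeric vector of (mean) activities by
#'   condition label.
#' @param control label of the untreated control (activity > 0).
#' @param reference label of the reference inhibitor.
#' @return data.frame: \code{condition}, \code{activity},
#'   \code{pct_inhibition}, \code{pct_of_reference} (NA with a flag column
#'   \code{reference_undefined} when the reference shows no inhibition).
#' @export
relative_inhibition <- function(activities, control, reference) {
  stopifnot(is.numeric(activities), !is.null(names(activities)))
  if (!control %in% names(activities)) stop("control label not found")
  if (!reference %in% names(activities)) stop("reference label not found")
  a0 <- activities[[control]]
  if (!is.finite(a0) || a0 <= 0)
    stop("control activity must be positive")
  inhibition <- 100 * (1 - activities / a0)
  ref_inh <- inhibition[[reference]]
  undefined <- !is.finite(ref_inh) || ref_inh == 0
  rel <- if (undefined) rep(NA_real_, length(activities))
         else 100 * inhibition / ref_inh
  data.frame(condition = names(activities),
             activity = unname(activities),
             pct_inhibition = unname(inhibition),
             pct_of_reference = unname(rel),
             reference_undefined = undefined,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Estimate the pH optimum of an activity profile
#'
#' Least-squares fit of a Gaussian bell
#' \eqn{a(pH) = A \exp(-(pH - \mu)^2 / (2\sigma^2))} to an activity-vs-pH
#' series; the optimum is the fitted mean \eqn{\mu}. When the fit fails the
#' estimate falls back to the argmax of the measured activities
#' (method \code{"argmax"}). A profile peaking at the edge of the sampled
#' range is flagged (\code{boundary = TRUE}: not peaked within range), and
#' the reported optimum is clamped to the sampled range.
#'
#' @param pH_values >= 5 pH points spanning the optimum.
#' @param activities measured activities.
#' @return An object of class \code{profile_fit}: \code{optimum},
#'   \code{parameters}, \code{method} ("fit" or "argmax"),
#'   \code{optimum_se}, \code{boundary}, \code{r_squared}.
#' @export
estimate_ph_optimum <- function(pH_values, activities) {
  x <- as.numeric(pH_values); y <- as.numeric(activities)
  stopifnot(length(x) == length(y))
  if (length(x) < 5L) stop("pH optimum estimation requires >= 5 points")
  o <- order(x); x <- x[o]; y <- y[o]
  mu0 <- x[which.max(y)]
  start <- c(A = max(y), mu = mu0, s = max(diff(range(x)) / 4, 1e-6))
  fit <- tryCatch(
    lm_least_squares(
      function(p) p[["A"]] * exp(-(x - p[["mu"]])^2 / (2 * p[["s"]]^2)),
      start, y, lower = c(A = 0, mu = -Inf, s = 1e-8), label = "pH profile"),
    error = function(e) NULL)
  if (is.null(fit)) {
    res <- list(optimum = mu0, parameters = c(A = max(y), mu = mu0, s = NA),
                method = "argmax", optimum_se = NA_real_,
                r_squared = NA_real_)
  } else {
    res <- list(optimum = fit$par[["mu"]],
                parameters = c(A = fit$par[["A"]], mu = fit$par[["mu"]],
                               s = fit$par[["s"]]),
                method = "fit", optimum_se = fit$se[["mu"]],
                r_squared = fit$r_squared)
  }
  boundary <- res$optimum <= min(x) || res$optimum >= max(x) ||
    which.max(y) %in% c(1L, length(y))
  res$optimum <- min(max(res$optimum, min(x)), max(x))
  res$boundary <- boundary
  res$x <- x; res$y <- y; res$what <- "pH optimum"
  class(res) <- "profile_fit"
  res
}

#' Estimate the thermal-inactivation midpoint
#'
#' Least-squares fit of a descending logistic
#' \eqn{a(T) = A / (1 + \exp((T - T_m)/w))} to an activity-vs-temperature
#' series; the midpoint \eqn{T_m} is the temperature of half-maximal
#' activity. Initialization interpolates the half-maximal temperature, so a
#' step-like profile yields the midpoint of the step interval. A profile
#' with no decline to half-maximal within the sampled range is flagged
#' (\code{boundary = TRUE}).
#'
#' @param temps >= 5 temperatures (deg C) bracketing the decline.
#' @param activities measured activities.
#' @return An object of class \code{profile_fit} with \code{optimum} = the
#'   half-maximal temperature (element \code{midpoint} is an alias).
#' @export
estimate_thermal_midpoint <- function(temps, activities) {
  x <- as.numeric(temps); y <- as.numeric(activities)
  stopifnot(length(x) == length(y))
  if (length(x) < 5L) stop("thermal midpoint estimation requires >= 5 points")
  o <- order(x); x <- x[o]; y <- y[o]
  half <- max(y) / 2
  below <- which(y <= half)[1]
  tm0 <- if (is.na(below) || below == 1L) stats::median(x) else {
    x0 <- x[below - 1L]; x1 <- x[below]
    y0 <- y[below - 1L]; y1 <- y[below]
    if (y1 == y0) (x0 + x1) / 2 else x0 + (half - y0) * (x1 - x0) / (y1 - y0)
  }
  start <- c(A = max(y), Tm = tm0, w = max(diff(range(x)) / 10, 1e-3))
  fit <- tryCatch(
    lm_least_squares(
      function(p) p[["A"]] / (1 + exp((x - p[["Tm"]]) / p[["w"]])),
      start, y, lower = c(A = 0, Tm = -Inf, w = 1e-8),
      label = "thermal profile"),
    error = function(e) NULL)
  if (is.null(fit)) {
    res <- list(optimum = tm0, parameters = c(A = max(y), Tm = tm0, w = NA),
                method = "argmax", optimum_se = NA_real_,
                r_squared = NA_real_)
  } else {
    res <- list(optimum = fit$par[["Tm"]],
                parameters = c(A = fit$par[["A"]], Tm = fit$par[["Tm"]],
                               w = fit$par[["w"]]),
                method = "fit", optimum_se = fit$se[["Tm"]],
                r_squared = fit$r_squared)
  }
  boundary <- !any(y <= half + 1e-12 * max(abs(y))) ||
    res$optimum <= min(x) || res$optimum >= max(x)
  res$optimum <- min(max(res$optimum, min(x)), max(x))
  res$midpoint <- res$optimum
  res$boundary <- boundary
  res$x <- x; res$y <- y; res$what <- "thermal midpoint"
  class(res) <- "profile_fit"
  res
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf("<profile_fit> %s = %.4g (%s%s%s)\n", x$what, x$optimum,
              x$method,
              if (is.finite(x$optimum_se)) sprintf(", se %.2g", x$optimum_se)
              else "",
              if (x$boundary) ", BOUNDARY: profile not peaked within range"
              else ""))
  invisible(x)
}

#' @export
coef.profile_fit <- function(object, ...) object$parameters

#' @export
plot.profile_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = x$what, ylab = "activity",
                 main = sprintf("%s = %.3g", x$what, x$optimum), ...)
  p <- x$parameters
  grid <- seq(min(x$x), max(x$x), length.out = 200)
  if (x$method == "fit") {
    curve_y <- if ("mu" %in% names(p))
      p[["A"]] * exp(-(grid - p[["mu"]])^2 / (2 * p[["s"]]^2))
    else p[["A"]] / (1 + exp((grid - p[["Tm"]]) / p[["w"]]))
    graphics::lines(grid, curve_y)
  }
  graphics::abline(v = x$optimum, lty = 2)
  invisible(x)
}
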