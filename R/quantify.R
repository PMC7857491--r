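#' Baseline intensity of a sample well
#'
#' The measured sample intensity at t = 0 (first read after preincubation),
#' \eqn{I_{M0}}, optionally averaged over the first \code{m} reads for noise
#' robustness.
#'
#' @param trace a [kinetic_trace()].
#' @param m number of initial reads to average (default 1, the t = 0 read).
#' @return numeric(1), AU.
#' @export
estimate_baseline <- function(trace, m = 1L) {
  stopifnot(inherits(trace, "kinetic_trace"))
  m <- as.integer(m)
  if (m < 1L || m > trace$n_reads)
    stop("m must lie in [1, n_reads]")
  mean(trace$intensities[seq_len(m)])
}

#' Linear drift slope of a control well
#'
#' Ordinary least-squares slope of intensity versus time over the full
#' trace of a substrate-only or enzyme-only control well; the estimator of
#' the control drift terms \eqn{dI_S/dt} and \eqn{dI_E/dt} in the trace
#' correction.
#'
#' @param control a [kinetic_trace()] with role \code{substrate_control} or
#'   \code{enzyme_control}, >= 3 reads.
#' @return numeric(1) slope in AU/min with attributes \code{se} (standard
#'   error) and \code{df}.
#' @export
estimate_drift <- function(control) {
  stopifnot(inherits(control, "kinetic_trace"))
  if (is.na(control$role) ||
      !control$role %in% c("substrate_control", "enzyme_control"))
    stop("estimate_drift expects a substrate_control or enzyme_control trace")
  if (control$n_reads < 3L)
    stop("drift estimation requires >= 3 reads")
  t <- control$times; y <- control$intensities
  n <- length(t)
  slope <- ols_slope(t, y)
  fitted <- mean(y) + slope * (t - mean(t))
  rss <- sum((y - fitted)^2)
  sxx <- sum((t - mean(t))^2)
  structure(slope, se = sqrt(rss / (n - 2L) / sxx), df = n - 2L)
}

#' Baseline- and drift-corrected sample trace
#'
#' Applies the EFQO correction
#' \deqn{I_C(t) = I_M(t) - I_{M0} - (dI_S/dt + dI_E/dt)\,t,}
#' subtracting the sample's own baseline and the summed linear drifts of
#' the substrate-only and enzyme-only controls. Negative corrected values
#' are preserved (diagnostic; see the below-detection handling in
#' [compute_activity()]).
#'
#' @param sample a [kinetic_trace()] with role \code{sample}.
#' @param I_M0 baseline, AU (e.g. [estimate_baseline()]).
#' @param s_S,s_E control drift slopes, AU/min (e.g. [estimate_drift()]).
#' @return An object of class \code{corrected_trace} with elements
#'   \code{well_id}, \code{times}, \code{corrected}, \code{baseline},
#'   \code{drift_substrate_slope}, \code{drift_enzyme_slope}.
#' @export
correct_trace <- function(sample, I_M0, s_S, s_E) {
  stopifnot(inherits(sample, "kinetic_trace"))
  if (is.na(sample$role) || sample$role != "sample")
    stop("correct_trace expects a trace with role 'sample'")
  I_M0 <- as.numeric(I_M0); s_S <- as.numeric(s_S); s_E <- as.numeric(s_E)
  stopifnot(is.finite(I_M0), is.finite(s_S), is.finite(s_E))
  corrected <- sample$intensities - I_M0 - (s_S + s_E) * sample$times
  structure(list(well_id = sample$well_id, times = sample$times,
                 corrected = corrected, baseline = I_M0,
                 drift_substrate_slope = s_S, drift_enzyme_slope = s_E),
            class = "corrected_trace")
}

#' @export
print.corrected_trace <- function(x, ...) {
  cat(sprintf("<corrected_trace> well %s: %d reads, I_C = %.4g..%.4g AU (baseline %.4g AU, drift %.4g AU/min)\n",
              x$well_id, length(x$times), min(x$corrected), max(x$corrected),
              x$baseline, x$drift_substrate_slope + x$drift_enzyme_slope))
  invisible(x)
}

trace_values <- function(x) {
  if (inherits(x, "corrected_trace")) list(times = x$times, y = x$corrected)
  else if (inherits(x, "kinetic_trace")) list(times = x$times, y = x$intensities)
  else stop("expected a kinetic_trace or corrected_trace")
}

#' Plateau intensity of a (corrected) trace
#'
#' Mean of the last \code{m} values, interpreted as \eqn{I_{max}}, the
#' fluorescence of the fully digested substrate amount. If the trace is
#' still rising at the end -- OLS slope over those \code{m} points exceeding
#' 5\% of the trace's maximal rolling slope -- a non-plateau warning is
#' emitted alongside the value.
#'
#' @param x a [kinetic_trace()] or [corrected_trace()].
#' @param m number of terminal reads to average (default 6).
#' @return numeric(1), AU.
#' @export
estimate_plateau <- function(x, m = 6L) {
  v <- trace_values(x)
  m <- as.integer(m)
  n <- length(v$y)
  if (m < 1L || m > n) stop("m must lie in [1, n_reads]")
  tail_idx <- seq(n - m + 1L, n)
  value <- mean(v$y[tail_idx])
  if (m >= 3L) {
    tail_slope <- ols_slope(v$times[tail_idx], v$y[tail_idx])
    max_slope <- max(abs(rolling_slopes(v$times, v$y, m)))
    if (max_slope > 0 && abs(tail_slope) > 0.05 * max_slope)
      warning(sprintf("well %s: trace has not plateaued (tail slope %.3g AU/min)",
                      if (!is.null(x$well_id)) x$well_id else "?", tail_slope))
  }
  value
}

ols_slope <- function(t, y) {
  tc <- t - mean(t)
  sum(tc * (y - mean(y))) / sum(tc^2)
}

rolling_slopes <- function(t, y, w) {
  n <- length(y)
  if (n < w) return(ols_slope(t, y))
  vapply(seq_len(n - w + 1L), function(i) {
    idx <- i:(i + w - 1L)
    ols_slope(t[idx], y[idx])
  }, numeric(1))
}

#' Fit the fluorescence calibration line
#'
#' OLS regression of plateau fluorescence \eqn{I_{max}} on moles of
#' substrate (free intercept). The slope is the fluorescence coefficient
#' \eqn{k} (AU per mole of hydrolyzed substrate) used to convert corrected
#' fluorescence rates into molar activities.
#'
#' @param amounts substrate amounts, mol (>= 2 distinct values, all >= 0).
#' @param imax plateau intensities, AU, same length.
#' @return An object of class \code{efqo_calibration} with elements
#'   \code{k}, \code{intercept}, \code{r_squared}, \code{k_se},
#'   \code{n_points}, \code{substrate_amounts}, \code{imax_values}.
#' @export
fit_calibration <- function(amounts, imax) {
  amounts <- as.numeric(amounts); imax <- as.numeric(imax)
  stopifnot(length(amounts) == length(imax))
  if (any(amounts < 0)) stop("substrate amounts must be >= 0")
  if (length(unique(amounts)) < 2L)
    stop("calibration requires >= 2 distinct substrate amounts")
  fit <- stats::lm(imax ~ amounts)
  k <- unname(stats::coef(fit)[2])
  if (!is.finite(k) || k <= 0)
    stop("invalid calibration: non-positive fitted slope")
  r2 <- if (length(amounts) > 2L) summary(fit)$r.squared else 1
  structure(list(k = k,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = min(max(r2, 0), 1),
                 k_se = unname(summary(fit)$coefficients[2, 2]),
                 n_points = length(amounts),
                 substrate_amounts = amounts,
                 imax_values = imax),
            class = "efqo_calibration")
}

#' @export
print.efqo_calibration <- function(x, ...) {
  cat(sprintf("<efqo_calibration> k = %.6g AU/mol (se %.3g), intercept %.4g AU, R^2 = %.5f, n = %d\n",
              x$k, x$k_se, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
coef.efqo_calibration <- function(object, ...) {
  c(intercept = object$intercept, k = object$k)
}

#' Initial-rate slope of a corrected trace
#'
#' Estimates \eqn{dI_C/dt} as a linear-regression slope. The default
#' \code{"initial_window"} policy fits the first \code{window} reads
#' (12 reads = 1 h at 5-min spacing), appropriate while substrate is in
#' excess; \code{"max_rolling"} returns the steepest OLS slope over all
#' contiguous windows of that width.
#'
#' @param corrected a [corrected_trace()] (or a [kinetic_trace()], fitted on
#'   raw intensities).
#' @param window window width in reads (default 12).
#' @param policy \code{"initial_window"} or \code{"max_rolling"}.
#' @return List with \code{slope} (AU/min), \code{window} = c(t_start,
#'   t_end) in min, \code{r_squared}, \code{n}.
#' @export
initial_rate <- function(corrected, window = 12L,
                         policy = c("initial_window", "max_rolling")) {
  policy <- match.arg(policy)
  v <- trace_values(corrected)
  n <- length(v$y)
  if (n < 4L) stop("initial_rate requires >= 4 reads")
  window <- as.integer(window)
  if (window < 4L) stop("window must span >= 4 reads")
  if (window > n) {
    warning(sprintf("window (%d reads) exceeds trace length (%d); using all reads",
                    window, n))
    window <- n
  }
  idx <- if (policy == "initial_window") {
    seq_len(window)
  } else {
    slopes <- rolling_slopes(v$times, v$y, window)
    i0 <- which.max(slopes)
    i0:(i0 + window - 1L)
  }
  t <- v$times[idx]; y <- v$y[idx]
  slope <- ols_slope(t, y)
  fitted <- mean(y) + slope * (t - mean(t))
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(slope = slope, window = c(t[1], t[length(t)]),
       r_squared = r2, n = length(idx))
}

#' Absolute, specific and integrated activity of one well
#'
#' Converts the corrected fluorescence kinetics into molar turnover using
#' the calibration coefficient \eqn{k}:
#' \deqn{A = \frac{dI_C/dt}{k} \quad [mol/min],}
#' with \eqn{dI_C/dt} from [initial_rate()]. Specific activity is
#' \eqn{A} divided by the well's protein mass (mg); integrated activity is
#' the trapezoidal area under \eqn{I_C(t)} divided by \eqn{k} (mol min)
#' over the full assay window. A negative fitted slope is reported as-is
#' with \code{below_detection = TRUE} rather than truncated.
#'
#' @param corrected a [corrected_trace()].
#' @param calib an [fit_calibration()] model or a positive numeric \eqn{k}
#'   (AU/mol).
#' @param protein_mass protein per well in mg, or \code{NULL} to omit
#'   specific activity.
#' @param window,policy passed to [initial_rate()].
#' @return An object of class \code{activity_result} (also a one-row
#'   data.frame via [as.data.frame()]): \code{well_id}, \code{A},
#'   \code{specific_activity}, \code{integrated_activity},
#'   \code{rate_slope}, \code{fit_window}, \code{fit_r_squared},
#'   \code{below_detection}.
#' @export
compute_activity <- function(corrected, calib, protein_mass = NULL,
                             window = 12L,
                             policy = c("initial_window", "max_rolling")) {
  policy <- match.arg(policy)
  k <- if (inherits(calib, "efqo_calibration")) calib$k else as.numeric(calib)
  if (!is.finite(k) || k <= 0)
    stop("invalid calibration: k must be a positive fluorescence coefficient")
  rate <- initial_rate(corrected, window = window, policy = policy)
  A <- rate$slope / k
  v <- trace_values(corrected)
  integrated <- pracma::trapz(v$times, v$y) / k
  spec <- if (!is.null(protein_mass)) {
    stopifnot(protein_mass > 0)
    A / protein_mass
  } else NA_real_
  structure(list(well_id = corrected$well_id, A = A,
                 specific_activity = spec,
                 integrated_activity = integrated,
                 rate_slope = rate$slope, fit_window = rate$window,
                 fit_r_squared = rate$r_squared,
                 below_detection = rate$slope < 0),
            class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("<activity_result> well %s: A = %.4g mol/min%s, integrated %.4g mol*min (window %g-%g min, R^2 %.4f)%s\n",
              x$well_id, x$A,
              if (is.finite(x$specific_activity))
                sprintf(", specific %.4g mol/min/mg", x$specific_activity)
              else "",
              x$integrated_activity, x$fit_window[1], x$fit_window[2],
              x$fit_r_squared,
              if (x$below_detection) " [below detection]" else ""))
  invisible(x)
}

#' @export
as.data.frame.activity_result <- function(x, ...) {
  data.frame(well = x$well_id, A = x$A,
             specific_activity = x$specific_activity,
             integrated_activity = x$integrated_activity,
             rate_slope = x$rate_slope,
             fit_t_start = x$fit_window[1], fit_t_end = x$fit_window[2],
             fit_r_squared = x$fit_r_squared,
             below_detection = x$below_detection,
             stringsAsFactors = FALSE)
}

#' Aggregate per-well activities into per-condition summaries
#'
#' Mean, standard error of the mean (SEM = sd/sqrt(n)) and n per condition
#' for the activity columns. With a single replicate the SEM is reported as
#' \code{NA}.
#'
#' @param results data.frame of per-well activities (e.g. from
#'   [quantify_plate()]) containing a grouping column and numeric activity
#'   columns.
#' @param by grouping column name (default \code{"condition"}).
#' @param columns numeric columns to summarize.
#' @return data.frame with one row per condition: \code{<col>_mean},
#'   \code{<col>_sem} for each column, plus \code{n}.
#' @export
aggregate_replicates <- function(results, by = "condition",
                                 columns = c("A", "specific_activity",
                                             "integrated_activity")) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) stop("no results to aggregate")
  if (!by %in% names(results)) stop("grouping column '", by, "' not found")
  columns <- intersect(columns, names(results))
  if (!length(columns)) stop("no activity columns found to aggregate")
  out <- lapply(split(results, results[[by]]), function(block) {
    row <- data.frame(condition = block[[by]][1], n = nrow(block),
                      stringsAsFactors = FALSE)
    names(row)[1] <- by
    for (col in columns) {
      vals <- block[[col]]
      row[[paste0(col, "_mean")]] <- mean(vals)
      row[[paste0(col, "_sem")]] <-
        if (length(vals) >= 2L) stats::sd(vals) / sqrt(length(vals)) else NA_real_
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Quantify a whole plate
#'
#' End-to-end per-well quantification: estimates the control drifts (OLS on
#' every substrate-only and enzyme-only control, averaged per role),
#' subtracts each sample's own baseline and the summed drifts
#' ([correct_trace()]), and computes absolute/specific/integrated activity
#' ([compute_activity()]) for every sample well, joined with the layout
#' condition columns.
#'
#' @param dataset a [plate_dataset()] containing at least one sample, one
#'   substrate-control and one enzyme-control well.
#' @param calib calibration model or numeric k (AU/mol).
#' @param window,policy,baseline_m rate-window and baseline settings.
#' @return data.frame with one row per sample well: layout annotation plus
#'   the [compute_activity()] columns.
#' @export
quantify_plate <- function(dataset, calib, window = 12L,
                           policy = c("initial_window", "max_rolling"),
                           baseline_m = 1L) {
  stopifnot(inherits(dataset, "plate_dataset"))
  policy <- match.arg(policy)
  roles <- vapply(dataset$traces, `[[`, character(1), "role")
  sub_ctrl <- dataset$traces[roles == "substrate_control"]
  enz_ctrl <- dataset$traces[roles == "enzyme_control"]
  samples <- dataset$traces[roles == "sample"]
  if (!length(samples)) stop("plate contains no sample wells")
  if (!length(sub_ctrl) || !length(enz_ctrl))
    stop("quantification requires at least one substrate_control and one enzyme_control well")
  s_S <- mean(vapply(sub_ctrl, function(tr) as.numeric(estimate_drift(tr)),
                     numeric(1)))
  s_E <- mean(vapply(enz_ctrl, function(tr) as.numeric(estimate_drift(tr)),
                     numeric(1)))
  rows <- lapply(samples, function(tr) {
    i0 <- estimate_baseline(tr, m = baseline_m)
    cor <- correct_trace(tr, i0, s_S, s_E)
    lay <- dataset$layout[match(tr$well_id, dataset$layout$well), , drop = FALSE]
    pm <- if ("protein_mg" %in% names(lay) && is.finite(lay$protein_mg) &&
              lay$protein_mg > 0) lay$protein_mg else NULL
    act <- compute_activity(cor, calib, protein_mass = pm,
                            window = window, policy = policy)
    df <- as.data.frame(act)
    extra <- lay[setdiff(names(lay), c("well", names(df)))]
    cbind(df["well"], extra, df[setdiff(names(df), "well")],
          row.names = NULL)
  })
  res <- do.call(rbind, rows)
  res <- res[order(well_index(res$well)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Calibrate from a substrate-dilution plate
#'
#' Runs the correction on every sample well of a dilution-series plate,
#' takes each well's plateau \eqn{I_{max}} ([estimate_plateau()]) and fits
#' the calibration line of \eqn{I_{max}} versus moles of substrate
#' (substrate_conc_M x volume) with [fit_calibration()].
#'
#' @param dataset a [plate_dataset()] whose layout carries
#'   \code{substrate_conc_M} for the sample wells.
#' @param volume reaction volume in L used to convert concentrations to
#'   moles (default 1e-4, the standard 100-ul reaction).
#' @param plateau_m terminal reads averaged for the plateau.
#' @param baseline_m initial reads averaged for the baseline.
#' @return An \code{efqo_calibration}.
#' @export
calibrate_plate <- function(dataset, volume = 1e-4, plateau_m = 6L,
                            baseline_m = 1L) {
  stopifnot(inherits(dataset, "plate_dataset"))
  roles <- vapply(dataset$traces, `[[`, character(1), "role")
  sub_ctrl <- dataset$traces[roles == "substrate_control"]
  enz_ctrl <- dataset$traces[roles == "enzyme_control"]
  samples <- dataset$traces[roles == "sample"]
  if (!length(samples)) stop("calibration plate contains no sample wells")
  if (!length(sub_ctrl) || !length(enz_ctrl))
    stop("calibration requires substrate_control and enzyme_control wells")
  if (!"substrate_conc_M" %in% names(dataset$layout))
    stop("layout lacks substrate_conc_M needed for calibration")
  s_S <- mean(vapply(sub_ctrl, function(tr) as.numeric(estimate_drift(tr)),
                     numeric(1)))
  s_E <- mean(vapply(enz_ctrl, function(tr) as.numeric(estimate_drift(tr)),
                     numeric(1)))
  amounts <- numeric(length(samples))
  imax <- numeric(length(samples))
  for (i in seq_along(samples)) {
    tr <- samples[[i]]
    cor <- correct_trace(tr, estimate_baseline(tr, m = baseline_m), s_S, s_E)
    imax[i] <- estimate_plateau(cor, m = plateau_m)
    conc <- dataset$layout$substrate_conc_M[match(tr$well_id,
                                                  dataset$layout$well)]
    amounts[i] <- conc * volume
  }
  fit_calibration(amounts, imax)
}
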