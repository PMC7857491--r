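#' Fold change between two groups
#'
#' Ratio of group means with a seeded bootstrap percentile confidence
#' interval. Negative group means are flagged rather than rejected
#' (below-detection semantics: a group whose corrected slope is negative).
#'
#' @param groupA,groupB numeric activity vectors; \code{mean(groupB)} must
#'   be nonzero.
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level.
#' @return An object of class \code{group_comparison}: \code{fold_change},
#'   \code{log2_fold}, \code{ci} (percentile bootstrap, method-tagged),
#'   per-group mean/SEM/n, \code{below_detection}.
#' @examples
#' fold_change(c(290, 310), c(0.9, 1.1))
#' @export
fold_change <- function(groupA, groupB, n_boot = 2000L, seed = 1L,
                        conf = 0.95) {
  groupA <- as.numeric(groupA); groupB <- as.numeric(groupB)
  if (!length(groupA) || !length(groupB))
    stop("both groups must be non-empty")
  mB <- mean(groupB)
  if (mB == 0) stop("fold change undefined: zero denominator group mean")
  mA <- mean(groupA)
  fc <- mA / mB
  below <- mA < 0 || mB < 0
  ci <- if (length(groupA) >= 2L || length(groupB) >= 2L) {
    boots <- with_local_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        a <- sample(groupA, replace = TRUE)
        b <- sample(groupB, replace = TRUE)
        if (mean(b) == 0) NA_real_ else mean(a) / mean(b)
      }, numeric(1))
    })
    stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    na.rm = TRUE, names = FALSE)
  } else c(NA_real_, NA_real_)
  structure(list(fold_change = fc,
                 log2_fold = if (fc > 0) log2(fc) else NA_real_,
                 ci = ci, ci_method = "bootstrap percentile",
                 conf = conf, n_boot = n_boot, seed = as.integer(seed),
                 mean_A = mA, mean_B = mB,
                 sem_A = sem(groupA), sem_B = sem(groupB),
                 n_A = length(groupA), n_B = length(groupB),
                 below_detection = below),
            class = "group_comparison")
}

sem <- function(x) if (length(x) >= 2L) stats::sd(x) / sqrt(length(x)) else NA_real_

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> fold change = %.4g (log2 %.3g)%s\n",
              x$fold_change, x$log2_fold,
              if (x$below_detection) " [below-detection group mean]" else ""))
  if (all(is.finite(x$ci)))
    cat(sprintf("  %g%% CI [%.4g, %.4g] (%s, %d resamples, seed %d)\n",
                100 * x$conf, x$ci[1], x$ci[2], x$ci_method, x$n_boot, x$seed))
  cat(sprintf("  A: mean %.4g (n=%d), B: mean %.4g (n=%d)\n",
              x$mean_A, x$n_A, x$mean_B, x$n_B))
  invisible(x)
}

#' One-way ANOVA with Dunnett's many-to-one comparison
#'
#' Compares every treatment group against a designated control using
#' Dunnett's procedure: pooled-variance t statistics
#' \eqn{t_i = (\bar{x}_i - \bar{x}_0) / (s\sqrt{1/n_i + 1/n_0})} with
#' \eqn{N - k} degrees of freedom, and two-sided adjusted p-values
#' \eqn{p_i = P(\max_j |T_j| \ge |t_i|)} under the equicorrelated
#' multivariate-t distribution with correlations
#' \eqn{\rho_{ij} = \lambda_i\lambda_j}, \eqn{\lambda_i =
#' \sqrt{n_i/(n_i+n_0)}}. The multivariate probability is evaluated by
#' deterministic Gauss-Hermite x Gauss-Legendre quadrature (absolute
#' accuracy well below 1e-6), not by simulation. Assumes homogeneous
#' within-group variance (the pooled one-way ANOVA estimate).
#'
#' Significance stars follow the four-tier scheme
#' 0.05 / 0.01 / 0.001 / 0.0001.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2)
#'   including the control.
#' @param control name of the control group.
#' @param alpha family-wise significance level (annotation only).
#' @return An object of class \code{dunnett_result} whose \code{table}
#'   element has one row per treatment: \code{group}, \code{estimate}
#'   (mean difference vs control), \code{t}, \code{df}, \code{p_unadjusted},
#'   \code{p_adjusted}, \code{stars}.
#' @export
dunnett_vs_control <- function(groups, control, alpha = 0.05) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (!control %in% names(groups)) stop("control group '", control, "' not found")
  if (length(groups) < 2L) stop("need >= 2 groups including the control")
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2L)) stop("every group needs n >= 2")
  x0 <- groups[[control]]
  trt <- groups[names(groups) != control]
  N <- sum(ns); k <- length(groups)
  df <- N - k
  s2 <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / df
  n0 <- length(x0)
  ni <- vapply(trt, length, integer(1))
  est <- vapply(trt, mean, numeric(1)) - mean(x0)
  se <- sqrt(s2 * (1 / ni + 1 / n0))
  tstat <- est / se
  lambda <- sqrt(ni / (ni + n0))
  p_unadj <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p_adj <- vapply(abs(tstat), function(q)
    1 - pmax_abs_dunnett(q, lambda, df), numeric(1))
  p_adj <- pmin(pmax(p_adj, p_unadj), 1)  # monotone vs unadjusted, in [0,1]
  tab <- data.frame(group = names(trt), estimate = unname(est),
                    t = unname(tstat), df = df,
                    p_unadjusted = unname(p_unadj),
                    p_adjusted = unname(p_adj),
                    stars = significance_stars(unname(p_adj)),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(control = control, alpha = alpha, df = df,
                 pooled_sd = sqrt(s2), table = tab),
            class = "dunnett_result")
}

# P(max_i |T_i| <= q) for the Dunnett equicorrelated multivariate t:
# condition on the pooled-variance scale W = sigma_hat/sigma ~ sqrt(chi^2_df/df)
# and on the control's standardized mean Z0, then the T_i are independent.
# Outer integral over w by Gauss-Legendre on (0, w_hi), inner over z by
# Gauss-Hermite; both deterministic.
pmax_abs_dunnett <- function(q, lambda, df, n_gh = 80L, n_gl = 96L) {
  if (q <= 0) return(0)
  gh <- pracma::gaussHermite(n_gh)
  z <- sqrt(2) * gh$x
  wz <- gh$w / sqrt(pi)
  w_hi <- sqrt(stats::qchisq(1 - 1e-13, df) / df)
  gl <- pracma::gaussLegendre(n_gl, 0, w_hi)
  w <- gl$x
  # density of W = sqrt(chi^2_df / df)
  fw <- 2 * df * w * stats::dchisq(df * w^2, df)
  qw <- outer(z * 0, q * w, `+`)     # n_gh x n_gl matrix of q*w_i
  prod_z <- matrix(1, length(z), length(w))
  for (j in seq_along(lambda)) {
    s <- sqrt(1 - lambda[j]^2)
    lz <- lambda[j] * z
    prod_z <- prod_z * (stats::pnorm((qw + lz) / s) -
                          stats::pnorm((-qw + lz) / s))
  }
  inner <- as.numeric(crossprod(wz, prod_z))
  min(max(sum(gl$w * fw * inner), 0), 1)
}

significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (!is.finite(pi)) return(NA_character_)
    if (pi <= 1e-4) "****" else if (pi <= 1e-3) "***"
    else if (pi <= 0.01) "**" else if (pi <= 0.05) "*" else "ns"
  }, character(1))
}

#' @export
print.dunnett_result <- function(x, ...) {
  cat(sprintf("<dunnett_result> vs control '%s' (df = %d, pooled sd = %.4g, alpha = %g)\n",
              x$control, x$df, x$pooled_sd, x$alpha))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Rank substrate variants by activity
#'
#' Orders conditions (e.g. substrates differing in their terminal 5' base)
#' by descending mean activity. Conditions whose mean +/- SEM intervals
#' overlap are flagged as tied (a shared \code{tie_group}) rather than
#' arbitrarily broken.
#'
#' @param activities_by_variant either a named list of replicate activity
#'   vectors, or a data.frame with columns \code{variant}, \code{mean},
#'   \code{sem}.
#' @return data.frame sorted by descending mean: \code{variant},
#'   \code{mean}, \code{sem}, \code{rank}, \code{tie_group}, \code{tied}.
#' @export
rank_preference <- function(activities_by_variant) {
  if (is.data.frame(activities_by_variant)) {
    stopifnot(all(c("variant", "mean") %in% names(activities_by_variant)))
    df <- activities_by_variant
    if (!"sem" %in% names(df)) df$sem <- NA_real_
    df <- df[, c("variant", "mean", "sem")]
  } else {
    stopifnot(is.list(activities_by_variant),
              !is.null(names(activities_by_variant)))
    df <- data.frame(variant = names(activities_by_variant),
                     mean = vapply(activities_by_variant, mean, numeric(1)),
                     sem = vapply(activities_by_variant, sem, numeric(1)),
                     stringsAsFactors = FALSE)
  }
  if (nrow(df) < 2L) stop("ranking requires >= 2 variants")
  df <- df[order(-df$mean), , drop = FALSE]
  rownames(df) <- NULL
  df$rank <- seq_len(nrow(df))
  # chain overlapping mean +/- SEM intervals into tie groups
  tie_group <- integer(nrow(df))
  tie_group[1] <- 1L
  for (i in 2:nrow(df)) {
    lo_prev <- df$mean[i - 1] - ifelse(is.na(df$sem[i - 1]), 0, df$sem[i - 1])
    hi_cur <- df$mean[i] + ifelse(is.na(df$sem[i]), 0, df$sem[i])
    tie_group[i] <- if (hi_cur >= lo_prev) tie_group[i - 1] else
      tie_group[i - 1] + 1L
  }
  df$tie_group <- tie_group
  df$tied <- ave(tie_group, tie_group, FUN = length) > 1
  df
}
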