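#' Integrated Michaelis-Menten progress curve
#'
#' Remaining substrate concentration for a single-substrate irreversible
#' Michaelis-Menten reaction, i.e. the solution of
#' \deqn{dS/dt = -V_{max} S / (K_m + S), \quad S(0) = S_0,}
#' which satisfies the implicit conservation relation
#' \eqn{K_m \ln(S_0/S) + (S_0 - S) = V_{max} t}. Evaluated in closed form via
#' the principal branch of the Lambert W function,
#' \eqn{S(t) = K_m W_0\!\left[(S_0/K_m)\exp((S_0 - V_{max} t)/K_m)\right]},
#' with a bracketed root solve of the conservation relation as fallback when
#' the W argument over/underflows.
#'
#' @param S0 initial substrate concentration, mol/L (>= 0).
#' @param Km Michaelis constant, mol/L (> 0 whenever Vmax > 0).
#' @param Vmax maximal rate, mol/(L min) (>= 0).
#' @param t time(s), min (>= 0); vectorized.
#' @return numeric vector \code{S(t)}, monotone non-increasing,
#'   \code{0 <= S(t) <= S0}.
#' @examples
#' integrated_mm_substrate(1e-6, 1e-6, 1e-7, c(0, 11.93147))
#' @export
integrated_mm_substrate <- function(S0, Km, Vmax, t) {
  if (any(c(S0, Km, Vmax) < 0) || any(t < 0))
    stop("integrated_mm_substrate: all arguments must be non-negative")
  if (Vmax > 0 && Km <= 0)
    stop("integrated_mm_substrate: Km must be > 0 when Vmax > 0")
  if (S0 == 0 || Vmax == 0) return(rep(S0, length(t)))
  arg <- (S0 / Km) * exp((S0 - Vmax * t) / Km)
  S <- vapply(seq_along(t), function(i) {
    a <- arg[i]
    if (is.finite(a) && a >= 0) {
      w <- lambert_w0(a)
      if (is.finite(w)) return(Km * w)
    }
    mm_root(S0, Km, Vmax, t[i])
  }, numeric(1))
  S <- pmin(pmax(S, 0), S0)
  if (any(!is.finite(S)))
    stop("integrated_mm_substrate: closed-form evaluation failed to converge")
  # verify the conservation relation (skip numerically exhausted points);
  # never return a silently wrong value
  chk <- S > S0 * 1e-12
  if (any(chk)) {
    resid <- abs(Km * log(S0 / S[chk]) + (S0 - S[chk]) - Vmax * t[chk])
    if (any(resid > 1e-6 * pmax(Vmax * t[chk], S0)))
      stop("integrated_mm_substrate: closed-form evaluation failed to converge")
  }
  S
}

# Principal branch W0 of the Lambert W function for x >= 0: solves
# w + log(w) = log(x) by guarded Newton iteration (the equation is monotone
# for w > 0, and x >= 0 keeps us off the branch point). Returns NA on
# non-convergence so the caller can fall back to the bracketed root solve.
lambert_w0 <- function(x) {
  if (x == 0) return(0)
  if (!is.finite(x) || x < 0) return(NA_real_)
  L <- log(x)
  w <- if (L > 1) L - log(L) else x / (1 + x)  # asymptotic / small-x guess
  w <- max(w, 1e-300)
  for (i in 1:100) {
    g <- w + log(w) - L
    dw <- g / (1 + 1 / w)
    w_new <- w - dw
    if (w_new <= 0) w_new <- w / 2   # keep iterates in the domain
    if (abs(w_new - w) <= 1e-15 * max(w_new, 1e-300)) return(w_new)
    w <- w_new
  }
  NA_real_
}

# Bracketed solve of Km*log(S0/S) + (S0 - S) - Vmax*t = 0 on (0, S0].
mm_root <- function(S0, Km, Vmax, t) {
  f <- function(S) Km * log(S0 / S) + (S0 - S) - Vmax * t
  lo <- S0 * 1e-18
  if (f(lo) < 0) return(0)  # substrate numerically exhausted
  stats::uniroot(f, lower = lo, upper = S0, tol = S0 * 1e-14)$root
}
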