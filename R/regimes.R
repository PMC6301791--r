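#' Regime structure of an allelic manifold
#'
#' On log-log axes, an allelic manifold traced by varying the RNAP binding
#' factor P exhibits up to five asymptotic regimes: (1) both channels
#' background-dominated, (2) one channel proportional to P while the other
#' is still background, (3) both proportional (the parallel-offset segment
#' whose offset measures 1/(1+F) or \eqn{\alpha'\beta'}), (4) one channel
#' saturated, (5) both saturated. The interior boundaries are the P values
#' where adjacent dominant terms of the exact rate expressions cross:
#'
#' * repression: `tbg/tsat`, `(1+F)*tbg/tsat`, `1`, `1+F`
#' * stabilization/acceleration: `tbg/(alpha'*beta'*tsat)`, `tbg/tsat`,
#'   `1/alpha'`, `1`
#'
#' These crossover boundaries tile (0, Inf) into five contiguous ranges.
#' Regimes are meaningful only when the boundaries are strictly increasing
#' (which requires F > 1 for repression, and
#' \eqn{t_{sat}/t_{bg} > \alpha'\beta' > 1} for activation); otherwise a
#' `regimes_undefined` error is raised rather than a silent answer.
#'
#' @param mechanism One of `"repression"`, `"stabilization"`,
#'   `"acceleration"`.
#' @param tsat,tbg Saturated and background transcription rates (a.u.).
#' @param F TF binding factor (repression and, with `alpha`, activation).
#' @param alpha,beta Cooperativity and acceleration factors (activation
#'   mechanisms; `beta` is forced to 1 for stabilization).
#' @return `regime_boundaries`: the four interior P boundaries, increasing.
#' @export
regime_boundaries <- function(mechanism = c("repression", "stabilization",
                                            "acceleration"),
                              tsat, tbg, F = 0, alpha = 1, beta = 1) {
  mechanism <- match.arg(mechanism)
  check_nonneg(tsat = tsat, tbg = tbg, F = F, alpha = alpha, beta = beta)
  if (mechanism == "stabilization") beta <- 1
  if (mechanism == "repression") {
    b <- c(tbg / tsat, (1 + F) * tbg / tsat, 1, 1 + F)
    ok <- F > 1 && tbg > 0
  } else {
    ap <- alpha_prime(alpha, F)
    bp <- beta_prime(alpha, beta, F)
    b <- c(tbg / (ap * bp * tsat), tbg / tsat, 1 / ap, 1)
    ok <- ap * bp > 1 && tbg > 0
  }
  if (!ok || any(diff(b) <= 0)) {
    stop_allelic(
      paste("regimes undefined: crossover boundaries do not form five",
            "ordered ranges (needs F > 1 for repression, or",
            "tsat/tbg >> alpha' >= alpha'*beta' > 1 for activation)"),
      "regimes_undefined")
  }
  b
}

#' Classify a point of an allelic manifold into a regime
#'
#' Assigns the regime (1-5) whose P-range contains `P`, and evaluates both
#' the exact model rates and the regime's dominant-term approximations at
#' that P. A `strictness` factor > 1 shrinks each regime symmetrically
#' about its log-midpoint (half-infinite outer regimes shrink only on their
#' finite side); a point falling in the excluded buffer is classified
#' `NA` with the two flanking regimes reported.
#'
#' @inheritParams regime_boundaries
#' @param P RNAP binding factor of the point, > 0.
#' @param strictness Range-shrink factor, >= 1; default 1 (exact tiling).
#' @return An object of class `"regime_label"`: list with `index` (1-5 or
#'   NA), `mechanism`, `P`, `range` (the unshrunk regime range),
#'   `approx_t_minus`, `approx_t_plus`, `exact_t_minus`, `exact_t_plus`.
#' @export
#' @examples
#' classify_regime(1e-2, "repression", tsat = 15.1, tbg = 0.0023, F = 23.9)
classify_regime <- function(P, mechanism = c("repression", "stabilization",
                                             "acceleration"),
                            tsat, tbg, F = 0, alpha = 1, beta = 1,
                            strictness = 1) {
  mechanism <- match.arg(mechanism)
  stopifnot(length(P) == 1, is.numeric(P), P > 0, strictness >= 1)
  if (mechanism == "stabilization") beta <- 1
  b <- regime_boundaries(mechanism, tsat, tbg, F, alpha, beta)
  lo <- c(0, b)
  hi <- c(b, Inf)
  idx <- findInterval(P, b) + 1L  # 1..5; boundary point goes up
  # strictness buffer in log space
  if (strictness > 1) {
    llo <- log(lo[idx]); lhi <- log(hi[idx])
    inside <- if (is.finite(llo) && is.finite(lhi)) {
      m <- (llo + lhi) / 2; h <- (lhi - llo) / 2
      abs(log(P) - m) <= h / strictness
    } else if (is.finite(lhi)) {        # regime 1
      log(P) <= lhi - (1 - 1 / strictness)
    } else {                            # regime 5
      log(P) >= llo + (1 - 1 / strictness)
    }
    if (!inside) idx <- NA_integer_
  }
  approx <- if (!is.na(idx)) {
    regime_approx(idx, P, mechanism, tsat, tbg, F, alpha, beta)
  } else list(t_minus = NA_real_, t_plus = NA_real_)
  tm <- t_minus(P, tsat, tbg)
  tp <- switch(mechanism,
    repression    = t_plus_repression(P, F, tsat, tbg),
    stabilization = t_plus_activation(P, F, alpha, tsat, tbg),
    acceleration  = t_plus_acceleration(P, F, alpha, beta, tsat, tbg))
  structure(list(index = idx, mechanism = mechanism, P = P,
                 range = if (!is.na(idx)) c(lo[idx], hi[idx]) else c(NA, NA),
                 approx_t_minus = approx$t_minus,
                 approx_t_plus = approx$t_plus,
                 exact_t_minus = tm, exact_t_plus = tp),
            class = "regime_label")
}

# dominant-term approximations per regime (Fig-style asymptotics)
regime_approx <- function(index, P, mechanism, tsat, tbg, F, alpha, beta) {
  if (mechanism == "repression") {
    tm <- switch(index, tbg, tsat * P, tsat * P, tsat, tsat)
    tp <- switch(index, tbg, tbg, tsat * P / (1 + F), tsat * P / (1 + F),
                 tsat)
  } else {
    ap <- alpha_prime(alpha, F)
    bp <- if (mechanism == "stabilization") 1 else beta_prime(alpha, beta, F)
    tm <- switch(index, tbg, tbg, tsat * P, tsat * P, tsat)
    tp <- switch(index, tbg, bp * tsat * ap * P, bp * tsat * ap * P,
                 bp * tsat, bp * tsat)
  }
  list(t_minus = tm, t_plus = tp)
}

#' Characteristic t+/t- ratio of the parallel regime
#'
#' In regime 3 both channels are proportional to P and the manifold runs
#' parallel to the diagonal, offset by a constant ratio: `1/(1+F)` under
#' repression, \eqn{\alpha'} under stabilization and \eqn{\alpha'\beta'}
#' under acceleration. This offset is what the manifold geometry measures
#' directly.
#'
#' @inheritParams regime_boundaries
#' @param regime Regime index; only 3 is supported.
#' @return Dimensionless ratio t+/t- deep in regime 3.
#' @export
regime_ratio <- function(regime, mechanism = c("repression", "stabilization",
                                               "acceleration"),
                         F = 0, alpha = 1, beta = 1) {
  mechanism <- match.arg(mechanism)
  if (!identical(as.integer(regime), 3L)) {
    stop_allelic("t+/t- ratio is constant only in regime 3",
                 "unsupported_regime")
  }
  check_nonneg(F = F, alpha = alpha, beta = beta)
  switch(mechanism,
    repression    = 1 / (1 + F),
    stabilization = alpha_prime(alpha, F),
    acceleration  = alpha_prime(alpha, F) * beta_prime(alpha, beta, F))
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("<regime %s> mechanism=%s P=%.3g range=[%.3g, %.3g)\n",
              ifelse(is.na(x$index), "NA (boundary buffer)", x$index),
              x$mechanism, x$P, x$range[1], x$range[2]))
  cat(sprintf("  exact  t-=%.4g t+=%.4g\n", x$exact_t_minus, x$exact_t_plus))
  cat(sprintf("  approx t-=%.4g t+=%.4g\n", x$approx_t_minus,
              x$approx_t_plus))
  invisible(x)
}
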