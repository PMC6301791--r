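#' Transcription rate without the transcription factor
#'
#' Equilibrium-occupancy model of a bacterial promoter read out in the
#' absence of the regulating TF. The promoter is either unbound (weight 1)
#' or RNAP-bound (weight P); only the RNAP-bound state initiates
#' transcripts, at rate `tsat`, and a constant background `tbg` is added:
#' \deqn{t^- = t_{sat} \frac{P}{1 + P} + t_{bg}.}
#'
#' @param P RNAP binding factor(s), dimensionless, \eqn{\ge 0}.
#' @param tsat Transcript initiation rate of an RNAP-saturated promoter
#'   (arbitrary units).
#' @param tbg Background transcription rate (same units), independent of
#'   the assayed RNAP site.
#' @return Transcription rate(s) in the same arbitrary units; strictly
#'   increasing in `P`, from `tbg` at P = 0 towards `tsat + tbg`.
#' @export
#' @examples
#' t_minus(1, tsat = 10, tbg = 0.01)  # 5.01
t_minus <- function(P, tsat, tbg) {
  check_rate_args(P = P, tsat = tsat, tbg = tbg)
  tsat * P / (1 + P) + tbg
}

#' Transcription rate under simple repression
#'
#' The TF binds a site occluding RNAP, adding a TF-bound (weight F) state
#' that produces no transcripts; the doubly bound state is sterically
#' forbidden:
#' \deqn{t^+ = t_{sat} \frac{P}{1 + F + P} + t_{bg}.}
#' With F = 0 this reduces to [t_minus()]; for F > 0 it is depressed below
#' it, and deep in the proportional regime \eqn{t^+ \approx t^-/(1+F)}.
#'
#' @inheritParams t_minus
#' @param F TF binding factor(s), dimensionless, \eqn{\ge 0}.
#' @return Transcription rate(s), arbitrary units.
#' @export
t_plus_repression <- function(P, F, tsat, tbg) {
  check_rate_args(P = P, F = F, tsat = tsat, tbg = tbg)
  tsat * P / (1 + F + P) + tbg
}

#' Renormalized cooperativity
#'
#' In the activation models, only the combination
#' \deqn{\alpha' = \frac{1 + \alpha F}{1 + F}}
#' is visible in the (t-, t+) manifold; it absorbs the TF binding factor F
#' into the TF-RNAP cooperativity \eqn{\alpha}. \eqn{\alpha' \le \alpha},
#' with \eqn{\alpha' \to \alpha} as \eqn{F \to \infty}.
#'
#' @param alpha Cooperativity factor(s), \eqn{\ge 0}.
#' @param F TF binding factor(s), \eqn{\ge 0}.
#' @return Dimensionless renormalized cooperativity.
#' @export
#' @examples
#' alpha_prime(712, 23.9)  # within 4% of alpha
alpha_prime <- function(alpha, F) {
  check_nonneg(alpha = alpha, F = F)
  (1 + alpha * F) / (1 + F)
}

# invert alpha_prime at known F
alpha_from_prime <- function(alpha_p, F) {
  check_nonneg(alpha_p = alpha_p)
  if (!is.finite(F)) return(alpha_p)
  if (F <= 0) stop_allelic("alpha is unidentifiable at F = 0", "domain_error")
  (alpha_p * (1 + F) - 1) / F
}

#' Renormalized acceleration
#'
#' The acceleration factor \eqn{\beta} (fold-change in initiation rate of
#' the TF-RNAP-DNA ternary complex) appears in the manifold only through
#' \deqn{\beta' = \frac{1 + \alpha \beta F}{1 + \alpha F},}
#' which equals 1 for pure stabilization (\eqn{\beta = 1}) and tends to
#' \eqn{\beta} as \eqn{\alpha F \to \infty}.
#'
#' @inheritParams alpha_prime
#' @param beta Acceleration factor(s), \eqn{\ge 0}.
#' @return Dimensionless renormalized acceleration.
#' @export
beta_prime <- function(alpha, beta, F) {
  check_nonneg(alpha = alpha, beta = beta, F = F)
  (1 + alpha * beta * F) / (1 + alpha * F)
}

beta_from_prime <- function(beta_p, alpha, F) {
  check_nonneg(beta_p = beta_p)
  if (!is.finite(F) || !is.finite(alpha)) return(beta_p)
  af <- alpha * F
  if (af <= 0) stop_allelic("beta is unidentifiable at alpha*F = 0",
                            "domain_error")
  (beta_p * (1 + af) - 1) / af
}

#' Transcription rate under activation by stabilization
#'
#' Four-state model (unbound, TF-bound, RNAP-bound, doubly bound with
#' cooperativity bonus \eqn{\alpha}); only RNAP-containing states
#' transcribe, both at rate `tsat`:
#' \deqn{t^+ = t_{sat} \frac{P + \alpha F P}{1 + F + P + \alpha F P} + t_{bg}
#'       = t_{sat} \frac{\alpha' P}{1 + \alpha' P} + t_{bg},}
#' the two forms being algebraically identical with \eqn{\alpha'} from
#' [alpha_prime()].
#'
#' @inheritParams t_plus_repression
#' @param alpha TF-RNAP cooperativity factor(s), \eqn{\ge 0}.
#' @param form `"states"` evaluates the explicit state-sum form;
#'   `"renormalized"` the collapsed form. They agree to ~1e-15 relative.
#' @return Transcription rate(s), arbitrary units.
#' @export
t_plus_activation <- function(P, F, alpha, tsat, tbg,
                              form = c("states", "renormalized")) {
  form <- match.arg(form)
  check_rate_args(P = P, F = F, tsat = tsat, tbg = tbg)
  check_nonneg(alpha = alpha)
  if (form == "states") {
    tsat * (P + alpha * F * P) / (1 + F + P + alpha * F * P) + tbg
  } else {
    ap <- alpha_prime(alpha, F)
    tsat * ap * P / (1 + ap * P) + tbg
  }
}

#' Transcription rate under combined stabilization and acceleration
#'
#' As [t_plus_activation()], but the doubly bound complex initiates at rate
#' \eqn{\beta t_{sat}} instead of \eqn{t_{sat}}:
#' \deqn{t^+ = t_{sat}\frac{P}{1+F+P+\alpha F P}
#'       + \beta t_{sat} \frac{\alpha F P}{1+F+P+\alpha F P} + t_{bg}
#'       = \beta' t_{sat} \frac{\alpha' P}{1 + \alpha' P} + t_{bg}.}
#' The manifold saturates at \eqn{\beta' t_{sat} + t_{bg}} while the
#' unregulated rate saturates at \eqn{t_{sat} + t_{bg}}: a saturation point
#' off the diagonal is the signature of acceleration.
#'
#' @inheritParams t_plus_activation
#' @param beta Acceleration factor(s), \eqn{\ge 0}.
#' @export
t_plus_acceleration <- function(P, F, alpha, beta, tsat, tbg,
                                form = c("states", "renormalized")) {
  form <- match.arg(form)
  check_rate_args(P = P, F = F, tsat = tsat, tbg = tbg)
  check_nonneg(alpha = alpha, beta = beta)
  if (form == "states") {
    denom <- 1 + F + P + alpha * F * P
    tsat * P / denom + beta * tsat * alpha * F * P / denom + tbg
  } else {
    ap <- alpha_prime(alpha, F)
    bp <- beta_prime(alpha, beta, F)
    bp * tsat * ap * P / (1 + ap * P) + tbg
  }
}

#' Equilibrium state probabilities of the promoter
#'
#' Normalized Boltzmann weights of the four promoter states: unbound (1),
#' TF-bound (F), RNAP-bound (P) and doubly bound (\eqn{\alpha F P}). For
#' the three-state repression model the doubly bound state is forbidden;
#' pass `doubly_bound = FALSE` (its probability is then exactly 0).
#'
#' @inheritParams t_plus_activation
#' @param doubly_bound Is the TF-RNAP-DNA ternary state allowed?
#' @return Named numeric vector of probabilities summing to 1, over
#'   `c("unbound", "tf_bound", "rnap_bound", "doubly_bound")`.
#' @export
state_probabilities <- function(P, F, alpha = 1, doubly_bound = TRUE) {
  check_nonneg(P = P, F = F, alpha = alpha)
  stopifnot(length(P) == 1, length(F) == 1, length(alpha) == 1)
  w <- c(unbound = 1, tf_bound = F, rnap_bound = P,
         doubly_bound = if (doubly_bound) alpha * F * P else 0)
  w / sum(w)
}

check_nonneg <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
      stop_allelic(sprintf("'%s' must be numeric and >= 0", nm),
                   "domain_error")
    }
  }
  invisible(TRUE)
}

check_rate_args <- function(..., tsat, tbg) {
  check_nonneg(..., tsat = tsat, tbg = tbg)
  invisible(TRUE)
}
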