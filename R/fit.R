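# Nonlinear least-squares inference of allelic-manifold parameters.
#
# The measurement model: each promoter i contributes a paired observation
# (t-_i, t+_i) generated by the mechanism's rate equations at an unknown
# RNAP binding factor P_i, with shared (tsat, tbg) and regulatory
# parameters (F, or alpha'/beta'). Fitting n promoters therefore involves
# n + 3 (or n + 4) parameters against 2n observations. Residuals are taken
# on log10 rates (measurements span >4 decades and replicate noise is
# multiplicative) and all positive parameters are optimized as logarithms,
# so positivity holds by construction. Only alpha' and beta' are visible in
# the manifold; alpha and beta are recovered from them using a separately
# measured TF binding factor `F_tf` (Eqs. for alpha'/beta' inverted at the
# estimate).

core_param_names <- function(mechanism) {
  switch(mechanism,
         repression    = c("tsat", "tbg", "F"),
         stabilization = c("tsat", "tbg", "alpha_p"),
         acceleration  = c("tsat", "tbg", "alpha_p", "beta_p"))
}

# translate user-facing fixed values (natural scale: tsat, tbg, F, alpha,
# beta) into the internal core parameterization
internal_fixed <- function(mechanism, fixed, F_tf) {
  out <- list()
  for (nm in c("tsat", "tbg")) if (!is.null(fixed[[nm]])) {
    if (fixed[[nm]] <= 0) stop_allelic(paste(nm, "must be > 0"), "domain_error")
    out[[nm]] <- fixed[[nm]]
  }
  if (mechanism == "repression") {
    if (!is.null(fixed$F)) out$F <- fixed$F
  } else {
    if (!is.null(fixed$alpha)) {
      out$alpha_p <- if (is.finite(F_tf)) {
        alpha_prime(fixed$alpha, F_tf)
      } else fixed$alpha
    }
    if (mechanism == "acceleration" && !is.null(fixed$beta)) {
      if (!is.null(fixed$alpha)) {
        out$beta_p <- if (is.finite(F_tf)) {
          beta_prime(fixed$alpha, fixed$beta, F_tf)
        } else fixed$beta
      } else if (fixed$beta == 1) {
        out$beta_p <- 1
      } else {
        stop_allelic("fixing beta != 1 with alpha free is not supported",
                     "config_error")
      }
    }
  }
  bad <- setdiff(names(fixed), c("tsat", "tbg", "F", "alpha", "beta"))
  if (length(bad)) {
    stop_allelic(paste("unknown fixed parameter(s):",
                       paste(bad, collapse = ", ")), "config_error")
  }
  out
}

# predicted rates from natural-scale core params + per-promoter P
predict_rates <- function(mechanism, core, P) {
  tm <- core[["tsat"]] * P / (1 + P) + core[["tbg"]]
  tp <- if (mechanism == "repression") {
    core[["tsat"]] * P / (1 + core[["F"]] + P) + core[["tbg"]]
  } else {
    ap <- core[["alpha_p"]]
    bp <- if (mechanism == "acceleration") core[["beta_p"]] else 1
    bp * core[["tsat"]] * ap * P / (1 + ap * P) + core[["tbg"]]
  }
  list(t_minus = tm, t_plus = tp)
}

#' Log-space residuals of a manifold model
#'
#' Per-observation residuals `log10(observed) - log10(predicted)`, t- block
#' first then t+ block; the squared sum of this vector is the loss
#' minimized by [fit_manifold()]. Exposed so that model adequacy can be
#' examined (and tested) independently of the optimizer.
#'
#' @param data A [measurement_table()] (outlier-flagged rows excluded).
#' @param mechanism Regulatory mechanism.
#' @param tsat,tbg,F,alpha,beta Natural-scale model parameters.
#' @param P Per-promoter RNAP binding factors, one per (non-outlier) row.
#' @param F_tf Known TF binding factor used to renormalize alpha/beta for
#'   activation mechanisms (`Inf` means alpha is already alpha-prime).
#' @return Numeric vector of length `2 * nrow(data)`.
#' @export
manifold_residuals <- function(data, mechanism = c("repression",
                                                   "stabilization",
                                                   "acceleration"),
                               tsat, tbg, F = NULL, alpha = NULL,
                               beta = 1, P, F_tf = Inf) {
  mechanism <- match.arg(mechanism)
  data <- data[!data$is_outlier, , drop = FALSE]
  stopifnot(length(P) == nrow(data))
  core <- if (mechanism == "repression") {
    list(tsat = tsat, tbg = tbg, F = F)
  } else {
    list(tsat = tsat, tbg = tbg,
         alpha_p = alpha_prime(alpha, F_tf),
         beta_p = beta_prime(alpha, beta, F_tf))
  }
  pred <- predict_rates(mechanism, core, P)
  c(log10(data$t_minus) - log10(pred$t_minus),
    log10(data$t_plus) - log10(pred$t_plus))
}

# heuristic initialization on the natural scale
init_core <- function(mechanism, tm, tp, fx) {
  tsat0 <- fx$tsat %||% (1.5 * max(tm, tp / 4))
  tbg0 <- fx$tbg %||% max(0.5 * min(tm, tp), 1e-12)
  core <- list(tsat = tsat0, tbg = tbg0)
  if (mechanism == "repression") {
    core$F <- fx$F %||% max(stats::median(tm / tp) - 1, 1e-2)
  } else {
    core$alpha_p <- fx$alpha_p %||%
      min(max(stats::median(tp / tm), 1e-3), 1e7)
    if (mechanism == "acceleration") {
      core$beta_p <- fx$beta_p %||% min(max(max(tp) / tsat0, 0.5), 50)
    }
  }
  core
}

# invert the unregulated rate equation for starting P values
init_P <- function(tm, tsat, tbg) {
  x <- pmin(pmax(tm - tbg, tsat * 1e-7), tsat * (1 - 1e-7))
  x / (tsat - x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single Levenberg-Marquardt solve from a given start; returns natural
# parameters, loss and the residual vector
lm_solve <- function(log_start, free_names, fx, mechanism, tm, tp,
                     weights = NULL, control = NULL) {
  n <- length(tm)
  unpack <- function(logtheta) {
    th <- exp(logtheta)
    core <- as.list(fx)
    core[free_names] <- th[seq_along(free_names)]
    P <- th[(length(free_names) + 1):length(th)]
    list(core = core, P = P)
  }
  sw <- if (is.null(weights)) NULL else sqrt(rep(weights, 2))
  residfun <- function(logtheta) {
    u <- unpack(logtheta)
    pred <- predict_rates(mechanism, u$core, u$P)
    r <- c(log10(tm) - log10(pred$t_minus),
           log10(tp) - log10(pred$t_plus))
    if (!is.null(sw)) r <- r * sw
    r
  }
  ctrl <- control %||% minpack.lm::nls.lm.control(
    maxiter = 1000, ftol = 1e-15, ptol = 1e-15, gtol = 0)
  ans <- tryCatch(
    minpack.lm::nls.lm(par = log_start, fn = residfun, control = ctrl),
    error = function(e) NULL)
  if (is.null(ans) || any(!is.finite(ans$par))) return(NULL)
  u <- unpack(ans$par)
  r <- residfun(ans$par)
  list(core = u$core, P = u$P, loss = sum(r^2), residuals = r,
       info = ans$info, niter = ans$niter)
}

fit_engine <- function(tm, tp, mechanism, fixed = list(), F_tf = Inf,
                       n_starts = 10, seed = 1, weights = NULL,
                       start = NULL) {
  n <- length(tm)
  fx <- internal_fixed(mechanism, fixed, F_tf)
  free_names <- setdiff(core_param_names(mechanism), names(fx))
  n_par <- length(free_names) + n
  if (2 * n <= n_par) {
    stop_allelic(sprintf(
      "unidentifiable fit: %d parameters for %d measurements (need 2n > n + %d, i.e. n >= %d)",
      n_par, 2 * n, length(free_names), length(free_names) + 1),
      "identifiability_error")
  }
  starts <- list()
  if (!is.null(start)) {
    starts[[1]] <- start  # log-scale vector, e.g. from a point estimate
  } else {
    core0 <- init_core(mechanism, tm, tp, fx)
    P0 <- init_P(tm, core0$tsat, core0$tbg)
    starts[[1]] <- log(unlist(c(core0[free_names], as.list(P0))))
    if (n_starts > 1) {
      starts <- c(starts, withr_seed(seed, {
        lapply(seq_len(n_starts - 1), function(k) {
          # perturb free core params log-uniformly within one decade,
          # re-derive P from the perturbed (tsat, tbg)
          core_k <- core0
          for (nm in free_names) {
            core_k[[nm]] <- core0[[nm]] *
              10^stats::runif(1, -1, 1)
          }
          Pk <- init_P(tm, core_k$tsat %||% fx$tsat, core_k$tbg %||% fx$tbg)
          log(unlist(c(core_k[free_names], as.list(Pk))))
        })
      }))
    }
  }
  best <- NULL
  n_fail <- 0
  for (s in starts) {
    ans <- lm_solve(s, free_names, fx, mechanism, tm, tp, weights)
    if (is.null(ans)) { n_fail <- n_fail + 1; next }
    if (is.null(best) || ans$loss < best$loss - 1e-12) best <- ans
  }
  if (is.null(best)) {
    stop_allelic("manifold fit failed from every start", "fit_failure")
  }
  best$free_names <- free_names
  best$fixed <- fx
  best
}

#' Fit an allelic manifold to paired measurements
#'
#' Infers the thermodynamic parameters of a regulatory mechanism, plus one
#' RNAP binding factor P per promoter, by nonlinear least squares on log10
#' rates (Levenberg-Marquardt, multistart, all positive parameters
#' optimized as logarithms). Rows flagged `is_outlier` are excluded and
#' reported.
#'
#' For the activation mechanisms only the renormalized quantities
#' \eqn{\alpha'} (and \eqn{\beta'}) are identifiable from the manifold;
#' supply the separately measured TF binding factor `F_tf` to convert them
#' to \eqn{\alpha} (and \eqn{\beta}). With the default `F_tf = Inf` the
#' reported alpha equals alpha-prime.
#'
#' @param data A [measurement_table()].
#' @param mechanism `"repression"`, `"stabilization"` or `"acceleration"`.
#' @param fixed Named list of parameters to hold fixed at known values:
#'   any of `tsat`, `tbg`, `F` (repression), `alpha`, `beta` (activation).
#' @param F_tf Known TF binding factor for activation mechanisms.
#' @param n_starts Number of multistart initializations (first is the
#'   data-driven heuristic; the rest perturb it log-uniformly within one
#'   decade, under a seeded stream).
#' @param seed Integer seed controlling the multistart perturbations.
#' @return Object of class `"manifold_fit"`: list with `estimates` (named
#'   vector: tsat, tbg and F, or alpha/alpha_prime and possibly
#'   beta/beta_prime), `dg` (free energies in kcal/mol, incl. per-promoter
#'   `dg_P`), `P_by_promoter`, `residuals` (t- block then t+ block),
#'   `loss`, `n_used`, `outliers_excluded`, `settings`.
#' @export
#' @examples
#' sim <- simulate_allelic_series(15, "repression", noise_cv = 0, seed = 2)
#' fit <- fit_manifold(sim$data, "repression", n_starts = 2)
#' fit$estimates[["F"]]  # ~23.9
fit_manifold <- function(data, mechanism = c("repression", "stabilization",
                                             "acceleration"),
                         fixed = list(), F_tf = Inf, n_starts = 10,
                         seed = 1) {
  mechanism <- match.arg(mechanism)
  stopifnot(inherits(data, "measurement_table"))
  used <- data[!data$is_outlier, , drop = FALSE]
  excluded <- data$promoter_id[data$is_outlier]
  best <- fit_engine(used$t_minus, used$t_plus, mechanism, fixed, F_tf,
                     n_starts = n_starts, seed = seed)
  finish_fit(best, used, excluded, mechanism, F_tf,
             settings = list(fixed = fixed, n_starts = n_starts,
                             seed = seed, F_tf = F_tf))
}

finish_fit <- function(best, used, excluded, mechanism, F_tf, settings) {
  core <- best$core
  est <- c(tsat = core$tsat, tbg = core$tbg)
  dg <- c()
  if (mechanism == "repression") {
    est <- c(est, F = core$F)
    dg <- c(dg_F = dg_from_factor(core$F))
  } else {
    alpha <- alpha_from_prime(core$alpha_p, F_tf)
    est <- c(est, alpha = alpha, alpha_prime = core$alpha_p)
    dg <- c(dg_alpha = if (alpha > 0) dg_from_factor(alpha) else NA_real_)
    if (mechanism == "acceleration") {
      beta <- beta_from_prime(core$beta_p, alpha, F_tf)
      est <- c(est, beta = beta, beta_prime = core$beta_p)
    }
  }
  P <- stats::setNames(best$P, used$promoter_id)
  structure(list(
    mechanism = mechanism,
    estimates = est,
    dg = c(dg, list(dg_P = dg_from_factor(P))),
    P_by_promoter = P,
    residuals = stats::setNames(best$residuals,
                                c(paste0("tminus.", used$promoter_id),
                                  paste0("tplus.", used$promoter_id))),
    loss = best$loss,
    n_used = nrow(used),
    outliers_excluded = excluded,
    free_names = best$free_names,
    settings = settings), class = "manifold_fit")
}

#' @export
print.manifold_fit <- function(x, ...) {
  cat(sprintf("<manifold_fit> mechanism=%s n=%d loss=%.4g\n",
              x$mechanism, x$n_used, x$loss))
  print(signif(x$estimates, 4))
  if (length(x$outliers_excluded)) {
    cat("excluded:", paste(x$outliers_excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Jointly fit several architectures with a shared saturated rate
#'
#' Promoter architectures measured in the same strain share the RNAP
#' saturation rate `tsat` even when their regulatory parameters differ.
#' This fit stacks the per-architecture residuals and estimates a single
#' tsat together with per-architecture (tbg, F or alpha) and per-promoter
#' P. Initialization comes from independent per-architecture fits; the
#' shared value starts at the estimate from the architecture whose data
#' reach highest (closest to saturation, where tsat is identified).
#'
#' @param datasets Named list of [measurement_table()]s, one per
#'   architecture (>= 2).
#' @inheritParams fit_manifold
#' @param F_tf Known TF binding factor; a single value or a named vector
#'   per architecture.
#' @return List of class `"joint_fit"`: `fits` (named list of
#'   `manifold_fit`), `tsat` (shared estimate), `loss` (total).
#' @export
joint_fit <- function(datasets, mechanism = c("repression", "stabilization",
                                              "acceleration"),
                      F_tf = Inf, fixed = list(), n_starts = 5, seed = 1) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.list(datasets), length(datasets) >= 2)
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    stop_allelic("datasets must be a named list (one name per architecture)",
                 "config_error")
  }
  archs <- names(datasets)
  Fv <- if (length(F_tf) == 1) stats::setNames(rep(F_tf, length(archs)), archs) else F_tf[archs]
  if (!is.null(fixed$tsat)) {
    # shared tsat known: joint fit decouples into independent fits
    fits <- lapply(archs, function(a) {
      fit_manifold(datasets[[a]], mechanism, fixed = fixed,
                   F_tf = Fv[[a]], n_starts = n_starts, seed = seed)
    })
    names(fits) <- archs
    return(structure(list(fits = fits, tsat = fixed$tsat,
                          loss = sum(vapply(fits, `[[`, 0, "loss"))),
                     class = "joint_fit"))
  }
  indep <- lapply(archs, function(a) {
    fit_manifold(datasets[[a]], mechanism, fixed = fixed, F_tf = Fv[[a]],
                 n_starts = n_starts, seed = seed)
  })
  names(indep) <- archs
  # tsat is identified by the architecture with points nearest saturation
  top <- which.max(vapply(archs, function(a) max(datasets[[a]]$t_minus), 0))
  tsat0 <- indep[[top]]$estimates[["tsat"]]

  used <- lapply(datasets, function(d) d[!d$is_outlier, , drop = FALSE])
  ns <- vapply(used, nrow, 0L)
  core_free <- setdiff(core_param_names(mechanism), c("tsat", names(internal_fixed(mechanism, fixed, Inf))))
  core_free <- setdiff(core_free, "tsat")
  nblock <- length(core_free)

  # parameter layout: log tsat, then per arch [core_free..., P_1..P_n]
  unpack <- function(logtheta) {
    tsat <- exp(logtheta[1])
    off <- 1L
    out <- vector("list", length(archs)); names(out) <- archs
    for (i in seq_along(archs)) {
      a <- archs[i]
      th <- exp(logtheta[off + seq_len(nblock + ns[i])])
      fx <- internal_fixed(mechanism, fixed, Fv[[a]])
      core <- c(list(tsat = tsat), fx)
      core[core_free] <- th[seq_len(nblock)]
      out[[a]] <- list(core = core, P = th[nblock + seq_len(ns[i])])
      off <- off + nblock + ns[i]
    }
    out
  }
  residfun <- function(logtheta) {
    u <- unpack(logtheta)
    unlist(lapply(archs, function(a) {
      pred <- predict_rates(mechanism, u[[a]]$core, u[[a]]$P)
      c(log10(used[[a]]$t_minus) - log10(pred$t_minus),
        log10(used[[a]]$t_plus) - log10(pred$t_plus))
    }), use.names = FALSE)
  }
  start <- log(c(tsat0, unlist(lapply(archs, function(a) {
    f <- indep[[a]]
    core <- f$estimates
    # per-arch internal free values at the independent estimate
    vals <- vapply(core_free, function(nm) {
      switch(nm,
             tbg = core[["tbg"]],
             F = core[["F"]],
             alpha_p = core[["alpha_prime"]],
             beta_p = core[["beta_prime"]])
    }, 0)
    c(vals, f$P_by_promoter)
  }))))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                     ptol = 1e-15, gtol = 0)
  ans <- minpack.lm::nls.lm(par = start, fn = residfun, control = ctrl)
  u <- unpack(ans$par)
  r <- residfun(ans$par)
  fits <- vector("list", length(archs)); names(fits) <- archs
  off <- 0L
  for (i in seq_along(archs)) {
    a <- archs[i]
    ri <- r[off + seq_len(2 * ns[i])]
    # reconstruct residual order: within residfun each arch contributes its
    # own t- then t+ block
    best <- list(core = u[[a]]$core, P = u[[a]]$P, loss = sum(ri^2),
                 residuals = ri, free_names = core_free)
    fits[[a]] <- finish_fit(best, used[[a]],
                            datasets[[a]]$promoter_id[datasets[[a]]$is_outlier],
                            mechanism, Fv[[a]],
                            settings = list(fixed = fixed, joint = TRUE,
                                            seed = seed))
    off <- off + 2 * ns[i]
  }
  structure(list(fits = fits, tsat = exp(ans$par[1]), loss = sum(r^2)),
            class = "joint_fit")
}

#' @export
print.joint_fit <- function(x, ...) {
  cat(sprintf("<joint_fit> %d architectures, shared tsat=%.4g, total loss=%.4g\n",
              length(x$fits), x$tsat, x$loss))
  for (a in names(x$fits)) {
    cat(sprintf("  %s: ", a)); print(signif(x$fits[[a]]$estimates, 4))
  }
  invisible(x)
}

#' Fit the acceleration model at a known saturated rate
#'
#' Quantifies possible acceleration by fitting the combined
#' stabilization/acceleration model with `tsat` held at a value determined
#' elsewhere (e.g. from a joint fit across architectures). `beta` is
#' identified by data near saturation (P around 1 and above); if none of
#' the inferred P reach 0.1 a warning flags the estimate as weakly
#' identified.
#'
#' @inheritParams fit_manifold
#' @param tsat Known saturated transcription rate (a.u.), held fixed.
#' @param F_tf Known TF binding factor used to convert alpha'/beta' to
#'   alpha/beta.
#' @return A `manifold_fit` (mechanism `"acceleration"`) whose estimates
#'   include `alpha` and `beta`.
#' @export
fit_beta <- function(data, tsat, F_tf = Inf, fixed = list(), n_starts = 10,
                     seed = 1) {
  stopifnot(is.numeric(tsat), tsat > 0)
  fixed$tsat <- tsat
  fit <- fit_manifold(data, "acceleration", fixed = fixed, F_tf = F_tf,
                      n_starts = n_starts, seed = seed)
  if (max(fit$P_by_promoter) < 0.1) {
    warn_allelic(
      "no promoters near saturation (all P < 0.1): beta is weakly identified",
      "weak_identifiability")
  }
  fit
}
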