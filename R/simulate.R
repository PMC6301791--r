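#' Simulate paired measurements for an allelic series
#'
#' Generates a measurement table with the statistical structure the
#' manifold analysis assumes: an allelic series of RNAP binding factors P
#' spanning several decades, forward-evaluated through the mechanism's
#' rate equations, with independent multiplicative (lognormal) noise on
#' each channel and an optional small fraction of outlier promoters whose
#' regulated channel is perturbed by a large fold-factor.
#'
#' Defaults mirror the experimental conditions the models describe:
#' `tsat = 15.1` a.u., `tbg = 0.0023` a.u., P log-uniform over
#' `[1e-4, 3]` (populating regimes 1-4; widen `P_range` to reach the
#' doubly saturated regime when acceleration is of interest), replicate
#' noise CV 10%, outliers multiplying t+ by a log-uniform factor within
#' +/- 1 decade but outside (0.5, 2).
#'
#' @param n_promoters Number of promoter variants.
#' @param mechanism `"repression"`, `"stabilization"` or `"acceleration"`.
#' @param tsat,tbg,F,alpha,beta True model parameters (see
#'   [t_plus_repression()], [t_plus_activation()],
#'   [t_plus_acceleration()]).
#' @param P_range Two positive numbers; P values are drawn from this range.
#' @param P_spacing `"log-uniform"` (random) or `"log-spaced"` (regular
#'   grid).
#' @param noise_cv Fractional replicate noise; each observed rate is the
#'   model value times `exp(e)`, `e ~ Normal(0, log(1 + cv))`,
#'   independently per row and channel.
#' @param outlier_fraction Fraction of promoters perturbed.
#' @param seed Integer seed; identical seed + configuration reproduces the
#'   table exactly.
#' @param architecture,condition Labels stamped on the rows.
#' @return List with `data` (a [measurement_table()]) and `truth` (the
#'   generating parameters, per-promoter P, and injected outlier ids).
#' @export
#' @examples
#' sim <- simulate_allelic_series(12, "repression", noise_cv = 0, seed = 1)
#' plot(sim$data$t_minus, sim$data$t_plus, log = "xy")
simulate_allelic_series <- function(n_promoters,
                                    mechanism = c("repression",
                                                  "stabilization",
                                                  "acceleration"),
                                    tsat = 15.1, tbg = 0.0023,
                                    F = 23.9, alpha = 712, beta = 1,
                                    P_range = c(1e-4, 3),
                                    P_spacing = c("log-uniform",
                                                  "log-spaced"),
                                    noise_cv = 0.1,
                                    outlier_fraction = 0,
                                    seed = 1,
                                    architecture = "synthetic",
                                    condition = "default") {
  mechanism <- match.arg(mechanism)
  P_spacing <- match.arg(P_spacing)
  if (n_promoters < 1 || noise_cv < 0 || outlier_fraction < 0 ||
      outlier_fraction >= 1 || any(P_range <= 0) || diff(P_range) < 0) {
    stop_allelic("invalid simulation configuration", "config_error")
  }
  if (mechanism == "stabilization") beta <- 1
  withr_seed(seed, {
    P <- if (P_spacing == "log-spaced") {
      10^seq(log10(P_range[1]), log10(P_range[2]), length.out = n_promoters)
    } else {
      sort(10^stats::runif(n_promoters, log10(P_range[1]),
                           log10(P_range[2])))
    }
    tm <- t_minus(P, tsat, tbg)
    tp <- switch(mechanism,
      repression    = t_plus_repression(P, F, tsat, tbg),
      stabilization = t_plus_activation(P, F, alpha, tsat, tbg),
      acceleration  = t_plus_acceleration(P, F, alpha, beta, tsat, tbg))
    sigma <- log(1 + noise_cv)
    tm_obs <- tm * exp(stats::rnorm(n_promoters, 0, sigma))
    tp_obs <- tp * exp(stats::rnorm(n_promoters, 0, sigma))
    n_out <- round(outlier_fraction * n_promoters)
    out_idx <- if (n_out > 0) sample(n_promoters, n_out) else integer(0)
    if (n_out > 0) {
      tp_obs[out_idx] <- tp_obs[out_idx] * outlier_multiplier(n_out)
    }
    ids <- sprintf("p%03d", seq_len(n_promoters))
    data <- measurement_table(ids, tm_obs, tp_obs,
                              architecture = architecture,
                              condition = condition)
    truth <- list(mechanism = mechanism, tsat = tsat, tbg = tbg, F = F,
                  alpha = alpha, beta = beta, P_by_promoter = stats::setNames(P, ids),
                  noise_cv = noise_cv, outlier_fraction = outlier_fraction,
                  outlier_ids = ids[sort(out_idx)], P_range = P_range,
                  seed = seed)
    list(data = data, truth = truth)
  })
}

# log-uniform fold-factor within +/- 1 decade, excluding (0.5, 2): outliers
# must be distinguishable from replicate noise
outlier_multiplier <- function(n) {
  lo <- log10(2)  # excluded half-width
  u <- stats::runif(n, 0, 2 * (1 - lo))
  expo <- ifelse(u < (1 - lo), -1 + u, lo + (u - (1 - lo)))
  10^expo
}

#' Simulate a small-molecule titration of TF activity
#'
#' Emulates measuring one allelic manifold per effector concentration
#' (e.g. cAMP controlling active CRP): the TF binding factor follows a
#' power law \eqn{F(c) = F_{ref} (c/c_{ref})^{exponent}} while `t_minus`
#' (measured without the effector) is independent of c. Each concentration
#' reuses the same allelic series of promoters.
#'
#' @inheritParams simulate_allelic_series
#' @param concentrations Positive effector concentrations (default: seven
#'   log-spaced points from 2.5 to 250, in micromolar).
#' @param exponent Power-law exponent of F versus concentration.
#' @param F_ref Binding factor at `c_ref`.
#' @param c_ref Reference concentration; defaults to the largest.
#' @return List with `datasets` (named list of measurement tables, one per
#'   concentration) and `truth` (including the per-concentration F).
#' @export
simulate_titration <- function(n_promoters = 20,
                               concentrations = 10^seq(log10(2.5),
                                                       log10(250),
                                                       length.out = 7),
                               exponent = 1.41,
                               F_ref = 23.9, c_ref = max(concentrations),
                               tsat = 15.1, tbg = 0.0023,
                               P_range = c(1e-4, 3),
                               noise_cv = 0.1, seed = 1) {
  if (any(concentrations <= 0) || F_ref <= 0 || c_ref <= 0) {
    stop_allelic("concentrations and F_ref must be positive", "config_error")
  }
  Fs <- F_ref * (concentrations / c_ref)^exponent
  datasets <- vector("list", length(concentrations))
  names(datasets) <- format(concentrations, trim = TRUE)
  for (i in seq_along(concentrations)) {
    sim <- simulate_allelic_series(
      n_promoters, "repression", tsat = tsat, tbg = tbg, F = Fs[i],
      P_range = P_range, P_spacing = "log-spaced", noise_cv = noise_cv,
      seed = seed + i, condition = names(datasets)[i])
    sim$data$cAMP_uM <- concentrations[i]
    datasets[[i]] <- sim$data
  }
  list(datasets = datasets,
       truth = list(exponent = exponent, F_by_conc = stats::setNames(Fs, names(datasets)),
                    concentrations = concentrations, F_ref = F_ref,
                    c_ref = c_ref, tsat = tsat, tbg = tbg,
                    noise_cv = noise_cv, seed = seed))
}

# evaluate expr with a local, restored RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
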