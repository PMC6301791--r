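#' Bootstrap uncertainty for manifold parameters
#'
#' Resamples promoters (rows, i.e. (t-, t+) pairs) with replacement,
#' refits the manifold to each replicate, and summarizes the draws with
#' percentile confidence intervals (16/84 for "68%", 2.5/97.5 for "95%").
#' Each replicate fit starts from the point estimate, which makes the
#' procedure fast and deterministic; replicates whose fit fails are
#' dropped and counted, and more than 20% failures aborts.
#'
#' @inheritParams fit_manifold
#' @param n_boot Number of bootstrap replicates (>= 1; 100 by default).
#' @param seed Integer seed; the same seed reproduces the ensemble
#'   bit-for-bit.
#' @return Object of class `"manifold_boot"`: `point` (the full-data
#'   `manifold_fit`), `draws` (data.frame of parameter and free-energy
#'   draws), `ci68`, `ci95` (named lists `c(lo, hi)`), `n_boot`,
#'   `n_failed`, `seed`.
#' @export
#' @examples
#' sim <- simulate_allelic_series(12, "repression", seed = 3)
#' bs <- bootstrap_manifold(sim$data, "repression", n_boot = 20, seed = 1)
#' bs$ci68$dg_F
bootstrap_manifold <- function(data, mechanism = c("repression",
                                                   "stabilization",
                                                   "acceleration"),
                               fixed = list(), F_tf = Inf, n_boot = 100,
                               seed = 1, n_starts = 10) {
  mechanism <- match.arg(mechanism)
  stopifnot(n_boot >= 1)
  point <- fit_manifold(data, mechanism, fixed = fixed, F_tf = F_tf,
                        n_starts = n_starts, seed = seed)
  used <- data[!data$is_outlier, , drop = FALSE]
  n <- nrow(used)
  fx <- internal_fixed(mechanism, point$settings$fixed, F_tf)
  free_names <- point$free_names
  core_log <- log(vapply(free_names, function(nm) {
    switch(nm,
           tsat = point$estimates[["tsat"]],
           tbg = point$estimates[["tbg"]],
           F = point$estimates[["F"]],
           alpha_p = point$estimates[["alpha_prime"]],
           beta_p = point$estimates[["beta_prime"]])
  }, 0))
  logP <- log(point$P_by_promoter)

  draws <- vector("list", n_boot)
  n_failed <- 0
  withr_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      start <- c(core_log, logP[idx])
      ans <- tryCatch(
        fit_engine(used$t_minus[idx], used$t_plus[idx], mechanism,
                   fixed = point$settings$fixed, F_tf = F_tf,
                   n_starts = 1, start = start),
        error = function(e) NULL)
      if (is.null(ans)) { n_failed <- n_failed + 1; next }
      core <- ans$core
      row <- c(tsat = core$tsat, tbg = core$tbg)
      if (mechanism == "repression") {
        row <- c(row, F = core$F, dg_F = dg_from_factor(core$F))
      } else {
        alpha <- alpha_from_prime(core$alpha_p, F_tf)
        row <- c(row, alpha = alpha, alpha_prime = core$alpha_p,
                 dg_alpha = if (alpha > 0) dg_from_factor(alpha) else NA)
        if (mechanism == "acceleration") {
          beta <- tryCatch(beta_from_prime(core$beta_p, alpha, F_tf),
                           error = function(e) NA_real_)
          row <- c(row, beta = beta, beta_prime = core$beta_p)
        }
      }
      row <- c(row, loss = ans$loss)
      draws[[b]] <- row
    }
  })
  if (n_failed > 0.2 * n_boot) {
    stop_allelic(sprintf("%d of %d bootstrap fits failed", n_failed, n_boot),
                 "fit_failure")
  }
  draws <- as.data.frame(do.call(rbind, draws[!vapply(draws, is.null, TRUE)]))
  ci <- function(p) {
    lapply(draws[setdiff(names(draws), "loss")], stats::quantile,
           probs = p, na.rm = TRUE, names = FALSE)
  }
  structure(list(point = point, draws = draws,
                 ci68 = ci(c(0.16, 0.84)), ci95 = ci(c(0.025, 0.975)),
                 n_boot = n_boot, n_failed = n_failed, seed = seed),
            class = "manifold_boot")
}

#' @export
print.manifold_boot <- function(x, ...) {
  cat(sprintf("<manifold_boot> %d draws (%d failed), seed=%d\n",
              x$n_boot, x$n_failed, x$seed))
  for (nm in names(x$ci68)) {
    cat(sprintf("  %-12s %.4g  [68%%: %.4g, %.4g]\n", nm,
                if (nm %in% names(x$point$estimates)) x$point$estimates[[nm]]
                else if (!is.null(x$point$dg[[nm]])) x$point$dg[[nm]]
                else NA,
                x$ci68[[nm]][1], x$ci68[[nm]][2]))
  }
  invisible(x)
}
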