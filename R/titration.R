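#' Infer TF binding factors across an effector titration
#'
#' Given one measurement table per effector concentration (e.g. a cAMP
#' titration modulating active CRP), fits a repression manifold to each
#' with `tsat` and `tbg` held at values determined elsewhere, leaving only
#' the TF binding factor F (and the per-promoter P) free. The dependence
#' of F on concentration is then summarized by an ordinary least-squares
#' regression of log F on log concentration -- by default over the largest
#' `select` concentrations, where F is well determined -- reporting the
#' power-law exponent with a 95% confidence interval.
#'
#' @param datasets Named list of [measurement_table()]s; concentrations
#'   are taken from each table's `cAMP_uM` column if present, else parsed
#'   from the list names.
#' @param tsat,tbg Fixed saturated and background rates (a.u.).
#' @param select Number of largest concentrations used in the slope
#'   regression (default 4); at least 3 are required for a CI.
#' @param n_boot Bootstrap replicates per concentration for F confidence
#'   intervals (0 skips the bootstrap).
#' @inheritParams fit_manifold
#' @return Object of class `"titration_fit"`: `table` (data.frame with
#'   concentration, F, dg_F, optional 68% CI, selected flag), `exponent`
#'   (OLS slope), `exponent_ci95`, `lm` (the regression fit), `fits`.
#' @export
#' @examples
#' sim <- simulate_titration(n_promoters = 8, noise_cv = 0, seed = 1)
#' tf <- titration_fit(sim$datasets, tsat = 15.1, tbg = 0.0023,
#'                     n_starts = 2)
#' tf$exponent  # ~1.41
titration_fit <- function(datasets, tsat, tbg, select = 4, n_boot = 0,
                          seed = 1, n_starts = 10) {
  stopifnot(is.list(datasets), length(datasets) >= 2,
            tsat > 0, tbg > 0)
  conc <- vapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    if (!is.null(d$cAMP_uM) && all(is.finite(d$cAMP_uM))) {
      unique(d$cAMP_uM)[1]
    } else {
      suppressWarnings(as.numeric(names(datasets)[i]))
    }
  }, 0)
  if (any(is.na(conc) | conc <= 0)) {
    stop_allelic("could not determine a positive concentration per dataset",
                 "config_error")
  }
  fits <- vector("list", length(datasets))
  Fhat <- lo68 <- hi68 <- rep(NA_real_, length(datasets))
  for (i in seq_along(datasets)) {
    if (n_boot > 0) {
      bs <- bootstrap_manifold(datasets[[i]], "repression",
                               fixed = list(tsat = tsat, tbg = tbg),
                               n_boot = n_boot, seed = seed + i,
                               n_starts = n_starts)
      fits[[i]] <- bs$point
      lo68[i] <- bs$ci68$F[1]
      hi68[i] <- bs$ci68$F[2]
    } else {
      fits[[i]] <- fit_manifold(datasets[[i]], "repression",
                                fixed = list(tsat = tsat, tbg = tbg),
                                n_starts = n_starts, seed = seed + i)
    }
    Fhat[i] <- fits[[i]]$estimates[["F"]]
  }
  ord <- order(conc)
  selected <- rep(FALSE, length(conc))
  selected[ord[seq.int(length(conc) - min(select, length(conc)) + 1,
                       length(conc))]] <- TRUE
  if (sum(selected) < 3) {
    stop_allelic("need at least 3 selected concentrations for a slope CI",
                 "config_error")
  }
  reg <- stats::lm(log(Fhat[selected]) ~ log(conc[selected]))
  # suppressed warning: confint on noiseless data reports a perfect fit
  ci <- suppressWarnings(stats::confint(reg, level = 0.95)[2, ])
  tab <- data.frame(concentration = conc, F = Fhat,
                    dg_F = dg_from_factor(Fhat),
                    F_lo68 = lo68, F_hi68 = hi68, selected = selected)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 exponent = unname(stats::coef(reg)[2]),
                 exponent_ci95 = unname(ci), lm = reg,
                 fits = stats::setNames(fits, names(datasets))),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("<titration_fit> F ~ c^%.3f  (95%% CI %.3f to %.3f; %d of %d concentrations used)\n",
              x$exponent, x$exponent_ci95[1], x$exponent_ci95[2],
              sum(x$table$selected), nrow(x$table)))
  print(x$table, digits = 4)
  invisible(x)
}
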