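#' Flag outlier promoters against a robust preliminary fit
#'
#' Variant promoters occasionally acquire mutations that do more than
#' change RNAP binding (e.g. create a new TF site), placing them far off
#' the manifold. These are detected with a robust preliminary fit: the
#' manifold is fit under a soft-L1 (pseudo-Huber) loss on the log10
#' residuals, implemented as iteratively reweighted least squares so that
#' gross outliers cannot drag the preliminary estimate.
#'
#' Flagging residuals are anchored on the unregulated channel: for each
#' row, P is read off by inverting the t- rate equation at the robust
#' (tsat, tbg) -- clipped into the background/saturation-limited range --
#' and both channels are compared with the model prediction at that P. A
#' promoter whose regulation deviates (the biologically expected outlier
#' mode) then shows its full deviation in the t+ residual instead of
#' having it split between channels by the free per-promoter P. Rows whose
#' worst-channel absolute log10 residual exceeds `threshold` (default 0.5,
#' about 3.2-fold) are flagged -- reported, never silently dropped; pass
#' the flagged table to [fit_manifold()] to refit on the survivors.
#'
#' If more than `max_flag_fraction` of rows would be flagged, the data do
#' not collapse to a one-dimensional manifold at all (the model itself is
#' falsified, as happens for some promoter architectures); a
#' `collapse_failure` error is raised instead of a flagged table.
#'
#' @inheritParams fit_manifold
#' @param threshold Flagging threshold on |log10 residual| (decades).
#' @param max_flag_fraction Refuse if more than this fraction is flagged.
#' @param irls_iter Reweighting iterations for the robust fit.
#' @return The input table with `is_outlier` updated, plus attributes
#'   `robust_fit` (the preliminary engine fit) and `max_abs_residual`
#'   (per-row, decades).
#' @export
detect_outliers <- function(data, mechanism = c("repression",
                                                "stabilization",
                                                "acceleration"),
                            fixed = list(), F_tf = Inf, threshold = 0.5,
                            max_flag_fraction = 0.25, irls_iter = 6,
                            n_starts = 5, seed = 1) {
  mechanism <- match.arg(mechanism)
  stopifnot(inherits(data, "measurement_table"), threshold > 0)
  tm <- data$t_minus
  tp <- data$t_plus
  n <- nrow(data)
  w <- rep(1, n)
  delta <- 0.1  # soft-L1 transition scale, decades
  best <- NULL
  anchored <- function(core) {
    Pa <- init_P(tm, core$tsat, core$tbg)
    pred <- predict_rates(mechanism, core, Pa)
    pmax(abs(log10(tm) - log10(pred$t_minus)),
         abs(log10(tp) - log10(pred$t_plus)))
  }
  for (it in seq_len(irls_iter)) {
    best <- fit_engine(tm, tp, mechanism, fixed = fixed, F_tf = F_tf,
                       n_starts = if (it == 1) n_starts else 1,
                       seed = seed,
                       weights = w,
                       start = if (it == 1) NULL else
                         c(log(unlist(best$core[best$free_names])),
                           log(best$P)))
    r_row <- anchored(best$core)
    w <- 1 / sqrt(1 + (r_row / delta)^2)  # soft-L1 IRLS weights
  }
  resid_max <- anchored(best$core)
  flag <- resid_max > threshold
  if (mean(flag) > max_flag_fraction) {
    stop_allelic(sprintf(
      paste("%d of %d rows deviate from the fitted manifold by more than",
            "%.2g decades: measurements do not collapse to a 1D allelic",
            "manifold (model falsified for this architecture)"),
      sum(flag), n, threshold), "collapse_failure")
  }
  out <- data
  out$is_outlier <- flag
  attr(out, "max_abs_residual") <- stats::setNames(resid_max,
                                                   data$promoter_id)
  attr(out, "robust_fit") <- best
  out
}
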