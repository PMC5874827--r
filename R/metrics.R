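# Pharmacokinetic summaries and validation statistics: Cmax/tmax/AUC
# (non-compartmental), Kp_brain, Kp_uu_brain, fold error, afe/rmse and the
# 2-fold / 5-fold acceptance bands.

#' Non-compartmental summary of one concentration series
#'
#' Cmax and tmax are read from the (dense) series; AUC(0-last) uses the
#' linear trapezoid. AUC(0-inf) optionally extrapolates with a log-linear
#' terminal slope fitted to the last `n_tail` positive points.
#'
#' @param times Strictly increasing times, min (>= 2 points).
#' @param conc Concentrations on `times`.
#' @param extrapolate Add `auc_0_inf` via log-linear tail extrapolation.
#' @param n_tail Number of terminal points for the tail fit.
#' @return List `cmax`, `tmax`, `auc_0_last` (and `auc_0_inf`).
#' @export
nca <- function(times, conc, extrapolate = FALSE, n_tail = 3) {
  if (length(times) < 2) stop("need at least 2 time points", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  stopifnot(length(conc) == length(times))
  i <- which.max(conc)
  out <- list(cmax = conc[i], tmax = times[i],
              auc_0_last = trapz(times, conc))
  if (extrapolate) {
    pos <- which(conc > 0)
    tail_i <- utils::tail(pos, n_tail)
    if (length(tail_i) >= 2) {
      fit <- stats::lm(log(conc[tail_i]) ~ times[tail_i])
      lz <- -coef(fit)[[2]]
      out$auc_0_inf <- if (lz > 0)
        out$auc_0_last + conc[length(conc)] / lz else NA_real_
    } else out$auc_0_inf <- NA_real_
  }
  out
}

# Linear trapezoidal quadrature.
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) +
                                         utils::tail(y, -1)) / 2)

#' Per-compartment pharmacokinetic summary of a simulation
#'
#' @param result A `simulation_result`.
#' @param compartments Compartment labels (default: all concentration
#'   columns).
#' @param units Concentration units for the reported Cmax/AUC.
#' @return Data frame (class `pk_summary`) with `compartment`, `cmax`,
#'   `tmax`, `auc_0_last`.
#' @export
pk_summary <- function(result, compartments = colnames(result$conc),
                       units = "mg/L") {
  rows <- lapply(compartments, function(cp) {
    s <- get_series(result, cp, units)
    n <- nca(s$time_min, s$conc)
    data.frame(compartment = cp, cmax = n$cmax, tmax = n$tmax,
               auc_0_last = n$auc_0_last)
  })
  out <- do.call(rbind, rows)
  attr(out, "units") <- units
  class(out) <- c("pk_summary", class(out))
  out
}

#' Total brain-to-plasma partition coefficient
#'
#' Elementwise ratio of brain to plasma concentration, or the ratio of
#' trapezoidal AUCs when `mode = "auc"`.
#'
#' @param c_brain,c_plasma Concentration series on a common grid.
#' @param times Times, required for `mode = "auc"`.
#' @param mode `"elementwise"` or `"auc"`.
#' @return Ratio(s).
#' @export
kp_brain <- function(c_brain, c_plasma, times = NULL,
                     mode = c("elementwise", "auc")) {
  mode <- match.arg(mode)
  if (mode == "elementwise") {
    if (any(c_plasma <= 0)) stop("plasma concentration must be > 0",
                                 call. = FALSE)
    c_brain / c_plasma
  } else {
    stopifnot(!is.null(times))
    den <- trapz(times, c_plasma)
    if (den <= 0) stop("plasma AUC must be > 0", call. = FALSE)
    trapz(times, c_brain) / den
  }
}

#' Unbound brain-to-plasma partition coefficient (Kp_uu_brain)
#'
#' \deqn{K_{p,uu,brain} = \frac{fu_{brain} \, AUC_{brain}}{fu_{plasma} \,
#'   AUC_{plasma}}}
#'
#' computed over the simulated window (0 to last by default; 0 to infinity
#' optionally via log-linear tail extrapolation of both series).
#'
#' @param times Common time grid.
#' @param brain_conc,plasma_conc Total concentration series.
#' @param fu_brain,fu_plasma Unbound fractions.
#' @param extrapolate Use AUC(0-inf) instead of AUC(0-last).
#' @return The Kp_uu ratio.
#' @export
kpuu_brain <- function(times, brain_conc, plasma_conc, fu_brain, fu_plasma,
                       extrapolate = FALSE) {
  get_auc <- function(conc) {
    n <- nca(times, conc, extrapolate = extrapolate)
    if (extrapolate && is.finite(n$auc_0_inf)) n$auc_0_inf else n$auc_0_last
  }
  den <- fu_plasma * get_auc(plasma_conc)
  if (den <= 0) stop("unbound plasma AUC must be > 0", call. = FALSE)
  fu_brain * get_auc(brain_conc) / den
}

#' Fold error
#'
#' `max(observed/predicted, predicted/observed)`; always >= 1 and symmetric
#' in its arguments.
#'
#' @param observed,predicted Positive values.
#' @return Fold error(s) >= 1.
#' @export
fold_error <- function(observed, predicted) {
  if (any(observed <= 0) || any(predicted <= 0))
    stop("fold error requires positive values", call. = FALSE)
  pmax(observed / predicted, predicted / observed)
}

#' Average fold error and root-mean-square error
#'
#' `afe = 10^(mean(log10(pred/obs)))` (geometric mean fold deviation; < 1
#' indicates net under-prediction) and `rmse = sqrt(mean((pred - obs)^2))`
#' on the concentration units of the compared data.
#'
#' @param observed,predicted Paired values (positive for afe).
#' @return List `afe`, `rmse`.
#' @export
afe_rmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1)
  if (any(observed <= 0) || any(predicted <= 0))
    stop("afe requires positive values", call. = FALSE)
  list(afe = 10 ^ mean(log10(predicted / observed)),
       rmse = sqrt(mean((predicted - observed) ^ 2)))
}

#' Fold-error acceptance band
#'
#' @param fe Fold error(s) >= 1.
#' @param threshold 2 or 5.
#' @return Logical; `TRUE` when `fe <= threshold` (boundary inclusive).
#' @export
acceptance_band <- function(fe, threshold = c(2, 5)) {
  threshold <- match.arg(as.character(threshold[1]), c("2", "5"))
  if (any(fe < 1)) stop("fold errors must be >= 1", call. = FALSE)
  fe <= as.numeric(threshold)
}
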