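# Two-parameter permeability sensitivity sweep: regional Cmax over a grid of
# the region's BBB PS and its inter-regional (region <-> rest-of-brain)
# diffusion PS, with optional 10-fold lower/higher rest-of-brain BBB PS
# scenarios.

#' Sweep specification
#'
#' @param pair `"hc"` (sweeps PS_BBB_HC and PS_HC_BT) or `"fc"` (sweeps
#'   PS_BBB_FC and PS_FC_BT).
#' @param range PS range in mL/min (default 0.01 to 100).
#' @param grid Points per axis (log-spaced; default 25).
#' @param scenario `"nominal"`, `"robPS_x0.1"` (rest-of-brain BBB PS scaled
#'   by 0.1) or `"robPS_x10"` (scaled by 10).
#' @return Object of class `sweep_spec`.
#' @export
sweep_spec <- function(pair = c("hc", "fc"), range = c(0.01, 100),
                       grid = 25, scenario = c("nominal", "robPS_x0.1",
                                               "robPS_x10")) {
  pair <- match.arg(pair)
  scenario <- match.arg(scenario)
  stopifnot(length(range) == 2, all(range > 0), range[1] < range[2],
            grid >= 1)
  structure(list(pair = pair, range = range, grid = as.integer(grid),
                 scenario = scenario), class = "sweep_spec")
}

#' Run a PS sensitivity sweep
#'
#' For every grid point the region's bidirectional BBB PS (`ps_in`,
#' `ps_out`) and its inter-regional diffusion PS are overridden directly
#' (post-scaling, on the mL/min axis), the model is simulated, and the
#' regional Cmax recorded. Scenario variants scale the rest-of-brain BBB PS
#' by 0.1 or 10. A degenerate 1x1 grid at the nominal PS reproduces the
#' unswept simulation's Cmax.
#'
#' @param spec A regional `model_spec` (a passive compound).
#' @param regimen A `dose_regimen`.
#' @param duration Simulation length, min.
#' @param sweep A `sweep_spec`.
#' @param dt_out Output interval for sweep simulations, min.
#' @param units Concentration units of the recorded Cmax (default umol/L).
#' @return Object of class `cmax_mesh`: `ps_bbb` and `ps_bt` axis values
#'   (mL/min), `cmax` matrix (rows = ps_bbb, cols = ps_bt), `scenario`,
#'   `failed` (grid locations of any solver failures).
#' @export
ps_sweep <- function(spec, regimen, duration, sweep = sweep_spec(),
                     dt_out = 1, units = "umol/L") {
  stopifnot(inherits(spec, "model_spec"), spec$cns == "regional")
  region <- sweep$pair
  # a degenerate 1x1 grid evaluates the nominal (unswept) PS values
  axis_bbb <- axis_bt <- if (sweep$grid == 1) NULL else
    exp(seq(log(sweep$range[1]), log(sweep$range[2]),
            length.out = sweep$grid))
  if (sweep$grid == 1) {
    axis_bbb <- spec$permeabilities[[paste0("ps_in_", region)]]
    axis_bt <- spec$permeabilities[[paste0("ps_bt_", region)]]
  }
  rob_scale <- switch(sweep$scenario, nominal = 1, "robPS_x0.1" = 0.1,
                      "robPS_x10" = 10)
  cmax <- matrix(NA_real_, sweep$grid, sweep$grid)
  failed <- NULL
  for (i in seq_len(sweep$grid)) {
    for (j in seq_len(sweep$grid)) {
      ov <- list()
      ov[[paste0("ps_in_", region)]] <- axis_bbb[i]
      ov[[paste0("ps_out_", region)]] <- axis_bbb[i]
      ov[[paste0("ps_bt_", region)]] <- axis_bt[j]
      ov$ps_in_rob <- spec$permeabilities$ps_in_rob * rob_scale
      ov$ps_out_rob <- spec$permeabilities$ps_out_rob * rob_scale
      spec_ij <- spec
      spec_ij$permeabilities[names(ov)] <- ov
      res <- tryCatch(simulate_pbpk(spec_ij, regimen, duration,
                                    dt_out = dt_out),
                      error = function(e) NULL)
      if (is.null(res)) {
        failed <- rbind(failed, c(i = i, j = j))
        next
      }
      s <- get_series(res, region, units)
      cmax[i, j] <- max(s$conc)
    }
  }
  structure(list(ps_bbb = axis_bbb, ps_bt = axis_bt, cmax = cmax,
                 pair = region, scenario = sweep$scenario, units = units,
                 failed = failed), class = "cmax_mesh")
}

#' Export a Cmax mesh as a long-format table
#'
#' @param mesh A `cmax_mesh`.
#' @param path Optional CSV output path.
#' @return Data frame `ps_bbb`, `ps_bt`, `cmax`, `scenario` (grid^2 rows).
#' @export
mesh_export <- function(mesh, path = NULL) {
  stopifnot(inherits(mesh, "cmax_mesh"))
  df <- data.frame(
    ps_bbb = rep(mesh$ps_bbb, times = length(mesh$ps_bt)),
    ps_bt = rep(mesh$ps_bt, each = length(mesh$ps_bbb)),
    cmax = as.vector(mesh$cmax),
    scenario = mesh$scenario)
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}

#' @export
print.cmax_mesh <- function(x, ...) {
  cat(sprintf(paste0("<cmax_mesh: %s pair, %s, %dx%d grid, Cmax ",
                     "[%.3g, %.3g] %s>\n"),
              x$pair, x$scenario, length(x$ps_bbb), length(x$ps_bt),
              min(x$cmax, na.rm = TRUE), max(x$cmax, na.rm = TRUE),
              x$units))
  invisible(x)
}
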