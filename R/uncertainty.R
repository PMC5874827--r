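# Monte Carlo propagation of regional ECF-volume uncertainty. Each
# simulation draws all three regional ECF volumes (ROB, HC, FC) jointly and
# independently from log-normal distributions, so one iteration perturbs
# three compartments at once (1000 iterations = 3000 compartment-runs, the
# study's stated budget).

#' Monte Carlo configuration
#'
#' @param cv Coefficient of variation of the log-normal ECF-volume
#'   perturbation (fraction; default 0.30).
#' @param n Number of simulations; each perturbs all three regional ECF
#'   volumes simultaneously (default 1000, i.e. 3000 compartment-runs).
#' @param seed Integer seed for the shared pseudo-random stream.
#' @param percentiles Band percentiles (default 5 and 95).
#' @param targets Compartments whose series are banded.
#' @param dt_out Output interval for iteration simulations, min.
#' @param lognormal_mean_mode If `FALSE` (default) the log-normal median
#'   equals the nominal volume, keeping the deterministic run the central
#'   trajectory; if `TRUE` the mean is nominal instead.
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(cv = 0.30, n = 1000, seed = 20180114L,
                      percentiles = c(5, 95),
                      targets = c("plasma", "rob", "hc", "fc"),
                      dt_out = 1, lognormal_mean_mode = FALSE) {
  stopifnot(cv >= 0, n >= 1, all(percentiles > 0), all(percentiles < 100))
  structure(list(cv = cv, n = as.integer(n), seed = as.integer(seed),
                 percentiles = sort(percentiles), targets = targets,
                 dt_out = dt_out,
                 lognormal_mean_mode = lognormal_mean_mode),
            class = "mc_config")
}

#' Draw perturbed regional ECF volumes
#'
#' Log-normal with `sdlog = sqrt(log(1 + cv^2))`; by default the median is
#' the nominal volume (`meanlog = log(nominal)`); in mean-preserving mode
#' `meanlog = log(nominal) - sdlog^2/2`.
#'
#' @param nominal Named numeric vector of nominal volumes.
#' @param cv Coefficient of variation.
#' @param n Number of draws.
#' @param mean_mode Preserve the mean instead of the median.
#' @return `n` x `length(nominal)` matrix of volumes.
#' @export
draw_ecf_volumes <- function(nominal, cv, n, mean_mode = FALSE) {
  if (cv == 0)
    return(matrix(rep(nominal, each = n), nrow = n,
                  dimnames = list(NULL, names(nominal))))
  sdlog <- sqrt(log(1 + cv ^ 2))
  meanlog <- log(nominal) - if (mean_mode) sdlog ^ 2 / 2 else 0
  m <- vapply(seq_along(nominal),
              function(j) stats::rlnorm(n, meanlog[j], sdlog),
              numeric(n))
  if (n == 1) m <- matrix(m, nrow = 1)
  colnames(m) <- names(nominal)
  m
}

#' Run the ECF-volume Monte Carlo
#'
#' Simulates the regional model repeatedly with jointly perturbed ROB, HC
#' and FC ECF volumes (parent tissue volumes, and hence the scaled PS
#' values, stay fixed), collecting pointwise percentile bands and
#' per-iteration Cmax/tmax/AUC samples. Failed solver iterations are
#' redrawn and counted; more than 1% failures aborts.
#'
#' @param spec A regional `model_spec`.
#' @param regimen A `dose_regimen`.
#' @param duration Simulation length, min.
#' @param config An `mc_config`.
#' @return Object of class `mc_bands`: `times`, `bands` (list per target
#'   compartment: matrix with one row per percentile plus the median),
#'   `samples` (per-iteration data frame of Cmax/tmax/AUC per target),
#'   `volumes` (drawn ECF volumes), `n_failed`, `config`, `nominal` (the
#'   deterministic run's summary).
#' @export
run_mc <- function(spec, regimen, duration, config = mc_config()) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$cns != "regional")
    stop("Monte Carlo requires the regional CNS model", call. = FALSE)
  set.seed(config$seed)
  nominal <- c(rob = spec$geometry$v_rob_ecf, hc = spec$geometry$v_hc_ecf,
               fc = spec$geometry$v_fc_ecf)
  vols <- draw_ecf_volumes(nominal, config$cv, config$n,
                           config$lognormal_mean_mode)
  targets <- config$targets
  det <- simulate_pbpk(spec, regimen, duration, dt_out = config$dt_out)
  times <- det$times
  series <- lapply(targets, function(tg)
    matrix(NA_real_, nrow = config$n, ncol = length(times)))
  names(series) <- targets
  samples <- vector("list", config$n)
  n_failed <- 0L
  max_failed <- max(1, ceiling(0.01 * config$n))

  for (i in seq_len(config$n)) {
    repeat {
      geo <- spec$geometry
      geo$v_rob_ecf <- unname(vols[i, "rob"])
      geo$v_hc_ecf <- unname(vols[i, "hc"])
      geo$v_fc_ecf <- unname(vols[i, "fc"])
      spec_i <- spec
      spec_i$geometry <- geo
      res <- tryCatch(simulate_pbpk(spec_i, regimen, duration,
                                    dt_out = config$dt_out),
                      error = function(e) NULL)
      if (!is.null(res)) break
      n_failed <- n_failed + 1L
      if (n_failed > max_failed)
        stop("more than 1% of Monte Carlo iterations failed", call. = FALSE)
      vols[i, ] <- draw_ecf_volumes(nominal, config$cv, 1,
                                    config$lognormal_mean_mode)[1, ]
    }
    row <- lapply(targets, function(tg) {
      s <- res$conc[, tg]
      series[[tg]][i, ] <<- s
      n <- nca(times, s)
      setNames(c(n$cmax, n$tmax, n$auc_0_last),
               paste0(tg, c("_cmax", "_tmax", "_auc")))
    })
    samples[[i]] <- unlist(row)
  }
  samples <- as.data.frame(do.call(rbind, samples))

  probs <- sort(unique(c(config$percentiles / 100, 0.5)))
  bands <- lapply(series, function(m)
    apply(m, 2, quantile, probs = probs, names = FALSE))
  for (tg in targets)
    rownames(bands[[tg]]) <- paste0("p", formatC(probs * 100))

  structure(list(times = times, bands = bands, samples = samples,
                 volumes = vols, n_failed = n_failed, config = config,
                 nominal = pk_summary(det, targets)),
            class = "mc_bands")
}

#' Summarize Monte Carlo samples as mean +/- SD
#'
#' Arithmetic mean and standard deviation of the per-iteration Cmax, tmax
#' and AUC for each banded compartment.
#'
#' @param bands An `mc_bands`.
#' @return Data frame with `compartment`, `metric`, `mean`, `sd`.
#' @export
summarize_mc <- function(bands) {
  stopifnot(inherits(bands, "mc_bands"))
  if (nrow(bands$samples) < 2)
    stop("need at least 2 iterations to summarize", call. = FALSE)
  cols <- names(bands$samples)
  parts <- strsplit(cols, "_(?=[^_]+$)", perl = TRUE)
  data.frame(
    compartment = vapply(parts, `[[`, character(1), 1),
    metric = vapply(parts, `[[`, character(1), 2),
    mean = vapply(bands$samples, mean, numeric(1), USE.NAMES = FALSE),
    sd = vapply(bands$samples, sd, numeric(1), USE.NAMES = FALSE))
}

#' @export
print.mc_bands <- function(x, ...) {
  cat(sprintf("<mc_bands: %d iterations (cv %.2g), %d failures, targets %s>\n",
              nrow(x$samples), x$config$cv, x$n_failed,
              paste(names(x$bands), collapse = "/")))
  invisible(x)
}
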