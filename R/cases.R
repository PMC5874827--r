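# Workflow drivers tying the pipeline together: the Step-1 ten-compound
# Kp_uu validation panel (one-compartment brain) and the three regional
# case studies (rat phenytoin, rat carbamazepine, human morphine), plus the
# run-manifest writer used by the command-line wrapper.

#' Step-1 Kp_uu validation panel
#'
#' Simulates each compound with the one-compartment permeability-limited
#' brain via an IV bolus, computes the predicted unbound brain-to-plasma
#' partition coefficient over the simulated window, and compares it to the
#' compound's observed value with a fold-error and 5-fold acceptance flag.
#' Compounds lacking an observed Kp_uu are skipped with a warning.
#'
#' @param compounds Compound fixture names (default: the ten-compound
#'   passive panel).
#' @param species Species fixture name (default rat).
#' @param duration Simulation length, min.
#' @param dose_mg_kg IV bolus dose (Kp_uu is dose-independent in this
#'   linear model; the dose only sets the concentration scale).
#' @param dt_out Output interval, min.
#' @return Data frame `compound`, `kpuu_pred`, `kpuu_obs`, `fe`,
#'   `within_5fold`, `within_2fold`.
#' @export
run_step1_panel <- function(compounds = c("benzylpenicillin", "buspirone",
                                          "caffeine", "carbamazepine",
                                          "diazepam", "midazolam",
                                          "phenytoin", "sertraline",
                                          "thiopental", "zolpidem"),
                            species = "rat", duration = 3000,
                            dose_mg_kg = 1, dt_out = 1) {
  phys <- load_physiology(species)
  geo <- load_cns_geometry(species)
  reg <- dose_regimen("iv_bolus", dose_mg_kg, "mg/kg")
  rows <- lapply(compounds, function(cn) {
    cmp <- load_compound(cn)
    obs <- cmp$observed_kpuu
    if (is.null(obs)) {
      warning(sprintf("no observed Kp_uu for '%s'; skipped", cn),
              call. = FALSE)
      return(NULL)
    }
    spec <- model_spec(phys, cmp, cns = "one_compartment", geometry = geo)
    res <- simulate_pbpk(spec, reg, duration, dt_out = dt_out)
    pred <- kpuu_brain(res$times, res$conc[, "brain"], res$conc[, "plasma"],
                       cmp$fu_brain, cmp$fu_plasma)
    fe <- fold_error(obs, pred)
    data.frame(compound = cn, kpuu_pred = pred, kpuu_obs = obs, fe = fe,
               within_5fold = acceptance_band(fe, 5),
               within_2fold = acceptance_band(fe, 2))
  })
  do.call(rbind, rows)
}

# Observed reference values for the case studies (summary statistics as
# reported for the source microdialysis/plasma studies).
.CASE_DEFS <- list(
  phenytoin_rat = list(
    compound = "phenytoin", species = "rat", regimen = "phenytoin_rat_ip",
    duration = 480, units = "umol/L",
    observed = data.frame(
      compartment = c("plasma", "hc", "fc"),
      cmax = c(61.69, 7.00, 3.98),
      auc = c(5924.55, 594.74, 370.97)),
    observed_kpuu = c(hc = 0.11, fc = 0.08)),
  carbamazepine_rat = list(
    compound = "carbamazepine", species = "rat",
    regimen = "carbamazepine_rat", duration = 300, units = "umol/L",
    observed = data.frame(
      compartment = c("plasma"), cmax = c(2.14), auc = c(NA)),
    observed_kpuu = c(hc = 1.02)),
  morphine_human = list(
    compound = "morphine", species = "human", regimen = "morphine_human",
    duration = 360, units = "ng/mL",
    observed = data.frame(
      compartment = c("plasma", "rob_better", "rob_worse"),
      model_compartment = c("plasma", "rob", "rob"),
      cmax = c(178, 10.1, 29.8),
      auc = c(7513, 941.7, 2732)),
    observed_kpuu = NULL)
)

#' Run a full regional case study
#'
#' Executes the complete pipeline for one of the bundled cases: derive
#' clearances and permeabilities, simulate the regional model under the
#' case regimen, run the ECF-volume Monte Carlo, and summarize predicted
#' against observed pharmacokinetics.
#'
#' @param case `"phenytoin_rat"`, `"carbamazepine_rat"` or
#'   `"morphine_human"`.
#' @param mc An `mc_config` (set `n` lower for quick runs), or `NULL` to
#'   skip the Monte Carlo stage.
#' @param dt_out Output interval of the deterministic run, min.
#' @return List (class `case_result`): `case`, `spec`, `result`
#'   (deterministic `simulation_result`), `summary` (`pk_summary` in case
#'   units), `kpuu` (regional predictions), `bands` (`mc_bands` or `NULL`),
#'   `mc_summary`, `observed`, `validation` (fold errors on Cmax where an
#'   observed value exists).
#' @export
run_case <- function(case = c("phenytoin_rat", "carbamazepine_rat",
                              "morphine_human"),
                     mc = mc_config(), dt_out = 0.1) {
  case <- match.arg(case)
  def <- .CASE_DEFS[[case]]
  phys <- load_physiology(def$species)
  geo <- load_cns_geometry(def$species)
  cmp <- load_compound(def$compound)
  reg <- load_regimen(def$regimen)
  spec <- model_spec(phys, cmp, cns = "regional", geometry = geo)

  res <- simulate_pbpk(spec, reg, def$duration, dt_out = dt_out)
  comps <- c("plasma", "rob", "hc", "fc", "csf")
  summ <- pk_summary(res, comps, units = def$units)

  kpuu <- vapply(c(rob = "rob", hc = "hc", fc = "fc"), function(r)
    kpuu_brain(res$times, res$conc[, r], res$conc[, "plasma"],
               cmp$fu_brain, cmp$fu_plasma), numeric(1))

  bands <- mc_summary <- NULL
  if (!is.null(mc)) {
    bands <- run_mc(spec, reg, def$duration, mc)
    mc_summary <- summarize_mc(bands)
    mc_summary$mean <- convert_conc_metric(mc_summary, def$units, cmp$mw,
                                           "mean")
    mc_summary$sd <- convert_conc_metric(mc_summary, def$units, cmp$mw,
                                         "sd")
  }

  obs <- def$observed
  model_cp <- obs$model_compartment %||% obs$compartment
  pred_cmax <- summ$cmax[match(model_cp, summ$compartment)]
  validation <- data.frame(
    compartment = obs$compartment, observed_cmax = obs$cmax,
    predicted_cmax = pred_cmax,
    fe = vapply(seq_along(pred_cmax), function(i)
      if (is.na(pred_cmax[i]) || pred_cmax[i] <= 0) NA_real_
      else fold_error(obs$cmax[i], pred_cmax[i]), numeric(1)))

  structure(list(case = case, spec = spec, result = res, summary = summ,
                 kpuu = kpuu, bands = bands, mc_summary = mc_summary,
                 observed = obs, observed_kpuu = def$observed_kpuu,
                 validation = validation, units = def$units),
            class = "case_result")
}

# Convert the concentration-bearing rows (cmax, auc) of an MC summary from
# internal mg/L to the case's reporting units; tmax rows pass through.
convert_conc_metric <- function(mc_summary, units, mw, col) {
  v <- mc_summary[[col]]
  is_conc <- mc_summary$metric %in% c("cmax", "auc")
  v[is_conc] <- convert_conc(v[is_conc], "mg/L", units, mw)
  v
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf("<case_result: %s (%s)>\n", x$case, x$units))
  print(x$summary)
  invisible(x)
}

#' Write a run manifest
#'
#' Records the command, resolved inputs, seed, package version, timestamp
#' and produced output files so that a stochastic run can be replayed
#' bit-for-bit.
#'
#' @param command Command or function name.
#' @param inputs Named list of resolved inputs/arguments.
#' @param seed Integer seed (or `NA` for deterministic runs).
#' @param outputs Character vector of output file paths.
#' @param path Manifest path (JSON).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(command, inputs, seed, outputs, path) {
  manifest <- list(
    command = command, inputs = inputs, seed = seed,
    version = as.character(utils::packageVersion("cnspbpk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
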