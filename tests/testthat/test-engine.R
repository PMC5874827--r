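test_that("no dose yields an all-zero trajectory", {
  spec <- probe_spec("regional", cl_h = 1)
  res <- simulate_pbpk(spec, NULL, 60, dt_out = 5)
  expect_true(all(res$amounts == 0))
  expect_true(all(res$conc == 0))
})

test_that("an IV bolus in a closed system conserves mass on the output grid", {
  spec <- probe_spec("regional", cl_h = 0, cl_r = 0)
  res <- simulate_pbpk(spec, dose_regimen("iv_bolus", 2, "mg"), 240,
                       dt_out = 1)
  tot <- rowSums(res$amounts)
  expect_equal(tot, rep(2, length(tot)), tolerance = 1e-9)
})

test_that("infusions deliver exactly rate times duration", {
  spec <- probe_spec("regional", cl_h = 0, cl_r = 0)
  reg <- dose_regimen("iv_infusion", 10, "mg", infusion_duration = 10)
  res <- simulate_pbpk(spec, reg, 60, dt_out = 0.5)
  tot <- rowSums(res$amounts)
  expect_equal(tot[res$times == 10], 10, tolerance = 1e-8)
  expect_equal(tot[res$times == 5], 5, tolerance = 1e-8)
  expect_equal(tail(tot, 1), 10, tolerance = 1e-8)
})

test_that("IP dosing books unabsorbed drug and conserves the balance", {
  spec <- probe_spec("regional", cl_h = 1)
  reg <- dose_regimen("ip", 4, "mg", ka = 0.2, f_abs = 0.8)
  res <- simulate_pbpk(spec, reg, 600, dt_out = 5)
  tot <- rowSums(res$amounts)
  expect_equal(tot, rep(4, length(tot)), tolerance = 1e-8)
  # at the end, ~all depot drained; 20% of absorbed flux went unabsorbed
  expect_lt(tail(res$amounts[, "depot"], 1), 1e-8)
  expect_gt(tail(res$amounts[, "eliminated"], 1), 0.8)
})

test_that("reported Cmax is not limited by the output grid", {
  spec <- phenytoin_spec()
  reg <- load_regimen("phenytoin_rat_ip")
  c1 <- max(simulate_pbpk(spec, reg, 240, dt_out = 1)$conc[, "plasma"])
  c2 <- max(simulate_pbpk(spec, reg, 240, dt_out = 0.5)$conc[, "plasma"])
  expect_lt(abs(c1 - c2) / c2, 0.005)
})

test_that("a 0.1-min infusion converges to the bolus profile", {
  spec <- probe_spec("regional", cl_h = 1)
  bol <- simulate_pbpk(spec, dose_regimen("iv_bolus", 2, "mg"), 120,
                       dt_out = 1)
  inf <- simulate_pbpk(spec, dose_regimen("iv_infusion", 2, "mg",
                                          infusion_duration = 0.1),
                       120, dt_out = 1)
  after5 <- bol$times >= 5
  rel <- abs(inf$conc[after5, "plasma"] - bol$conc[after5, "plasma"]) /
    bol$conc[after5, "plasma"]
  expect_lt(max(rel), 0.01)
})

test_that("doubling the dose doubles every concentration (linearity)", {
  spec <- phenytoin_spec()
  r1 <- simulate_pbpk(spec, dose_regimen("ip", 5, "mg", ka = 0.25), 240,
                      dt_out = 1)
  r2 <- simulate_pbpk(spec, dose_regimen("ip", 10, "mg", ka = 0.25), 240,
                      dt_out = 1)
  nz <- r1$conc > 1e-12
  expect_equal(r2$conc[nz] / r1$conc[nz],
               rep(2, sum(nz)), tolerance = 1e-6)
})

test_that("no state dips below the negativity tolerance on case fixtures", {
  spec <- phenytoin_spec()
  res <- simulate_pbpk(spec, load_regimen("phenytoin_rat_ip"), 480,
                       dt_out = 1)
  expect_gte(min(res$amounts), 0)   # clipped only below 1e-12-scale noise
})

test_that("observed series pair with simulated values via unit conversion", {
  spec <- phenytoin_spec()
  res <- simulate_pbpk(spec, load_regimen("phenytoin_rat_ip"), 240,
                       dt_out = 1)
  mw <- spec$compound$mw
  # grid-aligned observation in umol/L converts through MW exactly
  t_obs <- c(10, 60, 120)
  sim_umol <- get_series(res, "plasma", "umol/L")
  obs <- data.frame(time = t_obs,
                    conc = sim_umol$conc[match(t_obs, sim_umol$time_min)])
  f <- tempfile(fileext = ".csv")
  writeLines("# units: min, umol/L", f)
  suppressWarnings(write.table(obs, f, append = TRUE, sep = ",",
                               row.names = FALSE, col.names = TRUE))
  paired <- compare_to_observed(res, f, "plasma")
  expect_equal(paired$observed, paired$predicted, tolerance = 1e-12)
  expect_equal(paired$observed, obs$conc * mw / 1000)  # now in mg/L

  # empty observed set and out-of-window times are rejected
  empty <- data.frame(time = numeric(0), conc = numeric(0))
  expect_error(compare_to_observed(res, empty, "plasma"), "empty")
  late <- data.frame(time = 1000, conc = 1)
  expect_error(compare_to_observed(res, late, "plasma"), "beyond")
})

test_that("concentration unit conversions are exact and invertible", {
  mw <- 252.27
  expect_equal(convert_conc(1, "mg/L", "umol/L", mw), 1000 / mw)
  expect_equal(convert_conc(1, "mg/L", "ng/mL"), 1000)
  expect_equal(convert_conc(208.2, "ng/mL", "mg/L"), 0.2082)
  x <- runif(5, 0.1, 100)
  for (u in c("ng/mL", "umol/L", "nmol/L", "mg/mL"))
    expect_equal(convert_conc(convert_conc(x, "mg/L", u, mw), u, "mg/L", mw),
                 x)
  expect_error(convert_conc(1, "mg/L", "umol/L"), "molecular weight")
})
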