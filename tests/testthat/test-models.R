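test_that("the right-hand side vanishes at the zero state and flags bad input", {
  for (cns in c("one_compartment", "regional")) {
    spec <- probe_spec(cns, cl_h = 2, cl_r = 1)
    ns <- if (cns == "regional") 20 else 17
    expect_equal(pbpk_rhs(numeric(ns), spec), numeric(ns))
    y <- numeric(ns); y[5] <- NaN
    expect_error(pbpk_rhs(y, spec), "non-finite state")
  }
})

test_that("a closed system conserves total drug amount exactly", {
  set.seed(31)
  for (cns in c("one_compartment", "regional")) {
    spec <- probe_spec(cns, cl_h = 0, cl_r = 0)
    ns <- if (cns == "regional") 20 else 17
    for (i in 1:10) {
      y <- runif(ns)
      dy <- pbpk_rhs(y, spec, ka = 0.2, f_abs = 1)
      expect_equal(sum(dy), 0, tolerance = 1e-12)
    }
  }
})

test_that("eliminating fluxes are fully booked to the eliminated state", {
  set.seed(32)
  spec <- probe_spec("regional", cl_h = 3, cl_r = 1.2)
  for (i in 1:10) {
    y <- runif(20)
    dy <- pbpk_rhs(y, spec, ka = 0.2, f_abs = 0.8)
    expect_equal(sum(dy), 0, tolerance = 1e-12)  # elimination is a state
  }
})

test_that("the compiled and reference right-hand sides integrate identically", {
  spec <- phenytoin_spec()
  reg <- load_regimen("phenytoin_rat_ip")
  rc <- simulate_pbpk(spec, reg, 120, dt_out = 1, use_compiled = TRUE)
  rr <- simulate_pbpk(spec, reg, 120, dt_out = 1, use_compiled = FALSE)
  expect_equal(rc$amounts, rr$amounts, tolerance = 1e-7)
})

test_that("constant infusion reaches the R/CL plasma steady state", {
  # low-extraction probe so the one-compartment closed form applies:
  # Css = R / CL_H up to O(CL/Q) flow corrections
  cl_h <- 0.5
  spec <- probe_spec("one_compartment", cl_h = cl_h)
  reg <- dose_regimen("iv_infusion", 5000, "mg", infusion_duration = 1e5)
  res <- simulate_pbpk(spec, reg, 2e4, dt_out = 50)
  css <- tail(res$conc[, "plasma"], 1)             # mg/L
  expected <- (5000 / 1e5) / cl_h * 1000
  q_l <- 20
  expect_equal(css, expected, tolerance = 2 * cl_h / q_l)
})

test_that("efflux-scaled outward PS sets the steady-state unbound ratio to 1/ER", {
  er <- 3
  spec <- probe_spec("one_compartment", cl_h = 0.5)
  spec$permeabilities$whole_out <- er * spec$permeabilities$whole_in
  reg <- dose_regimen("iv_infusion", 5000, "mg", infusion_duration = 1e5)
  res <- simulate_pbpk(spec, reg, 2e4, dt_out = 50)
  fu <- spec$compound$fu_brain
  ratio <- (fu * tail(res$conc[, "brain"], 1)) /
    (spec$compound$fu_plasma * tail(res$conc[, "bb"], 1))
  expect_equal(ratio, 1 / er, tolerance = 1e-4)
})

test_that("zero permeability and bulk flow decouple the CNS block", {
  geo <- rat_geo()
  geo$q_bulk_rob <- geo$q_bulk_hc <- geo$q_bulk_fc <- 0
  geo$q_csf_production <- geo$q_csf_sink <- 0
  spec <- probe_spec("regional", cl_h = 1, geometry = geo)
  for (nm in c("ps_in_rob", "ps_in_hc", "ps_in_fc", "ps_out_rob",
               "ps_out_hc", "ps_out_fc", "ps_bt_hc", "ps_bt_fc"))
    spec$permeabilities[[nm]] <- 0
  idx <- compartment_index(spec)
  y0 <- numeric(20)
  y0[idx[c("rob", "hc", "fc", "csf")]] <- c(0.2, 0.05, 0.1, 0.15)
  y0[idx[["venous"]]] <- 1
  res <- simulate_pbpk(spec, NULL, 120, dt_out = 10, state0 = y0)
  for (cp in c("rob", "hc", "fc", "csf"))
    expect_equal(res$amounts[, cp], rep(y0[idx[[cp]]], length(res$times)),
                 tolerance = 1e-10)
})

test_that("a closed CNS block conserves its total amount", {
  geo <- rat_geo()
  geo$q_brain_blood <- 0
  geo$q_csf_production <- geo$q_csf_sink <- 0
  spec <- probe_spec("regional", geometry = geo)
  idx <- compartment_index(spec)
  y0 <- numeric(20)
  cns <- c("bb", "rob", "hc", "fc", "csf")
  y0[idx[cns]] <- c(0.5, 0.2, 0.05, 0.1, 0.15)
  res <- simulate_pbpk(spec, NULL, 200, dt_out = 20, state0 = y0)
  tot <- rowSums(res$amounts[, cns])
  expect_equal(tot, rep(1, length(tot)), tolerance = 1e-9)
})

test_that("the CNS block trajectory matches a matrix-exponential oracle", {
  geo <- rat_geo()
  geo$q_brain_blood <- 0
  geo$q_csf_production <- geo$q_csf_sink <- 0
  spec <- model_spec(rat_phys(), load_compound("phenytoin"), "regional",
                     geo, clearances = fixed_clearances())
  A <- cns_block_matrix(spec)
  y0cns <- c(bb = 0.5, rob = 0.2, hc = 0.05, fc = 0.1, csf = 0.15)
  idx <- compartment_index(spec)
  y0 <- numeric(20); y0[idx[names(y0cns)]] <- y0cns
  res <- simulate_pbpk(spec, NULL, 60, dt_out = 10, state0 = y0)
  for (tt in c(10, 30, 60)) {
    oracle <- as.numeric(Matrix::expm(A * tt) %*% y0cns)
    simv <- as.numeric(res$amounts[res$times == tt, names(y0cns)])
    expect_equal(simv, oracle, tolerance = 1e-6)
  }
})

test_that("symmetric permeability with uniform fu equalizes unbound CNS levels", {
  geo <- rat_geo()
  geo$q_brain_blood <- 0
  geo$q_csf_production <- geo$q_csf_sink <- 0
  geo$q_bulk_rob <- geo$q_bulk_hc <- geo$q_bulk_fc <- 0   # pure diffusion
  spec <- probe_spec("regional", fu = 0.5, geometry = geo)
  idx <- compartment_index(spec)
  y0 <- numeric(20); y0[idx[["bb"]]] <- 1
  res <- simulate_pbpk(spec, NULL, 5e4, dt_out = 1e3, state0 = y0)
  last <- nrow(res$conc)
  # with fu uniform across plasma/brain/CSF, unbound equality implies
  # equality of the (total) concentrations themselves
  cns <- res$conc[last, c("bb", "rob", "hc", "fc")]
  expect_lt(max(cns) / min(cns) - 1, 1e-3)
})
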