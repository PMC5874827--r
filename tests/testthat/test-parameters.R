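test_that("bundled physiology fixtures carry the tabulated volumes and flows", {
  rat <- load_physiology("rat")
  expect_equal(rat$tissues$liver$volume, 10.3)
  expect_equal(rat$tissues$liver$perfusion, 20)
  expect_equal(rat$arterial_volume, 6.8)
  expect_equal(rat$body_weight, 0.25)
  expect_equal(rat$bbb_surface_area, 150)
  expect_equal(rat$microsomal_protein, 45)
  expect_equal(rat$hepatocellularity, 130e6)

  hum <- load_physiology("human")
  expect_equal(hum$tissues$brain$perfusion, 750)
  expect_equal(hum$tissues$brain$volume, 1552.5)
  expect_equal(hum$bbb_surface_area, 157)
  expect_equal(hum$body_weight, 70)
})

test_that("cardiac output balances venous return under the portal topology", {
  for (sp in c("rat", "human")) {
    phys <- load_physiology(sp)
    q <- vapply(phys$tissues, `[[`, numeric(1), "perfusion")
    venous_return <- sum(q[c("adipose", "bone", "heart", "kidney", "liver",
                             "muscle", "skin", "brain")])
    expect_equal(cnspbpk:::cardiac_output(phys), venous_return)
    # hepatic artery flow must be non-negative
    expect_gte(q[["liver"]] - q[["gut"]] - q[["pancreas"]] - q[["spleen"]], 0)
  }
})

test_that("CNS geometry fixtures match the tabulated regional parameters", {
  rat <- load_cns_geometry("rat")
  expect_equal(rat$v_hc_ecf, 0.019)
  expect_equal(rat$q_bulk_hc, 0.00002)
  expect_equal(rat$v_bb, 0.025)
  expect_equal(rat$q_csf_production, 0.0037)

  hum <- load_cns_geometry("human", species = "human")
  expect_equal(hum$v_csf, 160)
  expect_equal(hum$q_csf_production, 0.35)
  expect_equal(hum$v_rob_ecf, 267)

  # regional bulk flows follow the 0.2 uL/min/g rule within table rounding
  masses <- c(rat$v_rob, rat$v_hc, rat$v_fc)       # density 1 g/mL
  rule <- 0.2e-3 * masses
  table_vals <- c(rat$q_bulk_rob, rat$q_bulk_hc, rat$q_bulk_fc)
  expect_true(all(abs(table_vals - rule) / table_vals < 0.10))

  # CNS sub-volumes add up to the whole brain weight at unit density
  expect_equal(rat$v_rob + rat$v_hc + rat$v_fc + rat$v_csf, 1.8,
               tolerance = 0.01)
})

test_that("ECF volumes derive from the interstitial fraction", {
  expect_equal(derive_ecf_volume(0.093, 0.188), 0.017484)
  expect_equal(derive_ecf_volume(283, 0.188), 53.204)
  expect_error(derive_ecf_volume(0.093, 0), "between 0 and 1")
  expect_error(derive_ecf_volume(0.093, 1), "between 0 and 1")
  expect_error(derive_ecf_volume(-1, 0.188), "> 0")
  # fixtures keep the printed table values over the derived products
  rat <- load_cns_geometry("rat")
  expect_equal(rat$v_hc_ecf, 0.019)          # table value, not 0.0175
  expect_equal(rat$v_fc_ecf, 0.038)          # printed value wins
})

test_that("malformed configurations are rejected with named errors", {
  raw <- yaml::read_yaml(pbpk_fixture("rat", "physiology"))
  bad <- raw
  bad$tissues$adipose$volume$value <- -1
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, f)
  expect_error(load_physiology(f), "volume")

  bad <- raw
  bad$tissues$kidney <- NULL
  yaml::write_yaml(bad, f)
  expect_error(load_physiology(f), "kidney")

  bad <- raw
  bad$gfr <- NULL
  yaml::write_yaml(bad, f)
  expect_error(load_physiology(f), "gfr")

  bad <- raw
  bad$tissues$liver$perfusion$units <- "L/h"
  yaml::write_yaml(bad, f)
  expect_error(load_physiology(f), "unit mismatch")

  g <- yaml::read_yaml(pbpk_fixture("rat", "cns"))
  g$v_hc_ecf$value <- 0.5                      # exceeds parent volume
  yaml::write_yaml(g, f)
  expect_error(load_cns_geometry(f), "parent tissue volume")
})

test_that("fixtures round-trip through serialization unchanged", {
  f <- tempfile(fileext = ".yaml")
  phys <- load_physiology("rat")
  write_config(phys, f)
  expect_equal(load_physiology(f), phys)

  geo <- load_cns_geometry("human")
  write_config(geo, f)
  expect_equal(load_cns_geometry(f), geo)

  reg <- load_regimen("phenytoin_rat_ip")
  write_config(reg, f)
  expect_equal(load_regimen(f), reg)
})

test_that("compound loader converts permeability units and flags symmetry", {
  cmp <- load_compound("phenytoin")
  # 12 x 1e-6 cm/s -> cm/min
  expect_equal(cmp$papp_ab, 12e-6 * 60)
  expect_true(cmp$papp_symmetric)
  expect_equal(cmp$efflux_ratio, 1)
  expect_equal(cmp$renal$kind, "none")
  expect_true(all(c("liver", "kidney", "lung") %in% names(cmp$kp_tissues)))
  # all bundled compounds load and validate
  for (cn in list_compounds()) {
    c2 <- load_compound(cn)
    expect_true(c2$fu_plasma > 0 && c2$fu_plasma <= 1, label = cn)
    expect_true(all(c2$kp_tissues > 0), label = cn)
  }
})

test_that("dose regimens resolve weight-based amounts and validate inputs", {
  reg <- load_regimen("phenytoin_rat_ip")
  expect_equal(reg$route, "ip")
  expect_equal(cnspbpk:::resolve_dose(reg, load_physiology("rat")),
               50 * 0.25)
  reg2 <- load_regimen("morphine_human")
  expect_equal(cnspbpk:::resolve_dose(reg2, load_physiology("human")), 10)
  expect_error(dose_regimen("iv_infusion", 10), "infusion_duration")
  expect_error(dose_regimen("ip", 10, ka = NULL), "ka")
  expect_error(dose_regimen("iv_bolus", -1), "amount")
})
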