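# Shared builders for the test suite. Everything is constructed in code from
# the bundled fixtures; no binary artifacts.

rat_phys <- function() load_physiology("rat")
rat_geo <- function() load_cns_geometry("rat")

# A structurally neutral probe compound: Rb = 1, uniform unbound fractions,
# unit tissue partitioning, symmetric moderate permeability. Used for the
# limit/identity properties where compound asymmetries would obscure the
# structural behaviour under test.
probe_compound <- function(fu = 0.5, papp = 1e-3) {
  cmp <- load_compound("phenytoin")
  cmp$name <- "probe"
  cmp$rb <- 1
  cmp$fu_plasma <- cmp$fu_brain <- cmp$fu_csf <- fu
  cmp$kp_tissues[] <- 1
  cmp$papp_ab <- papp
  cmp$papp_ba <- NULL
  cmp$papp_symmetric <- TRUE
  cmp$efflux_ratio <- 1
  cmp
}

fixed_clearances <- function(cl_h = 0, cl_r = 0) {
  structure(list(cl_h = cl_h, cl_r = cl_r, clint_invivo = NA_real_),
            class = "clearance_set")
}

probe_spec <- function(cns = "regional", cl_h = 0, cl_r = 0, fu = 0.5,
                       papp = 1e-3, geometry = rat_geo(), ...) {
  model_spec(rat_phys(), probe_compound(fu = fu, papp = papp), cns = cns,
             geometry = geometry,
             clearances = fixed_clearances(cl_h, cl_r), ...)
}

phenytoin_spec <- function() {
  model_spec(rat_phys(), load_compound("phenytoin"), "regional", rat_geo())
}

# Independent 5x5 flux matrix of the closed CNS block (amount space), built
# from first principles for the matrix-exponential oracle; q_brain, CSF
# production and sink are zero so the block is closed.
cns_block_matrix <- function(spec) {
  geo <- spec$geometry
  per <- spec$permeabilities
  cmp <- spec$compound
  fu_b <- cmp$fu_brain; fu_p <- cmp$fu_plasma
  V <- c(bb = geo$v_bb, rob = geo$v_rob_ecf, hc = geo$v_hc_ecf,
         fc = geo$v_fc_ecf, csf = geo$v_csf)
  psin <- c(per$ps_in_rob, per$ps_in_hc, per$ps_in_fc)
  psout <- c(per$ps_out_rob, per$ps_out_hc, per$ps_out_fc)
  qb <- c(geo$q_bulk_rob, geo$q_bulk_hc, geo$q_bulk_fc)
  A <- matrix(0, 5, 5, dimnames = list(names(V), names(V)))
  A["bb", "bb"] <- -sum(psin) * fu_p / V["bb"]
  regs <- c("rob", "hc", "fc")
  for (k in 1:3) {
    r <- regs[k]
    A["bb", r] <- psout[k] * fu_b / V[r]
    A[r, "bb"] <- psin[k] * fu_p / V["bb"]
    A[r, r] <- -(psout[k] + qb[k]) * fu_b / V[r]
    A["csf", r] <- qb[k] * fu_b / V[r]
  }
  A["hc", "rob"] <- per$ps_bt_hc * fu_b / V["rob"]
  A["fc", "rob"] <- per$ps_bt_fc * fu_b / V["rob"]
  A["rob", "hc"] <- per$ps_bt_hc * fu_b / V["hc"]
  A["rob", "fc"] <- per$ps_bt_fc * fu_b / V["fc"]
  A["rob", "rob"] <- A["rob", "rob"] -
    (per$ps_bt_hc + per$ps_bt_fc) * fu_b / V["rob"]
  A["hc", "hc"] <- A["hc", "hc"] - per$ps_bt_hc * fu_b / V["hc"]
  A["fc", "fc"] <- A["fc", "fc"] - per$ps_bt_fc * fu_b / V["fc"]
  A
}
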