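# Model assembly: perfusion-limited whole-body tissues bridged by lung and
# the two CNS variants (one-compartment permeability-limited brain; regional
# five-compartment block). The production right-hand side is compiled C
# (src/pbpk.c); pbpk_rhs() below is an R transcription of the same equations
# kept as an audit/reference path.

.BODY_TISSUES <- c("adipose", "bone", "gut", "heart", "kidney", "liver",
                   "muscle", "pancreas", "skin", "spleen")

#' Build a PBPK model specification
#'
#' Combines species physiology, compound profile, derived clearances and
#' permeabilities, and (for the regional variant) CNS geometry into a single
#' simulatable specification.
#'
#' @param physiology A `species_physiology`.
#' @param compound A `compound_profile`.
#' @param cns `"regional"` (five-compartment CNS block) or
#'   `"one_compartment"` (whole-brain permeability-limited compartment).
#' @param geometry A `cns_geometry`; required for the regional variant. For
#'   the one-compartment variant only its intracranial blood volume and
#'   cerebral blood flow are used (loaded from the species fixture when
#'   omitted).
#' @param clearances Optional `clearance_set`; derived from the compound via
#'   [build_clearances()] when omitted.
#' @param permeabilities Optional `permeability_set`; derived via
#'   [build_permeabilities()] when omitted.
#' @param csf_production_carries_drug If `TRUE` (default) CSF produced from
#'   intracranial blood carries unbound drug into the CSF compartment;
#'   if `FALSE` the produced fluid is drug-free.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(physiology, compound,
                       cns = c("regional", "one_compartment"),
                       geometry = NULL, clearances = NULL,
                       permeabilities = NULL,
                       csf_production_carries_drug = TRUE) {
  cns <- match.arg(cns)
  if (is.null(geometry)) geometry <- load_cns_geometry(physiology$species)
  if (cns == "regional" && is.null(geometry))
    stop("regional CNS model requires a cns_geometry", call. = FALSE)
  if (is.null(clearances)) clearances <- build_clearances(compound, physiology)
  if (is.null(permeabilities))
    permeabilities <- build_permeabilities(compound, physiology,
                                           if (cns == "regional") geometry)
  structure(list(physiology = physiology, compound = compound, cns = cns,
                 geometry = geometry, clearances = clearances,
                 permeabilities = permeabilities,
                 csf_production_carries_drug = csf_production_carries_drug),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec: %s, %s CNS, compound %s>\n",
              x$physiology$species,
              if (x$cns == "regional") "regional 5-compartment"
              else "one-compartment", x$compound$name))
  invisible(x)
}

#' Compartment index map of a model specification
#'
#' @param spec A `model_spec`.
#' @return Named integer vector mapping compartment labels to state
#'   positions (amounts vector).
#' @export
compartment_index <- function(spec) {
  base <- c(arterial = 1L, venous = 2L, lung = 3L,
            setNames(3L + seq_along(.BODY_TISSUES), .BODY_TISSUES))
  cns <- if (spec$cns == "one_compartment")
    c(bb = 14L, brain = 15L, depot = 16L, eliminated = 17L)
  else
    c(bb = 14L, rob = 15L, hc = 16L, fc = 17L, csf = 18L, depot = 19L,
      eliminated = 20L)
  c(base, cns)
}

# Distribution volumes (mL) per compartment, in state order. Regional CNS
# compartments distribute into their ECF volumes (the microdialysis
# biophase); depot/eliminated carry NA (amount bookkeeping only).
compartment_volumes <- function(spec) {
  phys <- spec$physiology
  geo <- spec$geometry
  v <- c(arterial = phys$arterial_volume, venous = phys$venous_volume,
         lung = phys$tissues$lung$volume,
         vapply(.BODY_TISSUES,
                function(t) phys$tissues[[t]]$volume, numeric(1)))
  if (spec$cns == "one_compartment")
    c(v, bb = geo$v_bb, brain = phys$brain_weight, depot = NA_real_,
      eliminated = NA_real_)
  else
    c(v, bb = geo$v_bb, rob = geo$v_rob_ecf, hc = geo$v_hc_ecf,
      fc = geo$v_fc_ecf, csf = geo$v_csf, depot = NA_real_,
      eliminated = NA_real_)
}

# Pack the full parameter vector consumed by the compiled RHS (and by the R
# reference RHS). Layout must stay in lock-step with src/pbpk.c.
pack_parms <- function(spec, rate = 0, ka = 0, f_abs = 1,
                       ps_override = NULL) {
  phys <- spec$physiology
  cmp <- spec$compound
  geo <- spec$geometry
  per <- spec$permeabilities
  if (!is.null(ps_override))
    per[names(ps_override)] <- ps_override
  Q <- vapply(.BODY_TISSUES, function(t) phys$tissues[[t]]$perfusion,
              numeric(1))
  V <- vapply(.BODY_TISSUES, function(t) phys$tissues[[t]]$volume,
              numeric(1))
  kp <- cmp$kp_tissues
  missing <- setdiff(.BODY_TISSUES, names(kp))
  if (length(missing))
    stop(sprintf("compound '%s' lacks Kp for: %s", cmp$name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  rbkp <- cmp$rb / kp[.BODY_TISSUES]
  q_ha <- Q[["liver"]] - Q[["gut"]] - Q[["pancreas"]] - Q[["spleen"]]
  if (q_ha < 0) stop("portal flows exceed total liver flow", call. = FALSE)

  p <- numeric(65)
  p[1] <- if (spec$cns == "one_compartment") 1 else 2
  p[2] <- cardiac_output(phys)
  p[3] <- phys$arterial_volume
  p[4] <- phys$venous_volume
  p[5] <- phys$tissues$lung$volume
  p[6] <- cmp$rb / (cmp$kp_tissues[["lung"]])
  p[7:16] <- Q
  p[17:26] <- V
  p[27:36] <- rbkp
  p[37] <- q_ha
  p[38] <- spec$clearances$cl_h
  p[39] <- spec$clearances$cl_r
  p[40] <- cmp$fu_plasma
  p[41] <- cmp$fu_brain
  p[42] <- cmp$fu_csf
  p[43] <- geo$q_brain_blood
  p[44] <- geo$v_bb
  p[45] <- ka
  p[46] <- f_abs
  p[47] <- rate
  p[48] <- as.numeric(isTRUE(spec$csf_production_carries_drug))
  if (spec$cns == "one_compartment") {
    p[49] <- per$whole_in
    p[52] <- per$whole_out
    p[62] <- phys$brain_weight          # brain volume at unit density
    p[65] <- 1                          # unused slots left non-zero-safe
  } else {
    p[49:51] <- c(per$ps_in_rob, per$ps_in_hc, per$ps_in_fc)
    p[52:54] <- c(per$ps_out_rob, per$ps_out_hc, per$ps_out_fc)
    p[55] <- per$ps_bt_hc
    p[56] <- per$ps_bt_fc
    p[57:59] <- c(geo$q_bulk_rob, geo$q_bulk_hc, geo$q_bulk_fc)
    p[60] <- geo$q_csf_production
    p[61] <- geo$q_csf_sink
    p[62:64] <- c(geo$v_rob_ecf, geo$v_hc_ecf, geo$v_fc_ecf)
    p[65] <- geo$v_csf
  }
  p
}

n_states <- function(spec) if (spec$cns == "one_compartment") 17L else 20L

#' Evaluate the model right-hand side (reference implementation)
#'
#' R transcription of the compiled derivative routine, exposed for audit and
#' used in the test suite to cross-check the compiled path. All exchange
#' across the blood-brain barrier, the inter-regional diffusion terms, the
#' ECF bulk flows and the CSF production/sink fluxes are gated by the
#' unbound concentration on their source side.
#'
#' @param state Numeric amounts vector (mg) in the order of
#'   [compartment_index()].
#' @param spec A `model_spec`.
#' @param t Time (min); the system is autonomous, `t` is accepted for
#'   solver compatibility.
#' @param rate Venous infusion rate, mg/min.
#' @param ka,f_abs Depot absorption constants (ip dosing).
#' @return Derivative vector d(state)/dt in mg/min.
#' @export
pbpk_rhs <- function(state, spec, t = 0, rate = 0, ka = 0, f_abs = 1) {
  if (any(!is.finite(state)))
    stop(sprintf("non-finite state in compartment(s): %s",
                 paste(names(compartment_index(spec))[!is.finite(state)],
                       collapse = ", ")), call. = FALSE)
  p <- pack_parms(spec, rate = rate, ka = ka, f_abs = f_abs)
  y <- unname(state)
  mode <- p[1]
  q_co <- p[2]; v_art <- p[3]; v_ven <- p[4]
  v_lung <- p[5]; rbkp_lung <- p[6]
  Q <- p[7:16]; V <- p[17:26]; RBKP <- p[27:36]
  q_ha <- p[37]; cl_h <- p[38]; cl_r <- p[39]
  fu_p <- p[40]; fu_b <- p[41]; fu_csf <- p[42]
  q_brain <- p[43]; v_bb <- p[44]
  ka <- p[45]; f_abs <- p[46]; rate <- p[47]; csf_carry <- p[48]

  c_art <- y[1] / v_art
  c_ven <- y[2] / v_ven
  c_lung_out <- y[3] / v_lung * rbkp_lung
  c_out <- y[4:13] / V * RBKP
  i_gut <- 3; i_heart <- 4; i_kid <- 5; i_liv <- 6; i_pan <- 8; i_spl <- 10
  i_dep <- if (mode == 1) 16 else 19
  i_eli <- i_dep + 1
  abs_flux <- ka * y[i_dep]

  dy <- numeric(length(y))
  dy[3] <- q_co * (c_ven - c_lung_out)
  draw <- q_brain + sum(Q) + q_ha - Q[i_liv]
  dy[1] <- q_co * c_lung_out - draw * c_art
  dy[4:13] <- Q * (c_art - c_out)
  dy[3 + i_liv] <- q_ha * c_art + Q[i_gut] * c_out[i_gut] +
    Q[i_pan] * c_out[i_pan] + Q[i_spl] * c_out[i_spl] +
    f_abs * abs_flux - (Q[i_liv] + cl_h) * c_out[i_liv]
  dy[3 + i_kid] <- dy[3 + i_kid] - cl_r * c_out[i_kid]

  ven_in <- rate + sum(Q[c(1, 2, i_heart, i_kid, i_liv, 7, 9)] *
                         c_out[c(1, 2, i_heart, i_kid, i_liv, 7, 9)])
  c_bb <- y[14] / v_bb
  if (mode == 1) {
    ps_in <- p[49]; ps_out <- p[52]; v_brain <- p[62]
    c_br <- y[15] / v_brain
    flux <- ps_in * fu_p * c_bb - ps_out * fu_b * c_br
    dy[14] <- q_brain * (c_art - c_bb) - flux
    dy[15] <- flux
    ven_in <- ven_in + q_brain * c_bb
  } else {
    ps_in <- p[49:51]; ps_out <- p[52:54]
    ps_bt_hc <- p[55]; ps_bt_fc <- p[56]
    q_bulk <- p[57:59]; q_prod <- p[60]; q_sink <- p[61]
    v_ecf <- p[62:64]; v_csf <- p[65]
    c_reg <- y[15:17] / v_ecf
    c_csf <- y[18] / v_csf
    f_reg <- ps_in * fu_p * c_bb - ps_out * fu_b * c_reg
    prod <- if (csf_carry > 0.5) q_prod * fu_p * c_bb else 0
    bt_hc <- ps_bt_hc * fu_b * (c_reg[2] - c_reg[1])
    bt_fc <- ps_bt_fc * fu_b * (c_reg[3] - c_reg[1])
    blk <- q_bulk * fu_b * c_reg
    sink <- q_sink * fu_csf * c_csf
    dy[14] <- q_brain * (c_art - c_bb) - sum(f_reg) - prod
    dy[15] <- f_reg[1] + bt_hc + bt_fc - blk[1]
    dy[16] <- f_reg[2] - bt_hc - blk[2]
    dy[17] <- f_reg[3] - bt_fc - blk[3]
    dy[18] <- sum(blk) + prod - sink
    ven_in <- ven_in + q_brain * c_bb + sink
  }
  dy[2] <- ven_in - q_co * c_ven
  dy[i_dep] <- -abs_flux
  dy[i_eli] <- cl_h * c_out[i_liv] + cl_r * c_out[i_kid] +
    (1 - f_abs) * abs_flux
  if (any(!is.finite(dy)))
    stop(sprintf("non-finite derivative in compartment(s): %s",
                 paste(names(compartment_index(spec))[!is.finite(dy)],
                       collapse = ", ")), call. = FALSE)
  dy
}
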