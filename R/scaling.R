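# In vitro - in vivo extrapolation arithmetic: well-stirred hepatic
# clearance, microsomal/hepatocyte intrinsic-clearance scale-up, GFR-corrected
# renal clearance, and Papp -> permeability-surface-area (PS) scaling.

#' Well-stirred liver hepatic clearance
#'
#' \deqn{CL_H = \frac{fu_p \, CL_{int,invivo} \, Q_L}{Q_L + fu_p \,
#'   CL_{int,invivo} / R_b}}
#'
#' The blood-to-plasma conversion enters once, as the `/Rb` divisor in the
#' denominator; the resulting clearance saturates at \eqn{Q_L R_b} as the
#' unbound intrinsic clearance grows.
#'
#' @param fu_plasma Fraction unbound in plasma, in (0, 1].
#' @param clint_invivo Whole-liver intrinsic clearance, mL/min.
#' @param q_liver Hepatic blood flow, mL/min.
#' @param rb Blood-to-plasma concentration ratio.
#' @return Hepatic clearance CL_H in mL/min.
#' @export
hepatic_clearance <- function(fu_plasma, clint_invivo, q_liver, rb) {
  if (q_liver <= 0) stop("q_liver must be > 0", call. = FALSE)
  stopifnot(fu_plasma > 0, fu_plasma <= 1, clint_invivo >= 0, rb > 0)
  num <- fu_plasma * clint_invivo * q_liver
  num / (q_liver + fu_plasma * clint_invivo / rb)
}

#' Scale in vitro intrinsic clearance to the whole liver
#'
#' Microsomal data scale through the microsomal protein content (mg
#' protein/g liver), hepatocyte data through the hepatocellularity
#' (cells/g liver); both then multiply by liver mass (liver weight per kg
#' body weight times body weight).
#'
#' @param clint_invitro In vitro intrinsic clearance, in uL/min/mg protein
#'   (microsomes) or uL/min/1e6 cells (hepatocytes). May be zero.
#' @param system `"microsomes"` or `"hepatocytes"`.
#' @param physiology A `species_physiology`.
#' @return Whole-liver in vivo intrinsic clearance, mL/min.
#' @export
scale_clint <- function(clint_invitro, system = c("microsomes",
                                                  "hepatocytes"),
                        physiology) {
  system <- match.arg(system)
  stopifnot(clint_invitro >= 0)
  liver_g <- physiology$liver_weight_per_kg * physiology$body_weight
  per_g <- switch(system,
    microsomes = clint_invitro * physiology$microsomal_protein,
    hepatocytes = clint_invitro * physiology$hepatocellularity / 1e6)
  per_g * liver_g / 1000           # uL/min -> mL/min
}

#' Renal clearance by GFR correction
#'
#' Cross-species scaling multiplies a source-species renal clearance by the
#' ratio of glomerular filtration rates; a fraction-of-filtration
#' specification returns `fraction * fu_plasma * GFR`. Compounds whose renal
#' route is excluded (kind `"none"`) return 0.
#'
#' @param compound A `compound_profile` (its `renal` block selects the rule).
#' @param physiology Target-species `species_physiology`.
#' @param source_clr Optional direct source-species CL_R (mL/min) overriding
#'   the compound's own renal block.
#' @param source_gfr Source-species GFR (mL/min), required with `source_clr`.
#' @return Renal clearance CL_R in mL/min.
#' @export
renal_clearance <- function(compound, physiology, source_clr = NULL,
                            source_gfr = NULL) {
  if (!is.null(source_clr)) {
    if (is.null(source_gfr) || source_gfr <= 0)
      stop("source_gfr must accompany source_clr", call. = FALSE)
    return(source_clr * physiology$gfr / source_gfr)
  }
  ren <- compound$renal
  switch(ren$kind,
    none = 0,
    observed_clr = ren$value,
    gfr_fraction = ren$value * compound$fu_plasma * physiology$gfr,
    cross_species = ren$value * physiology$gfr / ren$gfr_source,
    stop("renal specification missing", call. = FALSE))
}

#' Scale apparent permeability to a permeability-surface-area product
#'
#' \deqn{PS = P_{app} \times W \times SA \times CF}
#'
#' where `W` is the brain (or regional tissue) weight in grams at unit
#' density, `SA` the microvascular endothelial surface area per gram of
#' brain, and `CF` the in vitro-in vivo correction factor (a relative
#' expression factor REF occupies the same slot for transporter substrates).
#'
#' @param papp Apparent permeability, cm/min (>= 0).
#' @param region_weight Brain or regional tissue weight, g.
#' @param surface_area Endothelial surface area, cm^2/g brain.
#' @param cf Correction factor (or REF), > 0.
#' @return PS in mL/min.
#' @export
scale_ps <- function(papp, region_weight, surface_area, cf = 1) {
  stopifnot(papp >= 0, region_weight > 0, surface_area > 0, cf > 0)
  papp * region_weight * surface_area * cf
}

#' Directional PS pair for one brain region
#'
#' The blood-to-brain PS comes from Papp(A->B). When Papp(B->A) was measured
#' it drives the brain-to-blood PS; otherwise the PS is taken as
#' bidirectional. For efflux substrates the brain-to-blood PS is multiplied
#' by the efflux ratio.
#'
#' @param compound A `compound_profile`.
#' @param region_weight Regional tissue weight in g (volume at density 1).
#' @param physiology A `species_physiology` (supplies the surface area).
#' @return Named list `ps_in`, `ps_out` (mL/min).
#' @export
directional_ps <- function(compound, region_weight, physiology) {
  cf <- compound$ref %||% compound$cf
  ps_in <- scale_ps(compound$papp_ab, region_weight,
                    physiology$bbb_surface_area, cf)
  ps_out <- if (!is.null(compound$papp_ba))
    scale_ps(compound$papp_ba, region_weight, physiology$bbb_surface_area, cf)
  else ps_in
  if (compound$efflux_ratio < 1)
    stop("efflux_ratio must be >= 1", call. = FALSE)
  ps_out <- ps_out * compound$efflux_ratio
  list(ps_in = ps_in, ps_out = ps_out)
}

#' Assemble the clearance set for a compound in a species
#'
#' Resolves the compound's clearance specification: in vitro intrinsic
#' clearances are scaled up and passed through the well-stirred liver model;
#' in vivo systemic clearances are used directly as hepatic blood clearance
#' (plasma clearance is first divided by Rb). Renal clearance follows
#' [renal_clearance()].
#'
#' @param compound A `compound_profile`.
#' @param physiology A `species_physiology`.
#' @return Object of class `clearance_set` with `cl_h`, `cl_r`,
#'   `clint_invivo` (mL/min).
#' @export
build_clearances <- function(compound, physiology) {
  q_liver <- physiology$tissues$liver$perfusion
  cl <- compound$clearance
  clint <- NA_real_
  cl_h <- switch(cl$kind,
    clint_microsomes = {
      clint <- scale_clint(cl$value, "microsomes", physiology)
      hepatic_clearance(compound$fu_plasma, clint, q_liver, compound$rb)
    },
    clint_hepatocytes = {
      clint <- scale_clint(cl$value, "hepatocytes", physiology)
      hepatic_clearance(compound$fu_plasma, clint, q_liver, compound$rb)
    },
    blood_cl = cl$value,
    plasma_cl = cl$value / compound$rb)
  if (cl_h >= q_liver * compound$rb)
    stop(sprintf(paste0("hepatic clearance %.3g exceeds the well-stirred ",
                        "bound Q_liver*Rb = %.3g mL/min"),
                 cl_h, q_liver * compound$rb), call. = FALSE)
  structure(list(cl_h = cl_h,
                 cl_r = renal_clearance(compound, physiology),
                 clint_invivo = clint),
            class = "clearance_set")
}

#' Assemble the regional permeability set for a compound
#'
#' Scales the compound's Papp to directional PS values for the three brain
#' regions (rest-of-brain, hippocampus, frontal cortex) using the regional
#' tissue weight (volume at unit density), plus the inter-regional diffusion
#' clearances coupling hippocampus and frontal cortex to the rest-of-brain
#' hub (`ps_bt_hc`, `ps_bt_fc`), and the one-compartment whole-brain pair.
#'
#' @param compound A `compound_profile`.
#' @param physiology A `species_physiology`.
#' @param geometry A `cns_geometry` (regional weights); optional for the
#'   one-compartment pair only.
#' @return Object of class `permeability_set`.
#' @export
build_permeabilities <- function(compound, physiology, geometry = NULL) {
  whole <- directional_ps(compound, physiology$brain_weight, physiology)
  out <- list(whole_in = whole$ps_in, whole_out = whole$ps_out)
  if (!is.null(geometry)) {
    w <- c(rob = geometry$v_rob, hc = geometry$v_hc, fc = geometry$v_fc)
    for (r in names(w)) {
      ps <- directional_ps(compound, w[[r]], physiology)
      out[[paste0("ps_in_", r)]] <- ps$ps_in
      out[[paste0("ps_out_", r)]] <- ps$ps_out
    }
    # inter-regional diffusion scaled by the regional weight, like the BBB
    # term; hub-and-spoke topology (HC<->ROB and FC<->ROB only)
    out$ps_bt_hc <- directional_ps(compound, geometry$v_hc,
                                   physiology)$ps_in
    out$ps_bt_fc <- directional_ps(compound, geometry$v_fc,
                                   physiology)$ps_in
  }
  structure(out, class = "permeability_set")
}

#' @export
print.clearance_set <- function(x, ...) {
  cat(sprintf("<clearance_set: CL_H %.4g, CL_R %.4g, CLint %.4g mL/min>\n",
              x$cl_h, x$cl_r, x$clint_invivo))
  invisible(x)
}

#' @export
print.permeability_set <- function(x, ...) {
  cat(sprintf("<permeability_set: whole brain PS in/out %.4g/%.4g mL/min%s>\n",
              x$whole_in, x$whole_out,
              if (!is.null(x$ps_in_rob))
                sprintf("; regional in (ROB/HC/FC) %.3g/%.3g/%.3g",
                        x$ps_in_rob, x$ps_in_hc, x$ps_in_fc) else ""))
  invisible(x)
}
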