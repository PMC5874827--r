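#' @useDynLib cnspbpk, .registration = TRUE
#' @importFrom stats approx quantile rnorm sd setNames
#' @importFrom utils read.csv write.csv
NULL

# ---- quantity helpers -------------------------------------------------------

# Fixture/config quantities are {value, units} pairs so that every number in a
# configuration file declares its dimension. `.get_q` extracts and checks one.
.get_q <- function(node, field, units = NULL, required = TRUE, positive = TRUE,
                   context = "config") {
  x <- node[[field]]
  if (is.null(x)) {
    if (!required) return(NULL)
    stop(sprintf("missing field '%s' in %s", field, context), call. = FALSE)
  }
  if (is.numeric(x)) {        # bare numbers allowed only where units are fixed
    val <- x
  } else {
    val <- x[["value"]]
    if (is.null(val) || !is.numeric(val))
      stop(sprintf("field '%s' in %s has no numeric 'value'", field, context),
           call. = FALSE)
    if (!is.null(units) && !is.null(x[["units"]]) &&
        !(x[["units"]] %in% units))
      stop(sprintf("unit mismatch for '%s' in %s: got '%s', expected one of %s",
                   field, context, x[["units"]],
                   paste(sQuote(units), collapse = ", ")), call. = FALSE)
  }
  if (positive && any(val <= 0))
    stop(sprintf("field '%s' in %s must be > 0 (got %g)", field, context, val),
         call. = FALSE)
  as.numeric(val)
}

.quant <- function(value, units) list(value = value, units = units)

#' Path of a bundled fixture file
#'
#' Resolves a short fixture name (for example `"rat"`, `"phenytoin"`,
#' `"phenytoin_rat_ip"`) to the YAML file shipped with the package, or passes
#' an existing file path through unchanged.
#'
#' @param name Fixture name or path to a YAML file.
#' @param kind One of `"physiology"`, `"cns"`, `"compound"`, `"regimen"`.
#' @return Path to a YAML file.
#' @export
pbpk_fixture <- function(name, kind = c("physiology", "cns", "compound",
                                        "regimen")) {
  kind <- match.arg(kind)
  if (file.exists(name)) return(name)
  rel <- switch(kind,
    physiology = file.path("extdata", paste0("physiology_", name, ".yaml")),
    cns        = file.path("extdata", paste0("cns_", name, ".yaml")),
    compound   = file.path("extdata", "compounds", paste0(name, ".yaml")),
    regimen    = file.path("extdata", "regimens", paste0(name, ".yaml")))
  path <- system.file(rel, package = "cnspbpk")
  if (!nzchar(path))
    stop(sprintf("no bundled %s fixture '%s'", kind, name), call. = FALSE)
  path
}

#' List bundled compound fixtures
#' @return Character vector of compound names.
#' @export
list_compounds <- function() {
  dir <- system.file("extdata", "compounds", package = "cnspbpk")
  sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
}

# ---- species physiology -----------------------------------------------------

.TISSUES <- c("adipose", "bone", "brain", "gut", "heart", "kidney", "liver",
              "lung", "muscle", "pancreas", "skin", "spleen")

#' Load whole-body species physiology
#'
#' Reads a structured YAML description of tissue volumes (mL), perfusions
#' (mL/min), blood pool volumes and scale-up scalars, and validates it.
#' `"rat"` and `"human"` resolve to the bundled parameter sets.
#'
#' @param source Fixture name (`"rat"`, `"human"`) or a YAML file path.
#' @return An object of class `species_physiology`.
#' @export
load_physiology <- function(source = "rat") {
  path <- pbpk_fixture(source, "physiology")
  raw <- yaml::read_yaml(path)
  ctx <- paste0("physiology '", source, "'")
  species <- raw[["species"]]
  if (is.null(species) || !species %in% c("rat", "human"))
    stop("physiology 'species' must be 'rat' or 'human'", call. = FALSE)
  tissues <- raw[["tissues"]]
  missing <- setdiff(.TISSUES, names(tissues))
  if (length(missing))
    stop(sprintf("missing tissue(s) in %s: %s", ctx,
                 paste(missing, collapse = ", ")), call. = FALSE)
  tis <- lapply(.TISSUES, function(tn) {
    node <- tissues[[tn]]
    v <- .get_q(node, "volume", units = "mL",
                context = paste0(ctx, " tissue ", tn))
    q <- .get_q(node, "perfusion", units = "mL/min", positive = FALSE,
                context = paste0(ctx, " tissue ", tn))
    if (q < 0)
      stop(sprintf("perfusion of %s must be >= 0", tn), call. = FALSE)
    list(name = tn, volume = v, perfusion = q)
  })
  names(tis) <- .TISSUES
  phys <- structure(list(
    species = species,
    tissues = tis,
    arterial_volume = .get_q(raw, "arterial_volume", "mL", context = ctx),
    venous_volume   = .get_q(raw, "venous_volume", "mL", context = ctx),
    body_weight     = .get_q(raw, "body_weight", "kg", context = ctx),
    brain_weight    = .get_q(raw, "brain_weight", "g", context = ctx),
    bbb_surface_area = .get_q(raw, "bbb_surface_area", "cm^2/g", context = ctx),
    liver_weight_per_kg = .get_q(raw, "liver_weight_per_kg", "g/kg",
                                 context = ctx),
    microsomal_protein = .get_q(raw, "microsomal_protein", "mg/g",
                                context = ctx),
    hepatocellularity = .get_q(raw, "hepatocellularity", "cells/g",
                               context = ctx),
    gfr = .get_q(raw, "gfr", "mL/min", context = ctx)
  ), class = "species_physiology")
  phys
}

# Cardiac output = total venous return under the portal-vein topology
# (gut, spleen and pancreas drain through the liver). The lung/arterial
# bridge uses this value so flow balances exactly at the lung.
cardiac_output <- function(phys) {
  q <- vapply(phys$tissues, `[[`, numeric(1), "perfusion")
  sum(q[c("adipose", "bone", "heart", "kidney", "liver", "muscle", "skin",
          "brain")])
}

#' @export
print.species_physiology <- function(x, ...) {
  cat(sprintf("<species_physiology: %s, %g kg, %d tissues, CO %.3g mL/min>\n",
              x$species, x$body_weight, length(x$tissues),
              cardiac_output(x)))
  invisible(x)
}

# ---- CNS geometry -----------------------------------------------------------

.CNS_FIELDS <- c("v_bb", "v_rob", "v_rob_ecf", "v_hc", "v_hc_ecf", "v_fc",
                 "v_fc_ecf", "v_csf", "q_bulk_rob", "q_bulk_hc", "q_bulk_fc",
                 "q_csf_production", "q_csf_sink", "q_brain_blood")

#' Load regional CNS geometry
#'
#' Reads the five-compartment CNS system parameters: intracranial blood,
#' rest-of-brain, hippocampus and frontal cortex volumes with their
#' extracellular-fluid (ECF) sub-volumes, CSF volume, regional ECF-to-CSF
#' bulk flows, CSF production/absorption rates and cerebral blood flow.
#'
#' @param source Fixture name (`"rat"`, `"human"`) or a YAML file path.
#' @param species Optional species check against the file's own declaration.
#' @return An object of class `cns_geometry`.
#' @export
load_cns_geometry <- function(source = "rat", species = NULL) {
  path <- pbpk_fixture(source, "cns")
  raw <- yaml::read_yaml(path)
  ctx <- paste0("CNS geometry '", source, "'")
  if (!is.null(species)) {
    if (!species %in% c("rat", "human"))
      stop("species must be 'rat' or 'human'", call. = FALSE)
    if (!is.null(raw$species) && raw$species != species)
      stop(sprintf("%s declares species '%s', expected '%s'", ctx,
                   raw$species, species), call. = FALSE)
  }
  vals <- lapply(.CNS_FIELDS, function(f)
    .get_q(raw, f, units = c("mL", "mL/min"), context = ctx))
  names(vals) <- .CNS_FIELDS
  geo <- structure(c(vals, list(
    species = raw$species,
    ecf_fraction = .get_q(raw, "ecf_fraction", "fraction", required = FALSE)
  )), class = "cns_geometry")
  if (geo$v_rob_ecf >= geo$v_rob || geo$v_hc_ecf >= geo$v_hc ||
      geo$v_fc_ecf >= geo$v_fc)
    stop("each ECF volume must be smaller than its parent tissue volume",
         call. = FALSE)
  if (abs(geo$q_csf_sink - geo$q_csf_production) >
      1e-9 * geo$q_csf_production)
    stop("CSF absorption rate must equal CSF production rate", call. = FALSE)
  geo
}

#' @export
print.cns_geometry <- function(x, ...) {
  cat(sprintf(paste0("<cns_geometry: %s, ECF volumes ROB/HC/FC = ",
                     "%.3g/%.3g/%.3g mL, CSF %.3g mL>\n"),
              x$species %||% "?", x$v_rob_ecf, x$v_hc_ecf, x$v_fc_ecf,
              x$v_csf))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive an ECF volume from a tissue volume
#'
#' Product of a tissue volume and the fractional interstitial-space volume
#' (0.188 for brain). Used only when a tabulated ECF volume is absent; table
#' values always take precedence in the bundled fixtures.
#'
#' @param tissue_volume Tissue volume (mL), > 0.
#' @param ecf_fraction Fractional ECF volume, in (0, 1).
#' @return ECF volume in mL.
#' @export
derive_ecf_volume <- function(tissue_volume, ecf_fraction) {
  stopifnot(is.numeric(tissue_volume), is.numeric(ecf_fraction))
  if (any(tissue_volume <= 0))
    stop("tissue_volume must be > 0", call. = FALSE)
  if (any(ecf_fraction <= 0) || any(ecf_fraction >= 1))
    stop("ecf_fraction must lie strictly between 0 and 1", call. = FALSE)
  tissue_volume * ecf_fraction
}

# ---- compound profile -------------------------------------------------------

.papp_to_cm_min <- function(q, ctx) {
  if (is.null(q)) return(NULL)
  val <- q[["value"]]; un <- q[["units"]] %||% "cm/min"
  if (is.null(val)) val <- q
  val <- as.numeric(val)
  if (val < 0) stop(sprintf("Papp must be >= 0 in %s", ctx), call. = FALSE)
  switch(un,
    "cm/min" = val,
    "cm/s" = val * 60,
    "1e-6 cm/s" = val * 1e-6 * 60,
    stop(sprintf("unit mismatch for Papp in %s: '%s'", ctx, un),
         call. = FALSE))
}

#' Load a compound profile
#'
#' Reads the compound-dependent inputs: molecular weight, the
#' fraction-unbound triplet (plasma, brain ECF, CSF), blood-to-plasma ratio,
#' clearance specification (in vitro intrinsic clearance for microsomes or
#' hepatocytes, or an in vivo systemic clearance), renal specification,
#' in vitro apparent permeability (converted internally to cm/min), efflux
#' ratio, the in vitro-in vivo permeability correction factor CF (or a
#' relative expression factor REF for transporter substrates, which occupies
#' the same slot in the scaling arithmetic), and a tissue partition
#' coefficient (Kp) map.
#'
#' @param source Compound fixture name or a YAML file path.
#' @return An object of class `compound_profile`.
#' @export
load_compound <- function(source) {
  path <- pbpk_fixture(source, "compound")
  raw <- yaml::read_yaml(path)
  ctx <- paste0("compound '", source, "'")
  name <- raw$name %||% source

  frac <- function(f) {
    v <- .get_q(raw, f, "fraction", context = ctx)
    if (v > 1) stop(sprintf("%s must be in (0, 1] in %s", f, ctx),
                    call. = FALSE)
    v
  }
  cl <- raw$clearance
  if (is.null(cl$kind) ||
      !cl$kind %in% c("clint_microsomes", "clint_hepatocytes", "blood_cl",
                      "plasma_cl"))
    stop(sprintf("unknown clearance kind in %s", ctx), call. = FALSE)
  ren <- raw$renal %||% list(kind = "none")
  if (!ren$kind %in% c("none", "observed_clr", "gfr_fraction",
                       "cross_species"))
    stop(sprintf("unknown renal kind in %s", ctx), call. = FALSE)

  papp_ab <- .papp_to_cm_min(raw$papp_ab, ctx)
  if (is.null(papp_ab)) stop(sprintf("papp_ab missing in %s", ctx),
                             call. = FALSE)
  papp_ba <- .papp_to_cm_min(raw$papp_ba, ctx)
  er <- .get_q(raw, "efflux_ratio", "ratio", required = FALSE) %||% 1
  if (er < 1) stop("efflux_ratio must be >= 1", call. = FALSE)

  kp <- raw$kp_tissues
  if (is.null(kp)) stop(sprintf("kp_tissues missing in %s", ctx),
                        call. = FALSE)
  kp <- vapply(kp, as.numeric, numeric(1))
  if (any(kp <= 0)) stop("tissue Kp values must be > 0", call. = FALSE)

  structure(list(
    name = name,
    mw = .get_q(raw, "mw", "g/mol", context = ctx),
    fu_plasma = frac("fu_plasma"),
    fu_brain = frac("fu_brain"),
    fu_csf = frac("fu_csf"),
    rb = .get_q(raw, "rb", "ratio", context = ctx),
    clearance = list(kind = cl$kind,
                     value = .get_q(cl, "value",
                                    units = c("uL/min/mg", "uL/min/1e6cells",
                                              "mL/min"),
                                    positive = FALSE, context = ctx)),
    renal = list(kind = ren$kind,
                 value = if (ren$kind == "none") NULL else
                   .get_q(ren, "value", units = c("mL/min", "ratio"),
                          positive = FALSE, context = ctx),
                 gfr_source = if (ren$kind == "cross_species")
                   .get_q(ren, "gfr_source", "mL/min", context = ctx)
                 else NULL),
    papp_ab = papp_ab,
    papp_ba = papp_ba,
    papp_symmetric = is.null(papp_ba),
    efflux_ratio = er,
    cf = .get_q(raw, "cf", "ratio", required = FALSE) %||% 1,
    ref = .get_q(raw, "ref", "ratio", required = FALSE),
    kp_tissues = kp,
    observed_kpuu = .get_q(raw, "observed_kpuu", "ratio", required = FALSE)
  ), class = "compound_profile")
}

#' @export
print.compound_profile <- function(x, ...) {
  cat(sprintf(paste0("<compound_profile: %s, MW %.5g, fu(p/b/csf) = ",
                     "%.3g/%.3g/%.3g, Rb %.3g, Papp_AB %.3g cm/min%s>\n"),
              x$name, x$mw, x$fu_plasma, x$fu_brain, x$fu_csf, x$rb,
              x$papp_ab,
              if (x$papp_symmetric) " (bidirectional)" else ""))
  invisible(x)
}

# ---- dose regimen -----------------------------------------------------------

#' Load a dose regimen
#'
#' @param source Regimen fixture name or a YAML file path.
#' @return An object of class `dose_regimen` with fields `route`
#'   (`iv_bolus`, `iv_infusion` or `ip`), `amount`, `amount_units`
#'   (`mg` absolute or `mg/kg` weight-based), and route-specific fields
#'   `infusion_duration` (min), `ka` (1/min) and `f_abs`.
#' @export
load_regimen <- function(source) {
  path <- pbpk_fixture(source, "regimen")
  raw <- yaml::read_yaml(path)
  ctx <- paste0("regimen '", source, "'")
  route <- raw$route
  if (is.null(route) || !route %in% c("iv_bolus", "iv_infusion", "ip"))
    stop(sprintf("route must be iv_bolus, iv_infusion or ip in %s", ctx),
         call. = FALSE)
  amt <- raw$amount
  amount <- .get_q(raw, "amount", c("mg", "mg/kg"), context = ctx)
  units <- if (is.list(amt)) amt$units %||% "mg" else "mg"
  reg <- structure(list(
    route = route, amount = amount, amount_units = units,
    infusion_duration = if (route == "iv_infusion")
      .get_q(raw, "infusion_duration", "min", context = ctx) else NULL,
    ka = if (route == "ip") .get_q(raw, "ka", "1/min", context = ctx)
         else NULL,
    f_abs = if (route == "ip")
      .get_q(raw, "f_abs", "fraction", required = FALSE) %||% 1 else NULL
  ), class = "dose_regimen")
  reg
}

#' Construct a dose regimen in code
#'
#' @param route `"iv_bolus"`, `"iv_infusion"` or `"ip"`.
#' @param amount Dose amount.
#' @param amount_units `"mg"` (absolute) or `"mg/kg"` (resolved against
#'   body weight).
#' @param infusion_duration Infusion duration in minutes (infusion only).
#' @param ka First-order absorption rate constant, 1/min (ip only).
#' @param f_abs Fraction absorbed (ip only).
#' @return A `dose_regimen`.
#' @export
dose_regimen <- function(route = c("iv_bolus", "iv_infusion", "ip"),
                         amount, amount_units = "mg",
                         infusion_duration = NULL, ka = NULL, f_abs = 1) {
  route <- match.arg(route)
  stopifnot(amount > 0, amount_units %in% c("mg", "mg/kg"))
  if (route == "iv_infusion") {
    if (is.null(infusion_duration) || infusion_duration <= 0)
      stop("infusion_duration must be > 0 for infusions", call. = FALSE)
  }
  if (route == "ip") {
    if (is.null(ka) || ka <= 0) stop("ka must be > 0 for ip dosing",
                                     call. = FALSE)
    stopifnot(f_abs > 0, f_abs <= 1)
  }
  structure(list(route = route, amount = amount, amount_units = amount_units,
                 infusion_duration = infusion_duration, ka = ka,
                 f_abs = if (route == "ip") f_abs else NULL),
            class = "dose_regimen")
}

# Resolve a (possibly weight-based) dose against a physiology, in mg.
resolve_dose <- function(regimen, physiology) {
  if (regimen$amount_units == "mg/kg")
    regimen$amount * physiology$body_weight
  else regimen$amount
}

# ---- round-trip serialization ----------------------------------------------

#' Serialize a loaded parameter object back to YAML
#'
#' Writes the same `{value, units}` configuration dialect the loaders read,
#' so that any fixture round-trips to identical parameter values.
#'
#' @param x A `species_physiology`, `cns_geometry` or `dose_regimen`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(x, path) UseMethod("write_config")

#' @export
write_config.species_physiology <- function(x, path) {
  out <- list(
    species = x$species,
    body_weight = .quant(x$body_weight, "kg"),
    brain_weight = .quant(x$brain_weight, "g"),
    bbb_surface_area = .quant(x$bbb_surface_area, "cm^2/g"),
    liver_weight_per_kg = .quant(x$liver_weight_per_kg, "g/kg"),
    microsomal_protein = .quant(x$microsomal_protein, "mg/g"),
    hepatocellularity = .quant(x$hepatocellularity, "cells/g"),
    gfr = .quant(x$gfr, "mL/min"),
    arterial_volume = .quant(x$arterial_volume, "mL"),
    venous_volume = .quant(x$venous_volume, "mL"),
    tissues = lapply(x$tissues, function(t)
      list(volume = .quant(t$volume, "mL"),
           perfusion = .quant(t$perfusion, "mL/min"))))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @export
write_config.cns_geometry <- function(x, path) {
  out <- c(list(species = x$species),
           lapply(setNames(.CNS_FIELDS, .CNS_FIELDS), function(f)
             .quant(x[[f]], if (startsWith(f, "v_")) "mL" else "mL/min")))
  if (!is.null(x$ecf_fraction))
    out$ecf_fraction <- .quant(x$ecf_fraction, "fraction")
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @export
write_config.dose_regimen <- function(x, path) {
  out <- list(route = x$route, amount = .quant(x$amount, x$amount_units))
  if (!is.null(x$infusion_duration))
    out$infusion_duration <- .quant(x$infusion_duration, "min")
  if (!is.null(x$ka)) out$ka <- .quant(x$ka, "1/min")
  if (!is.null(x$f_abs)) out$f_abs <- .quant(x$f_abs, "fraction")
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
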