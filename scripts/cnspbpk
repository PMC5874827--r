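#!/usr/bin/env Rscript
# Thin command-line wrapper over the cnspbpk package.
#
#   Rscript scripts/cnspbpk <simulate|scale|report|mc|sweep|panel|case> [options]
#
# All tabular output is CSV; every run writes a JSON manifest next to its
# outputs. Exit codes: 0 success, 2 validation error, 3 solver failure.

suppressPackageStartupMessages({
  library(optparse)
  library(cnspbpk)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  cat("usage: cnspbpk <simulate|scale|report|mc|sweep|panel|case> [options]\n")
  quit(status = 2)
}
cmd <- args[1]
rest <- args[-1]

common <- list(
  make_option("--species", default = "rat"),
  make_option("--compound", default = "phenytoin"),
  make_option("--regimen", default = "phenytoin_rat_ip"),
  make_option("--duration", type = "double", default = 480),
  make_option("--dt-out", dest = "dt_out", type = "double", default = 1),
  make_option("--cns", default = "regional"),
  make_option("--units", default = "umol/L"),
  make_option("--seed", type = "integer", default = 20180114L),
  make_option("--out-dir", dest = "out_dir", default = "."),
  make_option("--cv", type = "double", default = 0.30),
  make_option("--n", type = "integer", default = 1000L),
  make_option("--percentiles", default = "5,95"),
  make_option("--pair", default = "hc"),
  make_option("--grid", type = "integer", default = 25L),
  make_option("--scenario", default = "nominal"),
  make_option("--case", default = "phenytoin_rat"))
opt <- parse_args(OptionParser(option_list = common), args = rest)
dir.create(opt$out_dir, recursive = TRUE, showWarnings = FALSE)
outfile <- function(name) file.path(opt$out_dir, name)

build_spec <- function() {
  model_spec(load_physiology(opt$species), load_compound(opt$compound),
             cns = opt$cns, geometry = load_cns_geometry(opt$species))
}

manifest <- function(outputs) {
  write_manifest(cmd, opt[setdiff(names(opt), "help")], opt$seed, outputs,
                 outfile(paste0(cmd, "_manifest.json")))
}

status <- tryCatch({
  switch(cmd,
    simulate = {
      res <- simulate_pbpk(build_spec(), load_regimen(opt$regimen),
                           opt$duration, dt_out = opt$dt_out)
      df <- as.data.frame(res)
      names(df)[-1] <- paste0(names(df)[-1], "_mg_per_L")
      f <- outfile("simulation.csv")
      write.csv(df, f, row.names = FALSE)
      manifest(f)
    },
    scale = {
      phys <- load_physiology(opt$species)
      cmp <- load_compound(opt$compound)
      geo <- load_cns_geometry(opt$species)
      cls <- build_clearances(cmp, phys)
      per <- build_permeabilities(cmp, phys, geo)
      df <- data.frame(quantity = c("cl_h", "cl_r", "clint_invivo",
                                    names(unclass(per))),
                       ml_per_min = c(cls$cl_h, cls$cl_r, cls$clint_invivo,
                                      unlist(unclass(per))))
      f <- outfile("scaling.csv")
      write.csv(df, f, row.names = FALSE)
      print(df)
      manifest(f)
    },
    report = {
      res <- simulate_pbpk(build_spec(), load_regimen(opt$regimen),
                           opt$duration, dt_out = opt$dt_out)
      s <- pk_summary(res, units = opt$units)
      f <- outfile("pk_summary.csv")
      write.csv(s, f, row.names = FALSE)
      print(s)
      manifest(f)
    },
    mc = {
      pct <- as.numeric(strsplit(opt$percentiles, ",")[[1]])
      bands <- run_mc(build_spec(), load_regimen(opt$regimen), opt$duration,
                      mc_config(cv = opt$cv, n = opt$n, seed = opt$seed,
                                percentiles = pct, dt_out = opt$dt_out))
      band_df <- data.frame(time_min = bands$times)
      for (tg in names(bands$bands))
        for (r in rownames(bands$bands[[tg]]))
          band_df[[paste0(tg, "_", r)]] <- bands$bands[[tg]][r, ]
      f1 <- outfile("mc_bands.csv")
      write.csv(band_df, f1, row.names = FALSE)
      f2 <- outfile("mc_summary.json")
      jsonlite::write_json(summarize_mc(bands), f2, auto_unbox = TRUE,
                           digits = NA)
      manifest(c(f1, f2))
    },
    sweep = {
      mesh <- ps_sweep(build_spec(), load_regimen(opt$regimen),
                       opt$duration,
                       sweep_spec(opt$pair, grid = opt$grid,
                                  scenario = opt$scenario),
                       dt_out = opt$dt_out, units = opt$units)
      f <- outfile("sweep.csv")
      mesh_export(mesh, f)
      print(mesh)
      manifest(f)
    },
    panel = {
      panel <- run_step1_panel()
      f <- outfile("step1_panel.csv")
      write.csv(panel, f, row.names = FALSE)
      print(panel)
      manifest(f)
    },
    case = {
      cr <- run_case(opt$case, mc = mc_config(n = opt$n, seed = opt$seed,
                                              dt_out = opt$dt_out))
      f1 <- outfile("case_summary.csv")
      write.csv(cr$summary, f1, row.names = FALSE)
      f2 <- outfile("case_validation.csv")
      write.csv(cr$validation, f2, row.names = FALSE)
      f3 <- outfile("case_mc_summary.csv")
      write.csv(cr$mc_summary, f3, row.names = FALSE)
      print(cr)
      manifest(c(f1, f2, f3))
    },
    {
      cat("unknown subcommand:", cmd, "\n")
      quit(status = 2)
    })
  0L
}, error = function(e) {
  msg <- conditionMessage(e)
  cat("error:", msg, "\n")
  if (grepl("solver", msg)) 3L else 2L
})
quit(status = status)
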