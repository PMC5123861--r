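#!/usr/bin/env Rscript

# Fit the simulated calorimetric titration with the single-site isotherm
# (perfusion-corrected) and decompose the affinity into dG, dH and -TdS.

suppressPackageStartupMessages(library(c2membrane))

out <- "results/itc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

heats <- read_table("results/data/itc_heats.csv",
                    c(injection = "integer", molar_ratio = "numeric",
                      heat_kJ = "numeric"))
prot <- titration_protocol(1.4e-3, 50e-6, 1e-3, rep(10e-6, 25))
fit <- fit_isotherm(heats$heat_kJ, prot)

write_table(data.frame(
  quantity = c("n_sites", "K_d_M", "dH_kJ", "dG_kJ", "minus_TdS_kJ",
               "c_value"),
  estimate = c(fit$n, fit$K_d, fit$dH, fit$dG, fit$minus_TdS, fit$c_value),
  se = c(fit$se[["n"]], fit$se[["K_d"]], fit$se[["dH"]], NA, NA, NA)),
  file.path(out, "isotherm_fit.csv"))

cat(sprintf("n = %.3f, K_d = %.3g M (%.1f uM), dH = %.1f kJ/mol, c = %.0f\n",
            fit$n, fit$K_d, fit$K_d * 1e6, fit$dH, fit$c_value))
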