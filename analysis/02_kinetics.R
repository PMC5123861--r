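#!/usr/bin/env Rscript

# Fit the simulated stopped-flow traces: one single-exponential fit per
# vesicle concentration, then the pseudo-first-order rate law
# k_obs = k_on [vesicle] + k_off, giving k_on, k_off and K_d = k_off/k_on.

suppressPackageStartupMessages(library(c2membrane))

out <- "results/kinetics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

flat <- read_table("results/data/stopped_flow_traces.csv",
                   c(trace = "integer", lipid_M = "numeric",
                     vesicle_M = "numeric", t_s = "numeric", F = "numeric"))

fits <- lapply(split(flat, flat$trace), function(d)
  fit_monoexponential(kinetic_trace(d$t_s, d$F)))
v <- vapply(split(flat$vesicle_M, flat$trace), `[`, 1.0, 1)
kobs <- data.frame(vesicle_M = v,
                   k_obs = vapply(fits, `[[`, 1.0, "k_obs"),
                   k_obs_se = vapply(fits, function(f) f$se[["k_obs"]], 1.0))
write_table(kobs, file.path(out, "k_obs.csv"))

rl <- fit_rate_law(kinetic_series(kobs$vesicle_M, kobs$k_obs, kobs$k_obs_se))
write_table(data.frame(
  quantity = c("k_on_Mns", "k_off_s", "K_d_M"),
  estimate = c(rl$k_on, rl$k_off, rl$K_d),
  se = c(rl$se[["k_on"]], rl$se[["k_off"]], rl$se[["K_d"]])),
  file.path(out, "rate_constants.csv"))

cat(sprintf("k_on = %.3g /M/s, k_off = %.3g /s, K_d = %.3g M\n",
            rl$k_on, rl$k_off, rl$K_d))
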