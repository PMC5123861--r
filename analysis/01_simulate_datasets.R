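#!/usr/bin/env Rscript

# Simulate every synthetic dataset used by the downstream analysis scripts
# and write them as plain CSV under results/data/. All ground-truth
# parameters are recorded alongside so the fits can be checked.

suppressPackageStartupMessages(library(c2membrane))

SEED <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## --- stopped-flow traces over a vesicle titration --------------------------
comp <- lipid_composition(c(PtdChol = 0.88, PtdSer = 0.10, PtdInsP2 = 0.02))
lipid <- seq(30e-6, 270e-6, length.out = 6)
v <- vesicle_concentration(lipid, comp)
truth_kin <- list(k_on = 1e11, k_off = 20)
traces <- simulate_stopped_flow(truth_kin$k_on, truth_kin$k_off, v,
                                noise = noise_model(0.005, SEED + 10))
flat <- do.call(rbind, lapply(seq_along(traces), function(i) {
  tr <- traces[[i]]
  data.frame(trace = i, lipid_M = lipid[i], vesicle_M = v[i],
             t_s = tr$t, F = tr$F)
}))
write_table(flat, file.path(out, "stopped_flow_traces.csv"))

## --- ITC titration ----------------------------------------------------------
prot <- titration_protocol(1.4e-3, 50e-6, 1e-3, rep(10e-6, 25))
truth_itc <- list(n = 1, K_d = 14e-6, dH = -30)
sigma <- 0.02 * max(abs(predict_heats(truth_itc$n, truth_itc$K_d,
                                      truth_itc$dH, prot)$q))
itc <- simulate_itc(truth_itc$n, truth_itc$K_d, truth_itc$dH, prot,
                    noise_model(sigma, SEED + 20))
write_table(data.frame(injection = seq_along(itc$q),
                       molar_ratio = itc$molar_ratio, heat_kJ = itc$q),
            file.path(out, "itc_heats.csv"))

## --- sedimentation partitioning ---------------------------------------------
truth_K <- 2.2e4
L <- 10^seq(-6, -2.5, length.out = 12)
sed <- simulate_sedimentation(truth_K, L, noise_model(0.02, SEED + 30))
write_table(data.frame(lipid_total_M = sed$L / comp$accessible_fraction,
                       f_b = sed$f_b),
            file.path(out, "sedimentation.csv"))

## --- EPR power-saturation curves ---------------------------------------------
truth_ph <- c(N2 = 2, O2 = 12, NiEDDA = 5)
curves <- simulate_power_saturation(truth_ph,
                                    noise = noise_model(0.004, SEED + 40))
sat <- do.call(rbind, lapply(names(curves), function(cond)
  data.frame(condition = cond, power_mW = curves[[cond]]$P,
             amplitude = curves[[cond]]$A)))
write_table(sat, file.path(out, "power_saturation.csv"))

## --- HSQC peak lists ---------------------------------------------------------
base <- data.frame(residue = 300:340,
                   dH_ppm = 8 + 0.4 * sin(300:340),
                   dN_ppm = 118 + 4 * cos(300:340))
planted <- list("325" = c(0.12, 0.8), "326" = c(0.15, 1.0),
                "327" = c(0.13, 0.9))
hsqc <- simulate_hsqc_shifts(base, planted, noise_model(0.002, SEED + 50))
write_table(hsqc$reference, file.path(out, "hsqc_reference.csv"))
write_table(hsqc$titrated, file.path(out, "hsqc_titrated.csv"))

## --- ground truth ledger ------------------------------------------------------
truth <- data.frame(
  quantity = c("k_on_Mns", "k_off_s", "itc_n", "itc_Kd_M", "itc_dH_kJ",
               "partition_K_Mn", "P_half_N2_mW", "P_half_O2_mW",
               "P_half_NiEDDA_mW"),
  value = c(truth_kin$k_on, truth_kin$k_off, truth_itc$n, truth_itc$K_d,
            truth_itc$dH, truth_K, truth_ph[["N2"]], truth_ph[["O2"]],
            truth_ph[["NiEDDA"]]))
write_table(truth, file.path(out, "ground_truth.csv"))
cat("simulated datasets written to", out, "\n")
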