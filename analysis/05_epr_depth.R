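#!/usr/bin/env Rscript

# EPR depth analysis: fit the simulated power-saturation curves for the
# three relaxant conditions, form the depth parameter
# Phi = ln(dP_half_O2 / dP_half_NiEDDA), calibrate Phi against depth with
# the measured (Phi, depth) pairs, and report leave-one-out errors of the
# calibration.

suppressPackageStartupMessages(library(c2membrane))

out <- "results/epr"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sat <- read_table("results/data/power_saturation.csv",
                  c(condition = "character", power_mW = "numeric",
                    amplitude = "numeric"))
fits <- lapply(split(sat, sat$condition), function(d)
  fit_saturation(saturation_curve(d$power_mW, d$amplitude, d$condition[1])))
ph <- vapply(fits, `[[`, 1.0, "P_half")
write_table(data.frame(condition = names(ph), P_half_mW = unname(ph),
                       eps = vapply(fits, `[[`, 1.0, "eps")),
            file.path(out, "saturation_fits.csv"))

dp <- depth_parameter(ph[["O2"]], ph[["NiEDDA"]], ph[["N2"]])

## calibration on the measured pairs + leave-one-out cross-validation
tab <- spin_label_depths()
cal <- fit_calibration(data.frame(phi = tab$phi, distance_A = tab$distance_A))
loo <- vapply(seq_len(nrow(tab)), function(i) {
  c_i <- fit_calibration(data.frame(phi = tab$phi[-i],
                                    distance_A = tab$distance_A[-i]))
  depth_from_phi(tab$phi[i], c_i)$x
}, 1.0)
write_table(cbind(tab, loo_pred_A = loo, loo_err_A = loo - tab$distance_A),
            file.path(out, "calibration_loo.csv"))

x <- depth_from_phi(dp$phi, cal)
write_table(data.frame(quantity = c("phi", "depth_A"),
                       value = c(dp$phi, x$x)),
            file.path(out, "simulated_site_depth.csv"))

cat(sprintf("Phi = %.3f -> depth %.2f A; median |LOO error| = %.2f A\n",
            dp$phi, x$x, median(abs(loo - tab$distance_A))))
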