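#!/usr/bin/env Rscript

# Chemical-shift perturbation mapping: compare the reference and titrated
# HSQC peak lists, compute the weighted CSP per residue, and rank residues
# above the mean + 1 SD threshold.

suppressPackageStartupMessages(library(c2membrane))

out <- "results/csp"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sch <- c(residue = "integer", dH_ppm = "numeric", dN_ppm = "numeric")
ref <- read_table("results/data/hsqc_reference.csv", sch)
tit <- read_table("results/data/hsqc_titrated.csv", sch)

prof <- csp_profile(ref, tit)
write_table(prof[c("residue", "dH", "dN", "csp")],
            file.path(out, "csp_profile.csv"))

top <- rank_perturbed(prof)
write_table(top[c("residue", "csp")], file.path(out, "perturbed_residues.csv"))

cat(sprintf("threshold %.4f ppm; perturbed residues: %s\n",
            attr(top, "cutoff"), paste(top$residue, collapse = ", ")))
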