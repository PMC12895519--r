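#!/usr/bin/env Rscript
# Channel flow arithmetic: wall shear rates and interfacial residence
# times across the experimental velocity range, plus the single-cell
# sensitivity implied by the population-scale coefficient.

suppressPackageStartupMessages(library(napltaxis))
dir.create("results", showWarnings = FALSE)

velocities <- c(0.5, 1, 5, 10)
tab <- data.frame(
  velocity_m_d = velocities,
  velocity_umps = convert_velocity(velocities),
  shear_rate_s = wall_shear_rate(velocities, depth = 20),
  residence_s = vapply(velocities, function(v)
    interfacial_residence_time(50, v)$seconds, numeric(1)),
  residence_display_s = vapply(velocities, function(v)
    interfacial_residence_time(50, v)$display, numeric(1))
)
write.table(format(tab, digits = 4), "results/01_geometry_flow.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
print(tab, digits = 4)

s <- sigma_star_from_chi(7.2e-5, v = 44)
cat(sprintf(
  "\nsigma* = chi_o / v^2 = %.3f s (displayed as %d s) for chi_o = 7.2e-5 cm^2/s, v = 44 um/s\n",
  s$seconds, s$display))
cat("Shear rates 0.58-11.57 1/s span the transition from chemotaxis-dominated\n")
cat("to convection-dominated transport; residence over the 50-um interface\n")
cat("drops below a single mean run time (2 s) above ~1 m/d.\n")
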