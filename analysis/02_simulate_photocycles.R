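#!/usr/bin/env Rscript
# Contrast the photocyclic and monostable kinetic schemes after a yellow
# flash: both lose the signalling-active meta II pool at the same rate, but
# only the photocyclic scheme refills the dark state.
#
# Writes: results/photocycle_contrast.csv (population time courses)

suppressPackageStartupMessages(library(photocycler))
dir.create("results", showWarnings = FALSE)

k <- 1 / 57.4  # thermal decay of meta II at 37 C in the photocyclic mutant
yellow <- list(branching = c("dark->metaII" = 1))

cyclic <- photocycle_model(c("dark", "metaII", "metaIII"),
                           c("metaII->dark" = k),
                           bands = list(yellow = yellow))
mono <- photocycle_model(c("dark", "metaII", "metaIII"),
                         c("metaII->metaIII" = k),
                         bands = list(yellow = yellow))

t_grid <- c(0.1, 1, 5, 10, 25, 57.4, 100, 200, 400, 600)
flash <- list(flash_event("yellow", 1))
sim_c <- simulate_photocycle(cyclic, flash, c(dark = 1), t_grid)
sim_m <- simulate_photocycle(mono, flash, c(dark = 1), t_grid)

out <- rbind(cbind(scheme = "photocyclic", sim_c),
             cbind(scheme = "monostable", sim_m))
write.csv(out, "results/photocycle_contrast.csv", row.names = FALSE)

cat(sprintf("Active (meta II) fraction at t = 57.4 s: %.4f in both schemes\n",
            sim_c$metaII[t_grid == 57.4]))
cat(sprintf("Terminal state at t = 600 s (~10 tau):\n"))
cat(sprintf("  photocyclic: dark %.4f, meta III %.4f\n",
            sim_c$dark[10], sim_c$metaIII[10]))
cat(sprintf("  monostable:  dark %.4f, meta III %.4f\n",
            sim_m$dark[10], sim_m$metaIII[10]))
cat("The photocyclic scheme returns >99% of pigment to the dark state;\n",
    "the monostable scheme strands it in meta III.\n", sep = "")
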