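#!/usr/bin/env Rscript

# Stage 4: interlocus gene conversion. Generates a diverged paralog pair
# with a planted conversion tract, profiles windowed identity and calls
# empirical tracts (runs of > 2 consecutive windows at exactly 100%).

suppressPackageStartupMessages(library(sdpopgen))
dir.create("results", showWarnings = FALSE)

pair <- plant_igc(30000, divergence = 0.02, tract = c(10001, 20000),
                  seed = 41)
prof <- identity_profile(pair$donor, pair$acceptor)
write.table(as.data.frame(prof), "results/identity_profile.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

tracts <- detect_igc_tracts(prof)
write.table(tracts, "results/igc_tracts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("planted tract: %d-%d\n", pair$truth$start, pair$truth$end))
cat(sprintf("detected %d tract(s):\n", nrow(tracts)))
print(tracts)
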