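#!/usr/bin/env Rscript
# Step 1: generate the validation phantom suite.
#
# Renders the fixed grid of synthetic fibrous images — dispersion levels
# sigma0 in {5, 15, 30, 60} degrees plus the uniform (isotropic) model,
# crossed with mean orientations mu0 in {0, 30, 90, 120} degrees, three
# replicates each (60 images, 825 x 825 px, 300 fibers) — together with a
# manifest recording the ground truth per file. Everything downstream reads
# only these files.

library(fibralign)

out_dir <- "results/phantoms"
manifest <- make_benchmark_suite(out_dir, seed = 7)

cat(sprintf("wrote %d phantoms under %s (manifest: %s)\n",
            nrow(manifest), out_dir, file.path(out_dir, "manifest.csv")))
print(table(ifelse(is.na(manifest$sigma0_deg), "uniform",
                   manifest$sigma0_deg)))
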