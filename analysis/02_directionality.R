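#!/usr/bin/env Rscript
# Step 2: run the FFT directionality pipeline over the phantom suite and
# summarize how well the alignment statistics recover the ground truth.
#
# Outputs:
#   results/directionality.csv         one row per image (eps, mu, sigma, ...)
#   results/directionality_series.csv  per-series summaries from run_batch()
#   results/recovery_summary.csv       per-dispersion-level medians + mu error
#
# Run analysis/01_simulate_phantoms.R first.

library(fibralign)

phantom_dir <- "results/phantoms"
if (!dir.exists(phantom_dir))
  stop("phantom suite not found; run analysis/01_simulate_phantoms.R first")

manifest <- read.csv(file.path(phantom_dir, "manifest.csv"))
batch <- run_batch(phantom_dir)
stopifnot(nrow(batch$errors) == 0)

res <- merge(batch$results,
             manifest[, setdiff(names(manifest), "series")], by = "file")
res$level <- ifelse(res$model == "uniform", "uniform",
                    sprintf("%02d", res$sigma0_deg))
circ_err <- function(a, b) {
  d <- (a - b) %% 180
  pmin(d, 180 - d)
}
res$mu_err_deg <- ifelse(is.na(res$mu0_deg), NA,
                         circ_err(res$mu_deg, res$mu0_deg))

write.csv(res[order(res$file),
              c("file", "series", "model", "mu0_deg", "sigma0_deg", "seed",
                "cutoff", "eccentricity", "mu_deg", "sigma_deg",
                "mu_err_deg", "flags")],
          "results/directionality.csv", row.names = FALSE)
write.csv(batch$summary, "results/directionality_series.csv",
          row.names = FALSE)

summ <- do.call(rbind, lapply(split(res, res$level), function(d) {
  data.frame(level = d$level[1], n = nrow(d),
             eps_median = median(d$eccentricity),
             sigma_median = median(d$sigma_deg),
             mu_err_mean = mean(d$mu_err_deg),
             mu_err_max = suppressWarnings(max(d$mu_err_deg)))
}))
summ <- summ[order(summ$level == "uniform",
                   suppressWarnings(as.numeric(summ$level))), ]
write.csv(summ, "results/recovery_summary.csv", row.names = FALSE)

cat("per-dispersion-level summary (medians over 12 images each):\n")
print(summ, row.names = FALSE, digits = 3)
cat("\nfindings:\n")
cat(sprintf(" - eccentricity medians %s monotonically with dispersion\n",
            if (all(diff(summ$eps_median) < 0)) "fall" else "do NOT fall"))
cat(sprintf(" - sigma-hat medians %s monotonically with dispersion\n",
            if (all(diff(summ$sigma_median) > 0)) "rise" else "do NOT rise"))
wn <- res[!is.na(res$mu_err_deg) & res$sigma0_deg <= 30, ]
cat(sprintf(" - prevailing direction recovered to %.1f deg on average (max %.1f) for sigma0 <= 30 deg\n",
            mean(wn$mu_err_deg), max(wn$mu_err_deg)))
cat(sprintf(" - isotropic phantoms: median eps %.2f; note a 300-fiber discrete mat retains ~1/sqrt(n) sampling anisotropy, so eps stays above the near-zero value a dense isotropic texture would give\n",
            summ$eps_median[summ$level == "uniform"]))
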