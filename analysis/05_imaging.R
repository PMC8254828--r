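#!/usr/bin/env Rscript
# Imaging statistics on synthetic recordings: FRAP recovery fitting and
# mobile fractions for a slow (WT-like) and a fast (binding-deficient
# mutant-like) condition, spine morphological-index dynamics, and
# puncta-size filtering.

suppressPackageStartupMessages(library(synapscreen))
dir.create("results", showWarnings = FALSE)

# two FRAP conditions, 7 cells each: the mutant-like condition has a
# larger recovering pool (higher plateau), as for a protein less stably
# anchored at the PSD
conds <- list(WT_like = 0.45, mutant_like = 0.63)
rows <- list()
for (cond in names(conds)) {
  for (cell in 1:7) {
    gen <- gen_frap_trace(plateau = conds[[cond]], rate = 0.02,
                          noise_sd = 0.02, f0 = 0.2,
                          seed = 600 + 10 * cell + (cond == "WT_like"))
    fa <- frap_analysis(gen$trace)
    rows[[length(rows) + 1]] <- data.frame(
      condition = cond, cell = cell,
      plateau = fa$fit$plateau, rate = fa$fit$rate,
      mobile_fraction_endpoint = fa$mobile_fraction_endpoint,
      mobile_fraction_plateau = fa$mobile_fraction_plateau)
  }
}
frap <- do.call(rbind, rows)
write.table(frap, "results/frap_fits.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
means <- tapply(frap$mobile_fraction_endpoint, frap$condition, mean)
message(sprintf("mobile fraction: WT-like %.1f%%, mutant-like %.1f%% (difference %.2f points)",
                means[["WT_like"]], means[["mutant_like"]],
                means[["mutant_like"]] - means[["WT_like"]]))
tt <- t.test(mobile_fraction_endpoint ~ condition, data = frap)
message(sprintf("two-sample comparison of conditions: t = %.2f, p = %.3g",
                unname(tt$statistic), tt$p.value))

# spine morphometrics: a remodeling spine vs a circle of varying radius
set.seed(41)
r <- 0.35 + cumsum(rnorm(11, 0, 0.02))
remodeling <- data.frame(frame_min = 0:10,
                         perimeter_um = 2 * pi * r * (1 + abs(rnorm(11, 0, 0.1))),
                         area_um2 = pi * r^2)
circle <- data.frame(frame_min = 0:10, perimeter_um = 2 * pi * r,
                     area_um2 = pi * r^2)
message(sprintf("M.I. dynamics: remodeling spine %.3f, ideal circle %.3f",
                spine_dynamics(remodeling, "mi"), spine_dynamics(circle, "mi")))

# puncta filter at the 0.006 um^2 cutoff
set.seed(42)
puncta <- data.frame(area = rlnorm(60, log(0.02), 1.2),
                     compartment = sample(c("spine", "dendrite"), 60,
                                          replace = TRUE))
filt <- filter_puncta(puncta, min_area = 0.006, dendrite_length_um = 100)
message("puncta: kept ", filt$summary$n_kept, "/", filt$summary$n_input,
        "; per-10-um densities spine/dendrite: ",
        paste(round(filt$summary$density_per_10um, 2), collapse = "/"),
        "; spine:dendrite ratio ",
        round(filt$summary$spine_dendrite_ratio, 2))
write.table(filt$puncta, "results/puncta_filtered.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
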