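#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with known ground truth.
#
# Emulates one cruise worth of data: amino-acid delta15N profiles for the
# four nutritional modes, a literature-style end-member table, pigment
# mixtures drawn from the final ratio matrix, two contrasting CTD/nutrient
# casts (plume and oceanic), and a planted station feature table. All
# downstream stages read only these files.

library(sestonmix)

seed <- 7
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

prof <- gen_aa_profiles(n_per_mode = 25, aa_noise_sd = 1.0, seed = seed)
write_table(prof, file.path(out, "aa_profiles.tsv"), meta = list(seed = seed))

em <- gen_endmembers(n_per_group = 8, seed = seed + 1)
write_table(em, file.path(out, "endmembers.tsv"), meta = list(seed = seed + 1))

pig <- gen_pigment_samples(16, ratio_matrix = ratio_matrix_final(),
                           cv = 0.01, seed = seed + 2)
write_table(data.frame(sample_id = rownames(pig$pigments),
                       as.data.frame(pig$pigments, check.names = FALSE),
                       check.names = FALSE),
            file.path(out, "pigments.tsv"), meta = list(seed = seed + 2))
write_table(data.frame(sample_id = rownames(pig$pigments),
                       as.data.frame(pig$fractions, check.names = FALSE),
                       check.names = FALSE),
            file.path(out, "pigment_truth.tsv"))

plume <- gen_ctd_cast(mld = 18, sal_surface = 30, nox_surface = 0.2,
                      nitracline = 35)
oceanic <- gen_ctd_cast(mld = 75, sal_surface = 36, sal_deep = 36.6,
                        sigma_surface = 23, sigma_deep = 25,
                        nox_surface = 0.1, nox_deep = 1.5)
for (nm in c("plume", "oceanic")) {
  cast <- get(nm)
  write_table(cast$ctd, file.path(out, paste0("ctd_", nm, ".tsv")))
  write_table(cast$nutrients, file.path(out, paste0("nutrients_", nm, ".tsv")))
}

stations <- gen_station_set(n = 100, seed = seed + 3)
write_table(stations, file.path(out, "stations.tsv"),
            meta = list(seed = seed + 3))

cat("Synthetic inputs written to", out, "\n")
cat(sprintf(" - %d amino-acid profiles (4 modes x 25)\n", nrow(prof)))
cat(sprintf(" - %d end-member records, %d pigment mixtures, %d stations\n",
            nrow(em), nrow(pig$pigments), nrow(stations)))
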