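#!/usr/bin/env Rscript
# Step 1: generate the synthetic study cohorts.
#
# Two cohorts emulating the study design: (a) a multi-age wild-type cohort
# (140 animals, 0.2-26 months, three sequencing batches) used for filtering,
# batch correction, age association, entropy and clock training; (b) a
# treatment cohort whose 22-month-old treated animals age along a
# half-speed clock. Ground truth (planted age sites, slopes, effective
# ages) is kept for later comparison.

suppressPackageStartupMessages(library(methclock))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
seed <- 20260922L %% 100000L

sp <- cohort_spec(n_samples = 140, n_sites = 500, n_age_sites = 100,
                  slope_scale = 0.04, mean_depth = 20, seed = seed)
co <- simulate_cohort(sp)

nt <- 120
plan <- data.frame(
  sex = rep_len(c("male", "female"), nt), strain = "UM-HET3",
  treatment = c(rep("none", 100), rep("rapamycin", 20)),
  study = rep_len(sp$batches$batch_id, nt))
ages <- c(2 ^ seq(log2(6), log2(790), length.out = 80), rep(669, 40))
spt <- cohort_spec(n_samples = nt, n_sites = 500, n_age_sites = 100,
                   slope_scale = 0.04, mean_depth = 20,
                   treatment_rate = 0.5, seed = seed + 1L)
cot <- simulate_cohort(spt, ages = ages, metadata_plan = plan)

write_sample_meta(co$meta, "results/cohort_meta.tsv")
write_sample_meta(cot$meta, "results/treatment_meta.tsv")
utils::write.table(co$truth$site, "results/cohort_truth_sites.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(list(co = co, cot = cot, seed = seed), "scratch/cohorts.rds")

cat(sprintf("wild-type cohort: %d samples x %d sites, %d planted age sites\n",
            nrow(co$meta), ncol(co$matrix$fraction),
            sum(co$truth$site$is_age_site)))
cat(sprintf("treatment cohort: %d samples (%d treated at 22 months, rate %.2f)\n",
            nrow(cot$meta), sum(cot$meta$treatment != "none"),
            spt$treatment_rate))
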