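#!/usr/bin/env Rscript
# Step 2: site/sample filtering and imputation.
#
# Applies the strict clock profile (>=2 reads in 97% of animals, autosomes,
# 0 < sd <= 0.20, sample rule, mean imputation) to the wild-type cohort and
# the relaxed >=1-read profile to both cohorts over the full site set.

suppressPackageStartupMessages(library(methclock))
st <- readRDS("scratch/cohorts.rds")

filt <- filter_clock(st$co$matrix)
rep <- filt$report
cat(sprintf("clock profile: %d/%d sites kept (%d sd, %d coverage, %d chrom removed); %d/%d samples kept; %d cells imputed\n",
            rep$sites_out, rep$sites_in, rep$sites_removed$sd,
            rep$sites_removed$coverage, rep$sites_removed$chromosome,
            rep$samples_out, rep$samples_in, rep$n_imputed))

imp <- project_relaxed(st$co$matrix, site_ids(st$co$matrix))
impt <- project_relaxed(st$cot$matrix, site_ids(st$cot$matrix))

utils::write.table(
  data.frame(rule = names(rep$sites_removed),
             sites_removed = unlist(rep$sites_removed)),
  "results/filter_report.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(list(filt = filt, imp = imp, impt = impt), "scratch/filtered.rds")
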