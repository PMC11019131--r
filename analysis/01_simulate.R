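#!/usr/bin/env Rscript
# Stage 1: generate the synthetic three-group study (15 YH / 8 YP / 37 OP)
# with planted pathology and primary-aging effects, a TMT-style protein
# layer and promoter sequences with a motif planted in the promoters of the
# down-regulated primary-aging genes.  All later stages regenerate the same
# objects from the same seed, so nothing large needs to be stored.

suppressPackageStartupMessages(library(agesplit))
dir.create("results", showWarnings = FALSE)

design <- study_design(seed = 42)   # 10,000 genes, defaults throughout
sim <- simulate_counts(design)
prot <- simulate_proteome(design, sim$counts)

cat("Simulated", nrow(sim$counts$counts), "genes x",
    ncol(sim$counts$counts), "samples\n")
cls <- table(sim$truth$effect_class)
print(cls)
cat("Protein layer:", length(prot$protein_ids), "detected proteins;",
    sprintf("%.1f%% values present\n",
            100 * mean(!is.na(prot$proteins$intensities))))

summary_tab <- data.frame(
  effect_class = names(cls),
  n_genes = as.integer(cls),
  n_detected_as_protein = as.integer(
    table(sim$truth$effect_class[sim$truth$detected_as_protein])[names(cls)])
)
write.table(summary_tab, "results/01_truth_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# a small demonstration fixture set (plain text, round-trippable)
demo <- study_design(n_genes = 60, group_sizes = c(YH = 4, YP = 3, OP = 5),
                     protein_fraction = 0.5, seed = 42)
dsim <- simulate_counts(demo)
dprot <- simulate_proteome(demo, dsim$counts, missing_fraction = 0)
pwms <- random_pwm_set(3, seed = 42)
dprom <- simulate_promoters(dsim$truth, pwms, length = 120, seed = 42)
write_fixtures(list(counts = dsim$counts, proteins = dprot$proteins,
                    truth = dsim$truth, promoters = dprom, pwms = pwms),
               "results/fixtures_demo", params = list(seed = 42))
cat("Wrote results/01_truth_summary.tsv and results/fixtures_demo/\n")
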