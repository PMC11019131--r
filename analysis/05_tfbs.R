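#!/usr/bin/env Rscript
# Stage 5: promoter TFBS enrichment.  Promoters are simulated for all
# genes with the planted PWM's motif inserted into promoters of the
# down-regulated primary-aging genes; the foreground (selected down-genes)
# is tested against 5000 sampled non-DE background promoters with the
# site-frequency cap (<= 1 per 2000 bp), adjusted fold enrichment (99% CI
# lower bound of the odds ratio), one-sided binomial/Fisher tests, BH FDR,
# per-TF collapse and the expressed-TF (TPM in OP > 1) filter.

suppressPackageStartupMessages(library(agesplit))
dir.create("results", showWarnings = FALSE)

design <- study_design(seed = 42)
sim <- simulate_counts(design)
ps <- simulate_proteome(design, sim$counts)
prot <- anova_tukey(filter_proteins(batch_normalize(ps$proteins)))
de <- list(YP_vs_YH = run_de(sim$counts, c("YP", "YH")),
           OP_vs_YH = run_de(sim$counts, c("OP", "YH")),
           OP_vs_YP = run_de(sim$counts, c("OP", "YP")))
sel <- select_primary_aging(de$OP_vs_YP, de$OP_vs_YH, prot)

pwms <- random_pwm_set(21, seed = 45)          # 1 planted + 20 decoys
prom <- simulate_promoters(sim$truth, pwms, length = 500, seed = 46)
cat(sprintf("Planted PWM %s into %d primary-down promoters\n",
            prom$planted_id, nrow(prom$plant)))

fg_genes <- sel$gene_id[sel$direction == "down"]
fg <- prom$seq[intersect(fg_genes, names(prom$seq))]
bg <- sample_background(prom$seq, de, n = 5000, seed = 47)
cat(sprintf("Foreground: %d promoters; background: %d sampled non-DE promoters\n",
            length(fg), length(bg)))

rec <- enrich_promoters(pwms, fg, bg)
tpm <- compute_tpm(sim$counts)
op_tpm <- rowMeans(tpm[, sim$counts$groups == "OP"])
tf_tpm <- setNames(op_tpm[1 + (seq_along(pwms) - 1) %% nrow(tpm)],
                   vapply(pwms, `[[`, "", "tf"))
fin <- collapse_and_filter(rec, tf_tpm)
top <- fin[1:5, c("matrix_id", "tf_name", "fe_adj_freq", "fe_adj_prom",
                  "binom_p", "fisher_p", "fdr", "significant")]
top[, 3:7] <- signif(top[, 3:7], 3)
print(top, row.names = FALSE)
cat(sprintf("Planted PWM rank by FE_adj: %d; significant PWMs: %d of %d\n",
            match(prom$planted_id, fin$matrix_id), sum(fin$significant),
            nrow(fin)))
write.table(fin, "results/05_tfbs_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Wrote results/05_tfbs_enrichment.tsv\n")
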