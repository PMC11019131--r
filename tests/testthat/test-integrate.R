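# small hand-built protein result table covering both orientations
fake_prot <- function(ids, sig_yh, dir_yh, sig_yp, dir_yp) {
  data.frame(protein_id = ids,
             anova_F = 10, anova_p = 1e-4, testable = TRUE, q_value = 0.01,
             tukey_p_OP_vs_YH = ifelse(sig_yh, 0.01, 0.5),
             direction_OP_vs_YH = dir_yh,
             sig_OP_vs_YH = sig_yh,
             tukey_p_OP_vs_YP = ifelse(sig_yp, 0.01, 0.5),
             direction_OP_vs_YP = dir_yp,
             sig_OP_vs_YP = sig_yp,
             stringsAsFactors = FALSE)
}

fake_de <- function(ids, status) {
  data.frame(gene_id = ids, log2_fc = ifelse(status == "up", 1,
                                             ifelse(status == "down", -1, 0)),
             padj = ifelse(status == "ns", 0.5, 0.001),
             status = status, stringsAsFactors = FALSE)
}

test_that("protein status flips orientation transparently", {
  pr <- fake_prot("p1", TRUE, 1, TRUE, -1)
  expect_equal(unname(protein_status(pr, c("OP", "YH"))), "up")
  expect_equal(unname(protein_status(pr, c("YH", "OP"))), "down")
  expect_equal(unname(protein_status(pr, c("OP", "YP"))), "down")
  expect_error(protein_status(pr, c("OP", "XX")), "not found")
})

test_that("concordance classes follow the definition and partition changed proteins", {
  ids <- paste0("p", 1:7)
  pr <- fake_prot(ids,
                  sig_yh = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
                  dir_yh = c(1, 1, 1, -1, -1, -1, 1),
                  sig_yp = rep(FALSE, 7), dir_yp = rep(1, 7))
  de <- fake_de(ids, c("up", "ns", "down", "down", "ns", "up", "up"))
  cc <- classify_concordance(de, pr, c("OP", "YH"))
  expect_equal(cc$table$concordance_class,
               c("protein UP-mRNA UP", "protein UP-mRNA NS",
                 "protein UP-mRNA DOWN", "protein DOWN-mRNA DOWN",
                 "protein DOWN-mRNA NS", "protein DOWN-mRNA UP", "none"))
  changed <- cc$table$protein_status != "ns"
  expect_true(all(cc$table$concordance_class[changed] != "none"))
  expect_true(all(cc$table$concordance_class[!changed] == "none"))
  expect_equal(cc$concordant_fraction, 2 / 6)
  # unknown protein ids are reported, not silently dropped
  pr2 <- fake_prot(c(ids, "zz"), rep(TRUE, 8), rep(1, 8),
                   rep(FALSE, 8), rep(1, 8))
  cc2 <- classify_concordance(de, pr2, c("OP", "YH"))
  expect_equal(cc2$skipped, "zz")
})

test_that("concordant fraction recovers the planted transcriptional share", {
  d <- study_design(n_genes = 3000, group_sizes = c(YH = 15, YP = 8, OP = 37),
                    class_fractions = c(null = 0.7, pathology_up = 0.1,
                                        pathology_down = 0.1,
                                        primary_up = 0.05, primary_down = 0.05),
                    lfc_magnitude = 1.5, protein_fraction = 0.5,
                    protein_mode_fractions = c(transcriptional = 0.5,
                                               post_transcriptional_only = 0.5,
                                               buffered = 0),
                    seed = 51)
  sim <- simulate_counts(d)
  ps <- simulate_proteome(d, sim$counts)
  prot <- anova_tukey(filter_proteins(batch_normalize(ps$proteins)))
  de <- run_de(sim$counts, c("OP", "YH"))
  cc <- classify_concordance(de, prot, c("OP", "YH"))
  expect_equal(cc$concordant_fraction, 0.5, tolerance = 0.1 / 0.5)
})

test_that("primary-aging selection enumerates the documented rule", {
  ids <- paste0("g", 1:8)
  # mRNA: up in both / up in both / up in one / up both / ns / down both /
  #       up both / up both
  de_yp <- fake_de(ids, c("up", "up", "ns", "up", "ns", "down", "up", "up"))
  de_yh <- fake_de(ids, c("up", "up", "up", "up", "ns", "down", "up", "up"))
  # proteins: g2 detected but flat; g4 detected and changed (same dir);
  # g6 undetected; g7 protein sig both (protein evidence wins);
  # g8 detected, changed in one comparison only
  pr <- fake_prot(c("g2", "g4", "g7", "g8"),
                  sig_yh = c(FALSE, TRUE, TRUE, TRUE),
                  dir_yh = c(1, 1, 1, 1),
                  sig_yp = c(FALSE, TRUE, TRUE, FALSE),
                  dir_yp = c(1, 1, 1, 1))
  sel <- select_primary_aging(de_yp, de_yh, pr)
  expect_setequal(sel$gene_id, c("g1", "g4", "g6", "g7", "g8"))
  expect_equal(sel$evidence[sel$gene_id == "g1"], "mRNA")     # undetected
  expect_equal(sel$evidence[sel$gene_id == "g4"], "protein")  # both layers
  expect_equal(sel$direction[sel$gene_id == "g6"], "down")
  expect_false("g2" %in% sel$gene_id)  # detected-but-flat protein vetoes
  expect_false("g3" %in% sel$gene_id)  # significant in one comparison only
  expect_equal(sel$evidence[sel$gene_id == "g8"], "mRNA")  # protein changed once
  # lenient protein mode admits one-significant + same-sign trend
  sel_len <- select_primary_aging(de_yp, de_yh, pr, lenient = TRUE)
  expect_equal(sel_len$evidence[sel_len$gene_id == "g8"], "protein")
  # without a protein layer everything rides on the mRNA rule
  sel_null <- select_primary_aging(de_yp, de_yh, NULL)
  expect_setequal(sel_null$gene_id, c("g1", "g2", "g4", "g6", "g7", "g8"))
})

test_that("trajectory z-scores standardize to mean 0, population sd 1", {
  x <- rbind(f1 = c(1, 2, 3), f2 = c(5, 5, 5), f3 = c(2, 8, 5))
  tz <- trajectory_zscores(x, c("YH", "YP", "OP"))
  expect_equal(unname(tz$z["f1", ]), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-6)
  expect_equal(tz$skipped, "f2")
  expect_true(all(abs(rowMeans(tz$z)) < 1e-12))
  pop_sd <- sqrt(rowMeans((tz$z - rowMeans(tz$z))^2))
  expect_true(all(abs(pop_sd - 1) < 1e-12))
  # planted monotone trajectory shows monotone group means
  set.seed(3)
  xm <- matrix(rnorm(20 * 30, sd = 0.2), 20, 30)
  shift <- rep(c(0, 1, 2), times = c(10, 10, 10))
  xm <- sweep(xm, 2, shift, "+")
  tz2 <- trajectory_zscores(xm, rep(c("YH", "YP", "OP"), each = 10))
  gm <- tz2$group_means
  expect_true(all(gm[, "YH"] < gm[, "YP"] & gm[, "YP"] < gm[, "OP"]))
})

test_that("overlap test matches full hypergeometric enumeration", {
  u <- 100
  a <- paste0("g", 1:5)
  # identical sets: the most extreme table
  res <- overlap_test(a, a, u)
  expect_equal(res$p_value, 1 / choose(100, 5), tolerance = 1e-12)
  # disjoint sets carry no enrichment signal
  res0 <- overlap_test(paste0("a", 1:5), paste0("b", 1:5), 20)
  expect_gte(res0$p_value, 0.5)
  # 5/0/0/5 in a universe of 10: 1/252
  res2 <- overlap_test(paste0("g", 1:5), paste0("g", 1:5), 10)
  expect_equal(res2$p_value, 1 / 252, tolerance = 1e-12)
  # random sets vs the enumeration oracle, universes <= 200
  set.seed(12)
  for (r in 1:20) {
    uu <- sample(30:200, 1)
    na <- sample(5:15, 1); nb <- sample(5:15, 1)
    genes <- paste0("g", 1:uu)
    sa <- sample(genes, na); sb <- sample(genes, nb)
    k <- length(intersect(sa, sb))
    expect_equal(overlap_test(sa, sb, uu)$p_value,
                 hyper_enum_oracle(k, na, nb, uu), tolerance = 1e-10)
  }
  expect_error(overlap_test(paste0("g", 1:30), a, 20), "universe")
})

test_that("PCA QC separates planted clusters and orders variance", {
  set.seed(14)
  x <- matrix(2^rnorm(100 * 20, 6), 100, 20)
  x[1:30, 11:20] <- x[1:30, 11:20] * 8
  pc <- pca_qc(x)
  expect_true(all(diff(pc$var_explained) < 1e-12))
  expect_lte(sum(pc$var_explained), 1 + 1e-9)
  labels <- rep(c("a", "b"), each = 10)
  expect_gt(silhouette_mean(pc$coords[, 1, drop = FALSE], labels), 0.5)
  # duplicated samples collapse to identical coordinates
  xd <- cbind(x[, 1], x[, 1], x[, 2])
  pcd <- pca_qc(xd)
  expect_equal(pcd$coords[1, ], pcd$coords[2, ], tolerance = 1e-9)
  expect_error(pca_qc(x[, 1, drop = FALSE]), "two samples")
})
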