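test_that("TRANSFAC parsing and round-trip writing preserve matrices", {
  path <- tempfile(fileext = ".transfac")
  writeLines(c(
    "DE  M0001  FOXO1",
    "P0      A      C      G      T",
    "01  10  0  0  0",
    "02  0  10  0  0",
    "03  0  0  10  0",
    "04  2  2  2  4",
    "XX",
    "//",
    "DE  M0002  MYC",
    "P0      A      C      G      T",
    "01  1  2  3  4",
    "02  4  3  2  1",
    "03  0  0  0  10",
    "04  10  0  0  0",
    "05  5  5  0  0",
    "XX",
    "//"
  ), path)
  ps <- read_transfac(path)
  expect_length(ps, 2)
  expect_equal(ps[[1]]$id, "M0001")
  expect_equal(ps[[1]]$tf, "FOXO1")
  expect_equal(ps[[1]]$width, 4)
  expect_equal(ps[[2]]$width, 5)
  # columns normalized with pseudocount
  expect_equal(colSums(ps[[1]]$prob), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(ps[[1]]$prob["A", 1]), 10.01 / 10.04, tolerance = 1e-12)
  # round trip
  out <- tempfile(fileext = ".transfac")
  write_transfac(ps, out)
  ps2 <- read_transfac(out)
  for (i in 1:2) {
    expect_equal(ps2[[i]]$prob, ps[[i]]$prob, tolerance = 1e-9)
    expect_equal(ps2[[i]]$id, ps[[i]]$id)
  }
  # malformed rows are rejected
  bad <- tempfile()
  writeLines(c("DE M1 X", "01 1 2 zz 4", "//"), bad)
  expect_error(read_transfac(bad), "malformed")
  expect_error(new_pwm("x", "x", matrix(1, 4, 3)), "width")
  expect_error(new_pwm("x", "x", cbind(matrix(1, 4, 3), 0)), "all-zero")
})

test_that("scanner finds consensus sites on both strands and skips Ns", {
  pwm <- consensus_pwm("ACGT")
  # forward hit
  hits <- scan_promoters(pwm, c(p1 = "AACGTT"), threshold = 4)
  # ACGT is its own reverse complement: the one match is seen on both strands
  expect_equal(unname(hits$sites["p1"]), 2)
  # non-palindromic motif on the minus strand only
  pwm2 <- consensus_pwm("AAGG")
  hits2 <- scan_promoters(pwm2, c(p1 = "TTCCTT"), threshold = 4)
  expect_equal(unname(hits2$sites["p1"]), 1)
  expect_equal(scan_promoters(pwm2, c(p1 = "AAGGAA"), threshold = 4,
                              bg = rep(0.25, 4))$sites[["p1"]], 1)
  # N windows never score
  hitsN <- scan_promoters(pwm, c(p1 = strrep("N", 50)), threshold = -100)
  expect_equal(unname(hitsN$sites["p1"]), 0)
  # sequence shorter than the motif yields zero sites and zero scanned bp
  short <- scan_promoters(pwm, c(p1 = "AC"), threshold = 0)
  expect_equal(unname(short$sites["p1"]), 0)
  expect_equal(unname(short$scanned_bp["p1"]), 0)
})

test_that("vectorized scanner equals the naive per-position oracle", {
  set.seed(22)
  pwms <- random_pwm_set(3, width_range = c(5, 9), seed = 23)
  seqs <- random_seqs(40, 120, seed = 24)
  names(seqs) <- paste0("p", seq_along(seqs))
  # inject some Ns
  substr(seqs[3], 10, 14) <- "NNNNN"
  for (p in pwms) {
    for (thr in c(2, 4, 6)) {
      fast <- scan_promoters(p, seqs, thr)$sites
      slow <- naive_scan_oracle(p, seqs, thr)
      expect_equal(unname(fast), unname(slow))
    }
  }
})

test_that("threshold calibration matches an exhaustive sweep and caps frequency", {
  set.seed(25)
  bg <- random_seqs(60, 400, seed = 26)
  names(bg) <- paste0("b", seq_along(bg))
  pwm <- random_pwm_set(1, width_range = c(8, 8), seed = 27)[[1]]
  cal <- calibrate_threshold(pwm, bg, max_freq = 1 / 2000)
  expect_true(cal$ok)
  expect_lte(cal$realized_freq, 1 / 2000)
  # realized frequency re-measured by an independent scan
  sc <- scan_promoters(pwm, bg, cal$threshold)
  expect_equal(sc$total_sites / sc$total_bp, cal$realized_freq,
               tolerance = 1e-12)
  # exhaustive sweep over the candidate score set (observed scores plus the
  # maximum achievable score) finds the same threshold
  max_score <- sum(apply(log(pwm$prob / rep(0.25, 4)), 2, max))
  cand <- sort(unique(c(scan_promoters(pwm, bg, -Inf)$scores, max_score)))
  feasible <- cand[vapply(cand, function(t) {
    s <- scan_promoters(pwm, bg, t)
    s$total_sites / s$total_bp <= 1 / 2000
  }, logical(1))]
  expect_equal(cal$threshold, min(feasible))
  # an information-free PWM matches everywhere and cannot be calibrated
  flat <- new_pwm("FLAT", "FLAT", matrix(5, 4, 6))
  calf <- calibrate_threshold(flat, bg)
  expect_false(calf$ok)
  expect_true(is.na(calf$threshold))
  expect_error(calibrate_threshold(pwm, bg[1:2]), "too small")
})

test_that("background sampling is reproducible and respects the non-DE pool", {
  proms <- random_seqs(300, 150, seed = 28)
  names(proms) <- sprintf("g%03d", 1:300)
  de1 <- data.frame(gene_id = names(proms),
                    padj = c(rep(0.01, 100), rep(0.9, 200)))
  de2 <- data.frame(gene_id = names(proms),
                    padj = c(rep(0.9, 50), rep(0.01, 30), rep(0.9, 220)))
  bg <- sample_background(proms, list(de1, de2), n = 100, seed = 5)
  expect_length(bg, 100)
  pool <- intersect(de1$gene_id[de1$padj > 0.4], de2$gene_id[de2$padj > 0.4])
  expect_true(all(names(bg) %in% pool))
  expect_identical(bg, sample_background(proms, list(de1, de2), n = 100,
                                         seed = 5))
  # pool of exactly n comes back whole; smaller pool warns
  bg_all <- sample_background(proms, list(de1, de2), n = length(pool), seed = 1)
  expect_setequal(names(bg_all), pool)
  expect_warning(sample_background(proms, list(de1, de2), n = 5000, seed = 1),
                 "smaller")
  de_all <- data.frame(gene_id = names(proms), padj = 0.01)
  expect_error(sample_background(proms, list(de_all), n = 10), "empty")
})

test_that("enrichment statistics match hand-computed odds ratios and p-values", {
  # no enrichment: equal rates give OR = 1 and a sub-unit lower bound
  r0 <- compute_enrichment(fg_sites = 10, bg_sites = 100,
                           fg_bp = 2000, bg_bp = 20000,
                           fg_prom_with = 5, bg_prom_with = 50,
                           fg_prom_total = 10, bg_prom_total = 100)
  expect_equal(r0$or_freq, 1, tolerance = 1e-9)
  expect_lt(r0$fe_adj_freq, 1)
  expect_gt(r0$binom_p, 0.3)
  # promoter table 30/100 vs 500/5000: OR and Woolf 99% lower bound
  r1 <- compute_enrichment(fg_sites = 30, bg_sites = 500,
                           fg_bp = 50000, bg_bp = 5e6,
                           fg_prom_with = 30, bg_prom_with = 500,
                           fg_prom_total = 100, bg_prom_total = 5000)
  or_hand <- (30 * 4500) / (70 * 500)
  se_hand <- sqrt(1 / 30 + 1 / 70 + 1 / 500 + 1 / 4500)
  expect_equal(r1$or_prom, or_hand, tolerance = 1e-9)
  expect_equal(r1$fe_adj_prom, exp(log(or_hand) - qnorm(0.995) * se_hand),
               tolerance = 1e-9)
  expect_equal(round(r1$or_prom, 3), 3.857)
  expect_equal(round(r1$fe_adj_prom, 2), 2.17)
  # one-sided Fisher on the all-or-nothing promoter table: 1/252
  r2 <- compute_enrichment(fg_sites = 5, bg_sites = 0, fg_bp = 100,
                           bg_bp = 100, fg_prom_with = 5, bg_prom_with = 0,
                           fg_prom_total = 5, bg_prom_total = 5)
  expect_equal(r2$fisher_p, 1 / 252, tolerance = 1e-12)
  # binomial tail against the closed form
  r3 <- compute_enrichment(fg_sites = 4, bg_sites = 100, fg_bp = 1000,
                           bg_bp = 100000, fg_prom_with = 4, bg_prom_with = 90,
                           fg_prom_total = 20, bg_prom_total = 2000)
  expect_equal(r3$binom_p, 1 - pbinom(3, 1000, 0.001), tolerance = 1e-12)
  expect_error(compute_enrichment(1, 1, 10, 0, 1, 1, 5, 5), "background")
})

test_that("the corrected fold enrichment approaches the raw OR as counts grow", {
  for (mult in c(1, 10, 100)) {
    r <- compute_enrichment(fg_sites = 30 * mult, bg_sites = 500 * mult,
                            fg_bp = 50000 * mult, bg_bp = 5e6 * mult,
                            fg_prom_with = 30 * mult, bg_prom_with = 500 * mult,
                            fg_prom_total = 100 * mult,
                            bg_prom_total = 5000 * mult)
    expect_lt(r$fe_adj_freq, r$or_freq)
    expect_lt(r$fe_adj_prom, r$or_prom)
    if (mult > 1) {
      expect_gt(r$fe_adj_prom, prev$fe_adj_prom)
      expect_equal(r$or_prom, prev$or_prom, tolerance = 1e-9)
    }
    prev <- r
  }
})

test_that("per-TF collapse keeps the most enriched PWM and filters by expression", {
  rec <- data.frame(
    matrix_id = c("M1", "M2", "M3", "M4", "M5"),
    tf_name = c("TFA", "TFA", "TFB", "TFC", "TFC"),
    fe_adj_freq = c(2.1, 3.0, 1.5, 2.0, 2.0),
    fe_adj_prom = c(2.0, 2.5, 1.4, 1.9, 1.9),
    binom_p = c(1e-4, 1e-6, 0.2, 1e-3, 1e-3),
    fisher_p = c(1e-3, 1e-5, 0.3, 1e-2, 1e-4),
    stringsAsFactors = FALSE
  )
  tpm <- c(TFA = 10, TFB = 0.5, TFC = 3)
  out <- collapse_and_filter(rec, tpm)
  # TFA keeps its most enriched matrix; TFB fails the TPM-in-OP gate
  expect_equal(out$matrix_id[out$tf_name == "TFA"], "M2")
  expect_false("TFB" %in% out$tf_name)
  # tie on fe_adj broken by smaller fisher_p
  expect_equal(out$matrix_id[out$tf_name == "TFC"], "M5")
  # sorted by decreasing adjusted fold enrichment
  expect_true(!is.unsorted(rev(out$fe_adj_freq)))
  # FDR computed over PWMs before the collapse by default
  expect_equal(out$fdr[out$matrix_id == "M2"],
               p.adjust(rec$binom_p, "BH")[2], tolerance = 1e-12)
  # a TF absent from the expression table is dropped with a warning
  expect_warning(collapse_and_filter(rec, tpm[c("TFA", "TFB")]), "missing")
})
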