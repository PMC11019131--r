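#' Transcripts per million
#'
#' `tpm(g,s) = (count/length) / sum_genes(count/length) * 1e6`.  Columns of
#' the result sum to 1e6; an all-zero sample yields an all-zero column.
#'
#' @param counts Count matrix (genes x samples) or a [count_matrix()].
#' @param gene_lengths Gene lengths in bp (ignored when `counts` is a
#'   `count_matrix`).
#' @return Numeric matrix of TPM values with the same dimnames.
#' @export
compute_tpm <- function(counts, gene_lengths = NULL) {
  if (inherits(counts, "count_matrix")) {
    gene_lengths <- counts$gene_lengths
    counts <- counts$counts
  }
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  rate <- counts / gene_lengths
  denom <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(denom == 0, 1, denom), "/") * 1e6
  tpm[, denom == 0] <- 0
  tpm
}

#' Median-of-ratios size factors
#'
#' For every sample, the median over reference genes (genes with positive
#' counts in all samples) of the ratio of that sample's count to the gene's
#' geometric mean across samples.
#'
#' @param counts Count matrix (genes x samples) or a [count_matrix()].
#' @return Named numeric vector of positive per-sample size factors.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) stop("no gene has positive counts in all samples")
  logc <- log(counts[ref, , drop = FALSE])
  geo <- rowMeans(logc)
  apply(exp(logc - geo), 2, stats::median)
}

#' Per-gene NB dispersion by method of moments with trend shrinkage
#'
#' Normalized counts are pooled within groups: per group,
#' `alpha_g = (s^2 - mean) / mean^2`; the per-gene raw estimate is the
#' df-weighted average over groups, floored at `floor`.  Because the raw
#' moment estimate is extremely noisy at small n (and hits the floor for a
#' large share of genes even under genuine overdispersion), the default adds
#' shrinkage toward a fitted mean-dispersion trend
#' `alpha(mu) = a0 + a1/mu` (the common parametric form): the final
#' estimate is a weighted combination, on the log scale, of the gene-wise
#' raw value and the trend.  With few samples per group the trend dominates;
#' the weight grows with the pooled residual degrees of freedom.
#'
#' @param counts Count matrix or [count_matrix()].
#' @param sf Per-sample size factors.
#' @param groups Group label per sample (ignored when `counts` is a
#'   `count_matrix`).
#' @param shrink Shrink toward the fitted trend (default TRUE).
#' @param floor Lower bound for the estimate.
#' @return Named per-gene dispersion vector.
#' @export
estimate_dispersion <- function(counts, sf, groups = NULL,
                                shrink = TRUE, floor = 1e-8) {
  if (inherits(counts, "count_matrix")) {
    groups <- counts$groups
    counts <- counts$counts
  }
  if (is.null(groups)) stop("groups required")
  norm <- sweep(counts, 2, sf, "/")
  g_levels <- unique(groups)
  num <- 0; den <- 0; df_tot <- 0
  mu_all <- rowMeans(norm)
  for (g in g_levels) {
    x <- norm[, groups == g, drop = FALSE]
    n_g <- ncol(x)
    if (n_g < 2) next
    m <- rowMeans(x)
    v <- rowSums((x - m)^2) / (n_g - 1)
    a_g <- ifelse(m > 0, (v - m) / pmax(m, 1e-8)^2, 0)
    num <- num + (n_g - 1) * a_g
    den <- den + (n_g - 1)
    df_tot <- df_tot + (n_g - 1)
  }
  if (den == 0) stop("need at least 2 samples in some group")
  raw <- pmax(num / den, floor)
  if (!shrink) {
    out <- raw
  } else {
    # parametric trend alpha(mu) = a0 + a1/mu fitted on informative genes
    use <- raw > floor & mu_all > 0
    if (sum(use) >= 50) {
      fit <- stats::lm(raw[use] ~ I(1 / mu_all[use]))
      a0 <- max(fit$coefficients[1], 1e-4)
      a1 <- max(fit$coefficients[2], 0)
      trend <- pmax(a0 + a1 / pmax(mu_all, 1e-8), floor)
      # log-scale weight on the gene-wise value grows with residual df
      w <- df_tot / (df_tot + 20)
      out <- exp(w * log(raw) + (1 - w) * log(trend))
      # moment estimates at the floor carry no information; use the trend
      out[raw <= floor * 1.0001] <- trend[raw <= floor * 1.0001]
    } else {
      out <- raw
    }
  }
  names(out) <- rownames(counts)
  pmax(out, floor)
}

# vectorized IRLS fit of the per-gene two-group NB GLM with log link,
# offsets log(sf), fixed dispersion. Returns per-gene log-ratio (B vs A),
# its SE, and a convergence flag.
.nb_two_group_fit <- function(counts, sf, is_b, alpha,
                              max_iter = 25, tol = 1e-8, mean_floor = 0.5) {
  norm <- sweep(counts, 2, sf, "/")
  mA <- rowMeans(norm[, !is_b, drop = FALSE])
  mB <- rowMeans(norm[, is_b, drop = FALSE])
  # documented zero-handling: group mean of normalized counts floored at
  # 0.5 keeps estimates finite and monotone for degenerate genes
  zero_deg <- mA < mean_floor | mB < mean_floor
  mA_f <- pmax(mA, mean_floor)
  mB_f <- pmax(mB, mean_floor)
  b0 <- log(mA_f)
  b1 <- log(mB_f) - log(mA_f)
  n_g <- nrow(counts)
  conv <- rep(FALSE, n_g)
  xb <- as.numeric(is_b)
  for (it in seq_len(max_iter)) {
    eta <- outer(b0, rep(1, ncol(counts))) +
      outer(b1, xb) + rep(log(sf), each = n_g)
    eta <- pmin(eta, 50)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)          # NB GLM working weight, log link
    r <- (counts - mu) / mu             # score contribution / weight
    sw <- rowSums(w)
    swx <- rowSums(w * rep(xb, each = n_g))
    u0 <- rowSums(w * r)
    u1 <- rowSums(w * r * rep(xb, each = n_g))
    det <- sw * swx - swx^2             # X'WX determinant (x binary)
    det <- pmax(det, 1e-12)
    d0 <- (swx * u0 - swx * u1) / det
    d1 <- (sw * u1 - swx * u0) / det
    # don't move degenerate genes off their floored moment solution
    d0[zero_deg] <- 0
    d1[zero_deg] <- 0
    b0 <- b0 + d0
    b1 <- b1 + d1
    done <- abs(d0) < tol & abs(d1) < tol
    conv <- conv | done
    if (all(done)) break
  }
  eta <- outer(b0, rep(1, ncol(counts))) + outer(b1, xb) +
    rep(log(sf), each = n_g)
  mu <- exp(pmin(eta, 50))
  w <- mu / (1 + alpha * mu)
  sw_a <- rowSums(w[, !is_b, drop = FALSE])
  sw_b <- rowSums(w[, is_b, drop = FALSE])
  se <- sqrt(1 / sw_a + 1 / sw_b)
  conv[zero_deg] <- TRUE
  list(log_ratio = b1, se = se, converged = conv,
       base_mean = rowMeans(norm))
}

#' Per-gene NB Wald test for one two-group contrast
#'
#' Fits, at fixed per-gene dispersion, a negative-binomial GLM with log link
#' and a group indicator (size factors as offsets) by iteratively reweighted
#' least squares; the Wald statistic is the coefficient over its standard
#' error with a two-sided normal p-value, adjusted by Benjamini-Hochberg
#' across tested genes.  Genes where a group has (near-)zero counts use a
#' documented floor of 0.5 normalized counts on the group mean so reported
#' fold changes stay finite.
#'
#' @param counts [count_matrix()] or plain matrix.
#' @param sf Size factors.
#' @param dispersions Per-gene dispersion vector.
#' @param contrast Character 2-vector `c(test, reference)`: positive
#'   log2 fold change means higher in `test`.
#' @param groups Group labels (taken from the `count_matrix` if given).
#' @return data.frame: `gene_id`, `base_mean`, `log2_fc`, `se_log2_fc`,
#'   `stat`, `pvalue`, `padj`, `converged`.
#' @export
wald_test <- function(counts, sf, dispersions, contrast, groups = NULL) {
  if (inherits(counts, "count_matrix")) {
    groups <- counts$groups
    counts <- counts$counts
  }
  if (is.null(groups)) stop("groups required")
  test <- contrast[1]; ref <- contrast[2]
  keep <- groups %in% c(test, ref)
  if (sum(groups == test) < 2 || sum(groups == ref) < 2) {
    stop("both contrast groups need >= 2 samples")
  }
  cts <- counts[, keep, drop = FALSE]
  fit <- .nb_two_group_fit(cts, sf[keep], groups[keep] == test, dispersions)
  log2_fc <- fit$log_ratio / log(2)
  se2 <- fit$se / log(2)
  stat <- fit$log_ratio / fit$se
  p <- 2 * stats::pnorm(-abs(stat))
  p[!fit$converged] <- NA_real_
  padj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  padj[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(
    gene_id = rownames(cts),
    base_mean = fit$base_mean,
    log2_fc = log2_fc,
    se_log2_fc = se2,
    stat = stat,
    pvalue = p,
    padj = padj,
    converged = fit$converged,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Call differentially expressed genes with the study cut-offs
#'
#' Defaults are the study's gates: adjusted p < 0.01, fold change >= 1.25
#' (applied to the unshrunk point estimate `2^|log2_fc|`), and expression
#' TPM > 1, interpreted as mean TPM above the threshold in at least one of
#' the two contrast groups (so genes expressed in only one condition are
#' kept).
#'
#' @param de Result of [wald_test()].
#' @param tpm TPM matrix from [compute_tpm()].
#' @param groups Group label per TPM column.
#' @param contrast `c(test, reference)` as in [wald_test()].
#' @param padj_threshold,fc_threshold,tpm_threshold The three gates.
#' @return `de` with columns `mean_tpm_<test>`, `mean_tpm_<ref>`, `status`
#'   in `up`/`down`/`ns`.
#' @export
call_degs <- function(de, tpm, groups, contrast,
                      padj_threshold = 0.01,
                      fc_threshold = 1.25,
                      tpm_threshold = 1) {
  test <- contrast[1]; ref <- contrast[2]
  tpm <- tpm[de$gene_id, , drop = FALSE]
  mt <- rowMeans(tpm[, groups == test, drop = FALSE])
  mr <- rowMeans(tpm[, groups == ref, drop = FALSE])
  expressed <- mt > tpm_threshold | mr > tpm_threshold
  sig <- !is.na(de$padj) & de$padj < padj_threshold &
    2^abs(de$log2_fc) >= fc_threshold & expressed
  status <- rep("ns", nrow(de))
  status[sig & de$log2_fc > 0] <- "up"
  status[sig & de$log2_fc < 0] <- "down"
  de[[paste0("mean_tpm_", test)]] <- mt
  de[[paste0("mean_tpm_", ref)]] <- mr
  de$status <- status
  de
}

#' Full two-group DE for one contrast
#'
#' Convenience wrapper: size factors, dispersion estimation, Wald test and
#' DEG calling in one call.
#'
#' @param cm A [count_matrix()].
#' @param contrast `c(test, reference)`.
#' @param ... Gates passed to [call_degs()].
#' @return The annotated DE table.
#' @export
run_de <- function(cm, contrast, ...) {
  sf <- size_factors(cm)
  disp <- estimate_dispersion(cm, sf)
  de <- wald_test(cm, sf, disp, contrast)
  tpm <- compute_tpm(cm)
  call_degs(de, tpm, cm$groups, contrast, ...)
}

#' Simulation-based power and FDR of the DEG-calling procedure
#'
#' For each group size `n` in `n_grid`, simulates `reps` two-group datasets
#' (fraction `de_fraction` of genes truly DE at fold change `fold_change`
#' with random sign), runs the full pipeline (size factors, dispersion,
#' Wald test, BH, DEG gates) and reports power (mean fraction of truly DE
#' genes called in the right direction or at all) and the observed false
#' discovery rate, averaged over replicates.
#'
#' @param n_grid Group sizes to evaluate.
#' @param reps Replicate simulations per grid point (>= 1).
#' @param n_genes Genes per simulated dataset.
#' @param de_fraction Fraction of truly DE genes.
#' @param fold_change True fold change of DE genes (> 1).
#' @param dispersion NB dispersion.
#' @param baseline_range Log-uniform range of baseline means.
#' @param size_factor_range Log-uniform range of size factors.
#' @param seed Seed.
#' @param padj_threshold,fc_threshold,tpm_threshold DEG gates.
#' @return data.frame with one row per `n`: `n`, `power`, `fdr`, `n_called`.
#' @export
power_simulation <- function(n_grid = c(3, 5, 8, 12), reps = 5,
                             n_genes = 5000, de_fraction = 0.1,
                             fold_change = 2, dispersion = 0.05,
                             baseline_range = c(50, 2000),
                             size_factor_range = c(1, 1),
                             seed = 1L,
                             padj_threshold = 0.01,
                             fc_threshold = 1.25,
                             tpm_threshold = 1) {
  if (reps < 1) stop("reps must be >= 1")
  rows <- lapply(n_grid, function(n) {
    pw <- numeric(reps); fdr <- numeric(reps); called <- numeric(reps)
    for (r in seq_len(reps)) {
      res <- .power_one_rep(n, n_genes, de_fraction, fold_change,
                            dispersion, baseline_range, size_factor_range,
                            seed = seed + 1000L * match(n, n_grid) + r,
                            padj_threshold, fc_threshold, tpm_threshold)
      pw[r] <- res$power; fdr[r] <- res$fdr; called[r] <- res$n_called
    }
    data.frame(n = n, power = mean(pw), fdr = mean(fdr, na.rm = TRUE),
               n_called = mean(called))
  })
  do.call(rbind, rows)
}

.power_one_rep <- function(n, n_genes, de_fraction, fold_change, dispersion,
                           baseline_range, size_factor_range, seed,
                           padj_threshold, fc_threshold, tpm_threshold) {
  n_de <- round(de_fraction * n_genes)
  design <- study_design(
    n_genes = n_genes,
    group_sizes = c(YH = n, OP = n),
    class_fractions = c(null = 1 - n_de / n_genes,
                        primary_up = 0.5 * n_de / n_genes,
                        primary_down = 0.5 * n_de / n_genes),
    lfc_magnitude = log2(fold_change),
    dispersion = dispersion,
    protein_fraction = 0,
    seed = seed
  )
  sim <- simulate_counts(design, baseline_range = baseline_range,
                         size_factor_range = size_factor_range)
  de <- run_de(sim$counts, c("OP", "YH"),
               padj_threshold = padj_threshold,
               fc_threshold = fc_threshold,
               tpm_threshold = tpm_threshold)
  truly <- sim$truth$effect_class != "null"
  called <- de$status != "ns"
  power <- if (any(truly)) mean(called[truly]) else NA_real_
  fdr <- if (any(called)) mean(!truly[called]) else NA_real_
  list(power = power, fdr = fdr, n_called = sum(called))
}
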