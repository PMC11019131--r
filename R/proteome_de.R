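#' Cross-kit batch normalization of reporter intensities
#'
#' Rescales batch-A intensities by the ratio of present-value means,
#' `mean(batch B) / mean(batch A)`, so that after normalization the two
#' batch means agree to machine precision.  This mirrors normalizing the
#' mean reporter-ion intensity of the 10-plex-labelled samples to that of
#' the 16-plex-labelled samples.  The operation is idempotent.
#'
#' @param pm A [protein_matrix()] with exactly two batches.
#' @return The normalized `protein_matrix`.
#' @export
batch_normalize <- function(pm) {
  stopifnot(inherits(pm, "protein_matrix"))
  b_levels <- sort(unique(pm$batch))
  if (length(b_levels) != 2) stop("exactly two batches required")
  a <- pm$batch == b_levels[1]
  mean_a <- mean(pm$intensities[, a], na.rm = TRUE)
  mean_b <- mean(pm$intensities[, !a], na.rm = TRUE)
  if (!is.finite(mean_a) || !is.finite(mean_b)) {
    stop("a batch has no present values")
  }
  out <- pm
  out$intensities[, a] <- pm$intensities[, a] * (mean_b / mean_a)
  out
}

#' Presence filter
#'
#' Keeps proteins quantified in strictly more than `presence_fraction` of
#' samples (the ">70% of samples" rule; strict inequality, so 7 of 10
#' present is dropped while 8 of 10 is kept).
#'
#' @param pm A [protein_matrix()].
#' @param presence_fraction Required fraction, in (0, 1].
#' @return Filtered `protein_matrix`.
#' @export
filter_proteins <- function(pm, presence_fraction = 0.70) {
  stopifnot(inherits(pm, "protein_matrix"))
  if (presence_fraction <= 0 || presence_fraction > 1) {
    stop("presence_fraction must lie in (0, 1]")
  }
  frac <- rowMeans(!is.na(pm$intensities))
  keep <- frac > presence_fraction
  out <- pm
  out$intensities <- pm$intensities[keep, , drop = FALSE]
  out$protein_ids <- pm$protein_ids[keep]
  out
}

# one-sided direct sums-of-squares one-way ANOVA, vectorized over proteins;
# returns NA rows where a protein is untestable
.anova_rows <- function(x, groups, g_levels) {
  n_tot <- rowSums(!is.na(x))
  grand <- rowMeans(x, na.rm = TRUE)
  ssb <- 0; ssw <- 0
  n_groups_ok <- 0
  ok_counts <- matrix(0L, nrow(x), length(g_levels),
                      dimnames = list(NULL, g_levels))
  means <- matrix(NA_real_, nrow(x), length(g_levels),
                  dimnames = list(NULL, g_levels))
  for (g in g_levels) {
    xg <- x[, groups == g, drop = FALSE]
    ng <- rowSums(!is.na(xg))
    mg <- rowMeans(xg, na.rm = TRUE)
    ok_counts[, g] <- ng
    means[, g] <- mg
    ssb <- ssb + ifelse(ng > 0, ng * (mg - grand)^2, 0)
    ssw <- ssw + rowSums((xg - mg)^2, na.rm = TRUE)
  }
  k_eff <- rowSums(ok_counts >= 2)
  testable <- k_eff == length(g_levels) & rowSums(ok_counts) > length(g_levels)
  df1 <- length(g_levels) - 1
  df2 <- n_tot - length(g_levels)
  msb <- ssb / df1
  msw <- ssw / df2
  f <- ifelse(msw > 0, msb / msw, ifelse(msb == 0, 0, Inf))
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # degenerate convention: all values identical -> F = 0, p = 1
  p[msw == 0 & msb == 0] <- 1
  f[msw == 0 & msb == 0] <- 0
  list(f = f, p = p, msw = msw, df2 = df2, n = ok_counts,
       means = means, testable = testable)
}

#' One-way ANOVA with BH q-values and Tukey-Kramer post-hoc tests
#'
#' Intensities are log2-transformed (configurable), then each protein is
#' tested by one-way ANOVA across the groups; missing values are excluded
#' per protein and no imputation is performed.  Benjamini-Hochberg q-values
#' are computed over testable proteins only (proteins lacking two present
#' values in every group are flagged untestable and excluded from the BH
#' denominator).  Pairwise p-values come from the studentized-range
#' distribution with the Kramer correction for unequal group sizes; a
#' pairwise call requires `q < q_threshold` and Tukey `p < tukey_threshold`,
#' with direction the sign of the log2 group-mean difference.
#'
#' @param pm A [protein_matrix()].
#' @param log2_transform Analyze `log2(intensity)` (default) or raw values.
#' @param q_threshold,tukey_threshold Significance gates.
#' @return data.frame with per protein: `anova_F`, `anova_p`, `q_value`,
#'   `testable`, and per group pair `tukey_p_<A>_vs_<B>`,
#'   `direction_<A>_vs_<B>` (+1 higher in A, -1 lower), and
#'   `sig_<A>_vs_<B>`.
#' @export
anova_tukey <- function(pm, log2_transform = TRUE,
                        q_threshold = 0.05, tukey_threshold = 0.05) {
  stopifnot(inherits(pm, "protein_matrix"))
  x <- pm$intensities
  if (log2_transform) x <- log2(x)
  g_levels <- unique(pm$groups)
  if (length(g_levels) < 2) stop("need at least two groups")
  an <- .anova_rows(x, pm$groups, g_levels)
  res <- data.frame(protein_id = pm$protein_ids,
                    anova_F = an$f, anova_p = an$p,
                    testable = an$testable, stringsAsFactors = FALSE)
  res$anova_F[!an$testable] <- NA_real_
  res$anova_p[!an$testable] <- NA_real_
  res$q_value <- NA_real_
  res$q_value[an$testable] <- stats::p.adjust(res$anova_p[an$testable],
                                              method = "BH")
  k <- length(g_levels)
  pairs <- utils::combn(g_levels, 2, simplify = FALSE)
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    na_ <- an$n[, a]; nb_ <- an$n[, b]
    diff <- an$means[, a] - an$means[, b]
    se <- sqrt(an$msw / 2 * (1 / na_ + 1 / nb_))
    qs <- abs(diff) / se
    p <- stats::ptukey(qs, nmeans = k, df = an$df2, lower.tail = FALSE)
    p[an$msw == 0] <- 1
    tag <- paste0(a, "_vs_", b)
    p[!an$testable] <- NA_real_
    res[[paste0("tukey_p_", tag)]] <- p
    res[[paste0("direction_", tag)]] <- sign(diff)
    res[[paste0("sig_", tag)]] <- !is.na(p) & !is.na(res$q_value) &
      res$q_value < q_threshold & p < tukey_threshold
  }
  attr(res, "pairs") <- vapply(pairs, paste, "", collapse = "_vs_")
  attr(res, "n_untestable") <- sum(!an$testable)
  res
}
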