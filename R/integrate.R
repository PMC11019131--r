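#' Per-comparison protein status from an ANOVA/Tukey table
#'
#' Maps the pairwise columns of [anova_tukey()] output to a per-protein
#' status for one ordered comparison `c(test, reference)`: `up` / `down`
#' (significant with the matching sign), otherwise `ns`.  The stored pair
#' orientation is flipped transparently when needed.
#'
#' @param prot Result of [anova_tukey()].
#' @param comparison Character 2-vector `c(test, reference)`.
#' @return Named character vector of `up`/`down`/`ns` per protein.
#' @export
protein_status <- function(prot, comparison) {
  test <- comparison[1]; ref <- comparison[2]
  fwd <- paste0(test, "_vs_", ref)
  rev <- paste0(ref, "_vs_", test)
  if (paste0("sig_", fwd) %in% names(prot)) {
    sig <- prot[[paste0("sig_", fwd)]]
    dir <- prot[[paste0("direction_", fwd)]]
  } else if (paste0("sig_", rev) %in% names(prot)) {
    sig <- prot[[paste0("sig_", rev)]]
    dir <- -prot[[paste0("direction_", rev)]]
  } else {
    stop("comparison not found in protein results: ", fwd)
  }
  status <- rep("ns", nrow(prot))
  status[sig & dir > 0] <- "up"
  status[sig & dir < 0] <- "down"
  stats::setNames(status, prot$protein_id)
}

#' Classify protein-mRNA concordance for one comparison
#'
#' Joins a protein status with the mRNA DEG status of the same genes and
#' assigns each detected, significantly changed protein to one of six
#' classes ("protein UP-mRNA UP", "protein UP-mRNA NS", ...), the joint
#' categories used to distinguish transcriptional from post-transcriptional
#' regulation.  Proteins with `ns` status get class `none`.
#'
#' @param de DEG-annotated mRNA table (from [call_degs()]), column `status`.
#' @param prot Result of [anova_tukey()].
#' @param comparison `c(test, reference)`.
#' @return List with `table` (data.frame: gene_id, protein_status,
#'   mrna_status, concordance_class), `counts` (class tally) and
#'   `concordant_fraction` (share of changed proteins whose mRNA moved the
#'   same way).
#' @export
classify_concordance <- function(de, prot, comparison) {
  ps <- protein_status(prot, comparison)
  common <- intersect(names(ps), de$gene_id)
  skipped <- setdiff(names(ps), de$gene_id)
  ms <- stats::setNames(de$status, de$gene_id)[common]
  ps <- ps[common]
  cls <- rep("none", length(common))
  up <- ps == "up"; dn <- ps == "down"
  cls[up & ms == "up"] <- "protein UP-mRNA UP"
  cls[up & ms == "ns"] <- "protein UP-mRNA NS"
  cls[up & ms == "down"] <- "protein UP-mRNA DOWN"
  cls[dn & ms == "down"] <- "protein DOWN-mRNA DOWN"
  cls[dn & ms == "ns"] <- "protein DOWN-mRNA NS"
  cls[dn & ms == "up"] <- "protein DOWN-mRNA UP"
  tab <- data.frame(gene_id = common, protein_status = ps,
                    mrna_status = ms, concordance_class = cls,
                    stringsAsFactors = FALSE, row.names = NULL)
  changed <- up | dn
  concordant <- (up & ms == "up") | (dn & ms == "down")
  list(
    table = tab,
    counts = table(factor(cls[changed])),
    concordant_fraction = if (any(changed)) mean(concordant[changed]) else NA_real_,
    skipped = skipped
  )
}

#' Select primary-aging genes by cross-comparison unidirectional change
#'
#' A gene is associated with primary aging when its protein (or, failing
#' protein detection, its mRNA) changes expression in the SAME direction in
#' both the OP-vs-YP and OP-vs-YH comparisons.  Protein evidence: the
#' protein is significant (ANOVA q and Tukey p gates) with the same sign in
#' both comparisons.  mRNA evidence: the gene is a DEG with the same sign
#' in both comparisons AND its protein product is either undetected or also
#' changed - mRNAs whose detected protein did not change expression are
#' excluded.
#'
#' @param de_op_yp,de_op_yh DEG-annotated mRNA tables for OP vs YP and
#'   OP vs YH.
#' @param prot Result of [anova_tukey()] (or NULL when no protein layer).
#' @param lenient If TRUE, protein evidence needs significance in only one
#'   comparison plus a same-sign trend in the other (off by default; the
#'   strict both-significant reading is the primary rule).
#' @return data.frame: `gene_id`, `direction` (`up`/`down`), `evidence`
#'   (`protein`/`mRNA`), and supporting statistics from both comparisons.
#' @export
select_primary_aging <- function(de_op_yp, de_op_yh, prot = NULL,
                                 lenient = FALSE) {
  m_yp <- stats::setNames(de_op_yp$status, de_op_yp$gene_id)
  m_yh <- stats::setNames(de_op_yh$status, de_op_yh$gene_id)
  genes <- intersect(names(m_yp), names(m_yh))
  if (!is.null(prot)) {
    p_yp <- protein_status(prot, c("OP", "YP"))
    p_yh <- protein_status(prot, c("OP", "YH"))
    detected <- prot$protein_id
    if (lenient) {
      t_yp <- .protein_trend(prot, c("OP", "YP"))
      t_yh <- .protein_trend(prot, c("OP", "YH"))
      p_up <- (p_yp == "up" & t_yh > 0) | (p_yh == "up" & t_yp > 0)
      p_dn <- (p_yp == "down" & t_yh < 0) | (p_yh == "down" & t_yp < 0)
    } else {
      p_up <- p_yp == "up" & p_yh == "up"
      p_dn <- p_yp == "down" & p_yh == "down"
    }
    prot_dir <- rep(NA_character_, length(detected))
    prot_dir[p_up] <- "up"
    prot_dir[p_dn] <- "down"
    names(prot_dir) <- detected
    prot_changed_any <- p_yp != "ns" | p_yh != "ns"
    names(prot_changed_any) <- detected
  } else {
    detected <- character(0)
    prot_dir <- character(0)
    prot_changed_any <- logical(0)
  }
  rows <- list()
  # protein evidence
  sel_p <- names(prot_dir)[!is.na(prot_dir)]
  if (length(sel_p)) {
    rows$protein <- data.frame(gene_id = sel_p,
                               direction = prot_dir[sel_p],
                               evidence = "protein",
                               stringsAsFactors = FALSE)
  }
  # mRNA evidence: same-sign DEG in both comparisons; detected-but-flat
  # proteins veto the gene
  m_up <- genes[m_yp[genes] == "up" & m_yh[genes] == "up"]
  m_dn <- genes[m_yp[genes] == "down" & m_yh[genes] == "down"]
  mrna_sel <- c(m_up, m_dn)
  mrna_dir <- c(rep("up", length(m_up)), rep("down", length(m_dn)))
  veto <- mrna_sel %in% detected & !(mrna_sel %in% names(which(prot_changed_any)))
  keep <- !veto & !(mrna_sel %in% sel_p)   # protein evidence takes precedence
  if (any(keep)) {
    rows$mrna <- data.frame(gene_id = mrna_sel[keep],
                            direction = mrna_dir[keep],
                            evidence = "mRNA",
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), direction = character(0),
               evidence = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  # supporting statistics
  add <- function(de, suffix) {
    i <- match(out$gene_id, de$gene_id)
    out[[paste0("log2_fc_", suffix)]] <<- de$log2_fc[i]
    out[[paste0("padj_", suffix)]] <<- de$padj[i]
  }
  add(de_op_yp, "OP_vs_YP")
  add(de_op_yh, "OP_vs_YH")
  out
}

.protein_trend <- function(prot, comparison) {
  fwd <- paste0("direction_", comparison[1], "_vs_", comparison[2])
  rev <- paste0("direction_", comparison[2], "_vs_", comparison[1])
  d <- if (fwd %in% names(prot)) prot[[fwd]] else -prot[[rev]]
  stats::setNames(d, prot$protein_id)
}

#' Per-feature trajectory z-scores across the YH-YP-OP axis
#'
#' Standardizes each feature (protein or mRNA) across ALL samples to mean 0
#' and sd 1 (population sd, i.e. the n denominator, as is conventional for
#' z-score heatmaps), then summarizes the per-group mean z so group-ordered
#' expression trends can be displayed.  Zero-variance features are skipped.
#'
#' @param x Numeric matrix, features x samples (already on the analysis
#'   scale, e.g. log2).
#' @param groups Group label per sample.
#' @param feature_subset Optional feature ids to restrict to.
#' @return List with `z` (feature x sample z-score matrix), `group_means`
#'   (feature x group mean z) and `skipped` (zero-variance feature ids).
#' @export
trajectory_zscores <- function(x, groups, feature_subset = NULL) {
  if (!is.null(feature_subset)) {
    x <- x[intersect(feature_subset, rownames(x)), , drop = FALSE]
  }
  pop_sd <- function(m) {
    mu <- rowMeans(m, na.rm = TRUE)
    sqrt(rowMeans((m - mu)^2, na.rm = TRUE))
  }
  sds <- pop_sd(x)
  skipped <- rownames(x)[is.na(sds) | sds == 0]
  x <- x[!(rownames(x) %in% skipped), , drop = FALSE]
  m <- rowMeans(x, na.rm = TRUE)
  z <- (x - m) / pop_sd(x)
  g_levels <- unique(groups)
  gm <- vapply(g_levels, function(g)
    rowMeans(z[, groups == g, drop = FALSE], na.rm = TRUE),
    numeric(nrow(z)))
  if (nrow(z) == 1) gm <- matrix(gm, 1, dimnames = list(rownames(z), g_levels))
  list(z = z, group_means = gm, skipped = skipped)
}

#' Gene-set overlap test
#'
#' One-sided hypergeometric over-representation p-value and the sample odds
#' ratio of the 2x2 overlap table of two gene sets in a common universe.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe_size Size of the common universe (>= union of sets).
#' @return List with `overlap`, `odds_ratio`, `p_value`.
#' @export
overlap_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) > universe_size || length(set_b) > universe_size) {
    stop("sets larger than universe")
  }
  k <- length(intersect(set_a, set_b))
  a <- length(set_a); b <- length(set_b)
  p <- stats::phyper(k - 1, b, universe_size - b, a, lower.tail = FALSE)
  # sample OR of the 2x2 table (0.5 correction only when needed)
  t11 <- k; t12 <- a - k; t21 <- b - k
  t22 <- universe_size - a - b + k
  or <- if (t12 == 0 || t21 == 0) {
    ((t11 + 0.5) * (t22 + 0.5)) / ((t12 + 0.5) * (t21 + 0.5))
  } else {
    (t11 * t22) / (t12 * t21)
  }
  list(overlap = k, odds_ratio = or, p_value = p)
}

#' PCA quality control of an expression matrix
#'
#' Centered (optionally unit-scaled) principal component analysis of
#' log-transformed expression, samples as observations.
#'
#' @param x Features x samples matrix of non-negative expression values.
#' @param log_transform Apply `log2(x + 1)` first (default TRUE).
#' @param scale. Unit-scale features (default FALSE).
#' @param n_top Use the `n_top` most variable features (NULL = all).
#' @return List with `coords` (samples x PCs), `var_explained` (fractions,
#'   non-increasing, summing to <= 1).
#' @export
pca_qc <- function(x, log_transform = TRUE, scale. = FALSE, n_top = NULL) {
  if (ncol(x) < 2) stop("need at least two samples")
  if (log_transform) x <- log2(x + 1)
  v <- apply(x, 1, stats::var)
  x <- x[v > 0, , drop = FALSE]
  if (!is.null(n_top) && n_top < nrow(x)) {
    x <- x[order(apply(x, 1, stats::var), decreasing = TRUE)[seq_len(n_top)], ,
           drop = FALSE]
  }
  pc <- stats::prcomp(t(x), center = TRUE, scale. = scale.)
  list(coords = pc$x,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}
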