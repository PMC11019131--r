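#' Construct a position weight matrix object
#'
#' Stores the raw counts and the pseudocount-normalized per-position base
#' probabilities (rows A, C, G, T).  Width must be at least 4 and no
#' position may be all-zero.
#'
#' @param id Matrix identifier.
#' @param tf Transcription factor name.
#' @param counts 4 x width matrix of counts or frequencies, rows A,C,G,T.
#' @param pseudocount Added per cell before column normalization.
#' @return Object of class `pwm`.
#' @export
new_pwm <- function(id, tf, counts, pseudocount = 0.01) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PWM must have 4 rows (A,C,G,T)")
  if (ncol(counts) < 4) stop("PWM width must be >= 4")
  if (any(colSums(counts) == 0)) stop("PWM has an all-zero column")
  if (any(counts < 0)) stop("PWM entries must be non-negative")
  rownames(counts) <- c("A", "C", "G", "T")
  prob <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  structure(list(id = id, tf = tf, counts = counts, prob = prob,
                 width = ncol(counts)),
            class = "pwm")
}

#' Read a TRANSFAC-dialect PWM file
#'
#' Parses blocks of the TRANSFAC text format: an identifier line (`DE`,
#' with matrix id and TF name; `AC`/`ID` lines are honoured as fallbacks), a
#' `P0`/`PO` column header, numbered rows (`01` .. `NN`) of A/C/G/T counts,
#' and `XX` / `//` terminators.
#'
#' @param path File path.
#' @return Object of class `pwm_set` (list of [new_pwm()] objects).
#' @export
read_transfac <- function(path) {
  lines <- readLines(path)
  out <- list()
  id <- tf <- NA_character_
  rows <- list()
  flush <- function() {
    if (length(rows)) {
      counts <- t(do.call(rbind, rows))
      if (is.na(id)) id <- sprintf("M%04d", length(out) + 1L)
      if (is.na(tf)) tf <- id
      out[[length(out) + 1L]] <<- new_pwm(id, tf, counts)
    }
    id <<- NA_character_; tf <<- NA_character_; rows <<- list()
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || ln == "XX") next
    if (ln == "//") { flush(); next }
    tag <- sub("^(\\S+).*", "\\1", ln)
    rest <- trimws(sub("^\\S+", "", ln))
    if (tag == "DE") {
      parts <- strsplit(rest, "\\s+")[[1]]
      id <- parts[1]
      if (length(parts) > 1) tf <- parts[2]
    } else if (tag == "AC" && is.na(id)) {
      id <- rest
    } else if (tag == "ID" && is.na(tf)) {
      tf <- rest
    } else if (tag %in% c("P0", "PO")) {
      next
    } else if (grepl("^[0-9]+$", tag)) {
      vals <- strsplit(rest, "\\s+")[[1]]
      num <- suppressWarnings(as.numeric(vals[1:4]))
      if (any(is.na(num))) stop("malformed PWM row: ", ln)
      rows[[length(rows) + 1L]] <- num
    }
  }
  flush()
  ids <- vapply(out, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate matrix ids in ", path)
  structure(out, class = "pwm_set")
}

#' Write a `pwm_set` in TRANSFAC dialect
#'
#' @param pwm_set A `pwm_set`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_transfac <- function(pwm_set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwm_set) {
    writeLines(sprintf("DE  %s  %s", p$id, p$tf), con)
    writeLines("P0      A      C      G      T", con)
    for (j in seq_len(p$width)) {
      writeLines(sprintf("%02d  %g  %g  %g  %g", j,
                         p$counts[1, j], p$counts[2, j],
                         p$counts[3, j], p$counts[4, j]), con)
    }
    writeLines("XX", con)
    writeLines("//", con)
  }
  invisible(path)
}

# log-odds score matrix vs a background composition; 4 x width
.pwm_log_odds <- function(pwm, bg = rep(0.25, 4)) {
  log(pwm$prob / bg)
}

# reverse-complement a 4 x w score matrix
.rc_matrix <- function(m) {
  m[4:1, ncol(m):1, drop = FALSE]
}

# encode sequences to integers (A=1..T=4, anything else 0) and concatenate
# with w-length spacers of 0 so no scoring window crosses a boundary
.encode_concat <- function(seqs, w) {
  code <- integer(256)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  lens <- nchar(seqs)
  enc <- lapply(seqs, function(s) code[utf8ToInt(s)])
  spacer <- rep(0L, w)
  big <- unlist(lapply(enc, function(e) c(e, spacer)), use.names = FALSE)
  owner <- rep(seq_along(seqs), times = lens + w)
  list(big = big, owner = owner, lens = lens)
}

# score every position of the concatenated encoding against one 4 x w
# log-odds matrix; windows containing non-ACGT score -Inf
.score_positions <- function(big, lo) {
  w <- ncol(lo)
  npos <- length(big) - w + 1L
  bidx <- big
  bidx[bidx == 0L] <- 5L
  sc <- numeric(npos)
  for (j in seq_len(w)) {
    tab <- c(lo[, j], -Inf)
    sc <- sc + tab[bidx[j:(j + npos - 1L)]]
  }
  sc
}

#' Scan promoters with a PWM at a fixed log-odds threshold
#'
#' Scores every position of every promoter on both strands (the reverse
#' strand via the reverse-complemented matrix); a site is a position whose
#' log-odds score meets the threshold.  Overlapping sites are all counted;
#' windows containing N score minus infinity.
#'
#' @param pwm A [new_pwm()] object.
#' @param promoters Named character vector of sequences, or a
#'   `promoter_set`.
#' @param threshold Log-odds score threshold.
#' @param bg Background base composition (A,C,G,T) for the log-odds scores.
#' @return List with `sites` (named per-promoter site count),
#'   `scanned_bp` (per promoter, `2 * max(0, L - w + 1)`), `total_sites`,
#'   `total_bp`, and `scores` (all finite position scores, both strands).
#' @export
scan_promoters <- function(pwm, promoters, threshold, bg = rep(0.25, 4)) {
  if (inherits(promoters, "promoter_set")) promoters <- promoters$seq
  w <- pwm$width
  lo <- .pwm_log_odds(pwm, bg)
  ec <- .encode_concat(promoters, w)
  npos <- length(ec$big) - w + 1L
  owner <- ec$owner[seq_len(npos)]
  sc_f <- .score_positions(ec$big, lo)
  sc_r <- .score_positions(ec$big, .rc_matrix(lo))
  hits_f <- sc_f >= threshold
  hits_r <- sc_r >= threshold
  n_prom <- length(promoters)
  sites <- tabulate(owner[hits_f], nbins = n_prom) +
    tabulate(owner[hits_r], nbins = n_prom)
  names(sites) <- names(promoters)
  scanned <- 2 * pmax(0L, ec$lens - w + 1L)
  list(sites = sites,
       scanned_bp = stats::setNames(scanned, names(promoters)),
       total_sites = sum(sites),
       total_bp = sum(scanned),
       scores = c(sc_f[is.finite(sc_f)], sc_r[is.finite(sc_r)]))
}

#' Calibrate a PWM score threshold to a background site-frequency cap
#'
#' Finds the smallest log-odds threshold at which the PWM's site frequency
#' on the background promoter pool (both strands; sites per scanned bp,
#' scanned bp = `2 * (L - w + 1)` summed over promoters) does not exceed
#' `max_freq` (default one site per 2000 bp).  Implemented as a sweep over
#' the observed score set, which is exactly the exhaustive solution.  A PWM
#' that exceeds the cap even at its maximum attainable score is flagged
#' unscannable.
#'
#' @param pwm A [new_pwm()].
#' @param background Background promoters (character vector or
#'   `promoter_set`).
#' @param max_freq Maximum allowed background site frequency per bp.
#' @param bg Background base composition for log-odds scoring.
#' @return List with `threshold` (NA when unscannable), `ok`,
#'   `realized_freq`.
#' @export
calibrate_threshold <- function(pwm, background, max_freq = 1 / 2000,
                                bg = rep(0.25, 4)) {
  if (inherits(background, "promoter_set")) background <- background$seq
  if (sum(nchar(background)) < 10 * 2000) {
    stop("background pool too small for frequency calibration")
  }
  sc <- scan_promoters(pwm, background, threshold = -Inf, bg = bg)
  scores <- sort(sc$scores, decreasing = TRUE)
  allowed <- floor(max_freq * sc$total_bp)
  if (allowed < 1 || length(scores) == 0) {
    return(list(threshold = NA_real_, ok = FALSE, realized_freq = NA_real_))
  }
  # number of sites at threshold t = #(scores >= t); candidates are the
  # observed score values plus the PWM's maximum achievable score (which
  # may exceed every observed score when the consensus is absent from the
  # background); pick the smallest candidate whose count is within the cap
  max_score <- sum(apply(.pwm_log_odds(pwm, bg), 2, max))
  uq <- unique(scores)               # decreasing
  cnt <- cumsum(tabulate(match(scores, uq)))
  if (max_score > uq[1]) {
    uq <- c(max_score, uq)
    cnt <- c(0, cnt)
  }
  feas <- which(cnt <= allowed)
  if (!length(feas)) {
    # even the maximum achievable score occurs too often on the background
    return(list(threshold = NA_real_, ok = FALSE,
                realized_freq = cnt[1] / sc$total_bp))
  }
  thr <- uq[max(feas)]
  list(threshold = thr, ok = TRUE,
       realized_freq = cnt[max(feas)] / sc$total_bp)
}

#' Sample background promoters from the non-DE pool
#'
#' Uniform, seed-reproducible sample without replacement of promoters of
#' genes showing no differential expression in any contrast (adjusted
#' p > `padj_cutoff` in all supplied DE tables).
#'
#' @param promoters Named sequences or `promoter_set` covering all genes.
#' @param de_tables List of DE result tables (columns `gene_id`, `padj`).
#' @param n Background size (default 5000); if the pool is smaller, the
#'   whole pool is returned with a warning.
#' @param padj_cutoff Non-DE definition (default 0.4).
#' @param seed Seed.
#' @return Named character vector of background sequences.
#' @export
sample_background <- function(promoters, de_tables, n = 5000,
                              padj_cutoff = 0.4, seed = 1L) {
  if (inherits(promoters, "promoter_set")) promoters <- promoters$seq
  pool <- names(promoters)
  for (de in de_tables) {
    ok <- de$gene_id[!is.na(de$padj) & de$padj > padj_cutoff]
    pool <- intersect(pool, ok)
  }
  if (!length(pool)) stop("non-DE promoter pool is empty")
  set.seed(seed)
  if (length(pool) <= n) {
    if (length(pool) < n) {
      warning("non-DE pool smaller than requested background; using all ",
              length(pool), " promoters")
    }
    return(promoters[pool])
  }
  promoters[sample(pool, n)]
}

#' Enrichment statistics for one PWM from foreground/background counts
#'
#' Computes the raw odds ratios of the site-frequency table
#' `(fg_sites, fg_bp - fg_sites, bg_sites, bg_bp - bg_sites)` and of the
#' promoter-count table, and their adjusted fold enrichments
#' `FE_adj = exp(ln OR - z * SE_lnOR)` - the lower bound of the
#' (default 99%) confidence interval of the log odds ratio with Woolf's
#' standard error and the Haldane-Anscombe 0.5 correction on zero cells.
#' Significance of the site-frequency enrichment uses a one-sided binomial
#' test at the background rate; the promoter-count enrichment uses the
#' one-sided Fisher (hypergeometric) test.
#'
#' @param fg_sites,bg_sites Total site counts.
#' @param fg_bp,bg_bp Total scanned bp (both strands).
#' @param fg_prom_with,bg_prom_with Promoters containing >= 1 site.
#' @param fg_prom_total,bg_prom_total Promoter counts.
#' @param ci Confidence level for the corrected odds ratio.
#' @return One-row data.frame with counts, `or_freq`, `fe_adj_freq`,
#'   `or_prom`, `fe_adj_prom`, `binom_p`, `fisher_p`.
#' @export
compute_enrichment <- function(fg_sites, bg_sites, fg_bp, bg_bp,
                               fg_prom_with, bg_prom_with,
                               fg_prom_total, bg_prom_total,
                               ci = 0.99) {
  if (bg_bp <= 0) stop("zero background bp")
  z <- stats::qnorm(1 - (1 - ci) / 2)
  adj_or <- function(t11, t12, t21, t22) {
    if (any(c(t11, t12, t21, t22) == 0)) {
      t11 <- t11 + 0.5; t12 <- t12 + 0.5; t21 <- t21 + 0.5; t22 <- t22 + 0.5
    }
    or <- (t11 * t22) / (t12 * t21)
    se <- sqrt(1 / t11 + 1 / t12 + 1 / t21 + 1 / t22)
    c(or = or, fe = exp(log(or) - z * se))
  }
  freq <- adj_or(fg_sites, fg_bp - fg_sites, bg_sites, bg_bp - bg_sites)
  prom <- adj_or(fg_prom_with, fg_prom_total - fg_prom_with,
                 bg_prom_with, bg_prom_total - bg_prom_with)
  bg_rate <- bg_sites / bg_bp
  binom_p <- if (bg_rate <= 0) {
    as.numeric(fg_sites == 0)
  } else {
    stats::pbinom(fg_sites - 1, fg_bp, bg_rate, lower.tail = FALSE)
  }
  fisher_p <- stats::phyper(fg_prom_with - 1,
                            fg_prom_with + bg_prom_with,
                            (fg_prom_total - fg_prom_with) +
                              (bg_prom_total - bg_prom_with),
                            fg_prom_total, lower.tail = FALSE)
  data.frame(fg_sites = fg_sites, fg_bp = fg_bp,
             bg_sites = bg_sites, bg_bp = bg_bp,
             fg_promoters_with_site = fg_prom_with,
             bg_promoters_with_site = bg_prom_with,
             or_freq = freq["or"], fe_adj_freq = freq["fe"],
             or_prom = prom["or"], fe_adj_prom = prom["fe"],
             binom_p = binom_p, fisher_p = fisher_p,
             row.names = NULL)
}

#' Run the full TFBS enrichment over a PWM set
#'
#' For every PWM: calibrate the score threshold on the background pool
#' (site frequency cap), scan foreground and background promoters, and
#' compute the enrichment record.  The log-odds background composition is
#' estimated from the background pool.
#'
#' @param pwm_set A `pwm_set`.
#' @param foreground,background Named sequence vectors (or `promoter_set`).
#' @param max_freq Background site-frequency cap per bp.
#' @param ci Confidence level of the adjusted fold enrichment.
#' @return data.frame, one row per scannable PWM, with `matrix_id`,
#'   `tf_name`, `threshold` and all [compute_enrichment()] columns;
#'   unscannable PWMs are reported in the `dropped` attribute.
#' @export
enrich_promoters <- function(pwm_set, foreground, background,
                             max_freq = 1 / 2000, ci = 0.99) {
  if (inherits(foreground, "promoter_set")) foreground <- foreground$seq
  if (inherits(background, "promoter_set")) background <- background$seq
  bg_comp <- .base_composition(background)
  rows <- list(); dropped <- character(0)
  for (p in pwm_set) {
    cal <- calibrate_threshold(p, background, max_freq = max_freq,
                               bg = bg_comp)
    if (!cal$ok) { dropped <- c(dropped, p$id); next }
    fg <- scan_promoters(p, foreground, cal$threshold, bg = bg_comp)
    bg <- scan_promoters(p, background, cal$threshold, bg = bg_comp)
    rec <- compute_enrichment(fg$total_sites, bg$total_sites,
                              fg$total_bp, bg$total_bp,
                              sum(fg$sites > 0), sum(bg$sites > 0),
                              length(fg$sites), length(bg$sites), ci = ci)
    rows[[p$id]] <- cbind(data.frame(matrix_id = p$id, tf_name = p$tf,
                                     threshold = cal$threshold,
                                     stringsAsFactors = FALSE), rec)
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(out)) stop("no scannable PWM")
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

.base_composition <- function(seqs) {
  tab <- table(factor(strsplit(paste(seqs, collapse = ""), "")[[1]],
                      levels = c("A", "C", "G", "T")))
  p <- as.numeric(tab) / sum(tab)
  pmax(p, 1e-6) / sum(pmax(p, 1e-6))
}

#' FDR, per-TF collapse and expressed-TF filter of enrichment records
#'
#' Benjamini-Hochberg FDR is computed over the retained PWMs (on the
#' binomial site-frequency p-value by default, before per-TF collapse);
#' significance requires both adjusted fold enrichments above 1 and
#' FDR below the threshold.  When a TF has several PWMs, the record with
#' the largest site-frequency adjusted fold enrichment is kept (ties broken
#' by smaller Fisher p, then lexicographic matrix id).  TFs that are not
#' expressed (TPM in the OP group at or below `tpm_threshold`) are dropped.
#'
#' @param records Output of [enrich_promoters()].
#' @param tf_expression_tpm Named vector: TF name -> TPM in the OP group.
#'   TFs missing from the table are dropped with a warning.
#' @param fdr_threshold Significance FDR gate.
#' @param tpm_threshold Expression gate (strictly greater than).
#' @param collapse_first If TRUE, collapse per TF before computing FDR.
#' @return data.frame sorted by decreasing `fe_adj_freq`, with `fdr` and
#'   `significant` columns.
#' @export
collapse_and_filter <- function(records, tf_expression_tpm,
                                fdr_threshold = 0.05, tpm_threshold = 1,
                                collapse_first = FALSE) {
  collapse <- function(df) {
    keep <- unlist(lapply(split(seq_len(nrow(df)), df$tf_name), function(i) {
      d <- df[i, ]
      o <- order(-d$fe_adj_freq, d$fisher_p, d$matrix_id)
      i[o[1]]
    }))
    df[sort(keep), , drop = FALSE]
  }
  df <- records
  if (collapse_first) {
    df <- collapse(df)
    df$fdr <- stats::p.adjust(df$binom_p, method = "BH")
  } else {
    df$fdr <- stats::p.adjust(df$binom_p, method = "BH")
    df <- collapse(df)
  }
  known <- df$tf_name %in% names(tf_expression_tpm)
  if (any(!known)) {
    warning("dropping TFs missing from the expression table: ",
            paste(df$tf_name[!known], collapse = ", "))
  }
  df <- df[known, , drop = FALSE]
  df$tpm_op <- as.numeric(tf_expression_tpm[df$tf_name])
  df <- df[df$tpm_op > tpm_threshold, , drop = FALSE]
  df$significant <- df$fe_adj_freq > 1 & df$fe_adj_prom > 1 &
    df$fdr < fdr_threshold
  df <- df[order(-df$fe_adj_freq), , drop = FALSE]
  rownames(df) <- NULL
  df
}
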