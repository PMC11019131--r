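#' Three-group study design with planted effect classes
#'
#' Defines the simulated study: group sizes (defaults mirror the three-arm
#' muscle cohort: 15 young healthy, 8 young patients, 37 older patients),
#' the per-gene effect class, the protein detection/regulation layer, and a
#' master seed.  Effect classes encode the two axes of the design:
#' "pathology" effects are shared by both patient groups relative to the
#' healthy controls (YP and OP shifted equally vs YH), while "primary
#' aging" effects separate the older patients from both young groups (OP
#' shifted vs both YH and YP).
#'
#' Classes are assigned deterministically in contiguous blocks whose sizes
#' follow `class_fractions`, so a given design is fully reproducible and
#' the planted gene lists are trivially recoverable.  The protein layer
#' flags a fraction of genes as detected at the protein level and assigns
#' each a regulation mode: `transcriptional` (protein tracks the mRNA
#' effect), `post_transcriptional_only` (protein-only effect, mRNA flat) or
#' `buffered` (mRNA effect, protein flat).
#'
#' @param n_genes Number of genes.
#' @param group_sizes Named integer vector of samples per group; each >= 2.
#' @param class_fractions Named proportions over
#'   `c("null","pathology_up","pathology_down","primary_up","primary_down")`;
#'   must sum to 1.
#' @param lfc_magnitude Planted effect size in log2 units for non-null classes.
#' @param dispersion NB dispersion alpha (scalar or per-gene), variance
#'   `mu + alpha * mu^2`; must be > 0.
#' @param protein_fraction Fraction of genes detected at the protein level.
#' @param protein_mode_fractions Named proportions over the three regulation
#'   modes for detected genes.
#' @param seed Master seed; per-stage child seeds are derived by fixed
#'   offsets so stages are independently reproducible.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_genes = 10000,
                         group_sizes = c(YH = 15, YP = 8, OP = 37),
                         class_fractions = c(null = 0.955,
                                             pathology_up = 0.015,
                                             pathology_down = 0.015,
                                             primary_up = 0.0075,
                                             primary_down = 0.0075),
                         lfc_magnitude = 1,
                         dispersion = 0.05,
                         protein_fraction = 0.25,
                         protein_mode_fractions = c(transcriptional = 0.5,
                                                    post_transcriptional_only = 0.3,
                                                    buffered = 0.2),
                         seed = 1L) {
  if (n_genes < 1) stop("n_genes must be positive")
  if (any(group_sizes < 2)) stop("every group needs at least 2 samples")
  if (any(class_fractions < 0) || any(class_fractions > 1) ||
      abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class_fractions must lie in [0,1] and sum to 1")
  }
  if (any(dispersion <= 0)) stop("dispersion must be > 0")
  if (protein_fraction < 0 || protein_fraction > 1) {
    stop("protein_fraction must lie in [0,1]")
  }
  classes <- c("null", "pathology_up", "pathology_down",
               "primary_up", "primary_down")
  frac <- stats::setNames(rep(0, length(classes)), classes)
  frac[names(class_fractions)] <- class_fractions
  # contiguous blocks; non-null classes get at least their rounded share,
  # the null class absorbs the remainder
  n_per <- round(frac[classes != "null"] * n_genes)
  if (sum(n_per) > n_genes) stop("non-null classes exceed n_genes")
  effect_class <- rep("null", n_genes)
  at <- 1L
  for (cl in names(n_per)) {
    k <- n_per[[cl]]
    if (k > 0) {
      effect_class[at:(at + k - 1L)] <- cl
      at <- at + k
    }
  }
  # protein layer: spread detection evenly over the gene list (every
  # 1/fraction-th gene) so each effect class is proportionally represented
  detected <- rep(FALSE, n_genes)
  if (protein_fraction > 0) {
    step <- 1 / protein_fraction
    detected[unique(pmin(n_genes, ceiling(seq(1, n_genes, by = step))))] <- TRUE
  }
  mf <- protein_mode_fractions / sum(protein_mode_fractions)
  mode <- rep(NA_character_, n_genes)
  idx <- which(detected)
  if (length(idx)) {
    # modes interleaved in a short repeating cycle so every effect class
    # carries all regulation modes in the requested proportions
    cyc <- 20L
    n_cyc <- round(mf * cyc)
    n_cyc[1] <- cyc - sum(n_cyc[-1])
    pattern <- rep(names(mf), n_cyc)
    mode[idx] <- pattern[((seq_along(idx) - 1L) %% cyc) + 1L]
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      group_sizes = group_sizes,
      effect_class = effect_class,
      lfc_magnitude = lfc_magnitude,
      dispersion = rep_len(dispersion, n_genes),
      detected_as_protein = detected,
      protein_mode = mode,
      seed = as.integer(seed)
    ),
    class = "study_design"
  )
}

.contrast_names <- c("YP_vs_YH", "OP_vs_YH", "OP_vs_YP")

#' Per-group log2 offsets implied by an effect class
#'
#' @param effect_class Character vector of classes.
#' @param lfc Planted log2 magnitude.
#' @return Matrix genes x groups (YH, YP, OP) of log2 offsets.
#' @keywords internal
.class_offsets <- function(effect_class, lfc) {
  off <- matrix(0, length(effect_class), 3,
                dimnames = list(NULL, c("YH", "YP", "OP")))
  off[effect_class == "pathology_up", c("YP", "OP")] <- lfc
  off[effect_class == "pathology_down", c("YP", "OP")] <- -lfc
  off[effect_class == "primary_up", "OP"] <- lfc
  off[effect_class == "primary_down", "OP"] <- -lfc
  off
}

.offsets_to_lfc <- function(off) {
  cbind(YP_vs_YH = off[, "YP"] - off[, "YH"],
        OP_vs_YH = off[, "OP"] - off[, "YH"],
        OP_vs_YP = off[, "OP"] - off[, "YP"])
}

#' Simulate an NB count matrix with planted pathology and primary-aging effects
#'
#' Counts are drawn `NB(mean = baseline * size_factor * 2^offset,
#' variance = mu + alpha mu^2)`.  Pathology classes shift YP and OP equally
#' relative to YH; primary classes shift OP relative to both young groups.
#' Genes whose protein regulation mode is `post_transcriptional_only` get no
#' mRNA effect (their planted change lives purely in the protein layer), so
#' their true mRNA log2 fold changes are 0.
#'
#' @param design A [study_design()].
#' @param baseline_range Range of per-gene baseline means, drawn log-uniform.
#' @param length_range Range of gene lengths in bp, drawn log-uniform.
#' @param size_factor_range Range of per-sample size factors, drawn
#'   log-uniform; `c(1, 1)` fixes all factors at 1.
#' @return A list with elements `counts` (a [count_matrix()]) and `truth`
#'   (a data.frame with one row per gene: effect class, protein mode,
#'   true mRNA and protein log2 fold change per contrast).
#' @export
simulate_counts <- function(design,
                            baseline_range = c(20, 5000),
                            length_range = c(500, 10000),
                            size_factor_range = c(0.7, 1.4)) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed + 1L)
  n <- design$n_genes
  groups <- rep(names(design$group_sizes), design$group_sizes)
  n_samp <- length(groups)
  baseline <- exp(stats::runif(n, log(baseline_range[1]), log(baseline_range[2])))
  lengths <- round(exp(stats::runif(n, log(length_range[1]), log(length_range[2]))))
  sf <- exp(stats::runif(n_samp, log(size_factor_range[1]),
                         log(size_factor_range[2])))
  off <- .class_offsets(design$effect_class, design$lfc_magnitude)
  # protein-only regulation leaves the mRNA untouched
  pt_only <- design$detected_as_protein &
    !is.na(design$protein_mode) &
    design$protein_mode == "post_transcriptional_only"
  off[pt_only, ] <- 0
  mu <- baseline * 2^off[, groups, drop = FALSE] *
    rep(sf, each = n)
  counts <- matrix(
    stats::rnbinom(n * n_samp, mu = mu, size = 1 / design$dispersion),
    nrow = n,
    dimnames = list(sprintf("gene_%05d", seq_len(n)),
                    sprintf("s%03d_%s", seq_len(n_samp), groups))
  )
  cm <- count_matrix(counts, lengths, groups)
  mrna_lfc <- .offsets_to_lfc(off)
  prot_off <- .class_offsets(design$effect_class, design$lfc_magnitude)
  buffered <- design$detected_as_protein &
    !is.na(design$protein_mode) & design$protein_mode == "buffered"
  prot_off[buffered | !design$detected_as_protein, ] <- 0
  prot_lfc <- .offsets_to_lfc(prot_off)
  truth <- data.frame(
    gene_id = rownames(counts),
    effect_class = design$effect_class,
    detected_as_protein = design$detected_as_protein,
    protein_mode = design$protein_mode,
    motif_planted = FALSE,
    stringsAsFactors = FALSE
  )
  for (ct in .contrast_names) truth[[paste0("mrna_lfc_", ct)]] <- mrna_lfc[, ct]
  for (ct in .contrast_names) truth[[paste0("prot_lfc_", ct)]] <- prot_lfc[, ct]
  list(counts = cm, truth = truth)
}

#' Simulate a TMT-style protein layer on top of simulated counts
#'
#' For every gene flagged `detected_as_protein`, log2 reporter intensity is
#' `baseline + group effect + batch offset + Gaussian noise`.  The group
#' effect depends on the gene's regulation mode: `transcriptional` tracks
#' the planted mRNA effect, `post_transcriptional_only` applies the class
#' effect to the protein only, and `buffered` has no protein effect at all.
#' Samples are split into two batches (emulating 10-plex and 16-plex TMT
#' kits) interleaved within each biological group so batch is not
#' confounded with group; batch-A intensities are multiplied by
#' `batch_ratio`.  A fraction of values is set missing completely at random.
#'
#' @param design The [study_design()] used for [simulate_counts()].
#' @param counts The `count_matrix` returned by [simulate_counts()] (used
#'   for the sample layout).
#' @param batch_ratio Global intensity ratio batch A / batch B.
#' @param noise_sd Gaussian noise sd on the log2 scale.
#' @param missing_fraction Fraction of values set missing at random.
#' @param batch_fraction Fraction of samples assigned to batch A.
#' @return A list with elements `proteins` (a [protein_matrix()]) and
#'   `protein_ids` (the gene ids carried into the protein layer).
#' @export
simulate_proteome <- function(design, counts,
                              batch_ratio = 2,
                              noise_sd = 0.3,
                              missing_fraction = 0.05,
                              batch_fraction = 10 / 26) {
  stopifnot(inherits(design, "study_design"), inherits(counts, "count_matrix"))
  if (missing_fraction < 0 || missing_fraction > 1) {
    stop("missing_fraction must lie in [0,1]")
  }
  set.seed(design$seed + 2L)
  det <- which(design$detected_as_protein)
  if (!length(det)) stop("design has no detected proteins")
  groups <- counts$groups
  n_samp <- length(groups)
  # interleave batches within each group
  batch <- character(n_samp)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    k <- round(length(idx) * batch_fraction)
    batch[idx] <- c(rep("A", k), rep("B", length(idx) - k))
  }
  off <- .class_offsets(design$effect_class, design$lfc_magnitude)[det, , drop = FALSE]
  mode <- design$protein_mode[det]
  off[mode == "buffered", ] <- 0
  # transcriptional and post_transcriptional_only both carry the class
  # effect at the protein level; they differ in the mRNA layer
  base_log2 <- stats::runif(length(det), 4, 12)
  log2_int <- base_log2 + off[, groups, drop = FALSE] +
    matrix(stats::rnorm(length(det) * n_samp, 0, noise_sd), length(det)) +
    matrix(rep(log2(batch_ratio) * (batch == "A"), each = length(det)),
           length(det))
  intens <- 2^log2_int
  if (missing_fraction > 0) {
    drop <- stats::runif(length(intens)) < missing_fraction
    intens[drop] <- NA_real_
  }
  rownames(intens) <- counts$gene_ids[det]
  colnames(intens) <- counts$sample_ids
  list(
    proteins = protein_matrix(intens, batch, groups),
    protein_ids = counts$gene_ids[det]
  )
}

#' Simulate promoter sequences with planted motif instances
#'
#' One promoter per gene: i.i.d. background with configurable GC content,
#' plus consensus-like instances of a chosen "planted" PWM inserted into the
#' promoters of a target gene set (default: the down-regulated primary-aging
#' genes) at a configurable per-promoter rate.  Each planted instance is
#' sampled position-by-position from the PWM probabilities and its
#' coordinates recorded, so insertions are retrievable by string search.
#'
#' @param truth Truth table from [simulate_counts()].
#' @param pwm_set A `pwm_set` (see [read_transfac()] / [random_pwm_set()]);
#'   the first matrix (or `planted_id`) is the planted TF.
#' @param length Promoter length in bp (>= 100).
#' @param gc Background GC fraction.
#' @param target_class Effect class whose promoters receive insertions.
#' @param planting_rate Probability that a target promoter receives one
#'   insertion.
#' @param planted_id Matrix id of the planted PWM; default the first.
#' @param seed Seed for the sequence generator.
#' @return An object of class `promoter_set`: list with `seq` (named
#'   character vector), `plant` (data.frame of insertions with 1-based
#'   coordinates), `length`.
#' @export
simulate_promoters <- function(truth, pwm_set, length = 500,
                               gc = 0.5,
                               target_class = "primary_down",
                               planting_rate = 1,
                               planted_id = NULL,
                               seed = 1L) {
  if (length < 100) stop("promoter length must be >= 100 bp")
  stopifnot(inherits(pwm_set, "pwm_set"))
  if (is.null(planted_id)) planted_id <- pwm_set[[1]]$id
  pwm <- pwm_set[[match(planted_id, vapply(pwm_set, `[[`, "", "id"))]]
  w <- ncol(pwm$prob)
  if (w > length) stop("motif longer than promoter")
  set.seed(seed)
  n <- nrow(truth)
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- c("A", "C", "G", "T")
  mat <- matrix(sample(bases, n * length, replace = TRUE, prob = base_p),
                nrow = n)
  targets <- which(truth$effect_class == target_class)
  planted <- targets[stats::runif(length(targets)) <= planting_rate]
  plant <- data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), motif = character(0))
  if (length(planted)) {
    starts <- sample.int(length - w + 1L, length(planted), replace = TRUE)
    motifs <- vapply(seq_along(planted), function(i) {
      paste(vapply(seq_len(w), function(j) {
        sample(bases, 1, prob = pwm$prob[, j])
      }, ""), collapse = "")
    }, "")
    for (i in seq_along(planted)) {
      mat[planted[i], starts[i]:(starts[i] + w - 1L)] <-
        strsplit(motifs[i], "")[[1]]
    }
    plant <- data.frame(gene_id = truth$gene_id[planted],
                        start = starts, end = starts + w - 1L,
                        motif = motifs, stringsAsFactors = FALSE)
  }
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- truth$gene_id
  structure(list(seq = seqs, plant = plant, length = length,
                 planted_id = planted_id),
            class = "promoter_set")
}

#' Generate a set of random informative PWMs
#'
#' Decoy/planted matrices for enrichment tests: each position has one
#' dominant base (weight `strength`) and uniform remainder, giving motifs
#' specific enough for a background-frequency threshold to exist.
#'
#' @param n Number of matrices.
#' @param width_range Inclusive range of motif widths.
#' @param strength Probability mass on the dominant base per position.
#' @param seed Seed.
#' @param prefix Matrix id / TF name prefix.
#' @return A `pwm_set`.
#' @export
random_pwm_set <- function(n, width_range = c(8, 12), strength = 0.85,
                           seed = 1L, prefix = "M") {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  widths <- seq(width_range[1], width_range[2])
  out <- lapply(seq_len(n), function(i) {
    w <- widths[sample.int(length(widths), 1)]
    prob <- matrix((1 - strength) / 3, 4, w, dimnames = list(bases, NULL))
    dom <- sample.int(4, w, replace = TRUE)
    for (j in seq_len(w)) prob[dom[j], j] <- strength
    counts <- round(prob * 100)
    new_pwm(id = sprintf("%s%04d", prefix, i),
            tf = sprintf("%sTF%04d", prefix, i),
            counts = counts)
  })
  structure(out, class = "pwm_set")
}

#' Write simulated inputs to plain-text fixture files
#'
#' Writes counts, gene lengths, sample sheet, protein intensities, promoter
#' FASTA and PWMs in TRANSFAC text format, plus a JSON manifest recording
#' the seed and parameters, so a run can be reproduced byte-identically.
#'
#' @param sim List with elements among `counts` (a `count_matrix`),
#'   `proteins` (a `protein_matrix`), `promoters` (a `promoter_set`),
#'   `pwms` (a `pwm_set`), `truth` (data.frame).
#' @param dir Output directory (created if needed).
#' @param params Named list of generation parameters stored in the manifest.
#' @return Invisibly, the manifest as a list.
#' @export
write_fixtures <- function(sim, dir, params = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(params = params, files = list())
  wr <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$files[[file]] <<- file
  }
  if (!is.null(sim$counts)) {
    cm <- sim$counts
    wr(data.frame(gene_id = cm$gene_ids, cm$counts, check.names = FALSE),
       "counts.tsv")
    wr(data.frame(gene_id = cm$gene_ids, length_bp = cm$gene_lengths),
       "lengths.tsv")
    ss <- data.frame(sample_id = cm$sample_ids, group = cm$groups)
    if (!is.null(sim$proteins)) ss$batch <- sim$proteins$batch[cm$sample_ids]
    wr(ss, "samples.tsv")
  }
  if (!is.null(sim$proteins)) {
    pm <- sim$proteins
    wr(data.frame(protein_id = pm$protein_ids, pm$intensities,
                  check.names = FALSE), "proteins.tsv")
  }
  if (!is.null(sim$truth)) wr(sim$truth, "truth.tsv")
  if (!is.null(sim$promoters)) {
    path <- file.path(dir, "promoters.fasta")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sim$promoters$seq), path, width = 80L)
    manifest$files[["promoters.fasta"]] <- "promoters.fasta"
  }
  if (!is.null(sim$pwms)) {
    write_transfac(sim$pwms, file.path(dir, "pwms.transfac"))
    manifest$files[["pwms.transfac"]] <- "pwms.transfac"
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
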