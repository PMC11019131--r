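#' Construct a gene-level count matrix container
#'
#' Bundles raw counts with the per-gene lengths and the sample-to-group
#' assignment that every downstream RNA stage needs.  Counts are genes x
#' samples, non-negative integers.
#'
#' @param counts Integer matrix, genes in rows, samples in columns.  Row and
#'   column names are used as gene and sample identifiers.
#' @param gene_lengths Numeric vector of gene lengths in bp, one per gene
#'   (recycled names checked against `rownames(counts)`).
#' @param groups Character or factor vector, one group label per sample.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `gene_lengths`, `groups`, `gene_ids`, `sample_ids`.
#' @export
count_matrix <- function(counts, gene_lengths, groups) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene_%05d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sample_%03d", seq_len(ncol(counts)))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (length(gene_lengths) != nrow(counts)) {
    stop("gene_lengths must have one entry per gene")
  }
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (length(groups) != ncol(counts)) {
    stop("groups must have one entry per sample")
  }
  groups <- as.character(groups)
  names(groups) <- colnames(counts)
  structure(
    list(
      counts = counts,
      gene_lengths = stats::setNames(as.numeric(gene_lengths), rownames(counts)),
      groups = groups,
      gene_ids = rownames(counts),
      sample_ids = colnames(counts)
    ),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("groups:", paste(sprintf("%s=%d", names(table(x$groups)),
                               table(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a protein reporter-intensity matrix container
#'
#' Proteins x samples reporter-ion intensities with the TMT kit (batch)
#' label and biological group of every sample.  Missing quantifications are
#' `NA`; present values must be positive.
#'
#' @param intensities Numeric matrix, proteins in rows, samples in columns;
#'   `NA` marks a protein not quantified in that sample.
#' @param batch Character vector, one batch label per sample (two batches,
#'   e.g. the 10-plex and 16-plex TMT kits).
#' @param groups Character vector, one group label per sample.
#' @return An object of class `protein_matrix`.
#' @export
protein_matrix <- function(intensities, batch, groups) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities))) {
    rownames(intensities) <- sprintf("prot_%05d", seq_len(nrow(intensities)))
  }
  if (any(intensities <= 0, na.rm = TRUE)) {
    stop("present intensities must be positive")
  }
  if (length(batch) != ncol(intensities) || length(groups) != ncol(intensities)) {
    stop("batch and groups must have one entry per sample")
  }
  batch <- stats::setNames(as.character(batch), colnames(intensities))
  groups <- stats::setNames(as.character(groups), colnames(intensities))
  structure(
    list(
      intensities = intensities,
      batch = batch,
      groups = groups,
      protein_ids = rownames(intensities),
      sample_ids = colnames(intensities)
    ),
    class = "protein_matrix"
  )
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat("protein_matrix:", nrow(x$intensities), "proteins x",
      ncol(x$intensities), "samples;",
      sprintf("%.1f%% present\n", 100 * mean(!is.na(x$intensities))))
  invisible(x)
}

#' Read a count matrix from TSV files
#'
#' @param counts_path TSV with a `gene_id` column and one column per sample.
#' @param lengths_path TSV with columns `gene_id`, `length_bp`.
#' @param samples_path TSV with columns `sample_id`, `group` (and optionally
#'   `batch`, ignored here).
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, lengths_path, samples_path) {
  cts <- utils::read.delim(counts_path, check.names = FALSE)
  lens <- utils::read.delim(lengths_path, check.names = FALSE)
  ss <- utils::read.delim(samples_path, check.names = FALSE)
  m <- as.matrix(cts[, setdiff(colnames(cts), "gene_id"), drop = FALSE])
  rownames(m) <- cts$gene_id
  m <- m[, ss$sample_id, drop = FALSE]
  lens <- lens[match(cts$gene_id, lens$gene_id), ]
  count_matrix(m, lens$length_bp, ss$group)
}

#' Read a protein intensity matrix from TSV files
#'
#' @param proteins_path TSV with a `protein_id` column and one column per
#'   sample; empty cells are missing values.
#' @param samples_path TSV with columns `sample_id`, `group`, `batch`.
#' @return A [protein_matrix()].
#' @export
read_protein_matrix <- function(proteins_path, samples_path) {
  pm <- utils::read.delim(proteins_path, check.names = FALSE)
  ss <- utils::read.delim(samples_path, check.names = FALSE)
  if (is.null(ss$batch)) stop("sample sheet must have a batch column")
  m <- as.matrix(pm[, setdiff(colnames(pm), "protein_id"), drop = FALSE])
  rownames(m) <- pm$protein_id
  m <- m[, ss$sample_id, drop = FALSE]
  protein_matrix(m, ss$batch, ss$group)
}
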