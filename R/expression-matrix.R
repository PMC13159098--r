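#' Gene-by-sample expression matrix with a normalization state
#'
#' Lightweight container used throughout the package. Rows are genes, columns
#' are samples (bulk samples or Visium-style spots). The `state` tag records
#' which normalization has been applied so that downstream operations can
#' refuse inputs in the wrong state.
#'
#' @param values Numeric gene x sample matrix, non-negative. Row names are
#'   gene ids, column names sample/spot ids; both are required and gene ids
#'   must be unique.
#' @param state One of `"raw_counts"`, `"tpm"`, `"cpm"`, `"log2p1"`.
#' @param gene_lengths Optional named numeric vector of per-gene lengths in
#'   bases (required later for TPM conversion).
#' @param zero_cols Optional logical vector flagging columns that were
#'   all-zero in the raw counts (kept as zeros under TPM/CPM).
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, state = "raw_counts", gene_lengths = NULL,
                        zero_cols = NULL) {
  states <- c("raw_counts", "tpm", "cpm", "log2p1")
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || (ncol(values) > 0 && is.null(colnames(values))))
    stop("`values` must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("gene ids must be unique")
  if (any(values < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  state <- match.arg(state, states)
  if (!is.null(gene_lengths)) {
    gene_lengths <- gene_lengths[rownames(values)]
    if (anyNA(gene_lengths) || any(gene_lengths <= 0))
      stop("gene_lengths must be positive for every gene in the matrix")
  }
  if (is.null(zero_cols)) zero_cols <- colSums(values) == 0
  structure(
    list(values = values, state = state, gene_lengths = gene_lengths,
         zero_cols = zero_cols),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, state=%s, %d zero column(s)\n",
              nrow(x$values), ncol(x$values), x$state, sum(x$zero_cols)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

gene_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

stopifnot_state <- function(m, wanted) {
  if (!inherits(m, "expr_matrix")) stop("expected an `expr_matrix`")
  if (!m$state %in% wanted)
    stop(sprintf("expression matrix has state '%s'; expected %s",
                 m$state, paste(sQuote(wanted), collapse = " or ")))
}

#' Convert raw counts to transcripts per million (TPM)
#'
#' Counts are first divided by gene length in kilobases (a length-normalized
#' rate), then each column is rescaled to sum to one million. Columns that
#' were all-zero in the raw counts stay all-zero and are flagged in
#' `zero_cols` rather than becoming NaN.
#'
#' @param m An `expr_matrix` in state `raw_counts`.
#' @param lengths Named numeric vector of gene lengths in bases; must cover
#'   every gene of `m`. Defaults to `m$gene_lengths`.
#' @return An `expr_matrix` in state `tpm`.
#' @export
counts_to_tpm <- function(m, lengths = m$gene_lengths) {
  stopifnot_state(m, "raw_counts")
  if (is.null(lengths)) stop("TPM conversion requires per-gene lengths")
  lengths <- lengths[gene_ids(m)]
  bad <- gene_ids(m)[is.na(lengths) | lengths <= 0]
  if (length(bad))
    stop("missing or non-positive length for gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  rate <- m$values / (lengths / 1000)
  tot <- colSums(rate)
  zero <- tot == 0
  tot[zero] <- 1  # keep all-zero columns as zeros
  out <- sweep(rate, 2, tot, "/") * 1e6
  expr_matrix(out, "tpm", gene_lengths = lengths, zero_cols = zero)
}

#' Convert raw counts to counts per million (CPM)
#'
#' Each column is scaled so its sum is one million. All-zero columns are
#' preserved as zeros and flagged.
#'
#' @param m An `expr_matrix` in state `raw_counts`.
#' @return An `expr_matrix` in state `cpm`.
#' @export
counts_to_cpm <- function(m) {
  stopifnot_state(m, "raw_counts")
  tot <- colSums(m$values)
  zero <- tot == 0
  tot[zero] <- 1
  out <- sweep(m$values, 2, tot, "/") * 1e6
  expr_matrix(out, "cpm", zero_cols = zero)
}

#' Build a pseudo-bulk CPM profile from spot counts
#'
#' Sums raw spot counts gene-wise over all spots of a slide, then converts
#' the summed vector to CPM. Used as the slide-level (bulk-scale) target for
#' spatial samples.
#'
#' @param spots An `expr_matrix` of raw spot counts (genes x spots).
#' @return Named numeric vector (per-gene CPM) summing to 1e6.
#' @export
make_pseudobulk <- function(spots) {
  stopifnot_state(spots, "raw_counts")
  if (ncol(spots$values) < 1) stop("pseudo-bulk requires at least one spot")
  tot <- rowSums(spots$values)
  s <- sum(tot)
  if (s == 0) stop("all spots are empty; pseudo-bulk undefined")
  tot / s * 1e6
}

#' Log-transform normalized expression
#'
#' Applies `v -> log2(v + 1)` elementwise, bringing TPM and CPM values into a
#' comparable dynamic range for joint MSE training.
#'
#' @param m An `expr_matrix` in state `tpm` or `cpm`.
#' @return An `expr_matrix` in state `log2p1`.
#' @export
log_transform <- function(m) {
  stopifnot_state(m, c("tpm", "cpm"))
  if (any(m$values < 0)) stop("negative values cannot be log-transformed")
  expr_matrix(log2(m$values + 1), "log2p1", gene_lengths = m$gene_lengths,
              zero_cols = m$zero_cols)
}

#' Filter spots by the number of quantified genes
#'
#' Retains spots (columns) with at least `min_genes` genes detected
#' (value > 0). The boundary is inclusive: a spot with exactly `min_genes`
#' detected genes is kept. Column order is preserved.
#'
#' @param spots An `expr_matrix` (any state; detection is value > 0).
#' @param min_genes Minimum number of detected genes per spot (default 100).
#' @return A filtered `expr_matrix`; may have zero columns.
#' @export
filter_spots <- function(spots, min_genes = 100) {
  if (!inherits(spots, "expr_matrix")) stop("expected an `expr_matrix`")
  keep <- colSums(spots$values > 0) >= min_genes
  out <- spots$values[, keep, drop = FALSE]
  expr_matrix(out, spots$state, gene_lengths = spots$gene_lengths,
              zero_cols = spots$zero_cols[keep])
}

#' Restrict an expression matrix to protein-coding genes
#'
#' The coding-gene id set is supplied by the user; no annotation is bundled.
#' Gene order is preserved.
#'
#' @param m An `expr_matrix`.
#' @param coding_ids Character vector of gene ids to keep.
#' @return The filtered `expr_matrix`.
#' @export
restrict_to_protein_coding <- function(m, coding_ids) {
  if (!inherits(m, "expr_matrix")) stop("expected an `expr_matrix`")
  keep <- gene_ids(m) %in% coding_ids
  if (!any(keep)) stop("no genes of the matrix are in `coding_ids`")
  expr_matrix(m$values[keep, , drop = FALSE], m$state,
              gene_lengths = m$gene_lengths[keep],
              zero_cols = m$zero_cols)
}
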