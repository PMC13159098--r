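#' Select the image-predictable target-gene panel
#'
#' Scores every gene at each data level (bulk and spot) by its strongest
#' linear association with the image-derived features, ranks genes within
#' each level, averages the two ranks, and keeps the top `K` genes.
#'
#' The per-gene, per-level score is the maximum absolute Pearson correlation
#' between the gene's expression and any single feature dimension
#' (`score_fun = "max_abs"`, the default), or the mean of the top
#' `top_k_dims` absolute correlations (`score_fun = "mean_top_k"`). Ranks are
#' assigned with 1 = highest score and ties receive the average rank; the
#' two level ranks are averaged and the K genes with the best (smallest)
#' mean rank are selected, final ties broken by lexicographic gene id.
#'
#' @param bulk `expr_matrix` of bulk expression (genes x samples), typically
#'   log2(TPM+1).
#' @param bulk_features Numeric sample x d matrix of per-sample image
#'   features (rows aligned with `bulk` columns).
#' @param spot `expr_matrix` of spot expression (genes x spots), typically
#'   log2(CPM+1).
#' @param spot_features Numeric spot x d matrix aligned with `spot` columns.
#' @param K Panel size (default 1000).
#' @param score_fun `"max_abs"` or `"mean_top_k"`.
#' @param top_k_dims Number of dimensions averaged under `"mean_top_k"`.
#' @return A `gene_selection` object: a data frame with columns `gene_id`,
#'   `score_bulk`, `score_spot`, `rank_bulk`, `rank_spot`, `mean_rank`,
#'   `selected`, ordered by mean rank, plus attribute `K`.
#' @export
select_target_genes <- function(bulk, bulk_features, spot, spot_features,
                                K = 1000, score_fun = c("max_abs", "mean_top_k"),
                                top_k_dims = 5) {
  score_fun <- match.arg(score_fun)
  genes <- intersect(gene_ids(bulk), gene_ids(spot))
  if (K > length(genes))
    stop(sprintf("K = %d exceeds the %d genes common to both levels",
                 K, length(genes)))
  sb <- gene_feature_scores(bulk$values[genes, , drop = FALSE], bulk_features,
                            score_fun, top_k_dims)
  ss <- gene_feature_scores(spot$values[genes, , drop = FALSE], spot_features,
                            score_fun, top_k_dims)
  # rank 1 = highest score; ties get the average rank within a level
  rb <- rank(-sb, ties.method = "average")
  rs <- rank(-ss, ties.method = "average")
  mr <- (rb + rs) / 2
  ord <- order(mr, genes)  # lexicographic gene-id tie-break
  sel <- data.frame(
    gene_id = genes[ord],
    score_bulk = sb[ord], score_spot = ss[ord],
    rank_bulk = rb[ord], rank_spot = rs[ord],
    mean_rank = mr[ord],
    selected = seq_along(genes) <= K,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(sel, "K") <- K
  class(sel) <- c("gene_selection", class(sel))
  sel
}

# Max (or mean-top-k) absolute Pearson correlation of each gene (rows of
# `expr`) against the feature dimensions (columns of `features`). Constant
# genes or feature dimensions yield correlation 0 with one warning.
gene_feature_scores <- function(expr, features, score_fun, top_k_dims) {
  if (ncol(expr) != nrow(features))
    stop("expression columns and feature rows must align")
  cc <- suppressWarnings(stats::cor(t(expr), features))
  if (anyNA(cc)) {
    warning("constant gene or feature columns; their correlations set to 0")
    cc[is.na(cc)] <- 0
  }
  a <- abs(cc)
  if (score_fun == "max_abs") {
    s <- apply(a, 1, max)
  } else {
    k <- min(top_k_dims, ncol(a))
    s <- apply(a, 1, function(r) mean(sort(r, decreasing = TRUE)[seq_len(k)]))
  }
  names(s) <- rownames(expr)
  s
}

#' Write a gene selection table to TSV
#' @param sel A `gene_selection`.
#' @param path Output file.
#' @export
write_gene_selection <- function(sel, path) {
  utils::write.table(as.data.frame(sel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene selection table written by [write_gene_selection()]
#' @param path TSV file.
#' @return A `gene_selection` data frame.
#' @export
read_gene_selection <- function(path) {
  sel <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  attr(sel, "K") <- sum(sel$selected)
  class(sel) <- c("gene_selection", class(sel))
  sel
}
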