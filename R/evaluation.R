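#' Per-gene prediction accuracy metrics
#'
#' For each gene, computes the Pearson correlation (with a two-sided p-value
#' from the t approximation), and the mean squared error, over predictions
#' and ground truth concatenated across all samples (or spots). A gene is
#' called well-predicted when its correlation strictly exceeds the
#' scale-specific threshold — 0.4 at the bulk level, 0.2 at the spot level —
#' with p strictly below 0.05. Genes that are constant in either vector get
#' r = 0 with a degenerate flag and are excluded from the summary median.
#'
#' @param pred samples x G predicted matrix.
#' @param truth samples x G ground-truth matrix (same shape, same gene
#'   order; column names are used as gene ids when present).
#' @param level `"bulk"` or `"spot"` (selects the well-predicted threshold).
#' @return An `eval_report`: data frame with columns `gene_id`, `pearson_r`,
#'   `p_value`, `mse`, `degenerate`, `well_predicted`; attributes `level`,
#'   `median_r` (over non-degenerate genes), `frac_well_predicted`.
#' @export
per_gene_metrics <- function(pred, truth, level = c("bulk", "spot")) {
  level <- match.arg(level)
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth must have identical dimensions")
  n <- nrow(pred); G <- ncol(pred)
  if (n < 3) stop("at least 3 samples are needed for per-gene p-values")
  r_thr <- if (level == "bulk") 0.4 else 0.2
  ids <- colnames(truth) %||% paste0("gene", seq_len(G))
  r <- numeric(G); p <- numeric(G); mse <- numeric(G); degen <- logical(G)
  for (g in seq_len(G)) {
    x <- pred[, g]; y <- truth[, g]
    mse[g] <- mean((x - y)^2)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      r[g] <- 0; p[g] <- 1; degen[g] <- TRUE
    } else {
      r[g] <- stats::cor(x, y)
      tt <- r[g] * sqrt((n - 2) / max(1 - r[g]^2, .Machine$double.eps))
      p[g] <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
  }
  wp <- !degen & r > r_thr & p < 0.05
  rep_df <- data.frame(gene_id = ids, pearson_r = r, p_value = p, mse = mse,
                       degenerate = degen, well_predicted = wp,
                       stringsAsFactors = FALSE)
  attr(rep_df, "level") <- level
  attr(rep_df, "median_r") <- stats::median(r[!degen])
  attr(rep_df, "frac_well_predicted") <- mean(wp)
  class(rep_df) <- c("eval_report", class(rep_df))
  rep_df
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> level=%s, %d genes: median r = %.3f, %.1f%% well-predicted\n",
              attr(x, "level"), nrow(x), attr(x, "median_r"),
              100 * attr(x, "frac_well_predicted")))
  invisible(x)
}

#' Area under the ROC curve by the rank (Mann-Whitney) formula
#'
#' Ties in the scores receive midranks, so `auc(s, l) + auc(-s, l) = 1`.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1 or logical); both classes must occur.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both label classes must be present")
  rk <- rank(scores, ties.method = "average")
  (sum(rk[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bulk-spot expression similarity AUC
#'
#' Quantifies whether predicted spot profiles rank spots by their similarity
#' to bulk profiles the same way ground truth does. For n spots and m bulk
#' samples: (1) all n x m Pearson correlations between predicted spot and
#' predicted bulk expression profiles; (2) each spot's correlations are
#' averaged over the bulk samples, giving predicted spot scores; (3) the
#' same on ground-truth expression gives true spot scores; (4) spots are
#' labeled 1 when their true score strictly exceeds the median of the true
#' scores (ties at the median are labeled 0); (5) the AUC of the predicted
#' scores against those labels is computed by the rank formula with
#' midranks.
#'
#' @param pred_spot n x G predicted spot expression.
#' @param pred_bulk m x G predicted bulk expression.
#' @param true_spot,true_bulk Ground-truth matrices of the same shapes.
#' @return A `similarity_result`: list with `corr_matrix` (n x m, from the
#'   predictions), `spot_scores`, `true_scores`, `labels`, `auc`.
#' @export
bulk_spot_similarity_auc <- function(pred_spot, pred_bulk, true_spot,
                                     true_bulk) {
  mats <- list(pred_spot, pred_bulk, true_spot, true_bulk)
  if (nrow(pred_spot) < 2 || nrow(pred_bulk) < 2)
    stop("need at least 2 spots and 2 bulk samples")
  if (length(unique(vapply(mats, ncol, integer(1)))) != 1)
    stop("all matrices must share one gene panel")
  cor_rows <- function(A, B) {
    # n x m correlations between rows of A and rows of B; constant rows -> 0
    cc <- suppressWarnings(stats::cor(t(A), t(B)))
    flagged <- anyNA(cc)
    cc[is.na(cc)] <- 0
    attr(cc, "degenerate") <- flagged
    cc
  }
  cm_pred <- cor_rows(pred_spot, pred_bulk)
  cm_true <- cor_rows(true_spot, true_bulk)
  if (isTRUE(attr(cm_pred, "degenerate")) || isTRUE(attr(cm_true, "degenerate")))
    warning("constant expression profiles; their correlations set to 0")
  pred_scores <- rowMeans(cm_pred)
  true_scores <- rowMeans(cm_true)
  labels <- as.integer(true_scores > stats::median(true_scores))
  structure(list(corr_matrix = cm_pred, spot_scores = pred_scores,
                 true_scores = true_scores, labels = labels,
                 auc = rank_auc(pred_scores, labels)),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> %d spots x %d bulk samples: AUC = %.3f\n",
              nrow(x$corr_matrix), ncol(x$corr_matrix), x$auc))
  invisible(x)
}

#' Write an evaluation report as TSV plus a JSON summary
#' @param report An `eval_report`.
#' @param path Output TSV; a `.summary.json` file is written alongside.
#' @export
write_eval_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(level = attr(report, "level"), n_genes = nrow(report),
         median_r = attr(report, "median_r"),
         frac_well_predicted = attr(report, "frac_well_predicted")),
    paste0(path, ".summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
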