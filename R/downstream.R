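#' Apply a fitted proportional-hazards risk signature
#'
#' The risk score of a sample is the weighted sum of its expression over the
#' signature genes, `sum_i C_i * Exp_i`, where the coefficients come from an
#' externally fitted penalized Cox model (fitting is out of scope here; see
#' e.g. `glmnet::cv.glmnet(..., family = "cox")`).
#'
#' @param expr samples x genes expression matrix with gene column names.
#' @param model List (or data frame) with `gene_ids` and `coefficients`.
#' @return Named numeric vector of per-sample risk scores.
#' @export
risk_score <- function(expr, model) {
  expr <- as.matrix(expr)
  genes <- model$gene_ids %||% model$gene_id
  coefs <- model$coefficients %||% model$coefficient
  if (length(genes) != length(coefs)) stop("model genes/coefficients mismatch")
  missing <- setdiff(genes, colnames(expr))
  if (length(missing))
    stop("model gene(s) absent from expression: ",
         paste(missing, collapse = ", "))
  drop(expr[, genes, drop = FALSE] %*% coefs)
}

#' Stratify samples by the median score
#'
#' Samples scoring strictly above the median are labeled `"high"`, all
#' others (including ties at the median) `"low"`.
#'
#' @param scores Numeric vector (length >= 2, not all equal).
#' @return Factor with levels `low`, `high`.
#' @export
stratify_by_median <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 samples to stratify")
  if (length(unique(scores)) == 1)
    stop("all scores equal; median stratification undefined")
  med <- stats::median(scores)
  factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
}

#' Binarize tumor stage
#'
#' Normalizes stage annotations (case, `"Stage "` prefixes, sub-stage
#' letters such as `IIA`) to the Roman numerals I-IV, then groups stages
#' I-II as `"low"` and III-IV as `"high"`.
#'
#' @param stages Character (or factor) vector of stage annotations.
#' @return Factor with levels `low`, `high`.
#' @export
binarize_stage <- function(stages) {
  s <- toupper(trimws(as.character(stages)))
  s <- sub("^STAGE\\s*", "", s)
  s <- sub("^(IV|III|II|I)[ABC]?$", "\\1", s)
  bad <- !s %in% c("I", "II", "III", "IV")
  if (any(bad))
    stop("unparseable stage value(s): ",
         paste(unique(stages[bad]), collapse = ", "))
  factor(ifelse(s %in% c("I", "II"), "low", "high"), levels = c("low", "high"))
}

#' Rank-based differential expression with an FDR and fold-change filter
#'
#' Per gene, a Wilcoxon signed-rank test (paired groups) or rank-sum test
#' (independent groups) compares the two groups; p-values are adjusted by
#' Benjamini-Hochberg. The fold change is the ratio of group means on the
#' linear scale (log2(x+1) data is de-logged first when
#' `data_scale = "log2p1"`). A gene is called differentially expressed when
#' FDR < 0.05 and the fold change exceeds 1.25 in either direction (above
#' 1.25 up, below 1/1.25 down).
#'
#' @param groupA,groupB samples x genes matrices with matching gene columns.
#' @param paired Use the signed-rank test over sample pairs (rows aligned).
#' @param data_scale `"log2p1"` (values are log2(x+1); de-logged for fold
#'   change) or `"linear"`.
#' @param fdr_cutoff,fc_cutoff Call thresholds (defaults 0.05 and 1.25).
#' @return Data frame: `gene_id`, `statistic`, `p`, `fdr`, `fold_change`,
#'   `direction` (`up` = higher in A, `down`, or `ns`), `de` (logical).
#' @export
de_genes <- function(groupA, groupB, paired = FALSE,
                     data_scale = c("log2p1", "linear"),
                     fdr_cutoff = 0.05, fc_cutoff = 1.25) {
  data_scale <- match.arg(data_scale)
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (ncol(groupA) != ncol(groupB)) stop("gene panels differ between groups")
  if (paired && nrow(groupA) != nrow(groupB))
    stop("paired test requires equal sample counts")
  if (nrow(groupA) < 3 || nrow(groupB) < 3)
    stop("need at least 3 samples (or pairs) per group")
  Gn <- ncol(groupA)
  ids <- colnames(groupA) %||% paste0("gene", seq_len(Gn))
  delog <- function(m) if (data_scale == "log2p1") 2^m - 1 else m
  linA <- delog(groupA); linB <- delog(groupB)
  stat <- numeric(Gn); p <- numeric(Gn); fc <- numeric(Gn)
  for (g in seq_len(Gn)) {
    a <- groupA[, g]; b <- groupB[, g]
    wt <- suppressWarnings(
      if (paired) stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
      else stats::wilcox.test(a, b, exact = FALSE))
    stat[g] <- unname(wt$statistic)
    p[g] <- if (is.na(wt$p.value)) 1 else wt$p.value
    eps <- 1e-9
    fc[g] <- (mean(linA[, g]) + eps) / (mean(linB[, g]) + eps)
  }
  fdr <- stats::p.adjust(p, method = "BH")
  dir_ <- de_filter(fdr, fc, fdr_cutoff, fc_cutoff)
  data.frame(gene_id = ids, statistic = stat, p = p, fdr = fdr,
             fold_change = fc, direction = dir_, de = dir_ != "ns",
             stringsAsFactors = FALSE)
}

#' Differential-expression call rule
#'
#' Applies the joint filter: a gene is called when FDR < `fdr_cutoff` and
#' its fold change exceeds `fc_cutoff` (up) or falls below `1/fc_cutoff`
#' (down).
#'
#' @param fdr,fc Vectors of adjusted p-values and linear-scale fold changes.
#' @param fdr_cutoff,fc_cutoff Thresholds (defaults 0.05 and 1.25).
#' @return Character vector: `"up"`, `"down"`, or `"ns"`.
#' @export
de_filter <- function(fdr, fc, fdr_cutoff = 0.05, fc_cutoff = 1.25) {
  up <- fdr < fdr_cutoff & fc > fc_cutoff
  down <- fdr < fdr_cutoff & fc < 1 / fc_cutoff
  ifelse(up, "up", ifelse(down, "down", "ns"))
}

#' Meta-program definitions of transcriptional intratumor heterogeneity
#'
#' Builds the meta-program gene-set container used by
#' [metaprogram_spatial_correlation()]. The four recurrent programs are cell
#' cycle, stress/hypoxia, mesenchymal, and protein regulation; gene ids are
#' supplied by the user and intersected with the prediction panel.
#'
#' @param programs Named list of character vectors (program -> gene ids).
#' @param panel Optional character vector restricting each program.
#' @return Named list of non-empty gene-id vectors.
#' @export
meta_programs <- function(programs, panel = NULL) {
  if (!is.null(panel))
    programs <- lapply(programs, intersect, y = panel)
  empty <- names(programs)[vapply(programs, length, integer(1)) == 0]
  if (length(empty))
    stop("meta-program(s) empty after intersecting with the panel: ",
         paste(empty, collapse = ", "))
  programs
}

#' Cross-sample spatial co-expression of meta-program genes
#'
#' For every slide, the spot-level predictions of each program gene are
#' flattened to a 1D array and all pairwise Pearson correlations among the
#' program genes are computed over that slide's spots; the per-slide
#' matrices are averaged into a cross-sample spatial correlation matrix.
#' Hierarchical clustering (average linkage on the correlation distance
#' 1 - r) groups genes with similar spatial patterns.
#'
#' @param spot_preds List of per-slide spot x gene prediction matrices with
#'   gene column names.
#' @param programs Named list from [meta_programs()].
#' @param k Number of clusters cut from the dendrogram (default:
#'   `length(programs)`).
#' @return List with `correlation` (gene x gene averaged matrix), `hclust`,
#'   `clusters` (named integer vector), `membership` (gene -> program),
#'   `degenerate` (genes constant on every slide, rows/cols set to 0).
#' @export
metaprogram_spatial_correlation <- function(spot_preds, programs,
                                            k = length(programs)) {
  if (length(spot_preds) == 0) stop("need at least one slide")
  genes <- unique(unlist(programs))
  genes <- genes[genes %in% Reduce(intersect, lapply(spot_preds, colnames))]
  if (length(genes) < 2)
    stop("fewer than 2 program genes present in the prediction panel")
  acc <- matrix(0, length(genes), length(genes),
                dimnames = list(genes, genes))
  cnt <- acc
  for (sl in spot_preds) {
    m <- sl[, genes, drop = FALSE]
    cc <- suppressWarnings(stats::cor(m))
    ok <- !is.na(cc)
    acc[ok] <- acc[ok] + cc[ok]
    cnt <- cnt + ok
  }
  avg <- ifelse(cnt > 0, acc / pmax(cnt, 1), 0)
  degenerate <- genes[diag(cnt) == 0]
  avg[cnt == 0] <- 0
  diag(avg) <- ifelse(diag(cnt) > 0, 1, 0)
  hc <- stats::hclust(stats::as.dist(1 - avg), method = "average")
  clusters <- stats::cutree(hc, k = k)
  membership <- unlist(lapply(names(programs), function(p)
    stats::setNames(rep(p, length(programs[[p]])), programs[[p]])))
  membership <- membership[genes]
  list(correlation = avg, hclust = hc, clusters = clusters,
       membership = membership, degenerate = degenerate)
}

#' Phenotype-association selection fractions
#'
#' Configuration constants for external phenotype-linked cell-selection
#' tools: the fraction of spots selected for the binary tumor/normal
#' phenotype (3%) and of cancer spots for the recurrence phenotype (10%).
#' Shipped for interoperability; no selection algorithm is implemented here.
#' @export
scissor_fractions <- c(tumor_normal = 0.03, recurrence = 0.10)
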