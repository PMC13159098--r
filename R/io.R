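# Readers and writers for the pipeline's on-disk formats.
#
# Conventions stated in every sidecar: coordinates are 0-based pixel units,
# x = column, y = row; intervals are half-open.

#' Write an expression matrix as dense TSV
#'
#' Genes as rows (first column `gene_id`), samples as header columns.
#' @param m An `expr_matrix`.
#' @param path Output file.
#' @export
write_expr_tsv <- function(m, path) {
  df <- data.frame(gene_id = gene_ids(m), m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dense TSV expression matrix
#' @param path TSV written by [write_expr_tsv()] (or any genes x samples
#'   table with a `gene_id` first column).
#' @param state Normalization state tag of the stored values.
#' @return An `expr_matrix`.
#' @export
read_expr_tsv <- function(path, state = "raw_counts") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  expr_matrix(v, state)
}

#' Write an expression matrix as an MTX triplet
#'
#' Writes `<prefix>matrix.mtx` with `<prefix>genes.tsv` and
#' `<prefix>barcodes.tsv` companions.
#' @param m An `expr_matrix`.
#' @param dir Output directory (created if missing).
#' @param prefix Optional filename prefix.
#' @export
write_expr_mtx <- function(m, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE),
                  file.path(dir, paste0(prefix, "matrix.mtx")))
  writeLines(gene_ids(m), file.path(dir, paste0(prefix, "genes.tsv")))
  writeLines(sample_ids(m), file.path(dir, paste0(prefix, "barcodes.tsv")))
  invisible(dir)
}

#' Read an MTX triplet written by [write_expr_mtx()]
#' @param dir Directory holding the triplet.
#' @param prefix Filename prefix used at write time.
#' @param state Normalization state tag.
#' @return An `expr_matrix`.
#' @export
read_expr_mtx <- function(dir, prefix = "", state = "raw_counts") {
  v <- as.matrix(Matrix::readMM(file.path(dir, paste0(prefix, "matrix.mtx"))))
  rownames(v) <- readLines(file.path(dir, paste0(prefix, "genes.tsv")))
  colnames(v) <- readLines(file.path(dir, paste0(prefix, "barcodes.tsv")))
  expr_matrix(v, state)
}

#' Write a patch-embedding sequence (binary array + JSON sidecar)
#'
#' The embeddings are stored as little-endian doubles in row-major order;
#' the `.json` sidecar records slide id, dimensions, ordering convention,
#' encoder name, patch size and per-patch coordinates.
#' @param seq A [patch_sequence()].
#' @param path Output binary file (sidecar at `<path>.json`).
#' @param encoder_name Name recorded in the sidecar.
#' @export
write_embeddings <- function(seq, path, encoder_name = "unknown") {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(seq$embeddings)), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(slide_id = seq$slide_id, n = nrow(seq$embeddings),
         d = ncol(seq$embeddings), ordering = seq$ordering,
         encoder = encoder_name, patch_size = seq$patch_size,
         level_tag = seq$level_tag,
         coordinate_convention = "0-based pixels, x=column, y=row, half-open",
         coords = unname(apply(seq$coords, 1, as.list))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a patch-embedding sequence written by [write_embeddings()]
#' @param path Binary file with its `.json` sidecar.
#' @return A [patch_sequence()].
#' @export
read_embeddings <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  n <- meta$n; d <- meta$d
  v <- readBin(path, "double", n * d, size = 8, endian = "little")
  emb <- matrix(v, n, d, byrow = TRUE)
  coords <- do.call(rbind, lapply(meta$coords, function(cc)
    c(as.numeric(cc[[1]]), as.numeric(cc[[2]]))))
  patch_sequence(emb, coords, patch_size = meta$patch_size,
                 level_tag = meta$level_tag, slide_id = meta$slide_id,
                 ordering = meta$ordering)
}

#' Read a Visium-style tissue-positions table
#'
#' Expects the columns `barcode`, `in_tissue`, `array_row`, `array_col`,
#' `pixel_row`, `pixel_col` (TSV or CSV, with header).
#' @param path Positions file.
#' @return Data frame of the positions.
#' @export
read_spot_positions <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("barcode", "in_tissue", "array_row", "array_col", "pixel_row",
            "pixel_col")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("positions file lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write a Visium-style tissue-positions table
#' @param df Data frame with the standard columns.
#' @param path Output TSV.
#' @export
write_spot_positions <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Every CLI artifact directory carries a manifest naming the command, the
#' seed, the configuration, input paths with md5 checksums, the package
#' version, and a timestamp.
#' @param path Output JSON file.
#' @param command Subcommand name.
#' @param config Configuration list (may be NULL).
#' @param seed Seed used.
#' @param inputs Character vector of input paths (checksummed when present).
#' @param timestamp Timestamp string; defaults to the current time.
#' @export
write_manifest <- function(path, command, config = NULL, seed = NULL,
                           inputs = character(0),
                           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")) {
  sums <- if (length(inputs)) {
    ex <- inputs[file.exists(inputs) & !dir.exists(inputs)]
    as.list(tools::md5sum(ex))
  } else list()
  jsonlite::write_json(
    list(command = command, seed = seed, config = config,
         inputs = sums, package = "histoscale", version = "0.1.0",
         timestamp = timestamp),
    path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
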