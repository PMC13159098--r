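#' Synthetic cohort configuration
#'
#' Defines the generative conditions for a paired bulk + spatial cohort with
#' a known embedding-to-expression mapping. The defaults describe the
#' noiseless linear regime used throughout the package's recovery tests:
#' 40 bulk slides of 30 patches, 10 spatial slides of 50 spots, 16-dim
#' embeddings driven by 4 latent morphology factors, a 20-gene panel,
#' exact (noise-free) embeddings and deterministic expression targets
#' (`count_depth = Inf`). Setting a finite `count_depth` switches spot and
#' bulk expression to Poisson counts with realistic sparsity; `noise_sd`
#' adds Gaussian noise to the embeddings.
#'
#' @param n_patients Number of bulk slides (one slide per patient).
#' @param patches_per_slide Patches per bulk slide.
#' @param n_spot_slides Number of spatial slides (distinct patients).
#' @param spots_per_slide Spots per spatial slide.
#' @param n_genes Target panel size G.
#' @param embed_dim Embedding dimensionality d.
#' @param latent_dim Number of latent morphology factors L (must be <= d).
#' @param noise_sd Gaussian noise on embeddings (0 = exact affine map).
#' @param count_depth Expected library size per spot/patch; `Inf` yields
#'   deterministic log-scale expression instead of counts.
#' @param seed Master seed; fixes every draw.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_patients = 40L, patches_per_slide = 30L,
                         n_spot_slides = 10L, spots_per_slide = 50L,
                         n_genes = 20L, embed_dim = 16L, latent_dim = 4L,
                         noise_sd = 0, count_depth = Inf, seed = 0L) {
  cfg <- list(n_patients = as.integer(n_patients),
              patches_per_slide = as.integer(patches_per_slide),
              n_spot_slides = as.integer(n_spot_slides),
              spots_per_slide = as.integer(spots_per_slide),
              n_genes = as.integer(n_genes), embed_dim = as.integer(embed_dim),
              latent_dim = as.integer(latent_dim), noise_sd = noise_sd,
              count_depth = count_depth, seed = as.integer(seed))
  if (any(unlist(cfg[1:7]) <= 0)) stop("all size parameters must be positive")
  if (cfg$latent_dim > cfg$embed_dim)
    stop("latent_dim must not exceed embed_dim")
  class(cfg) <- "synth_config"
  cfg
}

# Smooth low-frequency latent field: for each latent factor, a mixture of
# three cosine waves over normalized slide coordinates plus a slide-level
# offset, giving both within-slide spatial structure and between-slide
# variation.
latent_field <- function(coords_norm, L, rs) {
  n <- nrow(coords_norm)
  t_mat <- matrix(0, n, L)
  for (l in seq_len(L)) {
    off <- rs$rnorm(1, 0, 0.7)
    val <- rep(off, n)
    for (j in 1:3) {
      fx <- rs$runif(1, 0.5, 2); fy <- rs$runif(1, 0.5, 2)
      ph <- rs$runif(1, 0, 2 * pi)
      amp <- rs$runif(1, 0.4, 1)
      val <- val + amp * cos(2 * pi * (fx * coords_norm[, 1] +
                                         fy * coords_norm[, 2]) + ph)
    }
    t_mat[, l] <- val
  }
  t_mat
}

grid_coords <- function(n, step = 256L) {
  ncol_g <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  cbind(x = (idx %% ncol_g) * step, y = (idx %/% ncol_g) * step)
}

#' Generate a paired synthetic bulk + spatial cohort
#'
#' Per slide, patch latents are drawn from a smooth spatial field;
#' embeddings are an affine map of the latents (plus optional Gaussian
#' noise) and per-patch/spot mean log-expression is a second, known affine
#' map of the same latents. With `count_depth = Inf` the expression targets
#' are those exact log-scale values (the noiseless linear regime); with
#' finite depth, counts are drawn as Poisson(depth x softmax(expression))
#' per spot/patch, bulk counts are the sum of the patch counts, and the
#' log2(CPM+1)-transformed counts become the targets. Everything is
#' deterministic under the config seed.
#'
#' @param cfg A [synth_config()].
#' @return List with `bulk` (list of bulk samples: `slide_id`, `patient_id`,
#'   `embeddings`, `coords`, `z_global`, optional `counts`), `spot` (spatial
#'   samples, additionally `z_local` and an `expr_matrix` of raw counts),
#'   and `truth` (the generative maps `E`, `e0`, `M`, `m0` and per-slide
#'   latents — sufficient to compute oracle-optimal predictions).
#' @export
generate_cohort <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  L <- cfg$latent_dim; d <- cfg$embed_dim; G <- cfg$n_genes
  rs_map <- make_rng(cfg$seed, "truth-maps")
  E <- matrix(rs_map$runif(d * L, -1, 1) / sqrt(L), d, L)
  e0 <- rs_map$runif(d, -0.5, 0.5)
  M <- matrix(rs_map$runif(G * L, -1, 1), G, L)
  m0 <- rs_map$runif(G, 0.5, 1.5)
  gene_names <- sprintf("gene%03d", seq_len(G))

  make_slide <- function(slide_id, n, with_local) {
    rs <- make_rng(cfg$seed, paste0("slide-", slide_id))
    coords <- grid_coords(n)
    cn <- sweep(coords, 2, pmax(apply(coords, 2, max), 1), "/")
    T_lat <- latent_field(cn, L, rs)
    emb <- T_lat %*% t(E) + rep(e0, each = n)
    if (cfg$noise_sd > 0)
      emb <- emb + matrix(rs$rnorm(n * d, 0, cfg$noise_sd), n, d)
    Z <- T_lat %*% t(M) + rep(m0, each = n)
    colnames(Z) <- gene_names
    s <- list(slide_id = slide_id, embeddings = emb, coords = coords,
              latents = T_lat)
    if (is.finite(cfg$count_depth)) {
      prob <- exp(Z - apply(Z, 1, max))
      prob <- prob / rowSums(prob)
      lam <- cfg$count_depth * prob
      counts <- matrix(rs$rpois(length(lam), as.vector(lam)), nrow(lam),
                       ncol(lam))
      counts_gs <- t(counts)  # genes x spots
      dimnames(counts_gs) <- list(gene_names,
                                  sprintf("%s_u%03d", slide_id, seq_len(n)))
      em <- expr_matrix(counts_gs, "raw_counts")
      zl <- t(log2(counts_to_cpm(em)$values + 1))
      zg <- log2(make_pseudobulk(em) + 1)
      s$counts <- em
      s$z_local <- zl
      s$z_global <- as.numeric(zg)
    } else {
      s$z_local <- Z
      s$z_global <- colMeans(Z)
    }
    if (!with_local) s$z_local <- NULL
    s
  }

  bulk <- lapply(seq_len(cfg$n_patients), function(i) {
    s <- make_slide(sprintf("B%03d", i), cfg$patches_per_slide,
                    with_local = FALSE)
    s$patient_id <- sprintf("P%03d", i)
    s
  })
  spot <- lapply(seq_len(cfg$n_spot_slides), function(i) {
    s <- make_slide(sprintf("S%03d", i), cfg$spots_per_slide,
                    with_local = TRUE)
    s$patient_id <- sprintf("Q%03d", i)
    s
  })
  list(bulk = bulk, spot = spot,
       truth = list(E = E, e0 = e0, M = M, m0 = m0,
                    gene_names = gene_names, cfg = cfg))
}

#' Split a synthetic cohort into train/val(/test) sample lists
#'
#' Convenience wrapper around [make_cv_splits()] for one fold of a cohort
#' generated by [generate_cohort()].
#'
#' @param samples List of samples carrying `patient_id`.
#' @param split A single split from [make_cv_splits()].
#' @return List with `train`, `val`, `test` sample lists.
#' @export
split_samples <- function(samples, split) {
  pid <- vapply(samples, function(s) s$patient_id, character(1))
  list(train = samples[pid %in% split$train_patients],
       val = samples[pid %in% split$val_patients],
       test = samples[pid %in% split$test_patients])
}

#' Generate a synthetic tissue image with a ground-truth mask
#'
#' A white background with colored elliptical tissue blobs; the returned
#' binary mask makes per-tile true coverage computable exactly, for testing
#' the tiling and tissue-filtering path. No histological realism is
#' attempted.
#'
#' @param width,height Image size in pixels.
#' @param n_blobs Number of elliptical blobs (0 = blank image).
#' @param seed Seed for blob placement.
#' @return List with `image` (H x W x 3 array in `[0, 1]`) and `mask`
#'   (H x W logical, TRUE = tissue).
#' @export
generate_tissue_image <- function(width = 1024L, height = 1024L, n_blobs = 5L,
                                  seed = 0L) {
  rs <- make_rng(seed, "tissue-image")
  img <- array(1, dim = c(height, width, 3))
  mask <- matrix(FALSE, height, width)
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), times = width), height, width)
  for (b in seq_len(n_blobs)) {
    cx <- rs$runif(1, 0.1, 0.9) * width
    cy <- rs$runif(1, 0.1, 0.9) * height
    rx <- rs$runif(1, 0.08, 0.25) * width
    ry <- rs$runif(1, 0.08, 0.25) * height
    col <- c(rs$runif(1, 0.6, 0.9), rs$runif(1, 0.1, 0.4),
             rs$runif(1, 0.5, 0.8))
    inside <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
    mask <- mask | inside
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[inside] <- col[ch]
      img[, , ch] <- plane
    }
  }
  list(image = img, mask = mask)
}
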