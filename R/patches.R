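#' Ordered patch-embedding sequence for one slide
#'
#' @param embeddings n x d numeric matrix, one row per patch.
#' @param coords n x 2 integer matrix of 0-based pixel origins, columns
#'   `x` (column) and `y` (row).
#' @param patch_size Patch side length in pixels.
#' @param level_tag `"bulk_tile"` or `"spot_patch"`.
#' @param slide_id Slide identifier.
#' @param ordering Ordering convention used for the sequence (recorded in
#'   checkpoints; the recurrence is order-sensitive).
#' @return A `patch_sequence` object.
#' @export
patch_sequence <- function(embeddings, coords, patch_size = 256L,
                           level_tag = c("bulk_tile", "spot_patch"),
                           slide_id = "slide", ordering = "x_major") {
  level_tag <- match.arg(level_tag)
  embeddings <- as.matrix(embeddings)
  coords <- as.matrix(coords)
  if (nrow(embeddings) != nrow(coords))
    stop("embeddings and coords must have one row per patch")
  if (!all(is.finite(embeddings))) stop("embeddings must be finite")
  colnames(coords) <- c("x", "y")
  structure(list(embeddings = embeddings, coords = coords,
                 patch_size = as.integer(patch_size), level_tag = level_tag,
                 slide_id = slide_id, ordering = ordering),
            class = "patch_sequence")
}

#' @export
print.patch_sequence <- function(x, ...) {
  cat(sprintf("<patch_sequence> %s: %d x %d (%s, %dpx, %s order)\n",
              x$slide_id, nrow(x$embeddings), ncol(x$embeddings),
              x$level_tag, x$patch_size, x$ordering))
  invisible(x)
}

check_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] < 3)
    stop("image must be an H x W x 3 array (values in [0, 1])")
  image
}

#' Tile a slide image into a non-overlapping patch grid
#'
#' Partitions the image into non-overlapping `patch_size` x `patch_size`
#' tiles; partial border tiles are discarded. Tiles are ordered
#' lexicographically by their (x, y) origin — x-major by default,
#' configurable to y-major.
#'
#' @param image H x W x 3 array with values in `[0, 1]` (e.g. from
#'   [png::readPNG()]).
#' @param patch_size Tile side in pixels (default 256).
#' @param ordering `"x_major"` (sort by x then y) or `"y_major"`.
#' @return List with `coords` (n x 2 matrix of 0-based x, y origins) and
#'   `patches` (list of patch arrays in the same order).
#' @export
tile_slide <- function(image, patch_size = 256L, ordering = c("x_major", "y_major")) {
  check_image(image)
  ordering <- match.arg(ordering)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h < patch_size || w < patch_size)
    stop(sprintf("image (%d x %d) smaller than one %d-pixel patch", h, w, patch_size))
  xs <- seq(0L, w - patch_size, by = patch_size)
  ys <- seq(0L, h - patch_size, by = patch_size)
  grid <- if (ordering == "x_major") {
    cbind(x = rep(xs, each = length(ys)), y = rep(ys, times = length(xs)))
  } else {
    cbind(x = rep(xs, times = length(ys)), y = rep(ys, each = length(xs)))
  }
  patches <- lapply(seq_len(nrow(grid)), function(i) {
    x0 <- grid[i, "x"]; y0 <- grid[i, "y"]
    image[(y0 + 1):(y0 + patch_size), (x0 + 1):(x0 + patch_size), 1:3, drop = FALSE]
  })
  list(coords = grid, patches = patches, patch_size = as.integer(patch_size),
       ordering = ordering)
}

#' Fraction of tissue pixels in a patch
#'
#' A pixel counts as tissue when its darkest channel falls below
#' `white_cutoff` — i.e. it is not near-white background. This is a simple
#' deterministic stand-in for a tissue segmentation method; the cutoff is
#' configurable.
#'
#' @param patch Patch array (h x w x 3, values in `[0, 1]`).
#' @param white_cutoff Tissue threshold on `min(R, G, B)` (default 220/255).
#' @return Tissue fraction in `[0, 1]`.
#' @export
tissue_coverage <- function(patch, white_cutoff = 220 / 255) {
  check_image(patch)
  m <- pmin(patch[, , 1], patch[, , 2], patch[, , 3])
  mean(m < white_cutoff)
}

#' Filter tiles by tissue coverage
#'
#' Discards tiles with coverage strictly below `min_coverage`; a tile at
#' exactly the threshold is retained. Ordering is preserved.
#'
#' @param tiles Result of [tile_slide()].
#' @param min_coverage Coverage threshold (default 0.15).
#' @param white_cutoff Passed to [tissue_coverage()].
#' @return The filtered tile list, with a `coverage` element recording the
#'   retained tiles' coverages.
#' @export
filter_patches <- function(tiles, min_coverage = 0.15, white_cutoff = 220 / 255) {
  cov <- vapply(tiles$patches, tissue_coverage, numeric(1),
                white_cutoff = white_cutoff)
  keep <- cov >= min_coverage
  list(coords = tiles$coords[keep, , drop = FALSE],
       patches = tiles$patches[keep],
       coverage = cov[keep],
       patch_size = tiles$patch_size, ordering = tiles$ordering)
}

#' Slide-level quality control on the retained tile count
#'
#' A slide is kept only when strictly more than `min_tiles` tiles survive
#' tissue filtering (default 1000, matching full-resolution slides; tests
#' and small images use smaller values).
#'
#' @param n_tiles Number of retained tiles (or a tile list / patch_sequence).
#' @param min_tiles Threshold (strict; default 1000).
#' @return `TRUE` (keep) or `FALSE` (drop).
#' @export
slide_qc <- function(n_tiles, min_tiles = 1000L) {
  if (inherits(n_tiles, "patch_sequence")) n_tiles <- nrow(n_tiles$embeddings)
  if (is.list(n_tiles)) n_tiles <- length(n_tiles$patches)
  n_tiles > min_tiles
}

#' Crop a spot-centered patch
#'
#' Crops a `size` x `size` window centered on the given pixel coordinate.
#' Near the border the window is shifted inward so it fits entirely inside
#' the image (no padding with fabricated pixels); the shift is flagged.
#'
#' @param image H x W x 3 array.
#' @param center Numeric length-2 `(x, y)` pixel coordinate (0-based).
#' @param size Window side in pixels (default 256).
#' @return List with `patch`, `origin` (0-based x, y of the top-left
#'   corner), and `shifted` (TRUE when the window was clamped inward).
#' @export
crop_spot_patch <- function(image, center, size = 256L) {
  check_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  cx <- center[1]; cy <- center[2]
  if (cx < 0 || cy < 0 || cx >= w || cy >= h)
    stop(sprintf("spot center (%g, %g) lies outside the %d x %d image",
                 cx, cy, w, h))
  if (w < size || h < size) stop("image smaller than the crop window")
  x0 <- as.integer(floor(cx - size / 2))
  y0 <- as.integer(floor(cy - size / 2))
  x0c <- min(max(x0, 0L), w - size)
  y0c <- min(max(y0, 0L), h - size)
  patch <- image[(y0c + 1):(y0c + size), (x0c + 1):(x0c + size), 1:3, drop = FALSE]
  list(patch = patch, origin = c(x = x0c, y = y0c),
       shifted = (x0c != x0 || y0c != y0))
}

#' Embed patches through a pluggable encoder
#'
#' Applies the encoder to each patch in order, producing the n x d embedding
#' matrix the fusion model consumes.
#'
#' @param tiles A filtered tile list (from [tile_slide()] /
#'   [filter_patches()]) or a plain list of patch arrays with a `coords`
#'   companion.
#' @param encoder An encoder created with [make_encoder()] (or any list with
#'   `name`, `dim`, and a deterministic `fn(patch) -> d-vector`).
#' @param level_tag `"bulk_tile"` or `"spot_patch"`.
#' @param slide_id Slide identifier.
#' @return A [patch_sequence()].
#' @export
embed_patches <- function(tiles, encoder, level_tag = "bulk_tile",
                          slide_id = "slide") {
  pats <- tiles$patches
  n <- length(pats)
  if (n == 0) stop("no patches to embed")
  emb <- matrix(0, n, encoder$dim)
  for (i in seq_len(n)) {
    v <- encoder$fn(pats[[i]])
    if (length(v) != encoder$dim || !all(is.finite(v)))
      stop(sprintf("encoder returned a bad embedding for patch %d", i))
    emb[i, ] <- v
  }
  patch_sequence(emb, tiles$coords, patch_size = tiles$patch_size %||% 256L,
                 level_tag = level_tag, slide_id = slide_id,
                 ordering = tiles$ordering %||% "x_major")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a patch encoder
#'
#' Pretrained pathology foundation encoders are external to this package;
#' any deterministic function from an RGB patch to a fixed-length vector can
#' be plugged in here. The built-in `"projection"` encoder computes cheap
#' per-channel patch statistics (channel means and standard deviations over
#' a 2 x 2 spatial split) and projects them through a fixed seeded random
#' matrix — deterministic, fast, and sufficient for synthetic pipelines.
#'
#' @param name Encoder name; `"projection"` builds the built-in encoder, any
#'   other name requires `fn`.
#' @param dim Output dimensionality (default 512).
#' @param seed Seed fixing the projection matrix.
#' @param fn Optional custom function `patch -> d-vector`.
#' @return List with `name`, `dim`, `fn`.
#' @export
make_encoder <- function(name = "projection", dim = 512L, seed = 0L, fn = NULL) {
  if (is.null(fn)) {
    if (name != "projection")
      stop("custom encoders must supply `fn`")
    nfeat <- 24L  # 3 channels x (mean, sd) x 4 quadrants
    proj <- local({
      rs <- make_rng(seed, "projection-encoder")
      matrix(rs$runif(nfeat * dim, -1, 1) / sqrt(nfeat), nfeat, dim)
    })
    fn <- function(patch) {
      h <- dim(patch)[1]; w <- dim(patch)[2]
      hs <- list(1:(h %/% 2), (h %/% 2 + 1):h)
      ws <- list(1:(w %/% 2), (w %/% 2 + 1):w)
      f <- numeric(0)
      for (hi in hs) for (wi in ws) {
        q <- patch[hi, wi, 1:3, drop = FALSE]
        mu <- apply(q, 3, mean)
        sd3 <- apply(q, 3, stats::sd)
        f <- c(f, mu, sd3)
      }
      as.numeric(f %*% proj)
    }
  }
  list(name = name, dim = as.integer(dim), fn = fn)
}
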