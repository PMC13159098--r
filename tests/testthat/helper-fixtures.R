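# Shared fixtures and independent oracles for the test suite.

# Small counts matrix with gene/sample names.
counts_fixture <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  expr_matrix(m, "raw_counts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent hand-unrolled reference for the full fusion forward pass:
# plain loops over the recurrence and explicit head evaluation, sharing no
# code with fusion_forward().
reference_forward <- function(X, p) {
  d <- ncol(X)
  Xf <- rbind(X, p$cls)
  N <- nrow(Xf)
  h <- numeric(d)
  Y <- matrix(0, N, d)
  for (i in seq_len(N)) {
    x <- Xf[i, ]
    a <- colSums(x * p$Wa) + p$ba
    if (isTRUE(attr(p, "sigmoid_a"))) a <- 1 / (1 + exp(-a))
    b <- colSums(x * p$Wb) + p$bb
    cc <- colSums(x * p$Wc) + p$bc
    g <- colSums(x * p$Wg) + p$bg
    h <- a * h + b * x
    Y[i, ] <- g * (cc * h)
  }
  mlp <- function(y, W1, b1, W2, b2) {
    u <- colSums(y * W1) + b1
    z <- u * pnorm(u)
    colSums(z * W2) + b2
  }
  n <- N - 1
  pl <- matrix(unlist(lapply(seq_len(n), function(i)
    mlp(Y[i, ], p$Hl1, p$hl1, p$Hl2, p$hl2))), nrow = n, byrow = TRUE)
  pg <- mlp(Y[N, ], p$Hg1, p$hg1, p$Hg2, p$hg2)
  list(local = pl, global = pg, Y = Y)
}

# Fusion params with every array filled from a supplied draw function, and
# optionally all biases zeroed (for homogeneity checks).
draw_params <- function(d, G, seed, zero_bias = FALSE) {
  p <- init_fusion_params(d, G, seed = seed)
  if (zero_bias) {
    for (nm in c("ba", "bb", "bc", "bg", "hl1", "hl2", "hg1", "hg2"))
      p[[nm]][] <- 0
  }
  p
}

# Tiny training cohort (much smaller than the recovery-study cohort) for
# fast unit tests of the training loop.
tiny_cohort <- function(seed = 0) {
  generate_cohort(synth_config(
    n_patients = 10L, patches_per_slide = 6L, n_spot_slides = 4L,
    spots_per_slide = 8L, n_genes = 5L, embed_dim = 6L, latent_dim = 2L,
    seed = seed))
}

# Deterministic vector pair with an exact prescribed sample correlation.
vectors_with_cor <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  z <- rnorm(n)
  x <- (x - mean(x)) / sd(x)
  z <- resid(lm(z ~ x))
  z <- (z - mean(z)) / sd(z)
  y <- r * x + sqrt(1 - r^2) * z
  list(x = x, y = y)
}

run_cli <- function(...) pipeline_cli(c(...))
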