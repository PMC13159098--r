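#' Initialize fusion-model parameters
#'
#' The model is a single gated causal linear recurrence over a patch-embedding
#' sequence. Per position i with input x_i (a d-vector):
#' \deqn{h_i = a_i \odot h_{i-1} + b_i \odot x_i, \qquad
#'       y_i = g_i \odot (c_i \odot h_i)}
#' where the memory-decay (a), input-injection (b), read (c) and gating (g)
#' coefficients are learned affine maps of x_i. A learnable CLS token is
#' appended at the end of the sequence so its hidden state has integrated the
#' whole slide; two independent MLP heads (one hidden layer of width d, GELU
#' nonlinearity) map the per-patch outputs y_i to local (spot-level) gene
#' predictions and the CLS output to the global (slide-level) prediction.
#'
#' Initialization follows the state-space-model convention of starting near
#' an exponential moving average of the inputs: the memory-decay bias is 0.9
#' and the input-injection bias 0.1 (their sum ~ 1 keeps the hidden state on
#' the scale of a single embedding regardless of sequence length), the read
#' and gating biases are 1 (gates open), and the coefficient weight matrices
#' carry small uniform noise (`0.1/sqrt(d)`), so the model starts as a
#' near-linear, scale-stable sequence summarizer and training only has to
#' shape it. Head weights are drawn uniformly from
#' \eqn{[-1/\sqrt d, 1/\sqrt d]} with zero biases; the CLS embedding uses
#' the same distribution. All draws are seeded.
#'
#' @param d Embedding dimensionality (512 with pathology foundation
#'   encoders; smaller in synthetic runs).
#' @param G Number of target genes.
#' @param seed Integer seed for the initialization draws.
#' @param sigmoid_a If `TRUE`, the memory-decay coefficients are passed
#'   through a sigmoid, bounding them in (0, 1) for stability. Default
#'   `FALSE`: the coefficients are raw affine outputs.
#' @param loss_reduce `"mean"` (squared errors averaged over genes, so local
#'   and global losses share a scale regardless of G) or `"sum"`.
#' @return A `fusion_params` object (named list of weight arrays plus
#'   metadata attributes).
#' @export
init_fusion_params <- function(d, G, seed = 0L, sigmoid_a = FALSE,
                               loss_reduce = c("mean", "sum")) {
  loss_reduce <- match.arg(loss_reduce)
  rs <- make_rng(seed, "fusion-init")
  s <- 1 / sqrt(d)
  mat <- function(nr, nc, scale = s) matrix(rs$runif(nr * nc, -scale, scale),
                                            nr, nc)
  sw <- 0.1 / sqrt(d)  # small coefficient-weight noise around the EMA point
  p <- list(
    Wa = mat(d, d, sw), ba = rep(0.9, d),
    Wb = mat(d, d, sw), bb = rep(0.1, d),
    Wc = mat(d, d, sw), bc = rep(1, d),
    Wg = mat(d, d, sw), bg = rep(1, d),
    cls = rs$runif(d, -s, s),
    Hl1 = mat(d, d), hl1 = numeric(d),   # local head: d -> d -> G
    Hl2 = mat(d, G), hl2 = numeric(G),
    Hg1 = mat(d, d), hg1 = numeric(d),   # global head (independent weights)
    Hg2 = mat(d, G), hg2 = numeric(G)
  )
  attr(p, "d") <- as.integer(d)
  attr(p, "G") <- as.integer(G)
  attr(p, "sigmoid_a") <- isTRUE(sigmoid_a)
  attr(p, "loss_reduce") <- loss_reduce
  class(p) <- "fusion_params"
  p
}

gelu <- function(u) u * stats::pnorm(u)
gelu_grad <- function(u) stats::pnorm(u) + u * stats::dnorm(u)
sigmoid <- function(u) 1 / (1 + exp(-u))

#' Recurrence coefficients for one input vector
#'
#' Computes the memory-decay, input-injection, read and gating coefficient
#' vectors as learned affine maps of the input (optionally squashing the
#' memory-decay through a sigmoid when the model was built with
#' `sigmoid_a = TRUE`).
#'
#' @param x Input d-vector (patch embedding or CLS token).
#' @param params A `fusion_params`.
#' @return List with elements `a`, `b`, `c`, `g`.
#' @export
recurrence_coefficients <- function(x, params) {
  if (!all(is.finite(x))) stop("non-finite input to recurrence_coefficients()")
  a <- drop(x %*% params$Wa) + params$ba
  if (attr(params, "sigmoid_a")) a <- sigmoid(a)
  list(a = a,
       b = drop(x %*% params$Wb) + params$bb,
       c = drop(x %*% params$Wc) + params$bc,
       g = drop(x %*% params$Wg) + params$bg)
}

#' One step of the gated causal recurrence
#'
#' @param h_prev Previous hidden state (d-vector; the initial state is zero).
#' @param x Current input (d-vector).
#' @param params A `fusion_params`.
#' @return List with the new hidden state `h` and the gated output `y`.
#' @export
recurrence_step <- function(h_prev, x, params) {
  if (!all(is.finite(h_prev))) stop("non-finite hidden state")
  k <- recurrence_coefficients(x, params)
  h <- k$a * h_prev + k$b * x
  y <- k$g * (k$c * h)
  list(h = h, y = y)
}

#' Run the fusion model over a patch sequence
#'
#' Appends the CLS token after the n patch embeddings, runs the causal
#' recurrence over all n + 1 positions, and maps the outputs through the
#' local and global heads.
#'
#' @param seq A [patch_sequence()] or a plain n x d embedding matrix.
#' @param params A `fusion_params`.
#' @param keep_cache Internal: retain intermediates for backpropagation.
#' @return A `sequence_output`: list with `local_outputs` (n x d),
#'   `global_output` (d), `local_predictions` (n x G), `global_prediction`
#'   (G).
#' @export
fusion_forward <- function(seq, params, keep_cache = FALSE) {
  X <- if (inherits(seq, "patch_sequence")) seq$embeddings else as.matrix(seq)
  n <- nrow(X)
  if (n < 1) stop("fusion_forward requires at least one patch")
  d <- attr(params, "d")
  if (ncol(X) != d) stop(sprintf("embedding dim %d does not match model d=%d",
                                 ncol(X), d))
  Xf <- rbind(X, params$cls)
  N <- n + 1L
  A <- Xf %*% params$Wa + rep(params$ba, each = N)
  if (attr(params, "sigmoid_a")) A <- sigmoid(A)
  B <- Xf %*% params$Wb + rep(params$bb, each = N)
  C <- Xf %*% params$Wc + rep(params$bc, each = N)
  Gt <- Xf %*% params$Wg + rep(params$bg, each = N)
  H <- matrix(0, N, d)
  h <- numeric(d)
  for (i in seq_len(N)) {
    h <- A[i, ] * h + B[i, ] * Xf[i, ]
    H[i, ] <- h
  }
  Y <- Gt * C * H
  if (!all(is.finite(Y))) stop("non-finite recurrence output")
  Yloc <- Y[seq_len(n), , drop = FALSE]
  Ul <- Yloc %*% params$Hl1 + rep(params$hl1, each = n)
  Zl <- gelu(Ul)
  pred_local <- Zl %*% params$Hl2 + rep(params$hl2, each = n)
  ug <- drop(Y[N, ] %*% params$Hg1) + params$hg1
  zg <- gelu(ug)
  pred_global <- drop(zg %*% params$Hg2) + params$hg2
  out <- list(local_outputs = Yloc, global_output = Y[N, ],
              local_predictions = pred_local, global_prediction = pred_global)
  if (keep_cache)
    out$cache <- list(Xf = Xf, A = A, B = B, C = C, Gt = Gt, H = H, Y = Y,
                      Ul = Ul, Zl = Zl, ug = ug, zg = zg, n = n)
  class(out) <- "sequence_output"
  out
}

#' Local (spot-level) mean-squared-error loss
#'
#' Mean over spots of the per-spot squared error; with the default `"mean"`
#' reduction the squared error is itself averaged over genes, so local and
#' global losses share a scale regardless of panel size.
#'
#' @param pred n x G predicted matrix.
#' @param truth n x G target matrix.
#' @param reduce `"mean"` or `"sum"` over genes.
#' @return Non-negative scalar; zero iff `pred == truth`.
#' @export
loss_local <- function(pred, truth, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth))) stop("prediction/target shape mismatch")
  e2 <- (pred - truth)^2
  if (reduce == "mean") mean(rowMeans(e2)) else mean(rowSums(e2))
}

#' Global (slide-level) mean-squared-error loss
#' @param pred Predicted G-vector.
#' @param truth Target G-vector.
#' @param reduce `"mean"` or `"sum"` over genes.
#' @return Non-negative scalar.
#' @export
loss_global <- function(pred, truth, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  if (length(pred) != length(truth)) stop("prediction/target shape mismatch")
  e2 <- (pred - truth)^2
  if (reduce == "mean") mean(e2) else sum(e2)
}

#' Convex fine-tuning loss pair
#'
#' Mixes the local and global losses with weight `lambda`: the bulk-focused
#' model minimizes `lambda * local + (1 - lambda) * global`, the spot-focused
#' model the mirrored combination. `lambda` is the reciprocal of the spatial
#' up-sampling factor (0.1 for breast, 0.05 for colon and kidney cohorts).
#'
#' @param local Local loss value.
#' @param global Global loss value.
#' @param lambda Mixing weight, strictly inside (0, 1).
#' @return List with `loss_bulk` and `loss_spot`.
#' @export
finetune_losses <- function(local, global, lambda) {
  if (!is.finite(lambda) || lambda <= 0 || lambda >= 1)
    stop("lambda must lie strictly inside (0, 1)")
  list(loss_bulk = lambda * local + (1 - lambda) * global,
       loss_spot = (1 - lambda) * local + lambda * global)
}
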