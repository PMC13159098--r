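# Analytic reverse-mode gradients for the fusion model.
#
# The forward pass is a short chain (affine coefficient maps, an elementwise
# first-order scan, elementwise gating, two small MLP heads), so the adjoint
# is written out by hand: the scan is reversed position by position, and all
# coefficient adjoints reduce to two matrix products per weight.

#' Loss and parameter gradients for one sample
#'
#' Computes `w_local * loss_local + w_global * loss_global` and its gradient
#' with respect to every parameter group, in one forward + one backward pass.
#' Bulk samples use `w_local = 0` (no spot targets); spatial samples supply
#' both target sets.
#'
#' @param params A `fusion_params`.
#' @param X n x d embedding matrix (or a `patch_sequence`).
#' @param z_local Optional n x G local target matrix.
#' @param z_global Optional G-vector global target.
#' @param w_local,w_global Loss weights (either may be zero).
#' @return List with `loss`, `local`, `global` (component values, `NA` when
#'   the component has no target) and `grads` (named like the parameters).
#' @export
fusion_value_grad <- function(params, X, z_local = NULL, z_global = NULL,
                              w_local = 1, w_global = 1) {
  if (inherits(X, "patch_sequence")) X <- X$embeddings
  fw <- fusion_forward(X, params, keep_cache = TRUE)
  ca <- fw$cache
  n <- ca$n; N <- n + 1L
  d <- attr(params, "d"); G <- attr(params, "G")
  reduce <- attr(params, "loss_reduce")

  l_loc <- NA_real_; l_glob <- NA_real_
  dPl <- matrix(0, n, G); dpg <- numeric(G)
  if (!is.null(z_local) && w_local != 0) {
    l_loc <- loss_local(fw$local_predictions, z_local, reduce)
    sc <- if (reduce == "mean") 2 / (n * G) else 2 / n
    dPl <- w_local * sc * (fw$local_predictions - z_local)
  } else if (!is.null(z_local)) {
    l_loc <- loss_local(fw$local_predictions, z_local, reduce)
  }
  if (!is.null(z_global) && w_global != 0) {
    l_glob <- loss_global(fw$global_prediction, z_global, reduce)
    sc <- if (reduce == "mean") 2 / G else 2
    dpg <- w_global * sc * (fw$global_prediction - z_global)
  } else if (!is.null(z_global)) {
    l_glob <- loss_global(fw$global_prediction, z_global, reduce)
  }
  loss <- sum(c(if (!is.na(l_loc)) w_local * l_loc,
                if (!is.na(l_glob)) w_global * l_glob))

  g <- lapply(seq_along(params), function(i) {
    p <- params[[i]]
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  })
  names(g) <- names(params)

  dY <- matrix(0, N, d)
  # local head backward (rows 1..n)
  if (any(dPl != 0)) {
    g$Hl2 <- t(ca$Zl) %*% dPl
    g$hl2 <- colSums(dPl)
    dZl <- dPl %*% t(params$Hl2)
    dUl <- dZl * gelu_grad(ca$Ul)
    g$Hl1 <- t(ca$Y[seq_len(n), , drop = FALSE]) %*% dUl
    g$hl1 <- colSums(dUl)
    dY[seq_len(n), ] <- dUl %*% t(params$Hl1)
  }
  # global head backward (CLS row)
  if (any(dpg != 0)) {
    g$Hg2 <- outer(ca$zg, dpg)
    g$hg2 <- dpg
    dzg <- drop(params$Hg2 %*% dpg)
    dug <- dzg * gelu_grad(ca$ug)
    g$Hg1 <- outer(ca$Y[N, ], dug)
    g$hg1 <- dug
    dY[N, ] <- dY[N, ] + drop(params$Hg1 %*% dug)
  }

  # reverse scan: y_i = g_i * c_i * h_i ; h_i = a_i * h_{i-1} + b_i * x_i
  A <- ca$A; B <- ca$B; C <- ca$C; Gt <- ca$Gt; H <- ca$H; Xf <- ca$Xf
  dA <- matrix(0, N, d); dB <- dA; dC <- dA; dGt <- dA; dXf <- dA
  dh <- numeric(d)
  for (i in N:1) {
    dyi <- dY[i, ]
    dGt[i, ] <- dyi * C[i, ] * H[i, ]
    dC[i, ] <- dyi * Gt[i, ] * H[i, ]
    dh <- dh + dyi * Gt[i, ] * C[i, ]
    hprev <- if (i > 1) H[i - 1, ] else numeric(d)
    dA[i, ] <- dh * hprev
    dB[i, ] <- dh * Xf[i, ]
    dXf[i, ] <- dXf[i, ] + dh * B[i, ]
    dh <- dh * A[i, ]
  }
  if (attr(params, "sigmoid_a")) dA <- dA * A * (1 - A)  # A caches sigmoid(A_pre)
  g$Wa <- t(Xf) %*% dA; g$ba <- colSums(dA)
  g$Wb <- t(Xf) %*% dB; g$bb <- colSums(dB)
  g$Wc <- t(Xf) %*% dC; g$bc <- colSums(dC)
  g$Wg <- t(Xf) %*% dGt; g$bg <- colSums(dGt)
  dXf <- dXf + dA %*% t(params$Wa) + dB %*% t(params$Wb) +
    dC %*% t(params$Wc) + dGt %*% t(params$Wg)
  g$cls <- dXf[N, ]

  list(loss = loss, local = l_loc, global = l_glob, grads = g,
       prediction = fw)
}
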