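# Rectified Adam (RAdam) with decoupled weight decay.
#
# RAdam corrects the undefined variance of the adaptive learning rate during
# the first steps: while the variance estimate is untrustworthy the update
# falls back to plain momentum, afterwards a rectification factor scales the
# Adam step. Weight decay is applied decoupled from the gradient.

#' Initialize RAdam optimizer state
#' @param params A `fusion_params` (or any named list of numeric arrays).
#' @return Optimizer state holding first/second moment accumulators.
#' @export
radam_init <- function(params) {
  zeros <- lapply(params, function(p)
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p)))
  list(t = 0L, m = zeros, v = zeros)
}

#' One RAdam update
#'
#' @param params Current parameters (named list of arrays).
#' @param grads Gradients with the same names/shapes.
#' @param state State from [radam_init()] (threaded through calls).
#' @param lr Learning rate.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param beta1,beta2 Moment decay rates (defaults 0.9 / 0.999).
#' @param eps Numerical floor in the denominator.
#' @return List with updated `params` and `state`.
#' @export
radam_step <- function(params, grads, state, lr = 2e-4, weight_decay = 5e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  t <- state$t + 1L
  rho_inf <- 2 / (1 - beta2) - 1
  b2t <- beta2^t
  rho_t <- rho_inf - 2 * t * b2t / (1 - b2t)
  rect <- if (rho_t > 4) {
    sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
           ((rho_inf - 4) * (rho_inf - 2) * rho_t))
  } else NA_real_
  bias1 <- 1 - beta1^t
  bias2 <- 1 - b2t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    mhat <- state$m[[nm]] / bias1
    step <- if (!is.na(rect)) {
      vhat <- sqrt(state$v[[nm]] / bias2)
      rect * mhat / (vhat + eps)
    } else {
      mhat
    }
    params[[nm]] <- params[[nm]] - lr * (step + weight_decay * params[[nm]])
  }
  state$t <- t
  list(params = params, state = state)
}

#' Save a fusion-model checkpoint
#'
#' Writes a single container holding all parameters plus a JSON-encoded
#' header (embedding dim, gene panel, ordering convention, training stage).
#'
#' @param params A `fusion_params`.
#' @param path Output file (`.rds` container; a `.json` header sidecar is
#'   written next to it for inspection).
#' @param stage One of `pretrain_bulk`, `pretrain_spot`, `finetune_bulk`,
#'   `finetune_spot`.
#' @param gene_panel Character vector of target gene ids.
#' @param ordering Patch-ordering convention the model was trained with.
#' @param extra Optional named list merged into the header.
#' @export
save_checkpoint <- function(params, path, stage, gene_panel = NULL,
                            ordering = "x_major", extra = list()) {
  stage <- match.arg(stage, c("pretrain_bulk", "pretrain_spot",
                              "finetune_bulk", "finetune_spot"))
  header <- c(list(d = attr(params, "d"), G = attr(params, "G"),
                   sigmoid_a = attr(params, "sigmoid_a"),
                   loss_reduce = attr(params, "loss_reduce"),
                   gene_panel = gene_panel, ordering = ordering,
                   stage = stage, package_version = "0.1.0"), extra)
  saveRDS(list(header = header, params = unclass(params)), path)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a checkpoint written by [save_checkpoint()]
#' @param path Checkpoint file.
#' @return List with `header` and `params` (a restored `fusion_params`).
#' @export
read_checkpoint <- function(path) {
  ck <- readRDS(path)
  p <- ck$params
  attr(p, "d") <- ck$header$d
  attr(p, "G") <- ck$header$G
  attr(p, "sigmoid_a") <- isTRUE(ck$header$sigmoid_a)
  attr(p, "loss_reduce") <- ck$header$loss_reduce
  class(p) <- "fusion_params"
  list(header = ck$header, params = p)
}
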