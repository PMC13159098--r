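#' Training configuration
#'
#' Defaults follow the published training protocol: Rectified Adam with
#' batch size one, learning rate 2e-4 for pretraining (reduced to 2e-5 for
#' fine-tuning), weight decay 5e-3, up to 200 pretraining epochs, and a
#' patience of 20 epochs for the dual-criterion early-stopping rule. The
#' fine-tuning mixing weight `lambda` is 0.1 for the breast cohort and 0.05
#' for colon and kidney; the spatial up-sampling factor is its reciprocal.
#'
#' @param stage `"pretrain"` or `"finetune"`.
#' @param max_epochs Maximum epochs (default 200).
#' @param lr Learning rate (`NULL` = stage default: 2e-4 pretrain, 2e-5
#'   fine-tune).
#' @param weight_decay Decoupled weight decay (default 5e-3).
#' @param patience Early-stopping patience in epochs (default 20).
#' @param lambda Fine-tuning loss-mixing weight in (0, 1) (default 0.1).
#' @param clip_norm Global gradient-norm clip applied before every optimizer
#'   step (default 1). Batch-size-1 steps on long spot sequences can produce
#'   very large gradients, and the optimizer's first few un-rectified steps
#'   are not variance-adapted, so clipping is essential for stability.
#' @param seed Master seed for all stochastic parts of training.
#' @return A `train_config` list; `upsample_factor = round(1 / lambda)`.
#' @export
train_config <- function(stage = c("pretrain", "finetune"), max_epochs = 200L,
                         lr = NULL, weight_decay = 5e-3, patience = 20L,
                         lambda = 0.1, clip_norm = 1, seed = 0L) {
  stage <- match.arg(stage)
  if (lambda <= 0 || lambda >= 1) stop("lambda must lie strictly inside (0, 1)")
  if (is.null(lr)) lr <- if (stage == "pretrain") 2e-4 else 2e-5
  if (lr <= 0) stop("lr must be positive")
  structure(list(stage = stage, max_epochs = as.integer(max_epochs), lr = lr,
                 weight_decay = weight_decay, patience = as.integer(patience),
                 lambda = lambda,
                 upsample_factor = max(1L, as.integer(round(1 / lambda))),
                 clip_norm = clip_norm,
                 batch_size = 1L, seed = as.integer(seed)),
            class = "train_config")
}

#' Patient-wise cross-validation splits
#'
#' Partitions patients (never individual slides) into k folds. Each fold's
#' test set is one partition (about 20% of patients for k = 5); within the
#' remaining training portion, `inner_val_frac` of patients are held out as
#' the internal validation set used for early stopping.
#'
#' @param patient_ids Character vector of unique patient ids.
#' @param k Number of folds (default 5).
#' @param inner_val_frac Fraction of the training portion held out for
#'   validation (default 0.10).
#' @param seed Seed making the splits reproducible.
#' @return List of `k` splits, each a list with `fold_id`, `train_patients`,
#'   `val_patients`, `test_patients` (disjoint; union = all patients).
#' @export
make_cv_splits <- function(patient_ids, k = 5L, inner_val_frac = 0.10,
                           seed = 0L) {
  patient_ids <- unique(patient_ids)
  n <- length(patient_ids)
  if (k > n) stop(sprintf("k = %d folds exceed the %d patients", k, n))
  rs <- make_rng(seed, "cv-splits")
  perm <- patient_ids[rs$sample_int(n)]
  fold_of <- sort(rep_len(seq_len(k), n))  # contiguous blocks over the permutation
  lapply(seq_len(k), function(f) {
    test <- perm[fold_of == f]
    rest <- perm[fold_of != f]
    n_val <- max(1L, round(inner_val_frac * length(rest)))
    val <- rest[seq_len(n_val)]
    train <- setdiff(rest, val)
    list(fold_id = f, train_patients = train, val_patients = val,
         test_patients = test)
  })
}

#' Early-stopping and checkpointing decision
#'
#' Replays the epoch history plus the new epoch under the dual-criterion
#' rule: a checkpoint is saved whenever the MSE-based loss reaches a new
#' minimum; once the loss has failed to improve for `patience` consecutive
#' epochs, training stops unless the correlation has exceeded its best-so-far
#' value within that window (a new best correlation, like a new best loss,
#' resets the patience counter). With `criterion = "corr"` (the fine-tuning
#' rule) both saving and stopping are driven by correlation alone.
#'
#' @param history Data frame of past epochs with columns `loss` and `corr`
#'   (possibly zero rows).
#' @param loss,corr The new epoch's validation loss and correlation.
#' @param patience Consecutive non-improving epochs tolerated (default 20).
#' @param criterion `"both"` (pretraining) or `"corr"` (fine-tuning).
#' @return List with logicals `save` and `stop`.
#' @export
early_stop_update <- function(history, loss, corr, patience = 20L,
                              criterion = c("both", "corr")) {
  criterion <- match.arg(criterion)
  losses <- c(history$loss, loss)
  corrs <- c(history$corr, corr)
  best_loss <- Inf; best_corr <- -Inf; counter <- 0L
  save_new <- FALSE
  for (i in seq_along(losses)) {
    imp_loss <- is.finite(losses[i]) && losses[i] < best_loss
    imp_corr <- is.finite(corrs[i]) && corrs[i] > best_corr
    if (criterion == "both") {
      if (imp_loss || imp_corr) counter <- 0L else counter <- counter + 1L
      if (i == length(losses)) save_new <- imp_loss
    } else {
      if (imp_corr) counter <- 0L else counter <- counter + 1L
      if (i == length(losses)) save_new <- imp_corr
    }
    if (imp_loss) best_loss <- losses[i]
    if (imp_corr) best_corr <- corrs[i]
  }
  list(save = save_new, stop = counter >= patience)
}

# Rescale all gradient arrays so their joint Euclidean norm is at most
# `max_norm`.
clip_grads <- function(grads, max_norm = 1) {
  if (is.null(max_norm) || !is.finite(max_norm)) return(grads)
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (nrm > max_norm) grads <- lapply(grads, function(g) g * (max_norm / nrm))
  grads
}

# Pearson correlation that returns 0 (not NA) for constant vectors.
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

# Mean per-gene Pearson correlation between prediction and truth matrices
# (samples x genes).
mean_gene_cor <- function(pred, truth) {
  G <- ncol(truth)
  mean(vapply(seq_len(G), function(g) safe_cor(pred[, g], truth[, g]),
              numeric(1)))
}

# Stage loss and loss weights for one sample. Bulk samples carry only a
# global target; spatial samples carry both.
sample_weights <- function(sample) {
  if (is.null(sample$z_local)) c(w_local = 0, w_global = 1)
  else c(w_local = 1, w_global = 1)
}

# Evaluate the stage objective and the level-appropriate mean per-gene
# correlation on a validation sample list.
validate_samples <- function(params, samples) {
  losses <- numeric(length(samples))
  glob_pred <- NULL; glob_true <- NULL
  loc_pred <- NULL; loc_true <- NULL
  any_local <- any(vapply(samples, function(s) !is.null(s$z_local), logical(1)))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    fw <- fusion_forward(s$embeddings, params)
    w <- sample_weights(s)
    l <- 0
    if (w["w_local"] > 0) {
      l <- l + loss_local(fw$local_predictions, s$z_local,
                          attr(params, "loss_reduce"))
      loc_pred <- rbind(loc_pred, fw$local_predictions)
      loc_true <- rbind(loc_true, s$z_local)
    }
    l <- l + loss_global(fw$global_prediction, s$z_global,
                         attr(params, "loss_reduce"))
    losses[i] <- l
    glob_pred <- rbind(glob_pred, fw$global_prediction)
    glob_true <- rbind(glob_true, s$z_global)
  }
  corr <- if (any_local) mean_gene_cor(loc_pred, loc_true)
  else mean_gene_cor(glob_pred, glob_true)
  list(loss = mean(losses), corr = corr)
}

#' Pretrain a fusion model at one scale
#'
#' Stage one of the two-stage strategy: a bulk-focused model is trained on
#' bulk (and pseudo-bulk) samples with the global loss only; a spot-focused
#' model is trained on spatial samples with the sum of local and global
#' losses (the pseudo-bulk profile supplying the global target). Each
#' optimization step consumes one patient-level sample. Checkpointing and
#' early stopping follow the dual MSE/correlation criterion evaluated on the
#' validation samples after every epoch.
#'
#' @param params Initial `fusion_params` (see [init_fusion_params()]).
#' @param data List with `train` and `val`, each a list of samples; a sample
#'   is a list with `embeddings` (n x d), `z_global` (G), optionally
#'   `z_local` (n x G), and ids.
#' @param cfg A [train_config()] with `stage = "pretrain"`.
#' @return List with `params` (best checkpoint), `records` (one row per
#'   epoch: epoch, loss, corr, checkpointed, stopped), `best_epoch`.
#' @export
pretrain <- function(params, data, cfg = train_config("pretrain")) {
  run_training(params, data$train, data$val, cfg,
               step_fun = function(p, s) {
                 w <- sample_weights(s)
                 fusion_value_grad(p, s$embeddings, s$z_local, s$z_global,
                                   w_local = w["w_local"],
                                   w_global = w["w_global"])
               },
               criterion = "both", rng_name = "pretrain")
}

# Shared epoch loop for both stages. With `baseline = TRUE` (fine-tuning)
# the starting model's validation metrics seed the best-so-far values, so
# the saved checkpoint can never be worse than the starting model under the
# selection criterion.
run_training <- function(params, train, val, cfg, step_fun, criterion,
                         rng_name, baseline = FALSE) {
  if (length(train) == 0) stop("no training samples")
  if (length(val) == 0) stop("no validation samples")
  rs <- make_rng(cfg$seed, rng_name)
  opt <- radam_init(params)
  records <- data.frame(epoch = integer(), loss = numeric(), corr = numeric(),
                        checkpointed = logical(), stopped = logical())
  if (baseline) {
    v0 <- validate_samples(params, val)
    records <- data.frame(epoch = 0L, loss = v0$loss, corr = v0$corr,
                          checkpointed = FALSE, stopped = FALSE)
  }
  best <- params; best_epoch <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- rs$sample_int(length(train))
    for (i in ord) {
      vg <- step_fun(params, train[[i]])
      up <- radam_step(params, clip_grads(vg$grads, cfg$clip_norm), opt,
                       lr = cfg$lr, weight_decay = cfg$weight_decay)
      params <- up$params; opt <- up$state
    }
    v <- validate_samples(params, val)
    dec <- early_stop_update(records, v$loss, v$corr,
                             patience = cfg$patience, criterion = criterion)
    if (dec$save) { best <- params; best_epoch <- epoch }
    records <- rbind(records, data.frame(
      epoch = epoch, loss = v$loss, corr = v$corr,
      checkpointed = dec$save, stopped = dec$stop))
    if (dec$stop) break
  }
  if (best_epoch == 0L && !baseline) { best <- params; best_epoch <- nrow(records) }
  list(params = best, records = records, best_epoch = best_epoch)
}

#' Joint bi-scale fine-tuning
#'
#' Stage two: both pretrained models are trained further on paired steps.
#' The spatial sample pool is up-sampled (repeated, then truncated and
#' shuffled per epoch) so that every step pairs one spatial sample —
#' contributing the local loss and its pseudo-bulk global loss — with one
#' bulk sample contributing a global loss; the two global terms are
#' averaged. The bulk-focused model minimizes
#' `lambda * local + (1 - lambda) * global`, the spot-focused model the
#' mirrored combination. Checkpointing and early stopping use the
#' correlation criterion only, the learning rate drops to 2e-5, and each
#' model keeps its pretrained weights as the starting checkpoint, so the
#' saved fine-tuned checkpoint can only improve the correlation criterion.
#'
#' @param bulk_params,spot_params Pretrained `fusion_params` sharing (d, G).
#' @param bulk_data,spot_data Lists with `train`/`val` sample lists for each
#'   scale.
#' @param cfg A [train_config()] with `stage = "finetune"`.
#' @return List with `bulk` and `spot`, each as returned by [pretrain()].
#' @export
finetune <- function(bulk_params, spot_params, bulk_data, spot_data,
                     cfg = train_config("finetune")) {
  if (attr(bulk_params, "G") != attr(spot_params, "G") ||
      attr(bulk_params, "d") != attr(spot_params, "d"))
    stop("pretrained models must share embedding dim and gene panel size")
  n_steps <- length(bulk_data$train)
  if (n_steps == 0 || length(spot_data$train) == 0)
    stop("both scales need training samples")

  tune_one <- function(params, w_local, w_global, val, rng_name) {
    rs_pair <- make_rng(cfg$seed, paste0(rng_name, "-pairs"))
    pool_template <- rep(seq_along(spot_data$train),
                         length.out = max(n_steps, length(spot_data$train)))
    pool_template <- pool_template[seq_len(n_steps)]
    step_state <- new.env(parent = emptyenv())
    step_state$queue <- integer(0)
    paired_step <- function(p, bulk_sample) {
      if (length(step_state$queue) == 0)
        step_state$queue <- rs_pair$shuffle(pool_template)
      si <- step_state$queue[1]
      step_state$queue <- step_state$queue[-1]
      s <- spot_data$train[[si]]
      vg_s <- fusion_value_grad(p, s$embeddings, s$z_local, s$z_global,
                                w_local = w_local, w_global = w_global / 2)
      vg_b <- fusion_value_grad(p, bulk_sample$embeddings, NULL,
                                bulk_sample$z_global,
                                w_local = 0, w_global = w_global / 2)
      grads <- Map(`+`, vg_s$grads, vg_b$grads)
      list(loss = vg_s$loss + vg_b$loss, grads = grads)
    }
    run_training(params, bulk_data$train, val, cfg, paired_step,
                 criterion = "corr", rng_name = rng_name, baseline = TRUE)
  }

  lam <- cfg$lambda
  list(
    bulk = tune_one(bulk_params, w_local = lam, w_global = 1 - lam,
                    val = bulk_data$val, rng_name = "finetune-bulk"),
    spot = tune_one(spot_params, w_local = 1 - lam, w_global = lam,
                    val = spot_data$val, rng_name = "finetune-spot")
  )
}

#' Predict expression for a list of samples
#'
#' @param params A trained `fusion_params`.
#' @param samples List of samples (as in [pretrain()]).
#' @param level `"global"` returns one slide-level profile per sample
#'   (samples x G matrix); `"local"` returns the concatenated spot-level
#'   predictions with a `sample_index` attribute.
#' @return Numeric matrix of predictions.
#' @export
predict_expression <- function(params, samples, level = c("global", "local")) {
  level <- match.arg(level)
  if (level == "global") {
    out <- t(vapply(samples, function(s)
      fusion_forward(s$embeddings, params)$global_prediction,
      numeric(attr(params, "G"))))
    rownames(out) <- vapply(samples, function(s) s$slide_id %||% "", character(1))
    out
  } else {
    preds <- lapply(samples, function(s)
      fusion_forward(s$embeddings, params)$local_predictions)
    idx <- rep(seq_along(samples), vapply(preds, nrow, integer(1)))
    out <- do.call(rbind, preds)
    attr(out, "sample_index") <- idx
    out
  }
}
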