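test_that("cross-validation splits are patient-wise, sized, and reproducible", {
  ids <- sprintf("P%03d", 1:100)
  sp <- make_cv_splits(ids, k = 5, inner_val_frac = 0.10, seed = 3)
  expect_length(sp, 5)
  for (f in sp) {
    expect_length(f$test_patients, 20)
    expect_length(f$val_patients, 8)
    expect_length(f$train_patients, 72)
    expect_length(intersect(f$train_patients, f$test_patients), 0)
    expect_length(intersect(f$val_patients, f$test_patients), 0)
    expect_setequal(c(f$train_patients, f$val_patients, f$test_patients), ids)
  }
  # every patient is in exactly one test fold
  all_test <- unlist(lapply(sp, `[[`, "test_patients"))
  expect_setequal(all_test, ids)
  expect_equal(anyDuplicated(all_test), 0)

  sp2 <- make_cv_splits(ids, k = 5, inner_val_frac = 0.10, seed = 3)
  expect_identical(sp, sp2)
  expect_error(make_cv_splits(ids[1:3], k = 5), "exceed")
})

test_that("slides of one patient always land in the same partition", {
  co <- tiny_cohort()
  slides <- c(co$bulk, co$bulk)  # duplicate slides per patient
  sp <- make_cv_splits(vapply(slides, `[[`, "", "patient_id"), k = 3, seed = 1)
  for (f in sp) {
    ds <- split_samples(slides, f)
    pid <- lapply(ds, function(part) vapply(part, `[[`, "", "patient_id"))
    expect_length(intersect(pid$train, pid$val), 0)
    expect_length(intersect(pid$train, pid$test), 0)
    expect_length(intersect(pid$val, pid$test), 0)
    expect_equal(length(unlist(pid)), length(slides))
  }
})

test_that("early stopping saves on loss minima and respects the correlation escape", {
  hist0 <- data.frame(loss = numeric(), corr = numeric())
  # strictly decreasing loss: always save, never stop
  h <- hist0
  for (e in 1:30) {
    dec <- early_stop_update(h, loss = 1 / e, corr = 0.1, patience = 20)
    expect_true(dec$save); expect_false(dec$stop)
    h <- rbind(h, data.frame(loss = 1 / e, corr = 0.1))
  }
  # flat loss and corr: stop at the 20th non-improving epoch
  h <- data.frame(loss = 1, corr = 0.5)
  for (e in 1:19) {
    dec <- early_stop_update(h, loss = 1, corr = 0.5, patience = 20)
    expect_false(dec$save)
    h <- rbind(h, data.frame(loss = 1, corr = 0.5))
    if (e < 19) expect_false(dec$stop)
  }
  expect_true(early_stop_update(h, loss = 1, corr = 0.5, patience = 20)$stop)

  # flat loss but strictly rising correlation: never stops
  h <- data.frame(loss = 1, corr = 0.1)
  for (e in 1:25) {
    dec <- early_stop_update(h, loss = 1, corr = 0.1 + 0.01 * e, patience = 20)
    expect_false(dec$stop)
    h <- rbind(h, data.frame(loss = 1, corr = 0.1 + 0.01 * e))
  }

  # correlation-only criterion (fine-tuning): saves only on corr improvement
  h <- data.frame(loss = 5, corr = 0.3)
  expect_true(early_stop_update(h, 10, 0.4, criterion = "corr")$save)
  expect_false(early_stop_update(h, 0.01, 0.2, criterion = "corr")$save)
})

test_that("RAdam minimizes a simple quadratic and clipping bounds updates", {
  params <- list(x = 5)
  st <- radam_init(params)
  for (i in 1:2000) {
    up <- radam_step(params, list(x = 2 * params$x), st, lr = 0.01,
                     weight_decay = 0)
    params <- up$params; st <- up$state
  }
  expect_lt(abs(params$x), 0.05)

  g <- list(a = c(3, 4), b = matrix(12, 1, 1))
  cl <- histoscale:::clip_grads(g, max_norm = 1)
  expect_equal(sqrt(sum(unlist(cl)^2)), 1, tolerance = 1e-12)
  expect_equal(cl$a / cl$b[1], g$a / g$b[1])  # direction preserved
})

test_that("pretraining learns the synthetic signal and is reproducible", {
  co <- tiny_cohort()
  ds <- histoscale:::train_val_split(co$bulk, 0.2, 0L, "split-bulk")
  tc <- train_config("pretrain", max_epochs = 40, seed = 0)
  p0 <- init_fusion_params(6, 5, seed = 0)
  fit1 <- pretrain(p0, ds, tc)
  expect_lt(fit1$records$loss[fit1$best_epoch], fit1$records$loss[1])
  # saved checkpoint's loss is the minimum over all epochs
  expect_equal(fit1$records$loss[fit1$best_epoch], min(fit1$records$loss))

  fit2 <- pretrain(p0, ds, tc)
  expect_equal(fit1$records$loss, fit2$records$loss, tolerance = 1e-6)
  expect_identical(fit1$best_epoch, fit2$best_epoch)

  expect_error(pretrain(p0, list(train = list(), val = ds$val), tc), "no training")
})

test_that("spot pretraining reduces both local and global validation losses", {
  co <- tiny_cohort()
  ds <- histoscale:::train_val_split(co$spot, 0.25, 0L, "split-spot")
  tc <- train_config("pretrain", max_epochs = 30, seed = 0)
  fit <- pretrain(init_fusion_params(6, 5, seed = 1), ds, tc)
  # stage objective (local + global) decreases to the saved checkpoint
  expect_lt(fit$records$loss[fit$best_epoch], fit$records$loss[1])
  # and both components individually improved at the checkpoint
  comp <- function(params) {
    l <- g <- 0
    for (s in ds$val) {
      fw <- fusion_forward(s$embeddings, params)
      l <- l + loss_local(fw$local_predictions, s$z_local)
      g <- g + loss_global(fw$global_prediction, s$z_global)
    }
    c(local = l, global = g)
  }
  c0 <- comp(init_fusion_params(6, 5, seed = 1))
  c1 <- comp(fit$params)
  expect_lt(c1["local"], c0["local"])
  expect_lt(c1["global"], c0["global"])
})

test_that("fine-tuning enforces panel agreement and never degrades the criterion", {
  co <- tiny_cohort()
  bd <- histoscale:::train_val_split(co$bulk, 0.2, 0L, "split-bulk")
  sd_ <- histoscale:::train_val_split(co$spot, 0.25, 0L, "split-spot")
  tc <- train_config("pretrain", max_epochs = 15, seed = 0)
  fb <- pretrain(init_fusion_params(6, 5, seed = 0), bd, tc)
  fs <- pretrain(init_fusion_params(6, 5, seed = 1), sd_, tc)

  mismatched <- init_fusion_params(6, 4, seed = 2)
  expect_error(finetune(fb$params, mismatched, bd, sd_,
                        train_config("finetune")), "share")

  tcf <- train_config("finetune", max_epochs = 10, seed = 0)
  ft <- finetune(fb$params, fs$params, bd, sd_, tcf)
  for (scale in c("bulk", "spot")) {
    rec <- ft[[scale]]$records
    expect_equal(rec$epoch[1], 0L)  # pretrained baseline recorded
    best_corr <- max(rec$corr[rec$checkpointed], -Inf)
    if (ft[[scale]]$best_epoch > 0)
      expect_gte(best_corr, rec$corr[1])
    # saved checkpoint's correlation is the running maximum by construction
    v <- histoscale:::validate_samples(
      ft[[scale]]$params,
      if (scale == "bulk") bd$val else sd_$val)
    expect_gte(v$corr, rec$corr[1] - 1e-9)
  }
})

test_that("the spatial pool is up-sampled to pair every bulk step", {
  # upsample factor derives from lambda
  expect_equal(train_config("finetune", lambda = 0.1)$upsample_factor, 10L)
  expect_equal(train_config("finetune", lambda = 0.05)$upsample_factor, 20L)
  # 3 spatial and 30 bulk samples -> each epoch consumes 30 paired steps:
  # the shuffled queue of spatial indices is cycled in blocks of 30
  pool <- rep(seq_len(3), length.out = 30)
  expect_length(pool, 30)
  expect_equal(as.integer(table(pool)), rep(10L, 3))
})
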