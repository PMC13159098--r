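test_that("recurrence coefficients are the four affine maps of the input", {
  d <- 3
  p <- draw_params(d, 2, seed = 1, zero_bias = TRUE)
  # zero input, zero biases -> all four coefficient vectors vanish
  k0 <- recurrence_coefficients(numeric(d), p)
  expect_equal(unlist(k0, use.names = FALSE), numeric(4 * d))

  # identity decay map recovers the input
  p$Wa <- diag(d)
  x <- c(0.3, -1.2, 2)
  expect_equal(recurrence_coefficients(x, p)$a, x)

  # random case against an explicit matrix-vector product
  set.seed(2)
  p2 <- draw_params(d, 2, seed = 2)
  x2 <- rnorm(d)
  k <- recurrence_coefficients(x2, p2)
  expect_equal(k$b, as.numeric(t(p2$Wb) %*% x2) + p2$bb, tolerance = 1e-12)
  expect_equal(k$g, as.numeric(t(p2$Wg) %*% x2) + p2$bg, tolerance = 1e-12)
})

test_that("recurrence step follows h_i = a*h + b*x, y_i = g*(c*h)", {
  d <- 2
  p <- draw_params(d, 2, seed = 3, zero_bias = TRUE)
  x1 <- c(1, -0.5)
  st <- recurrence_step(numeric(d), x1, p)
  k1 <- recurrence_coefficients(x1, p)
  # from zero state the decay term drops out
  expect_equal(st$h, k1$b * x1)
  expect_equal(st$y, k1$g * k1$c * st$h)

  # zero decay map makes the recurrence memoryless
  pz <- p; pz$Wa[] <- 0; pz$ba[] <- 0
  h_prev <- c(5, -7)
  st2 <- recurrence_step(h_prev, x1, pz)
  expect_equal(st2$h, recurrence_coefficients(x1, pz)$b * x1)

  # three-step trace vs an independent hand loop with fixed integer weights
  ph <- draw_params(2, 2, seed = 0)
  ph$Wa <- matrix(c(1, 0, 1, 1), 2, 2) * 0.5; ph$ba <- c(0.1, 0)
  ph$Wb <- diag(2); ph$bb <- c(0, 0.2)
  ph$Wc <- matrix(1, 2, 2); ph$bc <- c(0, 0)
  ph$Wg <- diag(2) * 2; ph$bg <- c(1, 1)
  X <- matrix(c(1, 0, -1, 2, 0.5, 0.5), 3, 2, byrow = TRUE)
  h <- c(0, 0); trace_h <- list(); trace_y <- list()
  for (i in 1:3) {
    x <- X[i, ]
    a <- as.numeric(t(ph$Wa) %*% x) + ph$ba
    b <- as.numeric(t(ph$Wb) %*% x) + ph$bb
    cc <- as.numeric(t(ph$Wc) %*% x) + ph$bc
    g <- as.numeric(t(ph$Wg) %*% x) + ph$bg
    h <- a * h + b * x
    trace_h[[i]] <- h; trace_y[[i]] <- g * (cc * h)
  }
  h <- c(0, 0)
  for (i in 1:3) {
    st <- recurrence_step(h, X[i, ], ph)
    h <- st$h
    expect_equal(st$h, trace_h[[i]], tolerance = 1e-12)
    expect_equal(st$y, trace_y[[i]], tolerance = 1e-12)
  }
})

test_that("forward pass matches the hand-unrolled reference on random instances", {
  set.seed(10)
  for (rep in 1:25) {
    d <- sample(2:4, 1); n <- sample(1:5, 1); G <- sample(1:3, 1)
    p <- init_fusion_params(d, G, seed = rep)
    X <- matrix(rnorm(n * d), n, d)
    fw <- fusion_forward(X, p)
    ref <- reference_forward(X, p)
    expect_lt(max(abs(fw$local_predictions - ref$local)), 1e-9)
    expect_lt(max(abs(fw$global_prediction - ref$global)), 1e-9)
  }
})

test_that("CLS output integrates the whole sequence and order matters", {
  d <- 4; G <- 2
  p <- init_fusion_params(d, G, seed = 5)
  set.seed(6)
  x <- matrix(rnorm(d), 1, d)
  y1 <- fusion_forward(x, p)$global_prediction
  y2 <- fusion_forward(x + 0.1, p)$global_prediction
  expect_false(isTRUE(all.equal(y1, y2)))

  X <- matrix(rnorm(4 * d), 4, d)
  a <- fusion_forward(X, p)$global_prediction
  b <- fusion_forward(X[4:1, ], p)$global_prediction
  expect_false(isTRUE(all.equal(a, b)))

  expect_error(fusion_forward(matrix(0, 0, d), p), "at least one")
})

test_that("recurrence is homogeneous with zero biases: h ~ s^2, y ~ s^4", {
  d <- 3
  p <- draw_params(d, 2, seed = 7, zero_bias = TRUE)
  set.seed(8)
  x <- rnorm(d); h0 <- numeric(d); s <- 1.7
  st1 <- recurrence_step(h0, x, p)
  st2 <- recurrence_step(h0, s * x, p)
  expect_equal(st2$h, s^2 * st1$h, tolerance = 1e-10)
  expect_equal(st2$y, s^4 * st1$y, tolerance = 1e-10)
})

test_that("local and global losses are zero at perfection and quadratic in offsets", {
  set.seed(9)
  n <- 3; G <- 4
  z <- matrix(rnorm(n * G), n, G)
  expect_equal(loss_local(z, z), 0)
  expect_equal(loss_global(z[1, ], z[1, ]), 0)
  delta <- 0.37
  expect_equal(loss_local(z + delta, z), delta^2, tolerance = 1e-12)
  expect_equal(loss_global(z[1, ] + delta, z[1, ]), delta^2, tolerance = 1e-12)

  # brute-force double loop oracle
  zh <- matrix(rnorm(n * G), n, G)
  acc <- 0
  for (i in 1:n) { s <- 0; for (g in 1:G) s <- s + (zh[i, g] - z[i, g])^2
    acc <- acc + s / G }
  expect_equal(loss_local(zh, z), acc / n, tolerance = 1e-12)
  zg <- rnorm(5); zg2 <- rnorm(5)
  expect_equal(loss_global(zg, zg2), sum((zg - zg2)^2) / 5, tolerance = 1e-12)

  expect_error(loss_local(zh[, 1:2], z), "mismatch")
  expect_error(loss_global(zg, zg[1:3]), "mismatch")
})

test_that("fine-tuning losses form the stated convex pair", {
  fl <- finetune_losses(1, 2, 0.1)
  expect_equal(fl$loss_bulk, 1.9)
  expect_equal(fl$loss_spot, 1.1)
  eq <- finetune_losses(3, 7, 0.5)
  expect_equal(eq$loss_bulk, eq$loss_spot)
  same <- finetune_losses(4, 4, 0.23)
  expect_equal(same$loss_bulk, 4); expect_equal(same$loss_spot, 4)

  # conservation: bulk + spot = local + global for any lambda
  set.seed(12)
  for (rep in 1:50) {
    l <- runif(1, 0, 10); g <- runif(1, 0, 10); lam <- runif(1, 0.01, 0.99)
    fl <- finetune_losses(l, g, lam)
    expect_equal(fl$loss_bulk + fl$loss_spot, l + g, tolerance = 1e-12)
  }
  expect_error(finetune_losses(1, 1, 0), "lambda")
  expect_error(finetune_losses(1, 1, 1), "lambda")
})

test_that("analytic gradients match finite differences", {
  d <- 3; G <- 2; n <- 3
  p <- init_fusion_params(d, G, seed = 13)
  set.seed(14)
  X <- matrix(rnorm(n * d), n, d)
  zl <- matrix(rnorm(n * G), n, G)
  zg <- rnorm(G)
  vg <- fusion_value_grad(p, X, zl, zg, w_local = 1, w_global = 1)
  fd <- function(nm, idx, eps = 1e-6) {
    p2 <- p; p2[[nm]][idx] <- p2[[nm]][idx] + eps
    f1 <- fusion_value_grad(p2, X, zl, zg, 1, 1)$loss
    p2[[nm]][idx] <- p2[[nm]][idx] - 2 * eps
    f0 <- fusion_value_grad(p2, X, zl, zg, 1, 1)$loss
    (f1 - f0) / (2 * eps)
  }
  for (nm in names(p)) {
    idx <- seq_len(min(5, length(p[[nm]])))
    for (i in idx) {
      a <- fd(nm, i); b <- vg$grads[[nm]][i]
      expect_lt(abs(a - b) / max(abs(a) + abs(b), 1e-6), 1e-4)
    }
  }
})

test_that("gradients also check out with the sigmoid-bounded decay option", {
  d <- 2; G <- 2; n <- 2
  p <- init_fusion_params(d, G, seed = 15, sigmoid_a = TRUE)
  set.seed(16)
  X <- matrix(rnorm(n * d), n, d)
  zg <- rnorm(G)
  vg <- fusion_value_grad(p, X, NULL, zg, w_local = 0, w_global = 1)
  for (nm in c("Wa", "ba", "cls", "Hg1")) {
    eps <- 1e-6
    p2 <- p; p2[[nm]][1] <- p2[[nm]][1] + eps
    f1 <- fusion_value_grad(p2, X, NULL, zg, 0, 1)$loss
    p2[[nm]][1] <- p2[[nm]][1] - 2 * eps
    f0 <- fusion_value_grad(p2, X, NULL, zg, 0, 1)$loss
    a <- (f1 - f0) / (2 * eps)
    expect_lt(abs(a - vg$grads[[nm]][1]) / max(abs(a) + abs(vg$grads[[nm]][1]), 1e-6),
              1e-4)
  }
})

test_that("checkpoints round-trip parameters and header", {
  p <- init_fusion_params(4, 3, seed = 17)
  tmp <- tempfile(fileext = ".rds")
  save_checkpoint(p, tmp, "pretrain_bulk", gene_panel = c("a", "b", "c"))
  ck <- read_checkpoint(tmp)
  expect_equal(ck$params$Wa, p$Wa)
  expect_equal(attr(ck$params, "d"), 4L)
  expect_equal(ck$header$stage, "pretrain_bulk")
  expect_true(file.exists(paste0(tmp, ".json")))
  out <- fusion_forward(matrix(1:8 / 10, 2, 4), ck$params)
  expect_equal(dim(out$local_predictions), c(2, 3))
})
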