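test_that("NLL loss matches closed forms and a per-instance oracle", {
  # perfect predictions: zero loss
  P <- diag(4)[c(2, 4), ]
  expect_equal(nll_loss(P, c(2L, 4L)), 0)
  # uniform probabilities, one instance: ln O
  O <- 5
  expect_equal(nll_loss(matrix(1 / O, 1, O), 1L), log(O))
  # random batch equals the hand-summed oracle
  withr::with_seed(4, {
    raw <- matrix(runif(8 * 6), 8, 6)
    probs <- raw / rowSums(raw)
    gold <- sample(6, 8, replace = TRUE)
    oracle <- 0
    for (i in 1:8) oracle <- oracle - log(probs[i, gold[i]])
    expect_equal(nll_loss(probs, gold), oracle, tolerance = 1e-12)
  })
  # zero gold probability clamps with a warning
  expect_warning(l <- nll_loss(matrix(c(0, 1), 1, 2), 1L), "clamped")
  expect_equal(l, -log(1e-12))
})

test_that("input noise has the configured moments and spares padding rows", {
  V <- list(matrix(0, 4, 3))
  expect_equal(add_input_noise(V, 0, 0), V)
  # Monte-Carlo check of the mean over 1e6 draws
  big <- list(matrix(0, 1000, 1000))
  withr::with_seed(5, {
    Vp <- add_input_noise(big, noise_mean = 0.001, noise_std = 0.001)
  })
  diff <- Vp[[1]] - big[[1]]
  se <- 0.001 / sqrt(1e6)
  expect_lt(abs(mean(diff) - 0.001), 3 * se)
  expect_equal(sd(as.vector(diff)), 0.001, tolerance = 0.01)
  # rows beyond n_true untouched
  withr::with_seed(6, {
    Vm <- add_input_noise(list(matrix(1, 5, 3)), 0.5, 0.1, n_true = 3)
  })
  expect_true(all(Vm[[1]][4:5, ] == 1))
  expect_true(all(Vm[[1]][1:3, ] != 1))
})

test_that("Adadelta follows the reference recurrence and respects zero gradients", {
  th <- c(0.3, -1.2)
  st0 <- list(Eg = c(0, 0), Ed = c(0, 0))
  out <- adadelta_step(th, c(0, 0), st0)
  expect_equal(out$theta, th)
  expect_equal(out$state, st0)

  # single scalar parameter, one step, hand-computed
  rho <- 0.95; eps <- 1e-6; g <- 0.7
  Eg <- rho * 0 + (1 - rho) * g^2
  delta <- -sqrt(0 + eps) / sqrt(Eg + eps) * g
  Ed <- rho * 0 + (1 - rho) * delta^2
  res <- adadelta_step(2, g, NULL, rho = rho, eps = eps)
  expect_equal(res$theta, 2 + delta, tolerance = 1e-12)
  expect_equal(res$state$Eg, Eg, tolerance = 1e-12)
  expect_equal(res$state$Ed, Ed, tolerance = 1e-12)

  expect_error(adadelta_step(1, NaN, NULL), "non-finite")
})

test_that("max-norm rescales only rows above the bound", {
  W2 <- rbind(c(6, 8), c(3, 0), c(0, 0))      # norms 10, 3, 0
  out <- apply_maxnorm(W2, 5)
  expect_equal(sqrt(sum(out[1, ]^2)), 5, tolerance = 1e-12)
  expect_equal(out[1, ], c(3, 4))
  expect_equal(out[2, ], W2[2, ])
  expect_equal(out[3, ], c(0, 0))
})

test_that("analytic gradients agree with central finite differences", {
  emb <- random_embedding(v = 20, d = 6, cc = 2, seed = 42)
  vocab <- build_vocab(sprintf("t%02d", 1:15))
  model <- mccnn_init(emb, vocab, classes = letters[1:4], H = c(2, 3),
                      M = 3, seed = 9)
  withr::with_seed(43, {
    idx_list <- lapply(c(7, 3, 10), function(n) sample(2:20, n, replace = TRUE))
  })
  gold <- c(1L, 3L, 4L)
  analytic <- mccnn:::.batch_grads_flat(model, idx_list, gold, noise = NULL)
  theta <- mccnn:::param_flatten(model)
  f <- function(th) mccnn:::batch_nll(mccnn:::param_unflatten(th, model),
                                      idx_list, gold)
  expect_equal(analytic$loss, f(theta), tolerance = 1e-12)
  h <- 1e-5
  numeric_grad <- vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
  rel <- abs(numeric_grad - analytic$grad) /
    pmax(abs(numeric_grad), abs(analytic$grad), 1e-8)
  expect_lt(max(rel), 1e-4)
})

test_that("training reduces loss on a separable two-class problem", {
  data <- cue_dataset(200, seed = 31)
  kept <- Filter(function(i) i$label %in% c("effect", "negative"), data$kept)
  vocab <- build_vocab(kept)
  emb <- random_embedding(vocab$size, d = 12, cc = 2, seed = 32)
  model <- mccnn_train(kept, emb, vocab,
                       train_config(M = 8, H = c(3, 4), batch_size = 20,
                                    epochs = 5, seed = 33))
  hist <- attr(model, "history")
  expect_equal(nrow(hist), 5)
  expect_true(all(diff(hist$loss) < 0))
  # training fits the separable cue signal
  pred <- predict(model, kept)
  expect_gt(mean(pred$labels == instance_labels(kept)), 0.95)
})

test_that("zero epochs returns the initialization unchanged", {
  data <- cue_dataset(20, seed = 35)
  vocab <- build_vocab(data$kept)
  emb <- random_embedding(vocab$size, d = 6, cc = 1, seed = 36)
  cfg <- train_config(M = 4, H = c(3, 4), epochs = 0, seed = 37)
  model <- mccnn_train(data$kept, emb, vocab, cfg)
  init <- mccnn:::with_seed(cfg$seed, {
    mccnn_init(emb, vocab, sort(unique(instance_labels(data$kept))),
               cfg$H, cfg$M, seed = mccnn:::derive_seed(cfg$seed, 1L))
  })
  expect_equal(model$W2, init$W2)
  expect_equal(model$filters, init$filters)
  expect_equal(model$D, init$D)
  expect_equal(nrow(attr(model, "history")), 0)
})

test_that("training is bit-reproducible under a fixed seed", {
  data <- cue_dataset(60, seed = 38)
  vocab <- build_vocab(data$kept)
  emb <- random_embedding(vocab$size, d = 8, cc = 2, seed = 39)
  cfg <- train_config(M = 4, H = c(3, 4), epochs = 2, seed = 40)
  m1 <- mccnn_train(data$kept, emb, vocab, cfg)
  m2 <- mccnn_train(data$kept, emb, vocab, cfg)
  expect_identical(mccnn:::param_flatten(m1), mccnn:::param_flatten(m2))
  expect_identical(attr(m1, "history")$loss, attr(m2, "history")$loss)
})

test_that("the PAD embedding row stays frozen at zero through training", {
  data <- cue_dataset(40, seed = 44)
  vocab <- build_vocab(data$kept)
  emb <- random_embedding(vocab$size, d = 6, cc = 2, seed = 45)
  model <- mccnn_train(data$kept, emb, vocab,
                       train_config(M = 4, H = c(3, 4), epochs = 2, seed = 46))
  for (ch in model$D) expect_equal(ch[1, ], rep(0, 6))
})

test_that("empty training sets and foreign labels are rejected", {
  vocab <- build_vocab(character(0))
  emb <- random_embedding(vocab$size, d = 4, cc = 1, seed = 1)
  expect_error(mccnn_train(list(), emb, vocab), "empty training set")
  inst <- new_instance("s", "a", "b", c("Entity1", "x", "Entity2"), "weird")
  expect_error(mccnn_train(list(inst), emb, vocab, classes = c("negative")),
               "outside the class set")
})
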