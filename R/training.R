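## Minibatch NLL training with hand-derived backpropagation, Adadelta
## updates, Gaussian input noise and a max-norm constraint on the softmax
## weights. Parameters are updated through a flat-vector view so the
## optimizer state mirrors theta = (D, W, W2, b) element for element.

#' Training configuration
#'
#' Defaults follow the DDI setup: 200 filters per window, window sizes
#' 6/7/8/9, minibatches of 20, 10 epochs, Gaussian input noise with mean
#' 0.001, and a max-norm constraint of 5 on the softmax weight rows. For PPI
#' corpora, where sentences are shorter, `H = c(3, 4, 5, 6)` is the usual
#' choice. Adadelta uses the algorithm's canonical decay 0.95 and epsilon
#' 1e-6.
#'
#' @param M filters per window size.
#' @param H integer vector of convolution window sizes.
#' @param batch_size minibatch size `L`.
#' @param epochs number of full passes over the training set.
#' @param noise_mean,noise_std Gaussian input-noise parameters; set
#'   `noise_std = 0, noise_mean = 0` to disable.
#' @param maxnorm L2 bound applied to every softmax weight row after each
#'   update step.
#' @param rho,eps Adadelta decay and stabilizer.
#' @param seed master seed for initialization, shuffling and noise.
#' @return A `train_config` list.
#' @export
train_config <- function(M = 200L, H = c(6L, 7L, 8L, 9L), batch_size = 20L,
                         epochs = 10L, noise_mean = 0.001, noise_std = 0.001,
                         maxnorm = 5, rho = 0.95, eps = 1e-6, seed = 1L) {
  stopifnot(batch_size >= 1L, maxnorm > 0, epochs >= 0L, M >= 1L,
            rho > 0, rho < 1, eps > 0, noise_std >= 0)
  structure(list(M = as.integer(M), H = as.integer(sort(H)),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 noise_mean = noise_mean, noise_std = noise_std,
                 maxnorm = maxnorm, rho = rho, eps = eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Negative log-likelihood of a batch
#'
#' `loss = sum_i -log p(y_i | x_i)` over the batch. A gold-class probability
#' of exactly zero is clamped to 1e-12 with a warning.
#'
#' @param probs numeric matrix, one row per instance, rows summing to 1.
#' @param gold integer gold class indices (columns of `probs`).
#' @return Scalar loss.
#' @export
nll_loss <- function(probs, gold) {
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1L)
  stopifnot(length(gold) == nrow(probs))
  p <- probs[cbind(seq_len(nrow(probs)), gold)]
  if (any(p <= 0)) {
    warning("gold-class probability of 0 clamped to 1e-12", call. = FALSE)
    p <- pmax(p, 1e-12)
  }
  sum(-log(p))
}

#' Add Gaussian noise to a multichannel input
#'
#' Training-time regularizer: adds i.i.d. `Normal(noise_mean, noise_std^2)`
#' to every component of the real (non-padding) token positions. Padding
#' rows beyond `n_true` are left untouched, and noise is never applied at
#' prediction time.
#'
#' @param V list of channel matrices (see [embedding_lookup()]).
#' @param noise_mean,noise_std noise distribution parameters.
#' @param n_true number of real token rows; defaults to all rows.
#' @return Perturbed copy of `V`.
#' @export
add_input_noise <- function(V, noise_mean = 0.001, noise_std = 0.001,
                            n_true = nrow(V[[1]])) {
  for (i in seq_along(V)) {
    if (n_true > 0L) {
      d <- ncol(V[[i]])
      V[[i]][seq_len(n_true), ] <- V[[i]][seq_len(n_true), , drop = FALSE] +
        matrix(stats::rnorm(n_true * d, noise_mean, noise_std), n_true, d)
    }
  }
  V
}

#' One Adadelta update step
#'
#' Standard Adadelta recurrences on a flat parameter vector: accumulate the
#' squared gradient with decay `rho`, scale the step by the ratio of root
#' mean squares `RMS(delta)/RMS(g)`, apply it, and accumulate the squared
#' step. No global learning rate is needed.
#'
#' @param theta numeric parameter vector.
#' @param grad gradient of the loss w.r.t. `theta` (same length).
#' @param state accumulator list with `Eg` and `Ed` (created zeroed when
#'   `NULL`).
#' @param rho decay constant.
#' @param eps stabilizer.
#' @return List with updated `theta` and `state`. Non-finite gradients
#'   abort with a diagnostic.
#' @export
adadelta_step <- function(theta, grad, state = NULL, rho = 0.95, eps = 1e-6) {
  stopifnot(length(theta) == length(grad))
  if (any(!is.finite(grad))) {
    stop_validation("non-finite gradient in Adadelta step (%d bad component(s))",
                    sum(!is.finite(grad)))
  }
  if (is.null(state)) state <- list(Eg = numeric(length(theta)),
                                    Ed = numeric(length(theta)))
  state$Eg <- rho * state$Eg + (1 - rho) * grad^2
  delta <- -sqrt(state$Ed + eps) / sqrt(state$Eg + eps) * grad
  state$Ed <- rho * state$Ed + (1 - rho) * delta^2
  list(theta = theta + delta, state = state)
}

#' Apply the max-norm constraint to softmax weights
#'
#' Rows of `W2` whose L2 norm exceeds `maxnorm` are rescaled to norm exactly
#' `maxnorm`; other rows (including zero rows) are unchanged. Applied after
#' every update step during training.
#'
#' @param W2 numeric matrix (classes x features).
#' @param maxnorm positive norm bound.
#' @return Constrained copy of `W2`.
#' @export
apply_maxnorm <- function(W2, maxnorm = 5) {
  stopifnot(maxnorm > 0)
  norms <- sqrt(rowSums(W2^2))
  over <- norms > maxnorm
  if (any(over)) W2[over, ] <- W2[over, , drop = FALSE] * (maxnorm / norms[over])
  W2
}

## ---- flat parameter view -------------------------------------------------

param_flatten <- function(model) {
  c(unlist(lapply(model$D, as.vector), use.names = FALSE),
    unlist(lapply(model$filters, function(f) c(as.vector(f$W), f$b)),
           use.names = FALSE),
    as.vector(model$W2))
}

param_unflatten <- function(theta, model) {
  pos <- 0L
  take <- function(n) {
    out <- theta[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  for (i in seq_len(model$c)) {
    model$D[[i]] <- matrix(take(model$v * model$d), model$v, model$d)
  }
  for (j in seq_along(model$H)) {
    nw <- nrow(model$filters[[j]]$W) * ncol(model$filters[[j]]$W)
    model$filters[[j]]$W <- matrix(take(nw), nrow(model$filters[[j]]$W),
                                   ncol(model$filters[[j]]$W))
    model$filters[[j]]$b <- take(model$M)
  }
  model$W2 <- matrix(take(length(model$W2)), nrow(model$W2), ncol(model$W2))
  stopifnot(pos == length(theta))
  model
}

## TRUE for trainable components; the PAD embedding row of every channel is
## frozen (it must stay the zero vector).
trainable_mask <- function(model) {
  pad_row <- rep(FALSE, model$v)
  pad_row[.PAD_INDEX] <- TRUE
  d_mask <- rep(!rep(pad_row, model$d), model$c)
  n_rest <- sum(vapply(model$filters,
                       function(f) length(f$W) + length(f$b), numeric(1))) +
    length(model$W2)
  c(d_mask, rep(TRUE, n_rest))
}

## ---- backprop ------------------------------------------------------------

## Loss and parameter gradients for one instance. Gradients for D come back
## sparse as (rows, values) per channel. `noise` NULL disables input noise.
.instance_grads <- function(indices, gold, model, noise = NULL) {
  n_true <- length(indices)
  indices <- .pad_indices(indices, max(model$H))
  V <- embedding_lookup(indices, model)
  if (!is.null(noise)) {
    V <- add_input_noise(V, noise$mean, noise$std, n_true)
  }
  tr <- .forward_instance(indices, model, n_true, V = V)
  loss <- -log(max(tr$probs[gold], 1e-12))

  dI <- tr$probs
  dI[gold] <- dI[gold] - 1
  gW2 <- outer(dI, tr$r)
  dr <- as.vector(crossprod(model$W2, dI))

  c_ <- model$c; d <- model$d
  N <- length(tr$indices)
  dV <- lapply(seq_len(c_), function(i) matrix(0, N, d))
  gW <- vector("list", length(model$H))
  gb <- vector("list", length(model$H))
  offset <- 0L
  for (j in seq_along(model$H)) {
    h <- model$H[j]
    ph <- tr$per_h[[j]]
    drj <- dr[(offset + 1L):(offset + model$M)]
    offset <- offset + model$M
    P <- nrow(ph$Z)
    dZ <- matrix(0, P, model$M)
    sel <- cbind(ph$kstar, seq_len(model$M))
    dZ[sel] <- drj * (ph$Z[sel] > 0)
    gW[[j]] <- crossprod(ph$X, dZ)
    gb[[j]] <- colSums(dZ)
    dX <- dZ %*% t(model$filters[[j]]$W)
    for (i in seq_len(c_)) {
      for (r_ in 0:(h - 1L)) {
        block <- ((i - 1L) * h + r_) * d + seq_len(d)
        dV[[i]][(1L + r_):(P + r_), ] <- dV[[i]][(1L + r_):(P + r_), , drop = FALSE] +
          dX[, block, drop = FALSE]
      }
    }
  }
  ## scatter dV into embedding-row gradients; padding rows carry no signal
  gD <- vector("list", c_)
  real <- seq_len(n_true)
  for (i in seq_len(c_)) {
    agg <- rowsum(dV[[i]][real, , drop = FALSE], group = tr$indices[real])
    gD[[i]] <- list(rows = as.integer(rownames(agg)), values = agg)
  }
  list(loss = loss, gD = gD, gW = gW, gb = gb, gW2 = gW2,
       probs = tr$probs, predicted = tr$predicted)
}

## Batch loss with frozen parameters (no noise); used by finite-difference
## gradient checks.
batch_nll <- function(model, index_list, gold) {
  total <- 0
  for (i in seq_along(index_list)) {
    idx <- .pad_indices(index_list[[i]], max(model$H))
    tr <- .forward_instance(idx, model, n_true = length(index_list[[i]]))
    total <- total + (-log(max(tr$probs[gold[i]], 1e-12)))
  }
  total
}

## Accumulate one batch's gradients into a flat vector aligned with
## param_flatten().
.batch_grads_flat <- function(model, index_list, gold, noise = NULL) {
  gD <- lapply(seq_len(model$c), function(i) matrix(0, model$v, model$d))
  gW <- lapply(model$filters, function(f) matrix(0, nrow(f$W), ncol(f$W)))
  gb <- lapply(model$filters, function(f) numeric(model$M))
  gW2 <- matrix(0, nrow(model$W2), ncol(model$W2))
  loss <- 0
  for (i in seq_along(index_list)) {
    g <- .instance_grads(index_list[[i]], gold[i], model, noise)
    loss <- loss + g$loss
    for (ch in seq_len(model$c)) {
      rows <- g$gD[[ch]]$rows
      gD[[ch]][rows, ] <- gD[[ch]][rows, , drop = FALSE] + g$gD[[ch]]$values
    }
    for (j in seq_along(model$H)) {
      gW[[j]] <- gW[[j]] + g$gW[[j]]
      gb[[j]] <- gb[[j]] + g$gb[[j]]
    }
    gW2 <- gW2 + g$gW2
  }
  flat <- c(unlist(lapply(gD, as.vector), use.names = FALSE),
            unlist(lapply(seq_along(gW), function(j) c(as.vector(gW[[j]]), gb[[j]])),
                   use.names = FALSE),
            as.vector(gW2))
  list(loss = loss, grad = flat)
}

#' Train an MCCNN classifier
#'
#' Minibatch negative log-likelihood training of the full parameter set
#' `(D, W, W2, b)` — embeddings included — with Adadelta updates, Gaussian
#' input noise resampled per batch, and the max-norm constraint applied to
#' the softmax weights after every step. Instances are reshuffled each epoch
#' with the seeded RNG; a final short batch is used as-is. With a fixed seed
#' the whole trajectory is reproducible bit for bit.
#'
#' @param instances list of `mccnn_instance` training instances.
#' @param embedding an `mc_embedding` aligned to `vocab`.
#' @param vocab the `mccnn_vocab` built from the training instances.
#' @param config a [train_config()].
#' @param classes class label order; defaults to the sorted labels observed.
#' @return The trained `mccnn_model` with attribute `"history"`: a
#'   `data.frame` of per-epoch total and mean NLL, the post-step maximum
#'   softmax row norm, and elapsed seconds.
#' @export
mccnn_train <- function(instances, embedding, vocab, config = train_config(),
                        classes = NULL) {
  if (!length(instances)) stop_validation("empty training set")
  labels <- instance_labels(instances)
  classes <- classes %||% sort(unique(labels))
  if (!all(labels %in% classes)) {
    stop_validation("instance label outside the class set: %s",
                    paste(setdiff(labels, classes), collapse = ", "))
  }
  with_seed(config$seed, {
    model <- mccnn_init(embedding, vocab, classes, config$H, config$M,
                        seed = derive_seed(config$seed, 1L))
    index_list <- lapply(instances, function(i) encode_tokens(i$tokens, vocab))
    n_true <- lengths(index_list)
    gold <- match(labels, classes)
    theta <- param_flatten(model)
    mask <- trainable_mask(model)
    state <- NULL
    noise <- if (config$noise_std > 0 || config$noise_mean != 0) {
      list(mean = config$noise_mean, std = config$noise_std)
    } else NULL
    n <- length(instances)
    history <- data.frame(epoch = integer(), loss = numeric(),
                          mean_nll = numeric(), max_w2_norm = numeric(),
                          seconds = numeric())
    for (epoch in seq_len(config$epochs)) {
      t0 <- proc.time()[["elapsed"]]
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      epoch_loss <- 0
      max_norm_seen <- 0
      for (b in starts) {
        sel <- perm[b:min(b + config$batch_size - 1L, n)]
        res <- .batch_grads_flat(model, index_list[sel], gold[sel], noise)
        epoch_loss <- epoch_loss + res$loss
        grad <- res$grad
        grad[!mask] <- 0
        step <- adadelta_step(theta, grad, state, config$rho, config$eps)
        theta <- step$theta
        state <- step$state
        model <- param_unflatten(theta, model)
        model$W2 <- apply_maxnorm(model$W2, config$maxnorm)
        theta <- param_flatten(model)
        max_norm_seen <- max(max_norm_seen, sqrt(max(rowSums(model$W2^2))))
      }
      history <- rbind(history, data.frame(
        epoch = epoch, loss = epoch_loss, mean_nll = epoch_loss / n,
        max_w2_norm = max_norm_seen,
        seconds = proc.time()[["elapsed"]] - t0))
    }
    attr(model, "history") <- history
    attr(model, "config") <- config
    model
  })
}
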