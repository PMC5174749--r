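## The multichannel CNN classifier: embedding lookup, windowed convolution
## with ReLU, max-over-time pooling, multi-window concatenation, linear
## transform and softmax. Filters live in flattened form (one (c*h*d) x M
## matrix per window size); the unrolling order is channel-major, then
## window offset, then embedding dimension, matching im2col below.

.filter_ncol <- function(c, h, d) c * h * d

## Unroll windows of the multichannel input into rows: row k concatenates,
## for each channel i and offset r in 0:(h-1), the d-vector V[[i]][k+r, ].
.im2col <- function(V, h) {
  N <- nrow(V[[1]]); d <- ncol(V[[1]]); c <- length(V)
  P <- N - h + 1L
  X <- matrix(0, P, c * h * d)
  for (i in seq_len(c)) {
    for (r in 0:(h - 1L)) {
      X[, ((i - 1L) * h + r) * d + seq_len(d)] <- V[[i]][(1L + r):(P + r), , drop = FALSE]
    }
  }
  X
}

.flatten_filter <- function(W_array) {
  ## W_array is c x h x d -> flat vector in im2col column order
  c <- dim(W_array)[1]; h <- dim(W_array)[2]; d <- dim(W_array)[3]
  out <- numeric(c * h * d)
  for (i in seq_len(c)) {
    for (r in seq_len(h)) {
      out[((i - 1L) * h + r - 1L) * d + seq_len(d)] <- W_array[i, r, ]
    }
  }
  out
}

#' Look up the multichannel input for an index sequence
#'
#' @param indices integer vocabulary indices of length `N`.
#' @param embedding an `mc_embedding` (or a model; its `D` slot is used).
#' @return List of `c` matrices, each `N x d`: channel `i` holds
#'   `D[[i]][indices, ]`.
#' @export
embedding_lookup <- function(indices, embedding) {
  if (any(indices < 1L | indices > embedding$v)) {
    stop_validation("embedding index outside [1, %d]", embedding$v)
  }
  lapply(embedding$D, function(Di) Di[indices, , drop = FALSE])
}

#' Convolution feature map for one filter
#'
#' Slides an `h`-word window over the multichannel input and, at each
#' position `k`, sums the elementwise product of the window slice with the
#' filter over all channels, adds the bias, and applies the activation:
#' `m_k = f(sum_i sum(V_i[k:k+h-1, ] * W_i) + b)`, `k = 1..N-h+1`.
#'
#' @param V list of `c` matrices `N x d` (see [embedding_lookup()]).
#' @param W filter array `c x h x d`.
#' @param b scalar bias.
#' @param activation `"relu"` (the default) or `"identity"`.
#' @return Numeric feature map of length `N - h + 1`.
#' @export
conv_feature_map <- function(V, W, b, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  h <- dim(W)[2]
  if (nrow(V[[1]]) < h) {
    stop_validation("input length %d shorter than window size %d (pad upstream)",
                    nrow(V[[1]]), h)
  }
  z <- as.vector(.im2col(V, h) %*% .flatten_filter(W)) + b
  if (activation == "relu") pmax(z, 0) else z
}

#' Max-over-time pooling
#'
#' @param C non-empty numeric feature map.
#' @return Its maximum, a single scalar feature per filter.
#' @export
max_pool <- function(C) {
  if (!length(C)) stop_validation("cannot pool an empty feature map")
  max(C)
}

#' Initialize MCCNN parameters
#'
#' Filter and softmax weights use scaled-uniform (Glorot) initialization;
#' biases start at zero. The embedding tensor is adopted as given (all of it
#' is trainable except the `<PAD>` row).
#'
#' @param embedding an `mc_embedding` aligned to `vocab`.
#' @param vocab the `mccnn_vocab` the embedding was built on.
#' @param classes character vector of class labels (fixed order; argmax ties
#'   break toward the earlier label).
#' @param H integer vector of window sizes.
#' @param M filters per window size.
#' @param seed seed for weight initialization.
#' @return An object of class `mccnn_model`: the parameter set
#'   `(D, W, W2, b)` plus vocabulary, class labels and hyperparameters.
#' @export
mccnn_init <- function(embedding, vocab, classes, H, M, seed = 1L) {
  stopifnot(inherits(embedding, "mc_embedding"), M >= 1L, length(H) >= 1L)
  if (embedding$v != vocab$size) {
    stop_validation("embedding rows (%d) != vocabulary size (%d)",
                    embedding$v, vocab$size)
  }
  H <- as.integer(sort(H))
  O <- length(classes)
  K <- length(H)
  model <- with_seed(seed, {
    filters <- lapply(H, function(h) {
      fan_in <- .filter_ncol(embedding$c, h, embedding$d)
      lim <- sqrt(6 / (fan_in + M))
      list(W = matrix(stats::runif(fan_in * M, -lim, lim), fan_in, M),
           b = numeric(M))
    })
    names(filters) <- paste0("h", H)
    lim2 <- sqrt(6 / (K * M + O))
    W2 <- matrix(stats::runif(O * K * M, -lim2, lim2), O, K * M)
    list(filters = filters, W2 = W2)
  })
  structure(list(D = embedding$D, channels = embedding$channels,
                 c = embedding$c, v = embedding$v, d = embedding$d,
                 filters = model$filters, W2 = model$W2,
                 H = H, M = as.integer(M), classes = as.character(classes),
                 vocab = vocab),
            class = "mccnn_model")
}

#' @export
print.mccnn_model <- function(x, ...) {
  cat(sprintf("<mccnn_model: c=%d channels, v=%d, d=%d, H={%s}, M=%d, %d classes>\n",
              x$c, x$v, x$d, paste(x$H, collapse = ","), x$M,
              length(x$classes)))
  invisible(x)
}

.pad_indices <- function(indices, min_len) {
  if (length(indices) < min_len) {
    c(indices, rep(.PAD_INDEX, min_len - length(indices)))
  } else indices
}

## Core forward pass for one instance. Sequences shorter than max(H) are
## right-padded with PAD; window positions lying entirely beyond the true
## length (pure padding) are masked to -Inf before pooling so padding never
## wins the max. Returns the full trace needed for backprop.
.forward_instance <- function(indices, model, n_true = length(indices),
                              V = NULL) {
  indices <- .pad_indices(indices, max(model$H))
  N <- length(indices)
  if (is.null(V)) V <- embedding_lookup(indices, model)
  per_h <- vector("list", length(model$H))
  r <- numeric(0)
  for (j in seq_along(model$H)) {
    h <- model$H[j]
    X <- .im2col(V, h)
    Z <- X %*% model$filters[[j]]$W
    Z <- sweep(Z, 2L, model$filters[[j]]$b, "+")
    A <- pmax(Z, 0)
    P <- nrow(Z)
    masked <- seq_len(P) > n_true       # window start beyond real content
    if (any(masked)) A[masked, ] <- -Inf
    kstar <- max.col(t(A), ties.method = "first")
    pooled <- A[cbind(kstar, seq_len(ncol(A)))]
    per_h[[j]] <- list(X = X, Z = Z, A = A, kstar = kstar, pooled = pooled)
    r <- c(r, pooled)
  }
  I <- as.vector(model$W2 %*% r)
  e <- exp(I - max(I))
  S <- e / sum(e)
  list(indices = indices, n_true = n_true, V = V, per_h = per_h,
       r = r, confidences = I, probs = S,
       predicted = which.max(S))
}

#' MCCNN forward pass
#'
#' Runs one blinded, index-encoded sequence through the full network:
#' embedding lookup, per-window-size convolution + ReLU, max-over-time
#' pooling, concatenation over window sizes, linear transform and softmax.
#'
#' @param indices integer vocabulary indices.
#' @param model an `mccnn_model`.
#' @param n_true number of real (non-padding) tokens; defaults to
#'   `length(indices)`.
#' @return A forward trace: list with `V` (multichannel input),
#'   `feature_maps` (ReLU feature map per window size, positions x filters),
#'   `pooled` (the concatenated feature vector `r`, length
#'   `length(H) * M`), `confidences` (`I = W2 r`), `probs` (softmax `S`,
#'   sums to 1), and `predicted` (argmax class index; ties break to the
#'   lowest index).
#' @export
mccnn_forward <- function(indices, model, n_true = length(indices)) {
  tr <- .forward_instance(indices, model, n_true)
  list(V = tr$V,
       feature_maps = lapply(tr$per_h, function(p) p$Z * (p$Z > 0)),
       pooled = tr$r, confidences = tr$confidences, probs = tr$probs,
       predicted = tr$predicted)
}

#' Predict labels for instances
#'
#' Encodes each instance against the model vocabulary (out-of-vocabulary
#' tokens map to `<UNK>`) and applies the forward pass without input noise.
#'
#' @param object an `mccnn_model`.
#' @param instances list of `mccnn_instance` objects.
#' @param ... unused.
#' @return List with `labels` (predicted class per instance) and `probs`
#'   (instances x classes probability matrix).
#' @export
predict.mccnn_model <- function(object, instances, ...) {
  n <- length(instances)
  probs <- matrix(0, n, length(object$classes),
                  dimnames = list(NULL, object$classes))
  labels <- character(n)
  for (i in seq_len(n)) {
    idx <- encode_tokens(instances[[i]]$tokens, object$vocab)
    tr <- .forward_instance(idx, object, n_true = length(idx))
    probs[i, ] <- tr$probs
    labels[i] <- object$classes[tr$predicted]
  }
  list(labels = labels, probs = probs)
}

.mat_to_json <- function(m) list(dim = dim(m), data = as.vector(m))
.mat_from_json <- function(x) matrix(x$data, x$dim[1], x$dim[2])

#' Save a model checkpoint
#'
#' Serializes the full parameter set, vocabulary, window sizes, class labels
#' and channel manifest to a single versioned JSON archive at full floating
#' point precision.
#'
#' @param model an `mccnn_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(
    format = "mccnn-checkpoint", version = 1L,
    H = model$H, M = model$M, classes = model$classes,
    channels = model$channels, c = model$c, v = model$v, d = model$d,
    vocab = model$vocab$symbols,
    D = lapply(model$D, .mat_to_json),
    filters = lapply(model$filters, function(f) {
      list(W = .mat_to_json(f$W), b = f$b)
    }),
    W2 = .mat_to_json(model$W2))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return The restored `mccnn_model`.
#' @export
load_checkpoint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$format, "mccnn-checkpoint")) {
    stop_validation("'%s' is not an mccnn checkpoint", path)
  }
  num <- function(v) vapply(v, as.numeric, numeric(1))
  mat <- function(m) matrix(num(m$data), m$dim[[1]], m$dim[[2]])
  chr <- function(v) vapply(v, as.character, character(1))
  H <- vapply(x$H, as.integer, integer(1))
  D <- lapply(x$D, mat)
  filters <- lapply(x$filters, function(f) list(W = mat(f$W), b = num(f$b)))
  names(filters) <- paste0("h", H)
  vocab <- structure(list(symbols = chr(x$vocab), size = length(x$vocab)),
                     class = "mccnn_vocab")
  structure(list(D = D, channels = chr(x$channels),
                 c = as.integer(x$c), v = as.integer(x$v), d = as.integer(x$d),
                 filters = filters, W2 = mat(x$W2),
                 H = H, M = as.integer(x$M),
                 classes = chr(x$classes), vocab = vocab),
            class = "mccnn_model")
}
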