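#' Renormalized adjacency matrix
#'
#' The self-loop-augmented, symmetrically degree-normalized operator of the
#' graph-convolution layer: `A^ = D~^(-1/2) (A + I) D~^(-1/2)` where
#' `D~_ii = sum_j (A + I)_ij`. For a weighted brain graph pass the adjacency
#' rescaled to `[0, 1]` first (see [prepare_adjacency()]), otherwise raw
#' fiber counts in the hundreds swamp the unit self-loop.
#'
#' @param A Square symmetric non-negative numeric matrix.
#' @return Symmetric matrix of the same dimension.
#' @export
renormalize_adjacency <- function(A) {
  A <- as.matrix(A)
  if (any(A < 0)) stop("adjacency must be non-negative")
  if (max(abs(A - t(A))) > 1e-9) stop("adjacency must be symmetric")
  At <- A + diag(nrow(A))
  d_inv_sqrt <- 1 / sqrt(rowSums(At))
  At * outer(d_inv_sqrt, d_inv_sqrt)
}

#' Model-ready adjacency for a brain graph
#'
#' Binary pipeline: renormalizes the 0/1 adjacency. Weighted pipeline:
#' rescales weights by the network maximum to `[0, 1]` before
#' renormalization; with all-equal weights the two pipelines coincide.
#'
#' @param G A `brain_graph`.
#' @param weighted Feed edge weights to the model.
#' @return Renormalized q x q matrix.
#' @export
prepare_adjacency <- function(G, weighted = FALSE) {
  stopifnot(inherits(G, "brain_graph"))
  adj <- if (weighted) {
    mx <- max(G$adjacency)
    if (mx > 0) G$adjacency / mx else G$adjacency
  } else {
    (G$adjacency > 0) * 1
  }
  renormalize_adjacency(adj)
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

#' Graph-convolution layer forward pass
#'
#' `H = ReLU(A^ X W)`: the renormalized adjacency mixes each node's
#' neighborhood, the weight matrix projects features to k channels, and the
#' rectifier is applied elementwise.
#'
#' @param A_hat Renormalized q x q adjacency.
#' @param X q x d node-feature matrix.
#' @param W d x k layer weights.
#' @return q x k activation matrix.
#' @export
gc_layer_forward <- function(A_hat, X, W) {
  if (ncol(A_hat) != nrow(X) || ncol(X) != nrow(W))
    stop("incompatible shapes: need (q x q)(q x d)(d x k)")
  relu(A_hat %*% X %*% W)
}

#' Build the graph convolutional classifier
#'
#' One graph-convolution layer with k output channels and ReLU activation
#' (no bias, matching the layer formula), dropout on the activations during
#' training, a flatten step, and a fully connected softmax output layer with
#' bias. Weights use seeded uniform Glorot initialization (limit
#' `sqrt(6 / (fan_in + fan_out))`); the dense bias starts at zero.
#'
#' @param q Number of graph nodes.
#' @param d Node-feature dimension.
#' @param k Graph-convolution output channels (default 100).
#' @param n_classes Number of classes C.
#' @param seed Integer seed for weight initialization.
#' @param dropout_rate Dropout probability on the GC activations (default 0.3).
#' @return A `gcnn_model` with components `W` (d x k), `W_dense`
#'   ((q*k) x C), `b_dense` (length C) and the architecture constants.
#' @export
build_model <- function(q, d, k = 100L, n_classes, seed = 1L,
                        dropout_rate = 0.3) {
  stopifnot(q >= 1, d >= 1, k >= 1, n_classes >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  glorot <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  structure(list(W = glorot(d, k),
                 W_dense = glorot(q * k, n_classes),
                 b_dense = numeric(n_classes),
                 q = as.integer(q), d = as.integer(d), k = as.integer(k),
                 n_classes = as.integer(n_classes),
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "gcnn_model")
}

#' @export
print.gcnn_model <- function(x, ...) {
  cat(sprintf("<gcnn_model: q=%d, d=%d, k=%d, C=%d, %d trainable parameters>\n",
              x$q, x$d, x$k, x$n_classes, count_parameters(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' `d*k` graph-convolution weights plus `(q*k)*C` dense weights plus `C`
#' bias terms. The reference architecture (q = 84, identity features d = 84,
#' k = 100, C = 4) has 8400 + 33600 + 4 = 42004 parameters.
#'
#' @param model A `gcnn_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "gcnn_model"))
  length(model$W) + length(model$W_dense) + length(model$b_dense)
}

# stack per-sample A^ X products into one ((n*q) x d) matrix
stack_inputs <- function(dataset, model) {
  lapply(dataset, function(s) {
    if (!all(dim(s$A_hat) == c(model$q, model$q)) ||
        !all(dim(s$X) == c(model$q, model$d)))
      stop("sample shapes do not match the model architecture")
    s$A_hat %*% s$X
  })
}

# forward pass for stacked inputs; returns flat features and probabilities
forward_batch <- function(M_stack, model, n, mask = NULL) {
  q <- model$q; k <- model$k
  Z <- M_stack %*% model$W
  H <- relu(Z)
  if (!is.null(mask)) H <- H * mask
  arr <- array(H, c(q, n, k))
  Fmat <- t(matrix(aperm(arr, c(1L, 3L, 2L)), q * k, n))
  logits <- sweep(Fmat %*% model$W_dense, 2L, model$b_dense, "+")
  list(Z = Z, H = H, Fmat = Fmat, P = softmax_rows(logits))
}

#' Training configuration
#'
#' Adam hyperparameters and the early-stopping rule: a stratified 10%
#' validation split of the training data is monitored and training stops
#' when validation loss has not improved for `patience` epochs; the weights
#' at the best validation loss are returned. Gradient steps are full-batch
#' by default (`batch_size = NULL`).
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param max_epochs Maximum number of epochs (default 500).
#' @param patience Early-stopping patience in epochs (default 20).
#' @param validation_fraction Fraction of training samples held out for
#'   early stopping (default 0.1).
#' @param batch_size Mini-batch size; `NULL` for full batch.
#' @param seed Seed for the validation split and dropout masks.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, max_epochs = 500L,
                         patience = 20L, validation_fraction = 0.1,
                         batch_size = NULL, seed = 1L) {
  stopifnot(learning_rate >= 0, patience >= 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 batch_size = batch_size, seed = as.integer(seed)),
            class = "train_config")
}

cross_entropy <- function(P, y) {
  -mean(log(pmax(P[cbind(seq_along(y), y)], 1e-12)))
}

#' Train the classifier
#'
#' Full-batch Adam on the categorical cross-entropy, with inverted dropout
#' on the graph-convolution activations and early stopping on a held-out
#' validation split. Fully reproducible given the config seed.
#'
#' @param model A `gcnn_model` from [build_model()].
#' @param dataset List of samples, each a list with `A_hat` (q x q,
#'   renormalized), `X` (q x d) and `label` (integer in `1..C`).
#' @param config A [train_config()].
#' @return The trained model, with a `history` attribute (data frame of
#'   per-epoch train/validation loss) and `best_epoch`.
#' @export
train_gcnn <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(model, "gcnn_model"), inherits(config, "train_config"))
  if (length(dataset) == 0L) stop("empty training dataset")
  y <- vapply(dataset, function(s) as.integer(s$label), integer(1))
  if (any(y < 1L | y > model$n_classes)) stop("labels must lie in 1..n_classes")
  if (length(unique(y)) < 2L)
    warning("training set contains a single class")
  set.seed(config$seed)

  # stratified validation split for early stopping
  idx_val <- integer(0)
  if (config$validation_fraction > 0 && length(dataset) >= 10L) {
    for (cl in unique(y)) {
      members <- which(y == cl)
      n_take <- floor(config$validation_fraction * length(members))
      if (n_take >= 1L)
        idx_val <- c(idx_val, sample(members, n_take))
    }
  }
  idx_tr <- setdiff(seq_along(dataset), idx_val)

  M_list <- stack_inputs(dataset, model)
  M_tr <- do.call(rbind, M_list[idx_tr])
  y_tr <- y[idx_tr]
  n_tr <- length(idx_tr)
  has_val <- length(idx_val) > 0L
  if (has_val) {
    M_val <- do.call(rbind, M_list[idx_val])
    y_val <- y[idx_val]
  }

  q <- model$q; k <- model$k; C <- model$n_classes
  Y_tr <- matrix(0, n_tr, C); Y_tr[cbind(seq_len(n_tr), y_tr)] <- 1

  # Adam state
  params <- list(W = model$W, W_dense = model$W_dense, b_dense = model$b_dense)
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0L

  best_loss <- Inf; best_params <- params; best_epoch <- 0L; wait <- 0L
  hist_train <- numeric(0); hist_val <- numeric(0)

  for (epoch in seq_len(config$max_epochs)) {
    model$W <- params$W; model$W_dense <- params$W_dense
    model$b_dense <- params$b_dense

    mask <- NULL
    if (model$dropout_rate > 0) {
      keep <- 1 - model$dropout_rate
      mask <- matrix(stats::rbinom(n_tr * q * k, 1L, keep), n_tr * q, k) / keep
    }
    fw <- forward_batch(M_tr, model, n_tr, mask = mask)
    loss_tr <- cross_entropy(fw$P, y_tr)

    # backward
    dlogits <- (fw$P - Y_tr) / n_tr
    g_b <- colSums(dlogits)
    g_Wd <- crossprod(fw$Fmat, dlogits)
    dF <- tcrossprod(dlogits, model$W_dense)  # n x (q*k)
    arr <- array(t(dF), c(q, k, n_tr))
    dH <- matrix(aperm(arr, c(1L, 3L, 2L)), n_tr * q, k)
    if (!is.null(mask)) dH <- dH * mask
    dH <- dH * (fw$Z > 0)
    g_W <- crossprod(M_tr, dH)
    grads <- list(W = g_W, W_dense = g_Wd, b_dense = g_b)

    t_step <- t_step + 1L
    for (nm in names(params)) {
      mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * grads[[nm]]
      vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * grads[[nm]]^2
      mhat <- mstate[[nm]] / (1 - b1^t_step)
      vhat <- vstate[[nm]] / (1 - b2^t_step)
      params[[nm]] <- params[[nm]] -
        config$learning_rate * mhat / (sqrt(vhat) + eps)
    }

    # monitored loss: validation split if available, else training loss
    if (has_val) {
      model$W <- params$W; model$W_dense <- params$W_dense
      model$b_dense <- params$b_dense
      fv <- forward_batch(M_val, model, length(idx_val))
      loss_mon <- cross_entropy(fv$P, y_val)
    } else {
      loss_mon <- loss_tr
    }
    hist_train <- c(hist_train, loss_tr)
    hist_val <- c(hist_val, loss_mon)

    if (loss_mon < best_loss - 1e-8) {
      best_loss <- loss_mon; best_params <- params
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  model$W <- best_params$W
  model$W_dense <- best_params$W_dense
  model$b_dense <- best_params$b_dense
  attr(model, "history") <- data.frame(epoch = seq_along(hist_train),
                                       train_loss = hist_train,
                                       monitored_loss = hist_val)
  attr(model, "best_epoch") <- best_epoch
  model
}

#' Predict class probabilities for one graph
#'
#' Forward pass with dropout disabled.
#'
#' @param model A `gcnn_model`.
#' @param A_hat Renormalized q x q adjacency.
#' @param X q x d node-feature matrix.
#' @return Length-C probability vector (sums to 1).
#' @export
predict_gcnn <- function(model, A_hat, X) {
  stopifnot(inherits(model, "gcnn_model"))
  M <- stack_inputs(list(list(A_hat = A_hat, X = X)), model)[[1L]]
  fw <- forward_batch(M, model, 1L)
  as.numeric(fw$P)
}
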