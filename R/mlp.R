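# Multilayer-perceptron backend: architecture construction, forward pass,
# backpropagation with Adam, and early-stopped batch training. Written in
# base R matrix code; at the scale of one participant (~100 samples, 43
# features, hidden widths <= 60) this trains in well under a second.

#' Linearly interpolated layer widths
#'
#' The network width profile is defined by two numbers only: the first hidden
#' width and the output width. The remaining hidden widths are linear
#' interpolation between them at `n_layers + 1` equally spaced points, each
#' rounded to the nearest integer (ties away from zero). The first `n_layers`
#' entries are hidden widths; the last entry is the output layer.
#'
#' @param input_neurons width of the first hidden layer.
#' @param output_width 7 (classification) or 1 (regression).
#' @param n_layers number of hidden layers (>= 2).
#' @return integer vector of `n_layers + 1` widths, monotone non-increasing.
#' @examples
#' interpolate_layer_widths(31, 1, 2)  # 31 16 1
#' interpolate_layer_widths(39, 7, 3)  # 39 28 18 7
#' @export
interpolate_layer_widths <- function(input_neurons, output_width, n_layers) {
  if (n_layers < 2L) stop_config("n_layers must be >= 2")
  if (input_neurons <= output_width)
    stop_config("input_neurons must exceed output_width")
  pts <- seq(input_neurons, output_width, length.out = n_layers + 1L)
  as.integer(round_half_up(pts))
}

#' Architecture specification
#'
#' The four optimised hyperparameters of the pipeline -- hidden-layer count,
#' first-hidden-layer width, activation and batch size -- plus the problem
#' type, with the derived interpolated width profile. Bounds: 2--4 hidden
#' layers, 30--60 input neurons, activation in {tanh, relu, elu, linear},
#' batch size in {4, 6, 8}.
#'
#' @param n_layers hidden layer count in `[2, 4]`.
#' @param input_neurons first hidden width in `[30, 60]`.
#' @param activation hidden activation.
#' @param batch_size training batch size.
#' @param problem_type `"classification"` (7 softmax outputs) or
#'   `"regression"` (1 linear output).
#' @return object of class `arch_spec` with `layer_widths` attached.
#' @export
arch_spec <- function(n_layers, input_neurons,
                      activation = c("tanh", "relu", "elu", "linear"),
                      batch_size = c(4L, 6L, 8L),
                      problem_type = c("classification", "regression")) {
  activation <- match.arg(activation)
  problem_type <- match.arg(problem_type)
  batch_size <- as.integer(batch_size)[1L]
  if (!batch_size %in% c(4L, 6L, 8L))
    stop_config("batch_size must be one of 4, 6, 8")
  if (n_layers < 2L || n_layers > 4L)
    stop_config("n_layers must lie in [2, 4]")
  if (input_neurons < 30L || input_neurons > 60L)
    stop_config("input_neurons must lie in [30, 60]")
  out_w <- if (problem_type == "classification") 7L else 1L
  structure(list(n_layers = as.integer(n_layers),
                 input_neurons = as.integer(input_neurons),
                 activation = activation, batch_size = batch_size,
                 problem_type = problem_type,
                 layer_widths = interpolate_layer_widths(input_neurons, out_w,
                                                         n_layers)),
            class = "arch_spec")
}

#' @export
print.arch_spec <- function(x, ...) {
  cat("<arch_spec> ", x$problem_type, ": widths [",
      paste(x$layer_widths, collapse = ", "), "], activation ", x$activation,
      ", batch ", x$batch_size, "\n", sep = "")
  invisible(x)
}

n_model_params <- function(arch, n_features) {
  dims <- c(n_features, arch$layer_widths)
  sum(dims[-length(dims)] * dims[-1] + dims[-1])
}

activation_fun <- function(name) {
  switch(name,
         tanh = list(f = tanh, df = function(z, a) 1 - a^2),
         relu = list(f = function(z) pmax(z, 0),
                     df = function(z, a) (z > 0) * 1),
         elu = list(f = function(z) ifelse(z > 0, z, exp(z) - 1),
                    df = function(z, a) ifelse(z > 0, 1, a + 1)),
         linear = list(f = identity, df = function(z, a) 1),
         stop_config("unknown activation: ", name))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Build a seeded feed-forward network
#'
#' Dense layers following the architecture's interpolated width profile, with
#' the configured hidden activation; the output layer has 7 units squashed by
#' a softmax (classification, class probabilities) or a single unit with no
#' activation (regression). Weights use seeded Glorot-uniform initialisation,
#' so the same `(arch, n_features, seed)` always yields identical initial
#' weights.
#'
#' @param arch an [arch_spec()].
#' @param n_features input dimension.
#' @param seed integer seed for initialisation.
#' @return object of class `mlp_model`.
#' @export
build_mlp <- function(arch, n_features, seed = 1L) {
  dims <- c(n_features, arch$layer_widths)
  L <- length(dims) - 1L
  with_seed(derive_seed(seed, "init"), {
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      lim <- sqrt(6 / (dims[l] + dims[l + 1L]))
      W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1L], -lim, lim),
                       dims[l], dims[l + 1L])
      b[[l]] <- rep(0, dims[l + 1L])
    }
  })
  structure(list(W = W, b = b, arch = arch, n_features = n_features),
            class = "mlp_model")
}

mlp_forward <- function(model, X, keep = FALSE) {
  act <- activation_fun(model$arch$activation)
  L <- length(model$W)
  A <- list(X); Z <- vector("list", L)
  for (l in seq_len(L)) {
    Zl <- sweep(A[[l]] %*% model$W[[l]], 2, model$b[[l]], "+")
    Z[[l]] <- Zl
    A[[l + 1L]] <- if (l < L) act$f(Zl) else
      if (model$arch$problem_type == "classification") softmax_rows(Zl) else Zl
  }
  if (keep) list(A = A, Z = Z) else A[[L + 1L]]
}

#' Predict with an MLP
#'
#' @param model an `mlp_model`.
#' @param X numeric matrix on the scale the model was trained on.
#' @return classification: `n x 7` class-probability matrix (rows sum to 1);
#'   regression: length-`n` numeric vector.
#' @export
mlp_predict <- function(model, X) {
  out <- mlp_forward(model, as.matrix(X))
  if (model$arch$problem_type == "regression") drop(out) else out
}

#' Sparse categorical cross-entropy
#'
#' Mean over samples of `-log p(true class)`, the multiclass log loss on
#' integer labels. Probabilities are clipped at `1e-12` to avoid `log(0)`.
#'
#' @param y_true integer labels in `1..ncol(probs)`.
#' @param probs matrix of class probabilities, rows summing to 1.
#' @return non-negative scalar loss.
#' @examples
#' p <- matrix(1 / 7, 1, 7)
#' sparse_categorical_cross_entropy(3, p)  # log(7)
#' @export
sparse_categorical_cross_entropy <- function(y_true, probs) {
  probs <- matrix(probs, nrow = length(y_true))
  p_true <- probs[cbind(seq_along(y_true), y_true)]
  mean(-log(pmax(p_true, 1e-12)))
}

training_loss <- function(model, X, y, loss_kind) {
  out <- mlp_forward(model, X)
  switch(loss_kind,
         cross_entropy = sparse_categorical_cross_entropy(y, out),
         mse = mean((drop(out) - y)^2),
         mae = mean(abs(drop(out) - y)),
         stop_config("unknown loss: ", loss_kind))
}

# gradient of the loss w.r.t. all weights, evaluated on one batch
mlp_gradients <- function(model, X, y, loss_kind) {
  act <- activation_fun(model$arch$activation)
  L <- length(model$W)
  fw <- mlp_forward(model, X, keep = TRUE)
  A <- fw$A; Z <- fw$Z
  n <- nrow(X)
  out <- A[[L + 1L]]
  if (loss_kind == "cross_entropy") {
    Y <- matrix(0, n, ncol(out)); Y[cbind(seq_len(n), y)] <- 1
    dZ <- (out - Y) / n
  } else if (loss_kind == "mse") {
    dZ <- 2 * (out - y) / n
  } else {
    dZ <- sign(out - y) / n
  }
  dW <- vector("list", L); db <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(A[[l]], dZ)
    db[[l]] <- colSums(dZ)
    if (l > 1L) {
      dA <- dZ %*% t(model$W[[l]])
      dZ <- dA * act$df(Z[[l - 1L]], A[[l]])
    }
  }
  list(dW = dW, db = db)
}

#' Train an MLP with Adam and early stopping
#'
#' Stochastic training on shuffled batches with the Adam update (step size
#' 1e-3, beta1 0.9, beta2 0.999). A stratified 15% slice of the training data
#' is held out as a validation monitor; the weights from the best-monitored
#' epoch are retained, and training stops early once the monitor fails to
#' improve for `patience` epochs. With too few rows for a meaningful holdout
#' (< 20), the training loss itself is monitored.
#'
#' @param model an `mlp_model` from [build_mlp()].
#' @param X complete, normalised feature matrix.
#' @param y integer labels (classification) or numeric targets (regression).
#' @param loss_kind `"cross_entropy"`, `"mse"` or `"mae"`; default per
#'   problem type.
#' @param epochs maximum epochs (default 100).
#' @param patience early-stopping patience in epochs (default 10).
#' @param seed integer seed (shuffling and validation split).
#' @return the trained `mlp_model`, with attributes `history` (monitored loss
#'   per epoch) and `best_monitor`.
#' @export
mlp_train <- function(model, X, y, loss_kind = NULL, epochs = 100L,
                      patience = 10L, seed = 1L) {
  X <- as.matrix(X)
  cls <- model$arch$problem_type == "classification"
  if (is.null(loss_kind)) loss_kind <- if (cls) "cross_entropy" else "mse"
  if (cls && loss_kind != "cross_entropy")
    stop_config("classification uses the cross-entropy loss")
  n <- nrow(X)

  with_seed(derive_seed(seed, "train"), {
    if (n >= 20L) {
      val_idx <- stratified_holdout(y, frac = 0.15)
    } else val_idx <- integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xva <- X[val_idx, , drop = FALSE]; yva <- y[val_idx]

    mW <- lapply(model$W, function(w) w * 0); vW <- mW
    mb <- lapply(model$b, function(b) b * 0); vb <- mb
    lr <- 1e-3; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
    best <- Inf; best_model <- model; wait <- 0L
    history <- numeric(0)
    bs <- model$arch$batch_size

    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(ytr))
      starts <- seq(1L, length(ytr), by = bs)
      for (s in starts) {
        idx <- ord[s:min(s + bs - 1L, length(ytr))]
        g <- mlp_gradients(model, Xtr[idx, , drop = FALSE], ytr[idx], loss_kind)
        t <- t + 1L
        for (l in seq_along(model$W)) {
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$dW[[l]]
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$dW[[l]]^2
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$db[[l]]
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$db[[l]]^2
          mhW <- mW[[l]] / (1 - b1^t); vhW <- vW[[l]] / (1 - b2^t)
          mhb <- mb[[l]] / (1 - b1^t); vhb <- vb[[l]] / (1 - b2^t)
          model$W[[l]] <- model$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
          model$b[[l]] <- model$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
        }
      }
      monitor <- if (length(val_idx))
        training_loss(model, Xva, yva, loss_kind)
      else training_loss(model, Xtr, ytr, loss_kind)
      history <- c(history, monitor)
      if (monitor < best - 1e-9) {
        best <- monitor; best_model <- model; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })
  attr(best_model, "history") <- history
  attr(best_model, "best_monitor") <- best
  best_model
}

# stratified fraction holdout (indices), at least one row kept per side
stratified_holdout <- function(y, frac) {
  idx <- unlist(lapply(split(seq_along(y), y), function(ix) {
    take <- floor(length(ix) * frac)
    if (take == 0L) return(integer(0))
    sample(ix, take)
  }))
  as.integer(idx)
}
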