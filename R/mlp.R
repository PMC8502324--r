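#' Sigmoid activation functions
#'
#' `tansig(z) = 2/(1 + exp(-2 z)) - 1` (hyperbolic-tangent sigmoid) and
#' `logsig(z) = 1/(1 + exp(-z))` (logistic sigmoid): the two hidden-layer
#' activations of the network, related by
#' `tansig(z) = 2 * logsig(2 z) - 1`.
#'
#' @param z numeric vector or matrix.
#' @return transformed values, same shape as `z`.
#' @export
tansig <- function(z) 2 / (1 + exp(-2 * z)) - 1

#' @rdname tansig
#' @export
logsig <- function(z) 1 / (1 + exp(-z))

activation_fun <- function(kind) {
  switch(kind, tansig = tansig, logsig = logsig,
         stop_los("unknown activation '%s'", kind))
}

# Derivative expressed through the activation value h = sigma(z).
activation_deriv <- function(kind, h) {
  switch(kind, tansig = 1 - h^2, logsig = h * (1 - h))
}

#' Single-hidden-layer perceptron parameters
#'
#' Container for the synaptic weights of a feed-forward network with one
#' hidden layer: input-to-hidden weights `W_in` (hidden x inputs) with
#' biases `b_in`, hidden-to-output weights `w_out` (length hidden) with
#' bias `b_out`, a sigmoidal hidden activation (`tansig` or `logsig`)
#' and a linear output unit.
#'
#' @param W_in numeric matrix, hidden x inputs.
#' @param b_in numeric vector, length hidden.
#' @param w_out numeric vector, length hidden.
#' @param b_out numeric scalar.
#' @param activation `"tansig"` or `"logsig"`.
#' @param input_names optional character vector naming the input columns.
#' @return object of class `mlp_net`.
#' @export
mlp_network <- function(W_in, b_in, w_out, b_out,
                        activation = c("tansig", "logsig"),
                        input_names = NULL) {
  activation <- match.arg(activation)
  W_in <- as.matrix(W_in)
  h <- nrow(W_in)
  if (length(b_in) != h || length(w_out) != h || length(b_out) != 1)
    stop_los("inconsistent network dimensions")
  if (!all(is.finite(W_in)) || !all(is.finite(b_in)) ||
      !all(is.finite(w_out)) || !is.finite(b_out))
    stop_los("network weights must be finite")
  if (!is.null(input_names)) {
    if (length(input_names) != ncol(W_in))
      stop_los("input_names length must match number of inputs")
    colnames(W_in) <- input_names
  }
  structure(list(W_in = W_in, b_in = as.numeric(b_in),
                 w_out = as.numeric(w_out), b_out = as.numeric(b_out),
                 activation = activation),
            class = "mlp_net")
}

#' Forward pass of the perceptron
#'
#' Computes the linear-output score
#' `b_out + sum_j w_out[j] * sigma(W_in[j, ] %*% x + b_in[j])`
#' for each input row.
#'
#' @param net an `mlp_net`.
#' @param X numeric vector (one input) or matrix (one row per input).
#' @return numeric score vector, one element per input row.
#' @export
mlp_forward <- function(net, X) {
  stopifnot(inherits(net, "mlp_net"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != ncol(net$W_in))
    stop_los("input has %d columns, network expects %d",
             ncol(X), ncol(net$W_in))
  sigma <- activation_fun(net$activation)
  H <- sigma(X %*% t(net$W_in) +
               matrix(net$b_in, nrow(X), length(net$b_in), byrow = TRUE))
  as.numeric(H %*% net$w_out + net$b_out)
}

#' @describeIn mlp_forward Binary prediction: 1 when the score reaches
#'   the cutoff (boundary rule: a score exactly at the cutoff predicts 1).
#' @param object an `mlp_net`.
#' @param cutoff classification cutoff on the linear output (default 0.5
#'   for 0/1-coded targets).
#' @param ... unused.
#' @export
predict.mlp_net <- function(object, X, cutoff = 0.5, ...) {
  as.integer(mlp_forward(object, X) >= cutoff)
}

# Mean-squared error and its analytic gradient on a batch; the gradient
# is validated against finite differences in the test suite.
mlp_loss <- function(net, X, y) {
  mean((mlp_forward(net, X) - y)^2)
}

mlp_gradient <- function(net, X, y) {
  n <- nrow(X)
  sigma <- activation_fun(net$activation)
  H <- sigma(X %*% t(net$W_in) +
               matrix(net$b_in, n, length(net$b_in), byrow = TRUE))
  e <- as.numeric(H %*% net$w_out + net$b_out) - y
  d_out <- 2 * e / n                      # dMSE / dscore
  g_w_out <- as.numeric(t(H) %*% d_out)
  g_b_out <- sum(d_out)
  delta_H <- (d_out %o% net$w_out) * activation_deriv(net$activation, H)
  g_W_in <- t(delta_H) %*% X
  g_b_in <- colSums(delta_H)
  list(W_in = g_W_in, b_in = g_b_in, w_out = g_w_out, b_out = g_b_out)
}

#' Training hyperparameters
#'
#' @param n_hidden number of hidden neurons; `NULL` selects it
#'   empirically over the grid \{ceiling(p/2), p, 2p+1\} (p inputs) by
#'   validation balanced accuracy (see [choose_hidden_size()]).
#' @param learning_rate initial gradient-descent step size.
#' @param max_epochs maximum number of full-batch epochs.
#' @param error_threshold training stops once the MSE falls below this
#'   predefined error threshold.
#' @param activation hidden-layer activation, `"tansig"` or `"logsig"`.
#' @param seed integer seed for the random weight initialization.
#' @return list of class `training_control`.
#' @export
training_control <- function(n_hidden = NULL, learning_rate = 0.1,
                             max_epochs = 2000, error_threshold = 1e-4,
                             activation = c("tansig", "logsig"), seed = 1) {
  activation <- match.arg(activation)
  if (!is.null(n_hidden) && n_hidden < 1) stop_los("n_hidden must be >= 1")
  if (learning_rate <= 0) stop_los("learning_rate must be positive")
  if (error_threshold < 0) stop_los("error_threshold must be non-negative")
  structure(list(n_hidden = n_hidden, learning_rate = learning_rate,
                 max_epochs = max_epochs, error_threshold = error_threshold,
                 activation = activation, seed = as.integer(seed)),
            class = "training_control")
}

#' Train the perceptron by back-propagation
#'
#' Full-batch gradient descent on the mean-squared output error, with a
#' variable learning rate in the classic adaptive style: the step size
#' grows by 5% after every successful epoch and shrinks (with the step
#' rejected) when the error would rise by more than 4%.  Rejected steps
#' make the recorded training MSE non-increasing up to that tolerance.
#' Weights are initialized uniformly on (-0.5, 0.5) from the seeded
#' generator, so training is deterministic given the seed; training
#' stops at the predefined error threshold or at `max_epochs`.
#'
#' @param X numeric design matrix (n x p).
#' @param y 0/1 target vector of length n; both classes must be present.
#' @param control a [training_control()].
#' @return trained `mlp_net` with attributes `mse_trace` (per-epoch MSE)
#'   and `epochs`.
#' @export
mlp_train <- function(X, y, control = training_control()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop_los("X and y sizes differ")
  if (nrow(X) < 2) stop_los("need at least 2 training rows")
  if (length(unique(y)) < 2)
    stop_los("degenerate learning task: only one class present in y")
  p <- ncol(X)
  h <- control$n_hidden %||% max(1L, ceiling(p / 2))

  set.seed(control$seed)
  net <- mlp_network(
    W_in = matrix(runif(h * p, -0.5, 0.5), h, p),
    b_in = runif(h, -0.5, 0.5),
    w_out = runif(h, -0.5, 0.5),
    b_out = runif(1, -0.5, 0.5),
    activation = control$activation,
    input_names = colnames(X)
  )

  lr <- control$learning_rate
  mse <- mlp_loss(net, X, y)
  trace <- numeric(control$max_epochs)
  epoch <- 0L
  while (epoch < control$max_epochs && mse > control$error_threshold) {
    epoch <- epoch + 1L
    g <- mlp_gradient(net, X, y)
    cand <- net
    cand$W_in <- net$W_in - lr * g$W_in
    cand$b_in <- net$b_in - lr * g$b_in
    cand$w_out <- net$w_out - lr * g$w_out
    cand$b_out <- net$b_out - lr * g$b_out
    cand_mse <- mlp_loss(cand, X, y)
    if (cand_mse > mse * 1.04) {
      lr <- lr * 0.7                      # reject the step, cool down
    } else {
      net <- cand
      lr <- lr * 1.05
      mse <- cand_mse
    }
    trace[epoch] <- mse
  }
  attr(net, "mse_trace") <- trace[seq_len(epoch)]
  attr(net, "epochs") <- epoch
  net
}

#' @export
print.mlp_net <- function(x, ...) {
  cat(sprintf("Single-hidden-layer perceptron: %d inputs -> %d %s hidden -> linear output\n",
              ncol(x$W_in), nrow(x$W_in), x$activation))
  invisible(x)
}

#' Plain-text network serialization
#'
#' Writes the network to a small self-describing text file: a header
#' with the dimensions and the activation kind, then `b_out`, `w_out`,
#' `b_in` and the rows of `W_in`, all in full double precision.
#'
#' @param net an `mlp_net`.
#' @param path output path.
#' @return `path` (writer) or the restored `mlp_net` (reader).
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "mlp_net"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("mlp_net 1"),
    sprintf("inputs %d", ncol(net$W_in)),
    sprintf("hidden %d", nrow(net$W_in)),
    sprintf("activation %s", net$activation),
    sprintf("input_names %s",
            paste(colnames(net$W_in) %||% character(0), collapse = "\t")),
    paste("b_out", sprintf("%.17g", net$b_out)),
    paste("w_out", paste(sprintf("%.17g", net$w_out), collapse = " ")),
    paste("b_in", paste(sprintf("%.17g", net$b_in), collapse = " "))
  ), con)
  for (j in seq_len(nrow(net$W_in)))
    writeLines(paste("W_in", paste(sprintf("%.17g", net$W_in[j, ]),
                                   collapse = " ")), con)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "mlp_net"))
    stop_los("'%s' is not a network weight file", path)
  val <- function(key) {
    line <- lines[startsWith(lines, paste0(key, " "))][1]
    sub(paste0("^", key, " "), "", line)
  }
  p <- as.integer(val("inputs"))
  h <- as.integer(val("hidden"))
  nm <- strsplit(val("input_names"), "\t", fixed = TRUE)[[1]]
  w_rows <- lines[startsWith(lines, "W_in ")]
  W <- do.call(rbind, lapply(w_rows, function(l)
    as.numeric(strsplit(sub("^W_in ", "", l), " +")[[1]])))
  mlp_network(
    W_in = W,
    b_in = as.numeric(strsplit(val("b_in"), " +")[[1]]),
    w_out = as.numeric(strsplit(val("w_out"), " +")[[1]]),
    b_out = as.numeric(val("b_out")),
    activation = val("activation"),
    input_names = if (length(nm) == p) nm else NULL
  )
}
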