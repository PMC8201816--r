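# Minimal dense-network engine: seeded initialization, forward pass,
# backpropagation with an activation penalty injected at one designated
# "structured" layer, and Adam updates. Everything is plain vectorized matrix
# arithmetic; the architectures in scope are small (a few thousand weights),
# so no external framework is involved and runs are exactly reproducible.

#' Specify a dense model with one structured layer
#'
#' Describes either an autoencoder (encoder layer sizes given; decoder
#' mirrored) or a classifier. One hidden layer is designated as the
#' *structured* layer: its activations carry the graph penalty and are what
#' all downstream analysis reads out.
#'
#' @param task `"autoencoding"` or `"classification"`.
#' @param layer_sizes Integer vector `c(input, hidden..., embedding)`. For an
#'   autoencoder the decoder mirrors the encoder back to `input`; for a
#'   classifier a final layer of `n_classes` units with softmax is appended.
#' @param structured_layer_index Which hidden layer (1-based, counting dense
#'   layers after the input) is the structured one. Defaults to the last
#'   entry of `layer_sizes`, i.e. the embedding.
#' @param activation Hidden nonlinearity: `"relu"` (default), `"tanh"`, or
#'   `"sigmoid"`.
#' @param output One of `"linear"` (default; squared-error reconstruction)
#'   or `"sigmoid"` (sigmoid output with binary cross-entropy loss, for data
#'   in `[0, 1]`). Autoencoders only.
#' @param n_classes Number of classes (classification only).
#' @return An object of class `model_spec`. Its `embedding_dim` is the width
#'   of the structured layer and must match the node count of any attached
#'   graph.
#' @export
model_spec <- function(task = c("autoencoding", "classification"),
                       layer_sizes, structured_layer_index = NULL,
                       activation = c("relu", "tanh", "sigmoid"),
                       output = c("linear", "sigmoid"),
                       n_classes = NULL) {
  task <- match.arg(task)
  activation <- match.arg(activation)
  output <- match.arg(output)
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    stop("`layer_sizes` needs >= 2 positive entries: c(input, ..., embedding)")
  }
  if (task == "classification") {
    if (is.null(n_classes) || n_classes < 2L) {
      stop("classification requires `n_classes` >= 2")
    }
    n_classes <- as.integer(n_classes)
  }
  n_hidden <- length(layer_sizes) - 1L
  if (is.null(structured_layer_index)) structured_layer_index <- n_hidden
  if (structured_layer_index < 1L || structured_layer_index > n_hidden) {
    stop(sprintf("`structured_layer_index` must be in 1..%d", n_hidden))
  }
  structure(
    list(task = task, layer_sizes = layer_sizes,
         structured_layer_index = as.integer(structured_layer_index),
         activation = activation, output = output, n_classes = n_classes,
         embedding_dim = layer_sizes[structured_layer_index + 1L]),
    class = "model_spec")
}

# Full stack of layer widths, input first, output last.
model_stack_sizes <- function(spec) {
  if (spec$task == "autoencoding") {
    c(spec$layer_sizes, rev(spec$layer_sizes)[-1L])
  } else {
    c(spec$layer_sizes, spec$n_classes)
  }
}

act_fun <- function(name) {
  switch(name,
         relu = function(x) pmax(x, 0),
         tanh = tanh,
         sigmoid = function(x) 1 / (1 + exp(-x)))
}

# derivative expressed through the post-activation value
act_deriv <- function(name) {
  switch(name,
         relu = function(h) (h > 0) * 1,
         tanh = function(h) 1 - h^2,
         sigmoid = function(h) h * (1 - h))
}

#' Build a dense model with deterministic initialization
#'
#' Glorot-uniform weight initialization driven entirely by `seed`: the same
#' spec and seed always produce bit-identical parameters.
#'
#' @param spec A [model_spec].
#' @param seed Integer seed for the initialization RNG.
#' @return An object of class `structured_model` holding the weight matrices,
#'   biases, and the index of the structured layer.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  sizes <- model_stack_sizes(spec)
  set.seed(seed)
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]
    fan_out <- sizes[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    layers[[l]] <- list(
      W = matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
      b = rep(0, fan_out))
  }
  structure(
    list(spec = spec, sizes = sizes, layers = layers,
         structured = spec$structured_layer_index, opt = NULL),
    class = "structured_model")
}

#' @export
print.structured_model <- function(x, ...) {
  cat(sprintf("structured_model (%s): layers %s, structured layer #%d (%d units)\n",
              x$spec$task, paste(x$sizes, collapse = "-"),
              x$structured, x$sizes[x$structured + 1L]))
  invisible(x)
}

softmax_rows <- function(a) {
  a <- a - apply(a, 1L, max)
  e <- exp(a)
  e / rowSums(e)
}

#' Forward pass
#'
#' Runs `x` through the model and returns the task output together with the
#' structured layer's activations.
#'
#' @param model A `structured_model`.
#' @param x Numeric matrix, samples x input features.
#' @return List with `output` (reconstruction, or class probabilities with
#'   rows summing to 1) and `structured` (samples x embedding activations).
#' @export
model_forward <- function(model, x) {
  acts <- forward_pass(model, x)
  list(output = acts$h[[length(acts$h)]], structured = acts$h[[model$structured]])
}

# Internal forward keeping every layer's post-activation (h[[l]] for dense
# layer l; the input is acts$x).
forward_pass <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$sizes[1L]) {
    stop(sprintf("input has %d columns; model expects %d",
                 ncol(x), model$sizes[1L]))
  }
  f <- act_fun(model$spec$activation)
  n_layers <- length(model$layers)
  h <- vector("list", n_layers)
  cur <- x
  for (l in seq_len(n_layers)) {
    a <- cur %*% model$layers[[l]]$W +
      matrix(model$layers[[l]]$b, nrow(cur), ncol(model$layers[[l]]$W),
             byrow = TRUE)
    if (l == n_layers) {
      h[[l]] <- if (model$spec$task == "classification") {
        softmax_rows(a)
      } else if (identical(model$spec$output, "sigmoid")) {
        1 / (1 + exp(-a))
      } else {
        a
      }
    } else {
      h[[l]] <- f(a)
    }
    cur <- h[[l]]
  }
  list(x = x, h = h)
}

#' Structured-layer activations for a dataset
#'
#' @param model A `structured_model`.
#' @param x Samples x features matrix.
#' @return Samples x embedding activation matrix.
#' @export
structured_activations <- function(model, x) {
  model_forward(model, x)$structured
}

#' Training configuration
#'
#' @param alpha Nonnegative regularization weight on the activation penalty.
#' @param epochs Number of passes over the data.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling shuffling (and nothing else).
#' @param regularizer One of `"none"`, `"gsr"`, `"l1"`, `"l2"`; `"gsr"`
#'   requires a feature graph at training time.
#' @param optimizer `"adam"` (default) or `"sgd"` (gradient descent with
#'   momentum 0.9). SGD takes steps proportional to the raw gradient and
#'   needs a correspondingly larger learning rate; Adam's per-parameter
#'   normalization is the robust default at these scales.
#' @param coefficient_grid Optional numeric vector of candidate `alpha`
#'   values for cross-validated selection (see [compare_regularizers]).
#' @return An object of class `train_config`.
#' @export
train_config <- function(alpha = 0, epochs = 20L, batch_size = 64L,
                         learning_rate = 1e-3, seed = 1L,
                         regularizer = c("none", "gsr", "l1", "l2"),
                         optimizer = c("adam", "sgd"),
                         coefficient_grid = NULL) {
  regularizer <- match.arg(regularizer)
  optimizer <- match.arg(optimizer)
  if (alpha < 0) stop("`alpha` must be nonnegative")
  if (epochs < 1 || batch_size < 1 || learning_rate <= 0) {
    stop("`epochs`, `batch_size` must be >= 1 and `learning_rate` > 0")
  }
  structure(
    list(alpha = alpha, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, seed = as.integer(seed),
         regularizer = regularizer, optimizer = optimizer,
         coefficient_grid = coefficient_grid),
    class = "train_config")
}

# Penalty value of structured activations under a regularizer.
activation_penalty <- function(z, regularizer, graph = NULL) {
  switch(regularizer,
         none = 0,
         gsr = gsr_penalty(z, graph),
         l1 = mean(abs(z)),
         l2 = mean(z^2))
}

# Gradient of the penalty w.r.t. the structured activations z (B x e).
activation_penalty_grad <- function(z, regularizer, graph = NULL) {
  b <- nrow(z)
  switch(regularizer,
         none = 0,
         gsr = (2 / b) * (z %*% graph$laplacian),
         l1 = sign(z) / length(z),
         l2 = 2 * z / length(z))
}

#' Composite loss: task loss plus weighted activation penalty
#'
#' Returns `task_loss + alpha * penalty`, where the penalty is the graph
#' spectral penalty ([gsr_penalty]), the mean absolute activation (L1), the
#' mean squared activation (L2), or zero.
#'
#' @param task_loss Scalar task loss (MSE or cross-entropy).
#' @param activations Structured-layer activations, samples x neurons.
#' @param graph Feature graph; required when `config$regularizer == "gsr"`.
#' @param config A [train_config].
#' @return The composite scalar loss.
#' @export
composite_loss <- function(task_loss, activations, graph = NULL, config) {
  stopifnot(inherits(config, "train_config"))
  if (config$regularizer == "gsr" && is.null(graph)) {
    stop("regularizer 'gsr' requires a feature graph")
  }
  if (is.vector(activations)) activations <- matrix(activations, nrow = 1L)
  task_loss + config$alpha *
    activation_penalty(activations, config$regularizer, graph)
}

adam_init <- function(layers) {
  list(t = 0L,
       m = lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0)),
       v = lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0)))
}

#' Train a structured model
#'
#' Minibatch training with Adam. The objective is
#' `task loss + alpha * penalty`, with the penalty evaluated on the
#' structured layer's activations. Shuffling and initialization are fully
#' seeded, so identical configurations give identical loss traces. Optimizer
#' state is kept on the model, so successive calls fine-tune rather than
#' restart.
#'
#' @param model A `structured_model` from [build_model].
#' @param data Samples x features numeric matrix.
#' @param labels Class labels (classification only), any vector coercible to
#'   factor, aligned with rows of `data`.
#' @param graph Feature graph for the `"gsr"` regularizer; its node count
#'   must equal the structured layer width.
#' @param config A [train_config].
#' @return List of class `gsr_fit` with `model` (updated weights) and `trace`
#'   (data.frame: epoch, task_loss, penalty, composite), one row per epoch,
#'   each the mean over that epoch's minibatches. `composite` always equals
#'   `task_loss + alpha * penalty`.
#' @export
train <- function(model, data, labels = NULL, graph = NULL, config) {
  stopifnot(inherits(model, "structured_model"),
            inherits(config, "train_config"))
  if (!is.matrix(data)) data <- as.matrix(data)
  if (any(!is.finite(data))) stop("`data` contains non-finite values")
  reg <- config$regularizer
  if (reg == "gsr") {
    if (is.null(graph)) stop("regularizer 'gsr' requires a feature graph")
    e_dim <- model$sizes[model$structured + 1L]
    if (graph$n_nodes != e_dim) {
      stop(sprintf("graph has %d nodes but structured layer has %d units",
                   graph$n_nodes, e_dim))
    }
  }
  classify <- model$spec$task == "classification"
  if (classify) {
    if (is.null(labels)) stop("classification requires `labels`")
    yf <- factor(labels)
    if (nlevels(yf) > model$spec$n_classes) {
      stop("more label levels than model classes")
    }
    y_onehot <- diag(model$spec$n_classes)[as.integer(yf), , drop = FALSE]
  }
  n <- nrow(data)
  dact <- act_deriv(model$spec$activation)
  if (is.null(model$opt)) model$opt <- adam_init(model$layers)
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n_layers <- length(model$layers)
  trace <- data.frame(epoch = seq_len(config$epochs), task_loss = NA_real_,
                      penalty = NA_real_, composite = NA_real_)
  set.seed(config$seed)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_task <- 0; ep_pen <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      xb <- data[idx, , drop = FALSE]
      fp <- forward_pass(model, xb)
      bsz <- length(idx)
      out <- fp$h[[n_layers]]
      if (classify) {
        yb <- y_onehot[idx, , drop = FALSE]
        task <- -sum(yb * log(pmax(out, 1e-12))) / bsz
        delta <- (out - yb) / bsz           # grad w.r.t. output pre-activation
      } else if (identical(model$spec$output, "sigmoid")) {
        # mean binary cross-entropy; targets clipped into [0, 1]
        tb <- pmin(pmax(xb, 0), 1)
        task <- -mean(tb * log(pmax(out, 1e-12)) +
                        (1 - tb) * log(pmax(1 - out, 1e-12)))
        delta <- (out - tb) / length(out)      # grad w.r.t. pre-activation
      } else {
        task <- mean((out - xb)^2)
        delta <- 2 * (out - xb) / length(out)  # linear output
      }
      z <- fp$h[[model$structured]]
      pen <- activation_penalty(z, reg, graph)
      # backward
      grads <- vector("list", n_layers)
      for (l in rev(seq_len(n_layers))) {
        h_prev <- if (l == 1L) fp$x else fp$h[[l - 1L]]
        grads[[l]] <- list(W = crossprod(h_prev, delta), b = colSums(delta))
        if (l > 1L) {
          dh <- delta %*% t(model$layers[[l]]$W)
          if (l - 1L == model$structured && reg != "none" &&
              config$alpha > 0) {
            dh <- dh + config$alpha *
              activation_penalty_grad(fp$h[[model$structured]], reg, graph)
          }
          delta <- dh * dact(fp$h[[l - 1L]])
        }
      }
      # optimizer step
      model$opt$t <- model$opt$t + 1L
      if (config$optimizer == "adam") {
        bc1 <- 1 - beta1^model$opt$t
        bc2 <- 1 - beta2^model$opt$t
        for (l in seq_len(n_layers)) {
          for (p in c("W", "b")) {
            g <- grads[[l]][[p]]
            model$opt$m[[l]][[p]] <- beta1 * model$opt$m[[l]][[p]] +
              (1 - beta1) * g
            model$opt$v[[l]][[p]] <- beta2 * model$opt$v[[l]][[p]] +
              (1 - beta2) * g^2
            model$layers[[l]][[p]] <- model$layers[[l]][[p]] -
              lr * (model$opt$m[[l]][[p]] / bc1) /
                (sqrt(model$opt$v[[l]][[p]] / bc2) + eps)
          }
        }
      } else {
        for (l in seq_len(n_layers)) {
          for (p in c("W", "b")) {
            model$opt$m[[l]][[p]] <- 0.9 * model$opt$m[[l]][[p]] +
              grads[[l]][[p]]
            model$layers[[l]][[p]] <- model$layers[[l]][[p]] -
              lr * model$opt$m[[l]][[p]]
          }
        }
      }
      w <- bsz / n
      ep_task <- ep_task + w * task
      ep_pen <- ep_pen + w * pen
    }
    comp <- ep_task + config$alpha * ep_pen
    if (!is.finite(comp)) {
      stop(sprintf("non-finite loss at epoch %d (task %g, penalty %g); reduce the learning rate or alpha",
                   ep, ep_task, ep_pen))
    }
    trace$task_loss[ep] <- ep_task
    trace$penalty[ep] <- ep_pen
    trace$composite[ep] <- comp
  }
  structure(list(model = model, trace = trace, config = config),
            class = "gsr_fit")
}

#' @export
print.gsr_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf(
    "gsr_fit: %d epochs (%s, alpha = %g); final task loss %.5g, penalty %.5g\n",
    nrow(x$trace), x$config$regularizer, x$config$alpha,
    last$task_loss, last$penalty))
  invisible(x)
}

classifier_accuracy <- function(model, x, labels, levels_) {
  p <- model_forward(model, x)$output
  pred <- levels_[max.col(p, ties.method = "first")]
  mean(pred == as.character(labels))
}

#' Compare activation regularizers with cross-validated coefficients
#'
#' For each regularizer (`none`, `l1`, `l2`, `gsr`), selects the coefficient
#' from `grid` that maximizes validation accuracy on a seeded 80/20 split of
#' the training data, then retrains at the selected coefficient over
#' `n_replicates` seeds and reports mean and standard deviation of training
#' and test accuracy. L1/L2 are applied to the same structured-layer
#' activations as the graph penalty, so the comparison isolates the effect of
#' the graph structure itself.
#'
#' @param train_data,train_labels,test_data,test_labels The labeled split.
#' @param spec A classification [model_spec].
#' @param grid Numeric vector of candidate coefficients (e.g.
#'   `10^seq(-7, -2)`).
#' @param config Base [train_config]; its `seed`, `epochs`, `batch_size` and
#'   `learning_rate` are reused for every run.
#' @param graph Feature graph for the `gsr` rows.
#' @param regularizers Character subset of
#'   `c("none", "l1", "l2", "gsr")`.
#' @param n_replicates Replicate seeds at the selected coefficient
#'   (default 10).
#' @return data.frame with one row per regularizer: `regularizer`,
#'   `coefficient` (NA for `none`), `train_mean`, `train_sd`, `test_mean`,
#'   `test_sd`.
#' @export
compare_regularizers <- function(train_data, train_labels, test_data,
                                 test_labels, spec, grid = 10^seq(-7, -2),
                                 config = train_config(epochs = 30L),
                                 graph = NULL,
                                 regularizers = c("none", "l1", "l2", "gsr"),
                                 n_replicates = 10L) {
  stopifnot(inherits(spec, "model_spec"), spec$task == "classification")
  if (length(grid) == 0L) stop("coefficient `grid` must be non-empty")
  regularizers <- match.arg(regularizers, several.ok = TRUE)
  if ("gsr" %in% regularizers && is.null(graph)) {
    stop("comparing 'gsr' requires a feature graph")
  }
  train_data <- as.matrix(train_data)
  test_data <- as.matrix(test_data)
  levels_ <- levels(factor(c(as.character(train_labels),
                             as.character(test_labels))))
  set.seed(config$seed)
  n <- nrow(train_data)
  val_idx <- sample.int(n, size = max(1L, round(0.2 * n)))
  sub_x <- train_data[-val_idx, , drop = FALSE]
  sub_y <- train_labels[-val_idx]
  val_x <- train_data[val_idx, , drop = FALSE]
  val_y <- train_labels[val_idx]

  run_once <- function(reg, coef_, seed_, x, y) {
    cfg <- train_config(alpha = if (reg == "none") 0 else coef_,
                        epochs = config$epochs,
                        batch_size = config$batch_size,
                        learning_rate = config$learning_rate,
                        seed = seed_, regularizer = reg)
    m <- build_model(spec, seed = seed_)
    train(m, x, labels = y, graph = if (reg == "gsr") graph else NULL,
          config = cfg)$model
  }

  rows <- lapply(regularizers, function(reg) {
    if (reg == "none") {
      best <- NA_real_
    } else {
      val_acc <- vapply(grid, function(coef_) {
        m <- run_once(reg, coef_, config$seed, sub_x, sub_y)
        classifier_accuracy(m, val_x, val_y, levels_)
      }, numeric(1L))
      best <- grid[which.max(val_acc)]  # ties: first, i.e. smallest coef
    }
    accs <- vapply(seq_len(n_replicates), function(r) {
      m <- run_once(reg, best, config$seed + r, train_data, train_labels)
      c(classifier_accuracy(m, train_data, train_labels, levels_),
        classifier_accuracy(m, test_data, test_labels, levels_))
    }, numeric(2L))
    data.frame(regularizer = reg, coefficient = best,
               train_mean = mean(accs[1L, ]), train_sd = stats::sd(accs[1L, ]),
               test_mean = mean(accs[2L, ]), test_sd = stats::sd(accs[2L, ]))
  })
  do.call(rbind, rows)
}
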