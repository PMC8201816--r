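# Alternating feature-graph learning: pretrain without regularization, then
# repeatedly (i) rebuild the feature graph from the structured layer's
# co-activations with the adaptive Gaussian kernel and (ii) train for some
# epochs with the graph spectral penalty on that frozen graph. Smoothing on
# the current graph sharpens co-activation structure, which the next kernel
# pass reinforces; the reconstruction loss stops the graph from collapsing,
# so the alternation settles into a steady state.

#' Configuration for graph learning
#'
#' @param pretrain_epochs Epochs of unregularized pretraining (default 50).
#' @param outer_iterations Number of alternation rounds `T` (default 10); in
#'   each round the graph is rebuilt once and then held fixed.
#' @param inner_epochs Training epochs `m` per round on the frozen graph
#'   (default 20).
#' @param alpha Positive weight of the graph penalty during the alternation
#'   (default 1).
#' @param kernel [kernel_params] for the co-activation kernel (default
#'   `k = 1`: nearest-neighbour bandwidth).
#' @param component_threshold Edge weight cutoff used when counting connected
#'   components of learned graphs (default 0.01).
#' @param seed Master seed; pretraining and each round derive their shuffling
#'   seeds from it.
#' @param batch_size,learning_rate Passed through to [train].
#' @return An object of class `graph_learn_config`.
#' @export
graph_learn_config <- function(pretrain_epochs = 50L, outer_iterations = 10L,
                               inner_epochs = 20L, alpha = 1,
                               kernel = kernel_params(),
                               component_threshold = 0.01, seed = 1L,
                               batch_size = 64L, learning_rate = 1e-3) {
  if (pretrain_epochs < 1 || outer_iterations < 1 || inner_epochs < 1) {
    stop("`pretrain_epochs`, `outer_iterations`, `inner_epochs` must be >= 1")
  }
  if (alpha <= 0) stop("`alpha` must be > 0")
  if (component_threshold < 0) stop("`component_threshold` must be >= 0")
  stopifnot(inherits(kernel, "kernel_params"))
  structure(
    list(pretrain_epochs = as.integer(pretrain_epochs),
         outer_iterations = as.integer(outer_iterations),
         inner_epochs = as.integer(inner_epochs), alpha = alpha,
         kernel = kernel, component_threshold = component_threshold,
         seed = as.integer(seed), batch_size = as.integer(batch_size),
         learning_rate = learning_rate),
    class = "graph_learn_config")
}

#' Learn a feature graph by alternating kernel estimation and training
#'
#' Implements the two-phase procedure: pretrain the model with `alpha = 0`;
#' then for `T` rounds, compute the structured layer's activations on the
#' full dataset, build the adaptive Gaussian kernel graph over *features*
#' (the activation matrix transposed, so each neuron is a point whose
#' coordinates are its activations across samples), and train `m` epochs
#' with the graph spectral penalty on that frozen graph. Model weights and
#' optimizer state persist across rounds (fine-tuning, never reinitialized).
#'
#' @param spec A [model_spec]; autoencoders use MSE, classifiers their
#'   cross-entropy (then `labels` is required).
#' @param data Samples x features matrix.
#' @param config A [graph_learn_config].
#' @param labels Class labels, classification only.
#' @return An object of class `graph_learn_result`: list with
#'   * `final_graph` — kernel graph of the trained model's activations;
#'   * `graph_snapshots` — the `T` graphs used during training, in order;
#'   * `trained_model` — the final `structured_model`;
#'   * `components` — [connected_components] of `final_graph` at
#'     `config$component_threshold`;
#'   * `trace` — per-epoch loss trace across all phases, with a `phase`
#'     column (`"pretrain"` or `"iterN"`);
#'   * `penalty_per_iteration` — final-epoch penalty per round.
#' @export
learn_graph <- function(spec, data, config = graph_learn_config(),
                        labels = NULL) {
  stopifnot(inherits(spec, "model_spec"),
            inherits(config, "graph_learn_config"))
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("`data` contains non-finite values")
  model <- build_model(spec, seed = config$seed)
  pre_cfg <- train_config(alpha = 0, epochs = config$pretrain_epochs,
                          batch_size = config$batch_size,
                          learning_rate = config$learning_rate,
                          seed = config$seed, regularizer = "none")
  fit <- train(model, data, labels = labels, config = pre_cfg)
  model <- fit$model
  traces <- list(cbind(fit$trace, phase = "pretrain"))
  snapshots <- vector("list", config$outer_iterations)
  pen_per_iter <- numeric(config$outer_iterations)
  for (it in seq_len(config$outer_iterations)) {
    z <- structured_activations(model, data)
    if (any(!is.finite(z))) {
      stop(sprintf("non-finite activations at outer iteration %d", it))
    }
    g <- adaptive_gaussian_kernel(t(z), config$kernel)
    snapshots[[it]] <- g
    inner_cfg <- train_config(alpha = config$alpha,
                              epochs = config$inner_epochs,
                              batch_size = config$batch_size,
                              learning_rate = config$learning_rate,
                              seed = config$seed + it,
                              regularizer = "gsr")
    fit <- train(model, data, labels = labels, graph = g, config = inner_cfg)
    model <- fit$model
    traces[[it + 1L]] <- cbind(fit$trace, phase = sprintf("iter%d", it))
    pen_per_iter[it] <- fit$trace$penalty[nrow(fit$trace)]
  }
  z_final <- structured_activations(model, data)
  final_graph <- adaptive_gaussian_kernel(t(z_final), config$kernel)
  structure(
    list(final_graph = final_graph, graph_snapshots = snapshots,
         trained_model = model,
         components = connected_components(final_graph,
                                           config$component_threshold),
         trace = do.call(rbind, traces),
         penalty_per_iteration = pen_per_iter,
         config = config),
    class = "graph_learn_result")
}

#' @export
print.graph_learn_result <- function(x, ...) {
  cat(sprintf(
    "graph_learn_result: %d rounds; final graph %d nodes, %d components at threshold %g\n",
    length(x$graph_snapshots), x$final_graph$n_nodes,
    x$components$n_components, x$components$edge_threshold))
  invisible(x)
}

#' Connected-component recovery over repeated trials
#'
#' Generates fresh binary-module data with `n_modules` ground-truth modules
#' for each trial (distinct derived seeds), runs [learn_graph] with an
#' autoencoder whose structured layer is `2 * n_modules` wide, and counts the
#' connected components of each trial's final graph at the configured
#' threshold. Reports the mean with a normal-approximation 95% confidence
#' interval and the modal count; a correctly learned graph has `n_modules`
#' components.
#'
#' @param n_modules Ground-truth module count.
#' @param n_trials Number of independent trials (>= 2).
#' @param config A [graph_learn_config]; `config$seed` is the master seed and
#'   trial `t` uses `seed + 1000 * t` offsets for data and training. When
#'   `NULL` (default), the recovery protocol settings are used: pretraining
#'   50 epochs, 40 outer rounds of 100 inner epochs, full-batch gradients,
#'   learning rate `1e-3`, `k = 1` kernel, and `alpha` scaled so that
#'   `alpha` times the number of ordered node pairs is constant across layer
#'   widths (`alpha = 60 / (w * (w - 1))`, i.e. 2 for a 6-unit layer). See
#'   the package vignette for why full-batch training and this schedule are
#'   the conditions under which module fragmentation completes.
#' @param seed Master seed used when `config` is `NULL`.
#' @param n_samples Rows of module data per trial (default `64 * 2^n_modules`
#'   capped at 2048).
#' @param hidden_width Width of the autoencoder hidden layers (default 32).
#' @param embedding_width Structured layer width (default `2 * n_modules`).
#' @return List with `counts` (per-trial component counts; `NA` for failed
#'   trials), `mean`, `ci` (length-2 vector), `modal`, and `n_trials_ok`.
#' @export
component_recovery_trial <- function(n_modules, n_trials, config = NULL,
                                     seed = 1L,
                                     n_samples = min(64L * 2L^n_modules,
                                                     2048L),
                                     hidden_width = 32L,
                                     embedding_width = 2L * n_modules) {
  if (n_modules < 1) stop("`n_modules` must be >= 1")
  if (n_trials < 2) stop("`n_trials` must be >= 2")
  if (is.null(config)) {
    w <- embedding_width
    config <- graph_learn_config(
      pretrain_epochs = 50L, outer_iterations = 40L, inner_epochs = 100L,
      alpha = 60 / (w * (w - 1)), kernel = kernel_params(k = 1L),
      component_threshold = 0.01, seed = seed, batch_size = n_samples,
      learning_rate = 1e-3)
  }
  spec <- model_spec("autoencoding",
                     layer_sizes = c(n_modules, hidden_width,
                                     embedding_width))
  counts <- rep(NA_integer_, n_trials)
  for (tr in seq_len(n_trials)) {
    trial_seed <- config$seed + 1000L * tr
    res <- tryCatch({
      dat <- generate_module_data(n_modules, n_samples = n_samples,
                                  seed = trial_seed)
      cfg <- config
      cfg$seed <- trial_seed + 1L
      learn_graph(spec, dat$data, cfg)
    }, error = function(e) {
      warning(sprintf("trial %d failed: %s", tr, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) counts[tr] <- res$components$n_components
  }
  ok <- counts[!is.na(counts)]
  if (length(ok) == 0L) stop("all trials failed")
  m <- mean(ok)
  s <- stats::sd(ok)
  half <- if (length(ok) > 1L && is.finite(s)) {
    1.96 * s / sqrt(length(ok))
  } else 0
  tab <- table(ok)
  modal <- as.integer(names(tab)[which.max(tab)])
  list(counts = counts, mean = m, ci = c(m - half, m + half),
       modal = modal, n_trials_ok = length(ok))
}
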