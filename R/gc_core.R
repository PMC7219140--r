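#' Edge-detection settings for Granger-causality matrices
#'
#' @param method `"permutation_null"` compares each pair's dependency score
#'   against scores recomputed on circular-shift surrogates of the source
#'   channel (shifting destroys cross-channel coupling while preserving the
#'   channel's autocorrelation); `"fixed_threshold"` simply thresholds the
#'   averaged score.
#' @param alpha Significance level for the permutation test (default 0.05).
#' @param n_permutations Number of surrogate draws per pair (default 99,
#'   pooled across trials; minimum 20).
#' @param threshold Score threshold for `"fixed_threshold"`.
#' @return A list of class `detection_spec`.
#' @export
detection_spec <- function(method = c("permutation_null", "fixed_threshold"),
                           alpha = 0.05, n_permutations = 99, threshold = NULL) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (method == "permutation_null" && (!is_count(n_permutations) || n_permutations < 20)) {
    abort("`n_permutations` must be an integer >= 20.")
  }
  if (method == "fixed_threshold" && (!is.numeric(threshold) || length(threshold) != 1)) {
    abort("`threshold` must be a single number for fixed_threshold detection.")
  }
  structure(list(method = method, alpha = alpha,
                 n_permutations = as.integer(n_permutations),
                 threshold = threshold),
            class = "detection_spec")
}

#' Configuration of a Granger-causality estimation run
#'
#' @param estimator Which regression engine scores the directed
#'   dependencies: `"bilstm_gc"` (bidirectional stacked LSTM, past and
#'   future context), `"rnn_gc"` (unidirectional single-layer LSTM, past
#'   context), `"nn_gc"` (feed-forward network on a flattened lag window),
#'   or `"linear_gc_oracle"` (ordinary-least-squares vector autoregression,
#'   the classical linear statistic).
#' @param model_order Lag window for `"nn_gc"` and `"linear_gc_oracle"`
#'   (default 5; the long-delay benchmark with forward channels uses 7).
#' @param predictor A [predictor_config()]; the default uses a single
#'   hidden layer of 10 units for both LSTM engines (see
#'   [predictor_config()] on why shallow stacks are the default here).
#' @param n_trials Independent trials averaged into the final matrix
#'   (default 10). Each trial uses a fresh training seed, and a fresh
#'   realisation of the generating process when the input is a [sim_spec()].
#' @param restriction How the restricted (source-removed) model is formed:
#'   `"ablate_input_at_inference"` zeroes the source channel's standardized
#'   input stream of the trained full model (cheap, default);
#'   `"retrain_without_channel"` refits without the source channel (the
#'   stricter classical reading).
#' @param detection A [detection_spec()].
#' @param holdout Fraction of window positions (taken from the tail of the
#'   series) on which prediction errors are evaluated (default 0.2).
#'   Held-out evaluation avoids overfit-driven negative error ratios.
#' @param max_eval_windows Cap on evaluation windows (evenly subsampled).
#' @param seed Root seed; all per-trial simulation, training, and surrogate
#'   randomness is derived from it through named substreams.
#' @param keep_models Retain trained predictors inside the result so
#'   [detect_edges()] can reuse them (default `TRUE`).
#' @param n_null_replicates Under the retrain restriction with fewer than
#'   3 trials, number of extra full-model refits per target and trial
#'   (default 2). Their log error ratios against the original full model
#'   form a training-noise null that [detect_edges()] combines with the
#'   circular-shift null: a retrained restricted model is a different
#'   stochastic training run, so its error fluctuates by an amount the
#'   shift surrogates alone do not carry. With 3 or more trials the
#'   cross-trial consistency t-test plays this role instead and no
#'   replicates are fitted.
#' @return A list of class `gc_config`.
#' @export
gc_config <- function(estimator = c("bilstm_gc", "rnn_gc", "nn_gc", "linear_gc_oracle"),
                      model_order = 5, predictor = NULL, n_trials = 10,
                      restriction = c("ablate_input_at_inference", "retrain_without_channel"),
                      detection = detection_spec(), holdout = 0.2,
                      max_eval_windows = 256, seed = 1, keep_models = TRUE,
                      n_null_replicates = 2) {
  estimator <- match.arg(estimator)
  restriction <- match.arg(restriction)
  if (is.null(predictor)) predictor <- predictor_config()
  stopifnot(inherits(predictor, "predictor_config"),
            inherits(detection, "detection_spec"),
            is_count(model_order), is_count(n_trials),
            is.numeric(holdout), holdout > 0, holdout < 0.5,
            is_count(max_eval_windows, min = 16),
            is_count(n_null_replicates, min = 0))
  structure(list(estimator = estimator, model_order = as.integer(model_order),
                 predictor = predictor, n_trials = as.integer(n_trials),
                 restriction = restriction, detection = detection,
                 holdout = holdout, max_eval_windows = as.integer(max_eval_windows),
                 seed = as.integer(seed), keep_models = isTRUE(keep_models),
                 n_null_replicates = as.integer(n_null_replicates)),
            class = "gc_config")
}

# ---- window machinery ------------------------------------------------------

# Valid prediction positions for a given engine on an N-sample series.
valid_positions <- function(N, config) {
  est <- config$estimator
  if (est == "bilstm_gc") {
    k <- config$predictor$max_sequence_length %/% 2L
    seq.int(k + 1L, N - k)
  } else if (est == "rnn_gc") {
    S <- config$predictor$max_sequence_length
    seq.int(S + 1L, N)
  } else {
    seq.int(config$model_order + 1L, N)
  }
}

split_positions <- function(pos, config) {
  n_eval <- max(8L, floor(length(pos) * config$holdout))
  eval_pos <- tail(pos, n_eval)
  train_pos <- head(pos, length(pos) - n_eval)
  cap <- function(p, k) {
    if (length(p) > k) p[round(seq(1, length(p), length.out = k))] else p
  }
  list(train = cap(train_pos, config$predictor$max_train_windows),
       eval = cap(eval_pos, config$max_eval_windows))
}

# Sequence windows for the LSTM engines: array (channels x T x n_windows).
# Bidirectional windows flank the prediction position (k past, k future,
# centre excluded); unidirectional windows are the S past samples. The
# target channel is zeroed on the future side of bidirectional windows:
# with its own future available the regression degenerates into
# interpolation of the target and the error ratio loses all contrast.
lstm_windows <- function(x_std, positions, S, bidirectional, target = NULL) {
  if (bidirectional) {
    k <- S %/% 2L
    offsets <- c(seq.int(-k, -1L), seq.int(1L, k))
  } else {
    offsets <- seq.int(-S, -1L)
  }
  idx <- outer(offsets, positions, "+")
  arr <- array(t(x_std[as.vector(idx), , drop = FALSE]),
               dim = c(ncol(x_std), length(offsets), length(positions)))
  if (bidirectional && !is.null(target)) {
    arr[target, (S %/% 2L + 1L):S, ] <- 0
  }
  k <- if (bidirectional) S %/% 2L else S
  list(X = arr, p_f = k, p_b = if (bidirectional) k + 1L else 1L)
}

# Flattened lag design for the feed-forward and linear engines: one row per
# position, columns ordered channel-major then lag 1..p.
lag_design <- function(x_std, positions, order) {
  C <- ncol(x_std)
  cols <- vector("list", C * order)
  j <- 0L
  for (ch in seq_len(C)) {
    for (lag in seq_len(order)) {
      j <- j + 1L
      cols[[j]] <- x_std[positions - lag, ch]
    }
  }
  out <- do.call(cbind, cols)
  colnames(out) <- paste0(rep(colnames(x_std), each = order), "_lag", seq_len(order))
  out
}

design_cols_for_channel <- function(channel, order) {
  (channel - 1L) * order + seq_len(order)
}

# Least squares by truncated SVD. Identical to OLS on well-conditioned
# designs; on near-collinear designs (narrowband-filtered channels make
# neighbouring lags correlate > 0.99) directions with singular values
# below rtol * max are dropped instead of amplifying noise explosively.
svd_lstsq <- function(X, y, rtol = 1e-4) {
  s <- svd(X)
  keep <- s$d > rtol * s$d[1]
  coef <- s$v[, keep, drop = FALSE] %*%
    (crossprod(s$u[, keep, drop = FALSE], y) / s$d[keep])
  as.numeric(coef)
}

# ---- fitting ---------------------------------------------------------------

resolve_channel <- function(ch, labels, arg) {
  if (is.character(ch)) {
    i <- match(ch, labels)
    if (is.na(i)) abort(sprintf("Unknown channel `%s` in `%s`.", ch, arg))
    return(i)
  }
  i <- as.integer(ch)
  if (is.na(i) || i < 1L || i > length(labels)) {
    abort(sprintf("`%s` must be a channel index in 1..%d or a label.", arg, length(labels)))
  }
  i
}

#' Fit the full (all-channel) predictor for one target channel
#'
#' Trains the configured regression engine to predict the target channel
#' from context windows of all channels (both sides of the prediction
#' position for the bidirectional engine, past-only otherwise), and records
#' its training residual variance and held-out mean-squared error.
#'
#' @param series A samples x channels matrix (or data frame, or
#'   [simulate_gc_benchmark()] result).
#' @param target Target channel (index or label).
#' @param config A [gc_config()].
#' @param seed Training seed; defaults to a substream of `config$seed`.
#' @return An object of class `gc_predictor`.
#' @export
fit_full_model <- function(series, target, config, seed = NULL) {
  x <- as_series_matrix(series)
  if (ncol(x) < 2) abort("`series` must have at least 2 channels.")
  target <- resolve_channel(target, colnames(x), "target")
  if (sd(x[, target]) < .Machine$double.eps) {
    abort("Target channel is constant; nothing to predict.")
  }
  pos_all <- tryCatch(valid_positions(nrow(x), config),
                      error = function(e) abort("`series` is too short for one context window."))
  if (length(pos_all) < 40L) abort("`series` is too short for one context window.")
  x_std <- standardize_series(x)
  seed <- seed %||% substream_seed(config$seed, "train", target)
  fit_one_target(x_std, target, config, seed)
}

fit_one_target <- function(x_std, target, config, train_seed) {
  splits <- split_positions(valid_positions(nrow(x_std), config), config)
  est <- config$estimator
  y_tr <- x_std[splits$train, target]
  y_ev <- x_std[splits$eval, target]

  if (est %in% c("bilstm_gc", "rnn_gc")) {
    bi <- est == "bilstm_gc"
    S <- config$predictor$max_sequence_length
    wtr <- lstm_windows(x_std, splits$train, S, bi, target)
    init <- bilstm_params(ncol(x_std), hidden = config$predictor$hidden_units,
                          depth = config$predictor$depth, bidirectional = bi,
                          seed = train_seed)
    trained <- train_windows(init, wtr$X, y_tr, config$predictor,
                             wtr$p_f, wtr$p_b, train_seed)
    wev <- lstm_windows(x_std, splits$eval, S, bi, target)
    pr_tr <- predict_windows(trained$params, wtr$X, wtr$p_f, wtr$p_b)
    pr_ev <- predict_windows(trained$params, wev$X, wev$p_f, wev$p_b)
    model <- list(kind = "lstm", params = trained$params, bidirectional = bi,
                  S = S, p_f = wev$p_f, p_b = wev$p_b, target = target,
                  loss = trained$loss, val_loss = trained$val_loss,
                  best_epoch = trained$best_epoch)
  } else if (est == "nn_gc") {
    Xtr <- lag_design(x_std, splits$train, config$model_order)
    init <- feedforward_params(ncol(Xtr), seed = train_seed)
    params <- train_ffnn(init, Xtr, y_tr, config$predictor, train_seed)
    Xev <- lag_design(x_std, splits$eval, config$model_order)
    pr_tr <- feedforward_predict(Xtr, params)
    pr_ev <- feedforward_predict(Xev, params)
    model <- list(kind = "ffnn", params = params, order = config$model_order)
  } else {
    Xtr <- cbind(1, lag_design(x_std, splits$train, config$model_order))
    beta <- svd_lstsq(Xtr, y_tr)
    Xev <- cbind(1, lag_design(x_std, splits$eval, config$model_order))
    pr_tr <- as.numeric(Xtr %*% beta)
    pr_ev <- as.numeric(Xev %*% beta)
    # Xev is cached so channel-modified evaluations (ablation, circular
    # shifts) only rebuild that channel's lag columns
    model <- list(kind = "linear", beta = beta, order = config$model_order,
                  Xev = Xev)
  }

  structure(list(estimator = est, target = target,
                 labels = colnames(x_std), model = model,
                 train_pos = splits$train, eval_pos = splits$eval,
                 y_eval = y_ev,
                 train_mse = mean((pr_tr - y_tr)^2),
                 err_full = mean((pr_ev - y_ev)^2),
                 config = config, train_seed = train_seed),
            class = "gc_predictor")
}

#' @export
print.gc_predictor <- function(x, ...) {
  cat(sprintf("<gc_predictor> %s for target %s: held-out MSE %.4g (train %.4g)\n",
              x$estimator, x$labels[x$target], x$err_full, x$train_mse))
  invisible(x)
}

# Held-out MSE of a fitted predictor on a (possibly modified) standardized
# series. Targets always come from the unmodified series via fit$y_eval.
# `changed` names the single channel whose values differ from the fitting
# series, enabling the linear engine's cached-design fast path.
predictor_eval_err <- function(fit, x_std, changed = NULL) {
  m <- fit$model
  pred <- if (m$kind == "lstm") {
    w <- lstm_windows(x_std, fit$eval_pos, m$S, m$bidirectional, m$target)
    predict_windows(m$params, w$X, w$p_f, w$p_b)
  } else if (m$kind == "ffnn") {
    feedforward_predict(lag_design(x_std, fit$eval_pos, m$order), m$params)
  } else if (!is.null(changed) && !is.null(m$Xev)) {
    X <- m$Xev
    cols <- 1L + design_cols_for_channel(changed, m$order)
    X[, cols] <- lag_design(x_std[, changed, drop = FALSE], fit$eval_pos, m$order)
    as.numeric(X %*% m$beta)
  } else {
    as.numeric(cbind(1, lag_design(x_std, fit$eval_pos, m$order)) %*% m$beta)
  }
  mean((pred - fit$y_eval)^2)
}

ablate_channel <- function(x_std, channel) {
  x_std[, channel] <- 0
  x_std
}

shift_channel <- function(x_std, channel, shift) {
  n <- nrow(x_std)
  shift <- ((shift - 1L) %% n) + 1L
  x_std[, channel] <- x_std[c((shift + 1L):n, 1L:shift), channel]
  x_std
}

# Error of the restricted (source-removed) model.
restricted_err <- function(fit, x_std, source, config) {
  if (config$restriction == "ablate_input_at_inference") {
    return(predictor_eval_err(fit, ablate_channel(x_std, source),
                              changed = source))
  }
  refit <- fit_one_target_without(x_std, fit, source, config)
  refit$err_full
}

# Retrain the same engine without the source channel; the target index is
# remapped into the reduced channel set.
fit_one_target_without <- function(x_std, fit, source, config) {
  x_sub <- x_std[, -source, drop = FALSE]
  new_target <- fit$target - (source < fit$target)
  fit_one_target(x_sub, new_target, config, fit$train_seed)
}

gc_score <- function(err_restricted, err_full) {
  if (err_full < 1e-12) {
    abort("Perfect fit: the full model has (numerically) zero held-out error, so the error ratio is undefined.")
  }
  log(err_restricted / err_full)
}

#' Granger-causality score for a single directed pair
#'
#' Fits the full model for the target channel and returns
#' `max(0, ln(err_restricted / err_full))`, where `err_restricted` removes
#' the source channel according to `config$restriction` and both errors are
#' held-out mean-squared prediction errors.
#'
#' @inheritParams fit_full_model
#' @param source,target Channels (index or label); must differ.
#' @param signed If `TRUE`, return the signed log error ratio instead of
#'   flooring at zero.
#' @return A single numeric score.
#' @export
gc_pair <- function(series, source, target, config, seed = NULL, signed = FALSE) {
  x <- as_series_matrix(series)
  source <- resolve_channel(source, colnames(x), "source")
  target <- resolve_channel(target, colnames(x), "target")
  if (source == target) abort("`source` and `target` must differ.")
  fit <- fit_full_model(x, target, config, seed = seed)
  x_std <- standardize_series(x)
  s <- gc_score(restricted_err(fit, x_std, source, config), fit$err_full)
  if (signed) s else max(0, s)
}

# ---- matrix estimation -----------------------------------------------------

#' Estimate the full directed-dependency matrix
#'
#' Scores every ordered off-diagonal channel pair with the configured
#' engine, averaged over `config$n_trials` independent trials. Entry
#' `[i, j]` is the dependency of channel `j` on channel `i` (`i -> j`),
#' floored at zero; the diagonal carries no information and is `NA`.
#'
#' When `x` is a [sim_spec()], each trial simulates a fresh realisation of
#' the generating process; for a fixed matrix only the training seed varies
#' across trials.
#'
#' @param x A samples x channels matrix, data frame, `sim_dataset`, or
#'   [sim_spec()].
#' @param config A [gc_config()].
#' @param targets Optional subset of target channels (indices or labels).
#'   Only dependencies *into* these channels are estimated; the remaining
#'   matrix cells stay `NA`. Useful when a question concerns a few
#'   channels of a larger system.
#' @return An object of class `gc_matrix`; see [tidy.gc_matrix()],
#'   [autoplot.gc_matrix()], [detect_edges()].
#' @export
#' @examples
#' cfg <- gc_config("linear_gc_oracle", n_trials = 2,
#'                  predictor = predictor_config(seed = 1))
#' gcm <- estimate_gc(sim_spec("A", n = 600), cfg)
#' tidy(gcm)
estimate_gc <- function(x, config, targets = NULL) {
  stopifnot(inherits(config, "gc_config"))
  is_spec <- inherits(x, "sim_spec")
  base_mat <- if (!is_spec) as_series_matrix(x) else NULL
  if (!is_spec && ncol(base_mat) < 2) abort("`x` must have at least 2 channels.")

  trials <- vector("list", config$n_trials)
  labels <- NULL
  tgt_idx <- NULL
  for (tr in seq_len(config$n_trials)) {
    mat <- if (is_spec) {
      realise_spec(x, substream_seed(config$seed, "simulate", tr))$series
    } else {
      base_mat
    }
    labels <- colnames(mat)
    C <- ncol(mat)
    if (is.null(tgt_idx)) {
      tgt_idx <- if (is.null(targets)) seq_len(C) else
        sort(unique(vapply(targets, resolve_channel, integer(1),
                           labels = labels, arg = "targets")))
    }
    x_std <- standardize_series(mat)
    fits <- vector("list", C)
    err_restricted <- matrix(NA_real_, C, C) # [source, target]
    retrain <- config$restriction == "retrain_without_channel"
    replicate_lr <- if (retrain && config$n_null_replicates > 0) {
      matrix(NA_real_, C, config$n_null_replicates)
    }
    for (j in tgt_idx) {
      fits[[j]] <- fit_one_target(x_std, j, config,
                                  substream_seed(config$seed, "train", (tr - 1L) * C + j))
      for (i in seq_len(C)[-j]) {
        err_restricted[i, j] <- restricted_err(fits[[j]], x_std, i, config)
      }
      if (!is.null(replicate_lr) && config$n_trials < 3L) {
        for (r in seq_len(config$n_null_replicates)) {
          rep_fit <- fit_one_target(x_std, j, config,
                                    substream_seed(config$seed, "replicate",
                                                   ((tr - 1L) * C + j) * 8L + r))
          replicate_lr[j, r] <- log(rep_fit$err_full / fits[[j]]$err_full)
        }
      }
    }
    trials[[tr]] <- list(x_std = x_std, fits = fits,
                         err_restricted = err_restricted,
                         replicate_log_ratios = replicate_lr)
  }

  C <- length(labels)
  per_trial <- array(NA_real_, dim = c(config$n_trials, C, C),
                     dimnames = list(NULL, labels, labels))
  for (tr in seq_len(config$n_trials)) {
    t_ <- trials[[tr]]
    for (j in tgt_idx) {
      for (i in seq_len(C)[-j]) {
        per_trial[tr, i, j] <- gc_score(t_$err_restricted[i, j], t_$fits[[j]]$err_full)
      }
    }
  }
  signed <- apply(per_trial, c(2, 3), mean)
  values <- apply(pmax(per_trial, 0), c(2, 3), mean)
  diag(values) <- NA_real_
  diag(signed) <- NA_real_

  structure(list(values = values, signed = signed, per_trial = per_trial,
                 channel_labels = labels, estimator = config$estimator,
                 config = config, input = if (is_spec) x else NULL,
                 trials = if (config$keep_models) trials else NULL),
            class = "gc_matrix")
}

#' @export
print.gc_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<gc_matrix> %s, %d channels, %d trial(s)\n", x$estimator,
              length(x$channel_labels), x$config$n_trials))
  print(round(x$values, digits))
  invisible(x)
}

#' Tidy a Granger-causality matrix into an edge tibble
#'
#' @param x A `gc_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per ordered off-diagonal pair: `source`,
#'   `target`, labels, `score` (trial-averaged, floored at zero) and
#'   `log_ratio` (trial-averaged signed log error ratio).
#' @export
tidy.gc_matrix <- function(x, ...) {
  C <- length(x$channel_labels)
  grid <- expand.grid(source = seq_len(C), target = seq_len(C))
  grid <- grid[grid$source != grid$target, ]
  out <- tibble(
    source = as.integer(grid$source), target = as.integer(grid$target),
    source_label = x$channel_labels[grid$source],
    target_label = x$channel_labels[grid$target],
    score = x$values[cbind(grid$source, grid$target)],
    log_ratio = x$signed[cbind(grid$source, grid$target)]
  )
  out <- out[!is.na(out$score), ]   # unestimated cells (target subsets)
  dplyr::arrange(out, dplyr::desc(.data$score))
}

#' @export
glance.gc_matrix <- function(x, ...) {
  off <- x$values[row(x$values) != col(x$values)]
  tibble(estimator = x$estimator, n_channels = length(x$channel_labels),
         n_trials = x$config$n_trials, mean_score = mean(off, na.rm = TRUE),
         max_score = max(off, na.rm = TRUE))
}

#' Heatmap of a directed-dependency matrix
#'
#' Rows are source channels, columns targets; lighter tiles are stronger
#' dependencies. The diagonal (self-dependency) is blank.
#'
#' @param object A `gc_matrix`.
#' @param ... Unused.
#' @export
autoplot.gc_matrix <- function(object, ...) {
  df <- tidy(object)
  df$source_label <- factor(df$source_label, levels = rev(object$channel_labels))
  df$target_label <- factor(df$target_label, levels = object$channel_labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target_label, y = .data$source_label,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "target", y = "source", fill = "GC",
                  title = sprintf("%s dependency matrix", object$estimator))
}

# ---- edge detection --------------------------------------------------------

#' Detect directed edges from a Granger-causality matrix
#'
#' In `"permutation_null"` mode each pair's trial-averaged score is compared
#' with scores recomputed on surrogates in which the source channel is
#' circularly shifted by a random offset of at least the context length;
#' the shift destroys the cross-channel coupling but preserves the source's
#' autocorrelation. Surrogate draws are pooled across trials, so the null
#' reflects single-trial score spread while the observed statistic enjoys
#' trial averaging; the resulting test is conservative for null pairs. An
#' edge is declared when the permutation p-value
#' `(1 + #\{surrogate >= observed\}) / (n_permutations + 1)` is `<= alpha`.
#'
#' @param x A `gc_matrix` from [estimate_gc()] (with retained models), or a
#'   series/[sim_spec()] to be estimated first.
#' @param config A [gc_config()]; defaults to the one stored in `x`.
#' @return An object of class `gc_detection`; `tidy()` gives one row per
#'   pair with `score`, `log_ratio`, `null_q`, `p_value`, `detected`.
#' @export
detect_edges <- function(x, config = NULL) {
  if (!inherits(x, "gc_matrix")) {
    if (is.null(config)) abort("Supply a `gc_config` when `x` is not a gc_matrix.")
    x <- estimate_gc(x, config)
  }
  config <- config %||% x$config
  det <- config$detection
  C <- length(x$channel_labels)
  tab <- tidy(x)

  if (det$method == "fixed_threshold") {
    tab$null_q <- det$threshold
    tab$p_value <- NA_real_
    tab$detected <- tab$score > det$threshold
    return(new_gc_detection(tab, x, det))
  }

  if (is.null(x$trials)) {
    abort("Permutation detection needs retained models; rerun estimate_gc() with keep_models = TRUE.")
  }
  n_perm <- det$n_permutations
  n_tr <- length(x$trials)
  retrain_mode <- config$restriction == "retrain_without_channel"
  min_shift <- if (x$estimator %in% c("bilstm_gc", "rnn_gc")) {
    config$predictor$max_sequence_length
  } else {
    config$model_order
  }

  # training-noise null for the retrain restriction: log error ratios of
  # independently retrained full models, summarised by a normal tail. A
  # retrained restricted model is a different stochastic training run, so
  # under no coupling its log error ratio fluctuates exactly like these
  # draws. Training stability is target-specific (a hard-to-fit target has
  # noisier refits), so the scale is estimated per target and shrunk
  # towards the pooled value; the observed statistic averages n_trials
  # independent draws, hence the sqrt(n_trials) scaling.
  repl_by_target <- lapply(seq_len(C), function(j) {
    v <- unlist(lapply(x$trials, function(t_) t_$replicate_log_ratios[j, ]))
    v[is.finite(v)]
  })
  repl_pool <- unlist(repl_by_target)
  repl_tail_p <- function(obs, target) {
    if (length(repl_pool) < 10) return(0)
    mu <- mean(repl_pool)
    v_pool <- var(repl_pool)
    v_j <- repl_by_target[[target]]
    n_j <- length(v_j)
    v_tgt <- if (n_j >= 2) var(v_j) else v_pool
    sdv <- sqrt((n_j * v_tgt + 4 * v_pool) / (n_j + 4)) / sqrt(n_tr)
    if (sdv < 1e-10) return(as.numeric(obs <= mu + 1e-10))
    stats::pnorm(obs, mean = mu, sd = sdv, lower.tail = FALSE)
  }

  tab$null_q <- NA_real_
  tab$p_value <- NA_real_
  tab$detected <- FALSE
  for (r in seq_len(nrow(tab))) {
    i <- tab$source[r]; j <- tab$target[r]
    surr <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      tr <- ((p - 1L) %% n_tr) + 1L
      t_ <- x$trials[[tr]]
      N <- nrow(t_$x_std)
      shift <- with_seed(substream_seed(config$seed, "permute",
                                        (r - 1L) * n_perm + p),
                         sample.int(N - 2L * min_shift, 1L) + min_shift)
      err_full_surr <- predictor_eval_err(t_$fits[[j]],
                                          shift_channel(t_$x_std, i, shift),
                                          changed = i)
      surr[p] <- max(0, gc_score(t_$err_restricted[i, j], err_full_surr))
    }
    obs <- tab$score[r]
    tab$null_q[r] <- quantile(surr, 1 - det$alpha, names = FALSE, type = 1)
    p_shift <- (1 + sum(surr >= obs)) / (n_perm + 1)
    p_extra <- if (retrain_mode && n_tr >= 3L) {
      # consistency across independent trials: one-sided t-test of the
      # per-trial signed scores against zero. Each trial carries fresh
      # training (and realisation) noise, so this is self-calibrated; under
      # the retrain restriction null scores centre at or below zero (the
      # restricted model has fewer inputs to overfit), keeping it valid.
      s_tr <- x$per_trial[, i, j]
      s_tr <- s_tr[is.finite(s_tr)]
      sdv <- sd(s_tr)
      if (sdv < 1e-12) {
        as.numeric(mean(s_tr) <= 0)
      } else {
        stats::pt(mean(s_tr) / (sdv / sqrt(length(s_tr))),
                  df = length(s_tr) - 1, lower.tail = FALSE)
      }
    } else {
      repl_tail_p(tab$log_ratio[r], j)
    }
    tab$p_value[r] <- max(p_shift, p_extra)
    tab$detected[r] <- tab$p_value[r] <= det$alpha
  }
  new_gc_detection(tab, x, det)
}

new_gc_detection <- function(tab, gcm, det) {
  structure(list(table = tab, matrix = gcm, detection = det),
            class = "gc_detection")
}

#' @export
print.gc_detection <- function(x, ...) {
  n <- sum(x$table$detected)
  cat(sprintf("<gc_detection> %s: %d edge(s) detected of %d pairs (%s)\n",
              x$matrix$estimator, n, nrow(x$table), x$detection$method))
  print(dplyr::filter(x$table, .data$detected))
  invisible(x)
}

#' @export
tidy.gc_detection <- function(x, ...) x$table

#' @export
glance.gc_detection <- function(x, ...) {
  tibble(estimator = x$matrix$estimator, n_pairs = nrow(x$table),
         n_detected = sum(x$table$detected),
         method = x$detection$method, alpha = x$detection$alpha)
}

#' @export
autoplot.gc_detection <- function(object, ...) {
  df <- object$table
  df$source_label <- factor(df$source_label, levels = rev(object$matrix$channel_labels))
  df$target_label <- factor(df$target_label, levels = object$matrix$channel_labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target_label, y = .data$source_label,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$detected, ], colour = "red", size = 2) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "target", y = "source", fill = "GC",
                  title = "Detected directed dependencies")
}

#' Compare detected edges against a ground-truth edge set
#'
#' @param detection A `gc_detection`.
#' @param truth A tibble with `source` and `target` columns (e.g.
#'   [ground_truth_edges()]).
#' @return A one-row tibble with `n_true`, `n_detected`, `true_positives`,
#'   `false_positives`, `false_negatives`, `recall`, `precision`.
#' @export
score_detection <- function(detection, truth) {
  tab <- tidy(detection)
  key <- function(s, t) paste(s, t, sep = "->")
  det <- key(tab$source[tab$detected], tab$target[tab$detected])
  tru <- unique(key(truth$source, truth$target))
  tp <- sum(det %in% tru)
  tibble(n_true = length(tru), n_detected = length(det),
         true_positives = tp, false_positives = length(det) - tp,
         false_negatives = length(tru) - tp,
         recall = tp / length(tru),
         precision = if (length(det)) tp / length(det) else NA_real_)
}
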