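#' Hyperparameters of the gated recurrent sequence classifier
#'
#' A single-layer LSTM (input, forget and output gates) with a sigmoid
#' readout of the final hidden state is the default architecture; training
#' is backpropagation through time with Adam updates, inverse-frequency
#' class weights, per-feature z-scoring computed on the training set only,
#' and early stopping on a held-out validation fraction.
#'
#' @param hidden_units hidden-state size per layer (default 24).
#' @param n_layers stacked recurrent layers (default 1).
#' @param learning_rate Adam step size (default 1e-2).
#' @param max_epochs training-epoch cap (default 40).
#' @param batch_size trials per gradient step (default 16); `Inf` = full
#'   batch, which keeps training independent of trial order.
#' @param seed integer controlling initialization, validation split and any
#'   batch shuffling.
#' @param early_stop_patience epochs without monitored-loss improvement
#'   before stopping (default 8).
#' @param val_fraction fraction of training trials held out to monitor early
#'   stopping (default 0.15; 0 monitors training loss instead).
#' @return object of class `model_config`.
#' @export
model_config <- function(hidden_units = 24L, n_layers = 1L,
                         learning_rate = 1e-2, max_epochs = 40L,
                         batch_size = 16L, seed = 1L,
                         early_stop_patience = 8L, val_fraction = 0.15) {
  stopifnot(hidden_units >= 1, n_layers >= 1, learning_rate > 0,
            max_epochs >= 1, early_stop_patience >= 1,
            val_fraction >= 0, val_fraction < 1)
  structure(list(hidden_units = as.integer(hidden_units),
                 n_layers = as.integer(n_layers),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = batch_size,
                 seed = as.integer(seed),
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction),
            class = "model_config")
}

# Stack a list of windowed_sequence objects into the n x E x T array the
# C++ core consumes; enforces a common (T, E) across trials.
sequences_to_array <- function(sequences) {
  dims <- vapply(sequences, function(s) dim(s$vectors), integer(2))
  if (any(dims[2L, ] != dims[2L, 1L]))
    stop("all sequences must share the flattened window length E; got ",
         paste(unique(dims[2L, ]), collapse = ", "))
  if (any(dims[1L, ] != dims[1L, 1L]))
    stop("all sequences must share the number of windows T; got ",
         paste(unique(dims[1L, ]), collapse = ", "))
  T_ <- dims[1L, 1L]; E <- dims[2L, 1L]; n <- length(sequences)
  arr <- array(0, dim = c(n, E, T_))
  for (j in seq_len(n)) arr[j, , ] <- t(sequences[[j]]$vectors)
  arr
}

#' Train the sequence classifier on windowed rhythm sequences
#'
#' Fits the LSTM by backpropagation through time, minimizing class-weighted
#' binary cross-entropy on the final-state readout.  Inputs are z-scored per
#' feature with statistics from the training trials only; a stratified
#' validation split (seeded) monitors early stopping.  A fixed seed makes
#' the fitted parameters reproducible on identical input.
#'
#' @param sequences list of [segment()] outputs, one per trial, all sharing
#'   band, `E` and `T`.
#' @param labels a `trial_labels` data.frame aligned with `sequences`, or a
#'   0/1 vector (1 = positive/active class).
#' @param target `"valence"` or `"arousal"`.
#' @param config a [model_config()].
#' @return object of class `lstm_model`: fitted parameters, `config`,
#'   `input_dim`, `band`, `tS`, `target`, normalization statistics, epochs
#'   run and loss history.
#' @export
train <- function(sequences, labels, target = c("valence", "arousal"),
                  config = model_config()) {
  target <- match.arg(target)
  stopifnot(inherits(config, "model_config"))
  if (!length(sequences)) stop("no sequences supplied")
  bands <- unique(vapply(sequences, function(s) s$band, ""))
  if (length(bands) > 1L)
    stop("sequences mix bands: ", paste(bands, collapse = ", "))
  y <- binary_targets(labels, target)
  keep <- which(!is.na(y))
  if (!length(keep)) stop("all trials are excluded by the rating binarization")
  sequences <- sequences[keep]; y <- y[keep]
  if (length(unique(y)) < 2L)
    stop("training set contains a single class; need both")
  if (min(table(y)) < 2L)
    stop("need at least 2 trials per class")
  arr <- sequences_to_array(sequences)
  E <- dim(arr)[2L]

  # per-feature z-scoring from training data only
  mu <- numeric(E); sdv <- numeric(E)
  for (e in seq_len(E)) {
    v <- arr[, e, ]
    mu[e] <- mean(v)
    sdv[e] <- stats::sd(v)
  }
  sdv[sdv < 1e-8] <- 1
  arr <- sweep(arr, 2L, mu, "-")
  arr <- sweep(arr, 2L, sdv, "/")

  n <- dim(arr)[1L]
  # inverse-frequency class weights, normalized to mean 1
  tab <- table(factor(y, levels = c(0, 1)))
  wgt <- n / (2 * as.numeric(tab[as.character(y)]))

  # stratified validation split for early stopping
  val_idx <- integer(0)
  if (config$val_fraction > 0) {
    rng <- local_rng(config$seed + 7919L)
    ord <- rng$sample_order(n)
    for (cls in c(0L, 1L)) {
      cls_idx <- ord[y[ord] == cls]
      n_val <- floor(length(cls_idx) * config$val_fraction)
      if (length(cls_idx) - n_val >= 2L && n_val >= 1L)
        val_idx <- c(val_idx, cls_idx[seq_len(n_val)])
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  has_val <- length(val_idx) >= 2L && length(unique(y[val_idx])) == 2L
  if (!has_val) { tr_idx <- seq_len(n); val_idx <- integer(0) }

  Xtr <- arr[tr_idx, , , drop = FALSE]
  Xval <- if (length(val_idx)) arr[val_idx, , , drop = FALSE]
          else array(0, dim = c(0L, E, dim(arr)[3L]))
  bs <- if (is.finite(config$batch_size)) as.integer(config$batch_size) else 0L

  fit <- lstm_fit_cpp(Xtr, y[tr_idx], wgt[tr_idx],
                      Xval, y[val_idx], wgt[val_idx],
                      config$hidden_units, config$n_layers,
                      config$learning_rate, config$max_epochs, bs,
                      config$early_stop_patience, config$seed)

  structure(list(params = fit[c("layers", "w_out", "b_out", "hidden")],
                 config = config, input_dim = E,
                 n_windows = dim(arr)[3L],
                 band = bands, tS = sequences[[1L]]$tS, target = target,
                 feature_mean = mu, feature_sd = sdv,
                 epochs_run = fit$epochs_run, final_loss = fit$final_loss,
                 loss_history = fit$loss_history,
                 val_history = fit$val_history),
            class = "lstm_model")
}

#' @export
print.lstm_model <- function(x, ...) {
  cat(sprintf("<lstm_model> %s / band %s / tS %g s: E = %d, H = %d x %d layer(s); %d epoch(s), final loss %.4f\n",
              x$target, x$band, x$tS, x$input_dim, x$config$hidden_units,
              x$config$n_layers, x$epochs_run, x$final_loss))
  invisible(x)
}

#' Predict emotion class for windowed sequences
#'
#' @param object a fitted [train()] model.
#' @param sequences one `windowed_sequence` or a list of them; `E` must
#'   match the model's `input_dim`.
#' @param ... unused.
#' @return data.frame with `trial_id`, `score` (positive-class probability)
#'   and `class` (1 iff `score >= 0.5`).
#' @export
predict.lstm_model <- function(object, sequences, ...) {
  if (inherits(sequences, "windowed_sequence")) sequences <- list(sequences)
  E_in <- unique(vapply(sequences, function(s) ncol(s$vectors), integer(1)))
  if (length(E_in) != 1L || E_in != object$input_dim)
    stop("sequence feature length E = ", paste(E_in, collapse = "/"),
         " does not match the model's input_dim = ", object$input_dim)
  arr <- sequences_to_array(sequences)
  arr <- sweep(arr, 2L, object$feature_mean, "-")
  arr <- sweep(arr, 2L, object$feature_sd, "/")
  score <- as.numeric(lstm_predict_cpp(object$params, arr))
  data.frame(
    trial_id = vapply(sequences, function(s) s$trial_id, ""),
    score = score,
    class = as.integer(score >= 0.5),
    stringsAsFactors = FALSE)
}
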