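#' Classifier configuration
#'
#' Two variants share the stack-encoded input and the BiLSTM/dense head.
#' `contextual` inserts a from-scratch transformer-encoder stack between the
#' token embedding and the recurrent layer, so a doublet's representation
#' depends on its neighbours and position; `static` feeds the fixed token
#' embedding straight to the BiLSTM. Defaults mirror the reference
#' architecture: doublet encoding, embedding dimension 64, 6 encoder layers,
#' 8 attention heads.
#'
#' @param variant `"contextual"` or `"static"`.
#' @param k Encoding order (sequence length is `23 - k + 1`).
#' @param embed_dim Per-token embedding dimension `d` (default 64); must be
#'   divisible by `n_heads` for the contextual variant.
#' @param n_layers Encoder layers (contextual only, default 6).
#' @param n_heads Attention heads (contextual only, default 8).
#' @param lstm_units Hidden units per LSTM direction.
#' @param dense_units Widths of the two dense layers.
#' @param dropout Dropout rate in `[0, 1)` applied to embeddings, encoder
#'   sublayer outputs and dense activations during training.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param pos_weight Loss weight on the positive class (1 = unweighted).
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @return A `crispr_model_config` list.
#' @export
model_config <- function(variant = c("contextual", "static"),
                         k = 2,
                         embed_dim = 64,
                         n_layers = 6,
                         n_heads = 8,
                         lstm_units = 32,
                         dense_units = c(128, 64),
                         dropout = 0.1,
                         learning_rate = 1e-4,
                         batch_size = 64,
                         epochs = 10,
                         pos_weight = 1,
                         seed = 1) {
  variant <- match.arg(variant)
  k <- check_order(k)
  if (variant == "contextual" && embed_dim %% n_heads != 0) {
    stop("embed_dim must be divisible by n_heads", call. = FALSE)
  }
  if (length(dense_units) != 2L) {
    stop("dense_units must give exactly two layer widths", call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)", call. = FALSE)
  structure(
    list(
      variant = variant, k = k, seq_len = PAIR_LEN - k + 1L,
      vocab_size = 4L^(2L * k),
      embed_dim = as.integer(embed_dim),
      n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
      lstm_units = as.integer(lstm_units),
      dense_units = as.integer(dense_units),
      dropout = dropout, learning_rate = learning_rate,
      batch_size = as.integer(batch_size), epochs = as.integer(epochs),
      pos_weight = pos_weight, seed = as.integer(seed)
    ),
    class = "crispr_model_config"
  )
}

#' Build an untrained classifier
#'
#' Initializes all weights (Glorot-uniform for linear maps, small Gaussian
#' for embeddings, forget-gate bias open) under `cfg$seed`. The pipeline is:
#' token embedding (+ learned positional embedding, contextual variant) ->
#' encoder blocks -> BiLSTM whose final forward and backward hidden states are
#' concatenated -> two rectified dense layers -> one sigmoid unit.
#'
#' @param cfg A [model_config()].
#' @return A `crispr_model` with elements `config`, `params`, `n_parameters`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "crispr_model_config"))
  set.seed(cfg$seed)
  params <- init_params(cfg, cfg$vocab_size)
  structure(
    list(config = cfg, params = params, n_parameters = n_params(params)),
    class = "crispr_model"
  )
}

#' @export
print.crispr_model <- function(x, ...) {
  cat(sprintf(
    "<crispr_model> %s, k=%d (%d tokens), d=%d, %s%d+%d dense, %s parameters\n",
    x$config$variant, x$config$k, x$config$seq_len, x$config$embed_dim,
    if (x$config$variant == "contextual")
      sprintf("%dx%d attention, ", x$config$n_layers, x$config$n_heads) else "",
    x$config$dense_units[1], x$config$dense_units[2],
    format(x$n_parameters, big.mark = ",")
  ))
  invisible(x)
}

tokens_matrix <- function(pairs, cfg) {
  if (!"tokens" %in% names(pairs)) {
    pairs <- encode_pairs(pairs, k = cfg$k)
  }
  lens <- lengths(pairs$tokens)
  if (any(lens != cfg$seq_len)) {
    stop("encoded pairs have ", lens[lens != cfg$seq_len][1],
         " tokens; model expects ", cfg$seq_len, call. = FALSE)
  }
  m <- do.call(rbind, pairs$tokens)
  if (any(m < 0L | m >= cfg$vocab_size)) {
    stop("token index out of range for vocabulary of size ", cfg$vocab_size,
         call. = FALSE)
  }
  m
}

#' Train a classifier
#'
#' Minimizes binary cross-entropy by mini-batch Adam for `epochs` epochs,
#' logging per-epoch training loss and validation ROC/PR-AUC, and returns the
#' weights of the epoch with the best validation PR-AUC (the preferred metric
#' under class imbalance). Fully deterministic under `cfg$seed`.
#'
#' @param model A [build_model()] result.
#' @param train Encoded pair tibble (columns `tokens`, `label`) for training;
#'   must contain both classes.
#' @param val Encoded pair tibble for per-epoch validation.
#' @param verbose Print per-epoch progress?
#' @return A `crispr_fit`: `config`, `params` (best-epoch weights),
#'   `training_log` tibble (`epoch`, `train_loss`, `val_roc_auc`,
#'   `val_pr_auc`), `best_epoch`, `n_parameters`.
#' @export
train_model <- function(model, train, val, verbose = FALSE) {
  stopifnot(inherits(model, "crispr_model"))
  cfg <- model$config
  Xtr <- tokens_matrix(train, cfg)
  ytr <- as.numeric(train$label)
  if (length(unique(ytr)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  Xval <- tokens_matrix(val, cfg)
  yval <- as.numeric(val$label)
  params <- model$params
  state <- adam_init(params)
  set.seed(cfg$seed + 1L)
  n <- nrow(Xtr)
  log_rows <- vector("list", cfg$epochs)
  best <- list(pr = -Inf, params = params, epoch = 0L)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      xb <- Xtr[idx, , drop = FALSE]
      yb <- ytr[idx]
      fwd <- nn_forward(params, xb, cfg, train = TRUE)
      lg <- nn_loss_grad(fwd$prob, yb, cfg$pos_weight)
      if (!is.finite(lg$loss)) {
        stop("training aborted: non-finite loss at epoch ", ep,
             " (try a lower learning_rate)", call. = FALSE)
      }
      grads <- nn_backward(params, xb, cfg, fwd, lg$dlogit)
      step <- adam_step(params, grads, state, cfg$learning_rate)
      params <- step$params
      state <- step$state
      ep_loss <- ep_loss + lg$loss * length(idx)
    }
    val_scores <- nn_predict(params, Xval, cfg)
    v_roc <- if (length(unique(yval)) == 2L) roc_auc(yval, val_scores) else NA_real_
    v_pr <- if (any(yval == 1)) pr_auc(yval, val_scores) else NA_real_
    log_rows[[ep]] <- tibble::tibble(
      epoch = ep, train_loss = ep_loss / n, val_roc_auc = v_roc, val_pr_auc = v_pr
    )
    if (verbose) {
      message(sprintf("epoch %d  loss %.4f  val ROC %.4f  PR %.4f",
                      ep, ep_loss / n, v_roc, v_pr))
    }
    sel <- if (is.na(v_pr)) -Inf else v_pr
    if (sel > best$pr) best <- list(pr = sel, params = params, epoch = ep)
  }
  if (best$epoch == 0L) best <- list(pr = NA_real_, params = params,
                                     epoch = cfg$epochs)
  structure(
    list(
      config = cfg, params = best$params,
      training_log = dplyr::bind_rows(log_rows),
      best_epoch = best$epoch, n_parameters = model$n_parameters
    ),
    class = "crispr_fit"
  )
}

nn_predict <- function(params, X, cfg, chunk = 256L) {
  n <- nrow(X)
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    out[idx] <- nn_forward(params, X[idx, , drop = FALSE], cfg,
                           train = FALSE)$prob
  }
  out
}

#' @export
print.crispr_fit <- function(x, ...) {
  last <- x$training_log[nrow(x$training_log), ]
  cat(sprintf(
    "<crispr_fit> %s, %d epochs (best %d)  val ROC-AUC %.4f  PR-AUC %.4f\n",
    x$config$variant, nrow(x$training_log), x$best_epoch,
    last$val_roc_auc, last$val_pr_auc
  ))
  invisible(x)
}

#' Score pairs with a trained classifier
#'
#' @param object A `crispr_fit`.
#' @param pairs Pair tibble; encoded on the fly if it has no `tokens` column.
#' @param ... Unused.
#' @return A tibble with `guide_id`, `score` (probability in `[0, 1]`) and
#'   `label` when known; row order matches the input.
#' @export
predict.crispr_fit <- function(object, pairs, ...) {
  cfg <- object$config
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(guide_id = character(), score = numeric(),
                          label = integer()))
  }
  X <- tokens_matrix(pairs, cfg)
  out <- tibble::tibble(
    guide_id = if ("guide_id" %in% names(pairs)) pairs$guide_id else NA_character_,
    score = nn_predict(object$params, X, cfg)
  )
  if ("label" %in% names(pairs)) out$label <- pairs$label
  out
}

#' Save a trained classifier as a checkpoint directory
#'
#' Writes `config.json` (every [model_config()] field under its own key),
#' `weights.rds` (the learned parameter tree) and `training_log.csv`.
#'
#' @param fit A `crispr_fit`.
#' @param dir Checkpoint directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(fit, dir) {
  stopifnot(inherits(fit, "crispr_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- fit$config
  cfg_list <- unclass(cfg)
  jsonlite::write_json(cfg_list, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(fit$params, file.path(dir, "weights.rds"))
  readr::write_csv(fit$training_log, file.path(dir, "training_log.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' Load a classifier checkpoint
#'
#' @param dir Directory written by [save_checkpoint()].
#' @return A `crispr_fit` producing identical predictions to the saved one.
#' @export
load_checkpoint <- function(dir) {
  cfg_list <- jsonlite::read_json(file.path(dir, "config.json"),
                                  simplifyVector = TRUE)
  cfg <- do.call(model_config, cfg_list[c(
    "variant", "k", "embed_dim", "n_layers", "n_heads", "lstm_units",
    "dense_units", "dropout", "learning_rate", "batch_size", "epochs",
    "pos_weight", "seed"
  )])
  params <- readRDS(file.path(dir, "weights.rds"))
  log_path <- file.path(dir, "training_log.csv")
  training_log <- if (file.exists(log_path)) {
    readr::read_csv(log_path, show_col_types = FALSE, progress = FALSE)
  } else tibble::tibble()
  structure(
    list(config = cfg, params = params, training_log = training_log,
         best_epoch = NA_integer_, n_parameters = n_params(params)),
    class = "crispr_fit"
  )
}

#' Raw embedding-stage output for a batch of encoded pairs
#'
#' Exposes the representation handed to the recurrent layer: for the
#' contextual variant the encoder-stack output, for the static variant the
#' token embedding itself. Mostly useful for inspecting the architecture
#' contract (a `23 - k + 1` by `embed_dim` matrix per pair).
#'
#' @param model A `crispr_model` or `crispr_fit`.
#' @param pairs Encoded pair tibble.
#' @return Array of dim `(n, seq_len, embed_dim)`.
#' @export
embedding_output <- function(model, pairs) {
  cfg <- model$config
  X <- tokens_matrix(pairs, cfg)
  B <- nrow(X)
  fwd <- nn_forward(model$params, X, cfg, train = FALSE)
  x_arr <- fwd$cache$X_final
  dim(x_arr) <- c(cfg$seq_len, B, cfg$embed_dim)
  aperm(x_arr, c(2L, 1L, 3L))
}
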