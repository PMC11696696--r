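test_that("configuration invariants are enforced", {
  expect_error(model_config(embed_dim = 30, n_heads = 8), "divisible")
  expect_error(model_config(dense_units = c(10)), "two layer widths")
  expect_error(model_config(dropout = 1), "dropout")
  cfg <- model_config()
  expect_equal(cfg$seq_len, 22L)
  expect_equal(cfg$vocab_size, 256L)
  expect_equal(model_config(k = 3)$seq_len, 21L)
})

test_that("the embedding stage emits one seq_len x embed_dim matrix per pair", {
  pair <- encode_pairs(toy_pair_tbl("g", base_seq("A"),
                                    mutate_at(base_seq("A"), 3, "G"), 1L))
  # default architecture: 22 positions x 64 dimensions
  m_default <- build_model(model_config(seed = 2))
  expect_equal(dim(embedding_output(m_default, pair)), c(1L, 22L, 64L))
  # reduced contextual: 22 x 16
  m_red <- build_model(reduced_config(seed = 2))
  expect_equal(dim(embedding_output(m_red, pair)), c(1L, 22L, 16L))
  # static variant: the raw embedding passes straight through
  m_st <- build_model(tiny_config("static", seed = 2))
  expect_equal(dim(embedding_output(m_st, pair)), c(1L, 22L, 8L))
  expect_gt(m_default$n_parameters, m_red$n_parameters)
})

test_that("the recurrent layer concatenates forward and backward final states", {
  ns <- asNamespace("crisprstack")
  cfg <- tiny_config(seed = 4)  # lstm_units = 4
  model <- build_model(cfg)
  enc <- separable_set(8)
  X <- ns$tokens_matrix(enc, cfg)
  fwd <- ns$nn_forward(model$params, X, cfg, train = FALSE)
  expect_equal(dim(fwd$cache$Z), c(8L, 2L * cfg$lstm_units))
  # the two halves come from different networks and differ
  expect_false(isTRUE(all.equal(fwd$cache$Z[, 1:4], fwd$cache$Z[, 5:8])))
})

test_that("predictions are probabilities, order-preserving, deterministic, and empty-safe", {
  enc <- separable_set(40)
  cfg <- tiny_config(seed = 6)
  fit <- train_model(build_model(cfg), enc, enc)
  p1 <- predict(fit, enc)
  expect_equal(nrow(p1), 40L)
  expect_true(all(p1$score >= 0 & p1$score <= 1))
  expect_identical(p1, predict(fit, enc))
  expect_equal(p1$guide_id, enc$guide_id)
  p0 <- predict(fit, enc[0, ])
  expect_equal(nrow(p0), 0L)
})

test_that("training reduces loss on separable data for both variants", {
  enc <- separable_set(120)
  for (variant in c("contextual", "static")) {
    cfg <- tiny_config(variant, seed = 8)
    cfg$epochs <- 10L
    fit <- train_model(build_model(cfg), enc, enc)
    log <- tidy(fit)
    expect_lt(log$train_loss[nrow(log)], log$train_loss[1])
    expect_gt(log$val_roc_auc[nrow(log)], 0.9)  # separable by one token
  }
})

test_that("training is bit-identical under a fixed seed", {
  enc <- separable_set(60)
  cfg <- tiny_config(seed = 12)
  fit1 <- train_model(build_model(cfg), enc, enc)
  fit2 <- train_model(build_model(cfg), enc, enc)
  expect_identical(fit1$training_log, fit2$training_log)
  expect_identical(fit1$params, fit2$params)
})

test_that("label-permuted data trains to chance-level validation ROC", {
  enc <- separable_set(200, seed = 31)
  set.seed(32)
  enc$label <- sample(enc$label)
  sp <- single_split(enc, 0.3, seed = 33)
  cfg <- tiny_config(seed = 34)
  cfg$epochs <- 6L
  fit <- train_model(build_model(cfg), sp$train, sp$val)
  final_roc <- tidy(fit)$val_roc_auc[cfg$epochs]
  expect_gte(final_roc, 0.3)
  expect_lte(final_roc, 0.7)
})

test_that("degenerate training inputs raise informative errors", {
  enc <- separable_set(20)
  enc$label <- 1L
  expect_error(train_model(build_model(tiny_config()), enc, enc),
               "both classes")
  # wrong sequence length at prediction time
  fit <- train_model(build_model(tiny_config(seed = 3)), separable_set(30),
                     separable_set(30))
  bad <- separable_set(5)
  bad$tokens <- lapply(bad$tokens, function(t) t[1:10])
  expect_error(predict(fit, bad), "expects")
  bad2 <- separable_set(5)
  bad2$tokens[[1]][1] <- 999L
  expect_error(predict(fit, bad2), "out of range")
})

test_that("checkpoints reload to an identical predictor", {
  enc <- separable_set(40)
  cfg <- tiny_config(seed = 14)
  fit <- train_model(build_model(cfg), enc, enc)
  dir <- withr::local_tempdir()
  save_checkpoint(fit, dir)
  expect_true(file.exists(file.path(dir, "config.json")))
  expect_true(file.exists(file.path(dir, "weights.rds")))
  back <- load_checkpoint(dir)
  expect_equal(back$config$variant, cfg$variant)
  expect_equal(predict(back, enc)$score, predict(fit, enc)$score)
})

test_that("gradients of every parameter leaf match central finite differences", {
  ns <- asNamespace("crisprstack")
  for (variant in c("contextual", "static")) {
    cfg <- model_config(
      variant = variant, k = 2, embed_dim = 8, n_layers = 1, n_heads = 2,
      lstm_units = 3, dense_units = c(5, 4), dropout = 0, seed = 42
    )
    set.seed(42)
    params <- ns$init_params(cfg, cfg$vocab_size)
    tokens <- matrix(sample(0:255, 3 * cfg$seq_len, replace = TRUE), 3)
    y <- c(1, 0, 1)
    fwd <- ns$nn_forward(params, tokens, cfg, train = FALSE)
    lg <- ns$nn_loss_grad(fwd$prob, y)
    grads <- ns$nn_backward(params, tokens, cfg, fwd, lg$dlogit)
    eps <- 1e-5
    set.seed(7)
    pluck_keys <- function(lst, keys) {
      for (kk in keys) lst <- lst[[kk]]
      lst
    }
    assign_in <- function(lst, keys, i, v) {
      if (length(keys) == 1L) {
        lst[[keys[[1]]]][i] <- v
        return(lst)
      }
      lst[[keys[[1]]]] <- assign_in(lst[[keys[[1]]]], keys[-1], i, v)
      lst
    }
    check_leaf <- function(keys) {
      leaf <- pluck_keys(params, keys)
      g <- pluck_keys(grads, keys)
      for (i in sample(length(leaf), min(3L, length(leaf)))) {
        l1 <- ns$nn_loss_grad(
          ns$nn_forward(assign_in(params, keys, i, leaf[i] + eps),
                        tokens, cfg)$prob, y)$loss
        l2 <- ns$nn_loss_grad(
          ns$nn_forward(assign_in(params, keys, i, leaf[i] - eps),
                        tokens, cfg)$prob, y)$loss
        num <- (l1 - l2) / (2 * eps)
        rel <- abs(g[i] - num) / max(1e-6, abs(g[i]) + abs(num))
        expect_lt(rel, 1e-3)
      }
    }
    n_leaves <- 0L
    walk <- function(node, keys = list()) {
      ks <- if (is.null(names(node))) seq_along(node) else names(node)
      for (kk in ks) {
        if (is.list(node[[kk]])) {
          walk(node[[kk]], c(keys, list(kk)))
        } else {
          n_leaves <<- n_leaves + 1L
          check_leaf(c(keys, list(kk)))
        }
      }
    }
    walk(params)
    # every parameter leaf of the variant was visited, including attention
    expect_equal(n_leaves, if (variant == "contextual") 30L else 13L)
  }
})
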