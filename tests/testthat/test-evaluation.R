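test_that("roc_auc matches the brute-force pairwise oracle on random instances", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))  # both classes present
    scores <- sample(round(runif(n), 2))  # rounding forces frequent ties
    expect_equal(roc_auc(labels, scores), roc_oracle(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("pr_auc matches direct step-sum enumeration on random instances", {
  set.seed(102)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    labels <- c(1, sample(0:1, n - 1, replace = TRUE))
    scores <- sample(round(runif(n), 2))
    expect_equal(pr_auc(labels, scores), ap_oracle(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("closed forms hold exactly: perfect separation, all ties, prevalence", {
  expect_identical(roc_auc(c(1, 0), c(0.9, 0.1)), 1)
  expect_identical(roc_auc(c(1, 1, 0, 0), rep(0.3, 4)), 0.5)
  expect_identical(pr_auc(c(1, 0, 1, 0, 0), c(0.9, 0.1, 0.8, 0.2, 0.3)), 1)
  # all-ties average precision equals prevalence p/n
  expect_identical(pr_auc(c(1, 1, 0, 0, 0), rep(0.5, 5)), 2 / 5)
  # the worked 5-element example: enumerate the 6 positive-negative pairs
  labels <- c(1, 1, 0, 0, 0)
  scores <- c(0.8, 0.4, 0.6, 0.4, 0.1)
  expect_equal(roc_auc(labels, scores), roc_oracle(labels, scores),
               tolerance = 1e-12)
  expect_equal(roc_oracle(labels, scores), (1 + 1 + 0.5 + 0 + 1 + 1) / 6)
})

test_that("both AUCs agree with an independent ROC library and are monotone-invariant", {
  skip_if_not_installed("pROC")
  set.seed(103)
  labels <- sample(0:1, 80, replace = TRUE, prob = c(0.7, 0.3))
  labels[1:2] <- 0:1
  scores <- round(rnorm(80), 1)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(labels, scores), ref, tolerance = 1e-10)
  # strictly monotone transforms leave both areas unchanged
  for (f in list(function(x) 3 * x + 2, function(x) exp(x), function(x) x^3)) {
    expect_equal(roc_auc(labels, f(scores)), roc_auc(labels, scores))
    expect_equal(pr_auc(labels, f(scores)), pr_auc(labels, scores))
  }
})

test_that("score negation complements roc_auc and degenerate inputs error", {
  set.seed(104)
  scores <- runif(40)  # tie-free
  labels <- c(1, 0, sample(0:1, 38, replace = TRUE))
  expect_equal(roc_auc(labels, scores) + roc_auc(labels, -scores), 1)
  expect_error(roc_auc(rep(1, 5), runif(5)), "undefined")
  expect_error(pr_auc(rep(0, 5), runif(5)), "undefined")
})

test_that("subsampling negatives raises average precision but not expected roc_auc", {
  set.seed(105)
  n_pos <- 60
  n_neg <- 600
  scores_pos <- rnorm(n_pos, 1)
  scores_neg <- rnorm(n_neg, 0)
  labels <- c(rep(1, n_pos), rep(0, n_neg))
  scores <- c(scores_pos, scores_neg)
  full_roc <- roc_auc(labels, scores)
  full_pr <- pr_auc(labels, scores)
  roc_sub <- pr_sub <- numeric(30)
  for (i in 1:30) {
    keep <- c(seq_len(n_pos), n_pos + sample.int(n_neg, 60))
    roc_sub[i] <- roc_auc(labels[keep], scores[keep])
    pr_sub[i] <- pr_auc(labels[keep], scores[keep])
  }
  expect_lt(abs(mean(roc_sub) - full_roc), 0.02)
  expect_gt(mean(pr_sub), full_pr)
})

test_that("evaluate_scores assembles curves consistent with the scalar areas", {
  set.seed(106)
  scored <- tibble::tibble(
    label = c(1, 0, sample(0:1, 48, replace = TRUE)),
    score = runif(50)
  )
  ev <- evaluate_scores(scored)
  expect_s3_class(ev, "crispr_eval")
  expect_equal(ev$n_pos + ev$n_neg, 50)
  # trapezoid under the assembled ROC curve reproduces the rank-based area
  roc <- ev$roc_curve
  trap <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  expect_equal(trap, ev$roc_auc, tolerance = 1e-12)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_equal(max(roc$fpr), 1)
  expect_equal(max(roc$tpr), 1)
  g <- glance(ev)
  expect_equal(g$roc_auc, ev$roc_auc)
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(autoplot(ev, "pr"), "ggplot")
})

test_that("single_split is stratified, exhaustive and seed-reproducible", {
  pairs <- tibble::tibble(
    guide_id = "g", guide_seq = "x", target_seq = "x",
    label = c(rep(1L, 10), rep(0L, 90))
  )
  sp <- single_split(pairs, 0.1, seed = 42)
  expect_equal(nrow(sp$val), 10L)
  expect_equal(sum(sp$val$label), 1L)  # 10% of the 10 positives
  expect_equal(nrow(sp$train) + nrow(sp$val), 100L)
  sp2 <- single_split(pairs, 0.1, seed = 42)
  expect_identical(sp$val, sp2$val)
  expect_error(single_split(pairs, 1.2), "val_fraction")

  big <- tibble::tibble(guide_id = "g", guide_seq = "x", target_seq = "x",
                        label = rep(c(0L, 1L), 500))
  expect_equal(nrow(single_split(big, 0.1, seed = 1)$val), 100L)
})

test_that("kfold_split partitions the data with stratified folds", {
  pairs <- tibble::tibble(guide_id = sprintf("p%02d", 1:10),
                          guide_seq = "x", target_seq = "x",
                          label = rep(c(1L, 0L), 5))
  folds <- kfold_split(pairs, 5, seed = 7)
  expect_length(folds, 5L)
  val_sizes <- vapply(folds, function(f) nrow(f$val), integer(1))
  expect_true(all(val_sizes == 2L))
  expect_true(all(vapply(folds, function(f) sum(f$val$label), integer(1)) == 1L))
  # union of validation folds is the whole dataset, each pair exactly once
  all_val <- dplyr::bind_rows(lapply(folds, `[[`, "val"))
  expect_setequal(all_val$guide_id, pairs$guide_id)
  expect_equal(anyDuplicated(all_val$guide_id), 0L)
  folds2 <- kfold_split(pairs, 5, seed = 7)
  expect_identical(folds, folds2)
  expect_error(kfold_split(pairs, 20), "exceeds")
})

test_that("guide grouping reproduces hand-derived partitions under the min-positive rule", {
  mk <- function(counts) {
    dplyr::bind_rows(lapply(names(counts), function(g) {
      n <- counts[[g]]
      tibble::tibble(guide_id = g, label = c(rep(1L, n), 0L))
    }))
  }
  # every guide alone meets the threshold -> singletons
  g1 <- group_guides_for_loso(mk(c(g1 = 40, g2 = 35, g3 = 31)), min_pos = 30)
  expect_equal(max(g1$group), 3L)
  expect_true(all(table(g1$group) == 1L))
  # 5+10 < 30, +20 = 35 >= 30 -> {g1,g2,g3}, {g4}
  g2 <- group_guides_for_loso(mk(c(g1 = 5, g2 = 10, g3 = 20, g4 = 40)),
                              min_pos = 30)
  expect_equal(g2$group[match(c("g1", "g2", "g3", "g4"), g2$guide_id)],
               c(1L, 1L, 1L, 2L))
  # degenerate single under-threshold guide
  g3 <- group_guides_for_loso(mk(c(g1 = 12)), min_pos = 30)
  expect_equal(g3$group, 1L)
  expect_true(attr(g3, "degenerate"))
  # trailing short group merges backwards: 20+20 closes, 25 alone merges
  g4 <- group_guides_for_loso(mk(c(ga = 20, gb = 20, gc = 25)), min_pos = 30)
  expect_equal(max(g4$group), 1L)
  expect_error(group_guides_for_loso(
    tibble::tibble(guide_id = "g", label = 0L), min_pos = 30), "no positive")
})

test_that("grouping is a deterministic partition meeting min_pos on random profiles", {
  set.seed(108)
  for (i in 1:25) {
    counts <- sample(0:60, sample(3:12, 1), replace = TRUE)
    if (sum(counts) < 30) counts[1] <- counts[1] + 30
    names(counts) <- sprintf("g%02d", seq_along(counts))
    pairs <- dplyr::bind_rows(lapply(names(counts), function(g) {
      tibble::tibble(guide_id = g, label = c(rep(1L, counts[[g]]), 0L))
    }))
    grp <- group_guides_for_loso(pairs, min_pos = 30)
    # partition: every guide exactly once
    expect_setequal(grp$guide_id, names(counts))
    expect_equal(anyDuplicated(grp$guide_id), 0L)
    # every group meets the threshold
    per_group <- tapply(grp$n_pos, grp$group, sum)
    expect_true(all(per_group >= 30))
    # contiguous group ids
    expect_setequal(unique(grp$group), seq_len(max(grp$group)))
  }
})

test_that("leave-one-sgRNA-out scores every pair exactly once and recovers synthetic signal", {
  pairs <- simulate_pairs(synthetic_config(n_guides = 6, pairs_per_guide = 200,
                                           seed = 501))
  mcfg <- model_config(variant = "static", embed_dim = 16, lstm_units = 16,
                       dense_units = c(32, 16), dropout = 0.1,
                       learning_rate = 2e-3, batch_size = 64, epochs = 25,
                       seed = 9)
  res <- run_loso(pairs, config = mcfg, min_pos = 25, seed = 77)
  expect_s3_class(res, "crispr_loso")
  expect_equal(nrow(res$predictions), nrow(pairs))
  expect_equal(sort(table(res$predictions$group)),
               sort(table(res$groups$group[match(pairs$guide_id, res$groups$guide_id)])))
  expect_equal(res$global$n_pos + res$global$n_neg, nrow(pairs))
  # per-group reports pool into the global report
  expect_equal(nrow(res$per_group), max(res$groups$group))
  # both global and average aggregates are reported
  g <- glance(res)
  expect_true(all(c("global_roc_auc", "global_pr_auc",
                    "mean_roc_auc", "mean_pr_auc") %in% names(g)))
  # learnable mismatch-driven labels transfer to held-out guides
  expect_gte(res$global$roc_auc, 0.8)
})

test_that("evaluation reports write and reread as text", {
  ev <- evaluate_scores(tibble::tibble(label = c(1, 1, 0, 0),
                                       score = c(0.9, 0.4, 0.6, 0.1)))
  dir <- withr::local_tempdir()
  write_eval_report(ev, file.path(dir, "toy"))
  lines <- readLines(file.path(dir, "toy_metrics.txt"))
  expect_match(lines[1], "^roc_auc: ")
  roc_tab <- readr::read_csv(file.path(dir, "toy_roc.csv"),
                             show_col_types = FALSE)
  expect_equal(names(roc_tab), c("fpr", "tpr"))
})
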