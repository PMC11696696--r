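#' ROC-AUC by the rank (Mann-Whitney) formulation
#'
#' Equals the probability that a uniformly chosen positive outscores a
#' uniformly chosen negative, with ties counted one half. This is identical
#' to the trapezoidal area under the ROC curve when tied scores are processed
#' as a single threshold block.
#'
#' @param labels 0/1 vector.
#' @param scores Numeric scores, higher = more positive.
#' @return ROC-AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  check_scored(labels, scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC-AUC undefined: need at least one positive and one negative",
         call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' PR-AUC as average precision
#'
#' Average precision with step interpolation: the sum over score-descending
#' threshold blocks of (recall increment) times (precision at the block).
#' Tied scores enter the confusion counts together, so the value is invariant
#' to permutations within ties. Linear (trapezoidal) interpolation is
#' deliberately not used: it is optimistic on imbalanced data.
#'
#' @inheritParams roc_auc
#' @return Average precision in `[0, 1]`.
#' @export
pr_auc <- function(labels, scores) {
  check_scored(labels, scores)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("PR-AUC undefined: no positives", call. = FALSE)
  blocks <- threshold_blocks(labels, scores)
  sum((blocks$tp - dplyr::lag(blocks$tp, default = 0)) / n_pos * blocks$precision)
}

check_scored <- function(labels, scores) {
  if (length(labels) != length(scores) || length(labels) == 0) {
    stop("labels and scores must be non-empty vectors of equal length",
         call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  invisible(TRUE)
}

# cumulative confusion counts at each distinct score threshold, descending
threshold_blocks <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  last <- which(!duplicated(sc, fromLast = TRUE))  # block ends in sorted order
  ctp <- cumsum(lab == 1)[last]
  cn <- last  # items at or above threshold
  tibble::tibble(
    threshold = sc[last],
    tp = ctp,
    fp = cn - ctp,
    precision = ctp / cn
  )
}

#' Score a set of predictions into an evaluation report
#'
#' Computes ROC and precision-recall curves and their areas from a tibble of
#' labelled scores.
#'
#' @param scored Data frame with columns `label` (0/1) and `score`.
#' @return A `crispr_eval` object: `roc_auc`, `pr_auc`, `roc_curve`
#'   (`fpr`, `tpr`), `pr_curve` (`recall`, `precision`), `n_pos`, `n_neg`.
#' @export
evaluate_scores <- function(scored) {
  stopifnot(all(c("label", "score") %in% names(scored)))
  labels <- scored$label
  scores <- scored$score
  check_scored(labels, scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  blocks <- threshold_blocks(labels, scores)
  roc <- tibble::tibble(
    fpr = c(0, blocks$fp / max(n_neg, 1)),
    tpr = c(0, blocks$tp / max(n_pos, 1))
  )
  pr <- tibble::tibble(
    recall = blocks$tp / max(n_pos, 1),
    precision = blocks$precision
  )
  structure(
    list(
      roc_auc = if (n_pos > 0 && n_neg > 0) roc_auc(labels, scores) else NA_real_,
      pr_auc = if (n_pos > 0) pr_auc(labels, scores) else NA_real_,
      roc_curve = roc,
      pr_curve = pr,
      n_pos = n_pos,
      n_neg = n_neg
    ),
    class = "crispr_eval"
  )
}

#' @export
print.crispr_eval <- function(x, ...) {
  cat(sprintf(
    "<crispr_eval> %d pos / %d neg  ROC-AUC %.4f  PR-AUC %.4f\n",
    x$n_pos, x$n_neg, x$roc_auc, x$pr_auc
  ))
  invisible(x)
}

#' Stratified single train/validation split
#'
#' Splits within each class so the validation positive fraction matches the
#' overall one up to rounding; the total validation size is
#' `round(val_fraction * n)`.
#'
#' @param pairs Pair tibble with a `label` column.
#' @param val_fraction Fraction held out, in (0, 1).
#' @param seed Integer seed.
#' @return List with tibbles `train` and `val` (disjoint, exhaustive).
#' @export
single_split <- function(pairs, val_fraction = 0.1, seed = 1) {
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop("val_fraction must lie in (0, 1)", call. = FALSE)
  }
  stopifnot("label" %in% names(pairs))
  n <- nrow(pairs)
  n_val <- round(val_fraction * n)
  pos_idx <- which(pairs$label == 1)
  n_val_pos <- min(round(val_fraction * length(pos_idx)), n_val)
  set.seed(seed)
  val_pos <- sample(pos_idx, n_val_pos)
  neg_idx <- which(pairs$label != 1)
  val_neg <- sample(neg_idx, n_val - n_val_pos)
  val_rows <- sort(c(val_pos, val_neg))
  list(
    train = pairs[-val_rows, , drop = FALSE],
    val = pairs[val_rows, , drop = FALSE]
  )
}

#' Stratified k-fold split
#'
#' @param pairs Pair tibble with `label`.
#' @param k_folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of `k_folds` elements, each `list(train, val)`; the validation
#'   sets partition the data and each class is spread evenly across folds.
#' @export
kfold_split <- function(pairs, k_folds = 5, seed = 1) {
  n <- nrow(pairs)
  if (k_folds < 2) stop("k_folds must be >= 2", call. = FALSE)
  if (k_folds > n) stop("k_folds exceeds the number of pairs", call. = FALSE)
  stopifnot("label" %in% names(pairs))
  set.seed(seed)
  fold <- integer(n)
  for (cls in unique(pairs$label)) {
    idx <- which(pairs$label == cls)
    fold[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
  }
  lapply(seq_len(k_folds), function(f) {
    list(
      train = pairs[fold != f, , drop = FALSE],
      val = pairs[fold == f, , drop = FALSE]
    )
  })
}

#' Group guides for leave-one-sgRNA-out validation
#'
#' Guides with few validated positives give unstable per-guide metrics, so
#' guides are merged until every held-out group carries at least `min_pos`
#' positive pairs: guides are sorted ascending by positive count (ties broken
#' by `guide_id`) and accumulated greedily into the current group until its
#' positive total reaches `min_pos`, when a new group starts. A trailing group
#' below `min_pos` merges into the previous group. A dataset whose total
#' positives fall below `min_pos` yields a single (degenerate) group.
#'
#' @param pairs Pair tibble with `guide_id` and `label`.
#' @param min_pos Minimum positives per group (default 30).
#' @return A `crispr_groups` tibble: `guide_id`, `n_pos`, `group`; the
#'   `degenerate` attribute flags a single under-threshold group.
#' @export
group_guides_for_loso <- function(pairs, min_pos = 30) {
  stopifnot(all(c("guide_id", "label") %in% names(pairs)))
  if (min_pos < 1) stop("min_pos must be >= 1", call. = FALSE)
  counts <- pairs |>
    dplyr::group_by(.data$guide_id) |>
    dplyr::summarise(n_pos = sum(.data$label == 1), .groups = "drop") |>
    dplyr::arrange(.data$n_pos, .data$guide_id)
  if (sum(counts$n_pos) == 0) {
    stop("cannot group guides: dataset has no positive pairs", call. = FALSE)
  }
  group <- integer(nrow(counts))
  g <- 1L
  acc <- 0L
  for (i in seq_len(nrow(counts))) {
    group[i] <- g
    acc <- acc + counts$n_pos[i]
    if (acc >= min_pos && i < nrow(counts)) {
      g <- g + 1L
      acc <- 0L
    }
  }
  # trailing group short of min_pos merges backwards
  if (acc < min_pos && g > 1L && group[nrow(counts)] == g) {
    group[group == g] <- g - 1L
  }
  counts$group <- group
  degenerate <- max(group) == 1L && sum(counts$n_pos) < min_pos
  structure(counts, class = c("crispr_groups", class(counts)),
            degenerate = degenerate)
}

#' Leave-one-sgRNA-out cross-validation
#'
#' For each guide group from [group_guides_for_loso()], trains the configured
#' classifier on all other groups and scores the held-out group. Reports
#' per-group metrics, their averages, and a global report over the pooled
#' held-out predictions (each pair scored exactly once). Held-out groups with
#' a single class get `NA` metrics, are excluded from the averages, and still
#' contribute to the global pool.
#'
#' @param pairs Pair tibble (`guide_id`, `guide_seq`, `target_seq`, `label`).
#' @param config A [model_config()].
#' @param min_pos Minimum positives per held-out group.
#' @param seed Integer seed for grouping-independent training randomness.
#' @return A `crispr_loso` object: `per_group` tibble, `global` crispr_eval,
#'   `averages` (mean per-group ROC/PR-AUC), `groups`, and the pooled
#'   `predictions`.
#' @export
run_loso <- function(pairs, config = model_config(), min_pos = 30, seed = 1) {
  groups <- group_guides_for_loso(pairs, min_pos = min_pos)
  n_groups <- max(groups$group)
  if (n_groups < 2) {
    stop("leave-one-sgRNA-out needs at least two guide groups after merging",
         call. = FALSE)
  }
  enc <- encode_pairs(pairs, k = config$k)
  assign_grp <- groups$group[match(enc$guide_id, groups$guide_id)]
  per <- vector("list", n_groups)
  preds <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    train <- enc[assign_grp != g, , drop = FALSE]
    held <- enc[assign_grp == g, , drop = FALSE]
    cfg_g <- config
    cfg_g$seed <- seed + g
    split <- single_split(train, val_fraction = 0.1, seed = seed + g)
    fit <- train_model(build_model(cfg_g), split$train, split$val)
    scored <- predict(fit, held)
    scored$group <- g
    preds[[g]] <- scored
    ok <- length(unique(scored$label)) == 2L
    per[[g]] <- tibble::tibble(
      group = g,
      n_pos = sum(scored$label == 1),
      n_neg = sum(scored$label == 0),
      roc_auc = if (ok) roc_auc(scored$label, scored$score) else NA_real_,
      pr_auc = if (any(scored$label == 1)) pr_auc(scored$label, scored$score) else NA_real_
    )
  }
  per_group <- dplyr::bind_rows(per)
  pooled <- dplyr::bind_rows(preds)
  structure(
    list(
      per_group = per_group,
      global = evaluate_scores(pooled),
      averages = list(
        roc_auc = mean(per_group$roc_auc, na.rm = TRUE),
        pr_auc = mean(per_group$pr_auc, na.rm = TRUE)
      ),
      groups = groups,
      predictions = pooled
    ),
    class = "crispr_loso"
  )
}

#' @export
print.crispr_loso <- function(x, ...) {
  cat(sprintf(
    "<crispr_loso> %d groups  global ROC-AUC %.4f  PR-AUC %.4f  (avg %.4f / %.4f)\n",
    nrow(x$per_group), x$global$roc_auc, x$global$pr_auc,
    x$averages$roc_auc, x$averages$pr_auc
  ))
  invisible(x)
}

#' Write an evaluation report to text files
#'
#' Emits a `key: value` metrics file and optional curve tables
#' (`fpr,tpr` and `recall,precision` columns).
#'
#' @param eval A `crispr_eval`.
#' @param prefix Path prefix; writes `<prefix>_metrics.txt`,
#'   `<prefix>_roc.csv`, `<prefix>_pr.csv`.
#' @param curves Write curve tables too?
#' @return The metrics file path, invisibly.
#' @export
write_eval_report <- function(eval, prefix, curves = TRUE) {
  stopifnot(inherits(eval, "crispr_eval"))
  metrics_path <- paste0(prefix, "_metrics.txt")
  writeLines(c(
    sprintf("roc_auc: %.6f", eval$roc_auc),
    sprintf("pr_auc: %.6f", eval$pr_auc),
    sprintf("n_pos: %d", eval$n_pos),
    sprintf("n_neg: %d", eval$n_neg)
  ), metrics_path)
  if (curves) {
    readr::write_csv(eval$roc_curve, paste0(prefix, "_roc.csv"), progress = FALSE)
    readr::write_csv(eval$pr_curve, paste0(prefix, "_pr.csv"), progress = FALSE)
  }
  invisible(metrics_path)
}
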