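#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained classifier: its per-epoch training log
#'
#' @param x A `crispr_fit`.
#' @param ... Unused.
#' @return Tibble `epoch`, `train_loss`, `val_roc_auc`, `val_pr_auc`.
#' @method tidy crispr_fit
#' @export
tidy.crispr_fit <- function(x, ...) x$training_log

#' One-row summary of a trained classifier
#'
#' @param x A `crispr_fit`.
#' @param ... Unused.
#' @return Tibble with variant, sizes, parameter count and best-epoch
#'   validation metrics.
#' @method glance crispr_fit
#' @export
glance.crispr_fit <- function(x, ...) {
  best <- x$training_log[x$training_log$epoch == x$best_epoch, ]
  tibble::tibble(
    variant = x$config$variant,
    k = x$config$k,
    embed_dim = x$config$embed_dim,
    n_parameters = x$n_parameters,
    epochs = nrow(x$training_log),
    best_epoch = x$best_epoch,
    val_roc_auc = if (nrow(best)) best$val_roc_auc else NA_real_,
    val_pr_auc = if (nrow(best)) best$val_pr_auc else NA_real_
  )
}

#' Tidy an evaluation report into curve points
#'
#' @param x A `crispr_eval`.
#' @param curve `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return The requested curve as a tibble.
#' @method tidy crispr_eval
#' @export
tidy.crispr_eval <- function(x, curve = c("roc", "pr"), ...) {
  curve <- match.arg(curve)
  if (curve == "roc") x$roc_curve else x$pr_curve
}

#' One-row summary of an evaluation report
#'
#' @param x A `crispr_eval`.
#' @param ... Unused.
#' @return Tibble `roc_auc`, `pr_auc`, `n_pos`, `n_neg`.
#' @method glance crispr_eval
#' @export
glance.crispr_eval <- function(x, ...) {
  tibble::tibble(roc_auc = x$roc_auc, pr_auc = x$pr_auc,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy a leave-one-sgRNA-out result: per-group metrics
#'
#' @param x A `crispr_loso`.
#' @param ... Unused.
#' @return The per-group metric tibble.
#' @method tidy crispr_loso
#' @export
tidy.crispr_loso <- function(x, ...) x$per_group

#' One-row summary of a leave-one-sgRNA-out run
#'
#' @param x A `crispr_loso`.
#' @param ... Unused.
#' @return Tibble with global and average ROC/PR-AUC and group count.
#' @method glance crispr_loso
#' @export
glance.crispr_loso <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$per_group),
    global_roc_auc = x$global$roc_auc,
    global_pr_auc = x$global$pr_auc,
    mean_roc_auc = x$averages$roc_auc,
    mean_pr_auc = x$averages$pr_auc
  )
}

#' ROC and precision-recall curves of an evaluation report
#'
#' @param object A `crispr_eval`.
#' @param curve `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crispr_eval
#' @export
autoplot.crispr_eval <- function(object, curve = c("roc", "pr"), ...) {
  curve <- match.arg(curve)
  if (curve == "roc") {
    ggplot2::ggplot(object$roc_curve,
                    ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(linetype = "dotted") +
      ggplot2::coord_equal() +
      ggplot2::labs(
        x = "false-positive rate", y = "true-positive rate",
        title = sprintf("ROC-AUC = %.3f", object$roc_auc)
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$pr_curve,
                    ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(
        x = "recall", y = "precision",
        title = sprintf("PR-AUC = %.3f", object$pr_auc)
      ) +
      ggplot2::theme_minimal()
  }
}

#' Training curves of a fitted classifier
#'
#' @param object A `crispr_fit`.
#' @param ... Unused.
#' @return A ggplot object: loss and validation AUCs by epoch.
#' @method autoplot crispr_fit
#' @export
autoplot.crispr_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$training_log, -"epoch",
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}
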