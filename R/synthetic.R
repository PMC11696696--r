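#' Configuration for the synthetic sgRNA-DNA pair generator
#'
#' The generator emulates the structure of genome-wide off-target screens:
#' a set of guides, each with many aligned 23-bp candidate targets carrying
#' 0-6 substitution mismatches placed with positional bias, heavy class
#' imbalance, and labels that are a stochastic function of the mismatch
#' configuration only.
#'
#' Two label models are available. `threshold`: a target is cleaved iff its
#' mismatch count is at most `m_star`, then the label is flipped with
#' probability `eps` (a deterministic oracle plus symmetric noise).
#' `logistic`: `P(label = 1) = plogis(beta0 - sum of w_p over mismatched
#' positions p)`, a calibrated-probability regime.
#'
#' @param n_guides Number of distinct guides.
#' @param pairs_per_guide Targets generated per guide.
#' @param max_mismatches Maximum substitutions per pair (default 6, matching
#'   the usual candidate-site search radius).
#' @param mismatch_count_weights Probability weights over 0..`max_mismatches`
#'   mismatches. The default gives roughly 20% positives under the default
#'   threshold label model.
#' @param position_weights Length-23 non-negative vector biasing mismatch
#'   placement. The default decays from the PAM-distal end of the spacer
#'   (positions 1-20), where validated off-target sites tolerate mismatches
#'   best, and keeps the PAM (21-23) nearly intact.
#' @param label_model `"threshold"` or `"logistic"`.
#' @param label_params For `threshold`: list with `m_star` (cutoff) and `eps`
#'   (flip probability, `0 <= eps < 0.5`). For `logistic`: list with `beta0`
#'   and `w` (length-23 per-position penalties).
#' @param pam 3-letter PAM suffix for generated guides.
#' @param seed Integer seed; every draw is reproducible under it.
#' @return A `crispr_synth_config` list.
#' @export
synthetic_config <- function(n_guides = 20,
                             pairs_per_guide = 300,
                             max_mismatches = 6,
                             mismatch_count_weights =
                               c(0.02, 0.05, 0.10, 0.18, 0.25, 0.22, 0.18),
                             position_weights =
                               c(seq(3, 1, length.out = 20), rep(0.15, 3)),
                             label_model = c("threshold", "logistic"),
                             label_params = NULL,
                             pam = "AGG",
                             seed = 20260923) {
  label_model <- match.arg(label_model)
  if (is.null(label_params)) {
    label_params <- switch(label_model,
      threshold = list(m_star = 2L, eps = 0.05),
      logistic  = list(beta0 = 1.5, w = c(rep(0.6, 12), rep(1.2, 8), rep(1.8, 3)))
    )
  }
  if (length(mismatch_count_weights) != max_mismatches + 1L ||
      any(mismatch_count_weights < 0) || sum(mismatch_count_weights) <= 0) {
    stop("mismatch_count_weights must be ", max_mismatches + 1L,
         " non-negative values with positive sum", call. = FALSE)
  }
  if (length(position_weights) != PAIR_LEN || any(position_weights < 0) ||
      sum(position_weights > 0) < max_mismatches) {
    stop("position_weights must be 23 non-negative values with at least ",
         max_mismatches, " positive entries", call. = FALSE)
  }
  if (label_model == "threshold" &&
      (label_params$eps < 0 || label_params$eps >= 0.5)) {
    stop("flip noise eps must lie in [0, 0.5)", call. = FALSE)
  }
  if (nchar(pam) != 3L) stop("pam must be 3 letters", call. = FALSE)
  structure(
    list(
      n_guides = as.integer(n_guides),
      pairs_per_guide = as.integer(pairs_per_guide),
      max_mismatches = as.integer(max_mismatches),
      mismatch_count_weights = mismatch_count_weights / sum(mismatch_count_weights),
      position_weights = position_weights,
      label_model = label_model,
      label_params = label_params,
      pam = normalize_sequence(pam),
      seed = as.integer(seed)
    ),
    class = "crispr_synth_config"
  )
}

#' Generate distinct guide sequences
#'
#' Spacer positions 1-20 are drawn uniformly over A/C/G/T; positions 21-23
#' carry the configured PAM. Collisions are resampled so all guides are
#' distinct.
#'
#' @param cfg A [synthetic_config()].
#' @return Tibble with `guide_id` and `guide_seq`.
#' @export
generate_guides <- function(cfg) {
  stopifnot(inherits(cfg, "crispr_synth_config"))
  if (cfg$n_guides < 1L) stop("n_guides must be >= 1", call. = FALSE)
  set.seed(cfg$seed)
  draw <- function(n) {
    spacers <- vapply(seq_len(n), function(i) {
      paste(sample(BASES, 20L, replace = TRUE), collapse = "")
    }, character(1))
    paste0(spacers, cfg$pam)
  }
  guides <- unique(draw(cfg$n_guides))
  tries <- 0L
  while (length(guides) < cfg$n_guides) {
    guides <- unique(c(guides, draw(cfg$n_guides - length(guides))))
    tries <- tries + 1L
    if (tries > 100L) stop("could not generate distinct guides", call. = FALSE)
  }
  tibble::tibble(
    guide_id = sprintf("g%02d", seq_len(cfg$n_guides)),
    guide_seq = guides
  )
}

#' Generate aligned target sequences and labels for a set of guides
#'
#' For every target: a mismatch count `m` is drawn from
#' `mismatch_count_weights`; `m` distinct positions are chosen with
#' probability proportional to `position_weights`; each is substituted to a
#' uniformly random different base; the label is drawn from the configured
#' label model.
#'
#' @param guides Tibble from [generate_guides()] (columns `guide_id`,
#'   `guide_seq`).
#' @param cfg A [synthetic_config()].
#' @return Tibble of pairs: `guide_id`, `guide_seq`, `target_seq`, `label`,
#'   plus the generator-truth column `n_mismatch`.
#' @export
generate_pairs <- function(guides, cfg) {
  stopifnot(inherits(cfg, "crispr_synth_config"))
  set.seed(cfg$seed + 1L)
  n_per <- cfg$pairs_per_guide
  rows <- vector("list", nrow(guides))
  for (gi in seq_len(nrow(guides))) {
    gseq <- guides$guide_seq[gi]
    gdig <- base4_digits(gseq)[1L, ]
    m <- sample(0:cfg$max_mismatches, n_per, replace = TRUE,
                prob = cfg$mismatch_count_weights)
    targets <- character(n_per)
    for (j in seq_len(n_per)) {
      tdig <- gdig
      if (m[j] > 0L) {
        pos <- sample.int(PAIR_LEN, m[j], prob = cfg$position_weights)
        # substitute to a uniformly random *different* base
        tdig[pos] <- (tdig[pos] + sample.int(3L, m[j], replace = TRUE)) %% 4L
      }
      targets[j] <- paste(BASES[tdig + 1L], collapse = "")
    }
    lab <- draw_labels(gseq, targets, m, cfg)
    rows[[gi]] <- tibble::tibble(
      guide_id = guides$guide_id[gi],
      guide_seq = gseq,
      target_seq = targets,
      label = lab,
      n_mismatch = m
    )
  }
  dplyr::bind_rows(rows)
}

draw_labels <- function(gseq, targets, m, cfg) {
  p <- cfg$label_params
  if (cfg$label_model == "threshold") {
    clean <- as.integer(m <= p$m_star)
    flip <- runif(length(m)) < p$eps
    as.integer(ifelse(flip, 1L - clean, clean))
  } else {
    pos <- mismatch_positions(rep(gseq, length(targets)), targets)
    eta <- p$beta0 - vapply(pos, function(pp) sum(p$w[pp]), numeric(1))
    as.integer(runif(length(m)) < stats::plogis(eta))
  }
}

#' Simulate a full pair dataset in one call
#'
#' @param cfg A [synthetic_config()].
#' @return Tibble of generated pairs (see [generate_pairs()]).
#' @export
simulate_pairs <- function(cfg = synthetic_config()) {
  generate_pairs(generate_guides(cfg), cfg)
}

#' The fixed recoverable benchmark
#'
#' A standard synthetic dataset with recoverable signal: 20 guides times 300
#' pairs under the threshold label model (`m_star = 2`, flip noise 0.05),
#' roughly 20% positives, split 90/10 by stratified [single_split()]. It is
#' the reference fixture for the learnability checks of the classifier.
#'
#' @param cfg A [synthetic_config()]; the default is the benchmark condition.
#' @param val_fraction Held-out fraction (default 0.1).
#' @return List with tibbles `train` and `val`.
#' @export
recoverable_benchmark <- function(cfg = synthetic_config(), val_fraction = 0.1) {
  pairs <- simulate_pairs(cfg)
  single_split(pairs, val_fraction = val_fraction, seed = cfg$seed + 2L)
}
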