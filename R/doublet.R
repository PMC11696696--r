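#' Positional doublet-frequency matrix
#'
#' Tallies, for every stack token and every window position, how many pairs
#' carry that token at that position. With no restriction each position
#' column sums to the number of pairs analyzed. `mismatch_only` zeroes the
#' rows of fully matched tokens (guide half equal to target half) before any
#' ranking, since matched doublets would otherwise dominate; `positives_only`
#' restricts the tally to label-1 pairs, the class whose doublet composition
#' characterizes real off-target sites.
#'
#' @param pairs Pair tibble (`guide_seq`, `target_seq`, optionally `label`).
#' @param k Encoding order (default 2).
#' @param mismatch_only Zero matched-token rows? Default `TRUE`.
#' @param positives_only Use only label-1 pairs? Default `TRUE` (needs a
#'   `label` column; set `FALSE` to tally everything).
#' @return A `crispr_doublet_matrix`: integer matrix `4^(2k)` x `23 - k + 1`
#'   with token-string rownames and position colnames, plus attributes
#'   `n_pairs`, `k`, `mismatch_only`.
#' @export
positional_frequency <- function(pairs, k = 2, mismatch_only = TRUE,
                                 positives_only = TRUE) {
  k <- check_order(k)
  if (positives_only) {
    if (!"label" %in% names(pairs)) {
      stop("positives_only = TRUE needs a label column", call. = FALSE)
    }
    pairs <- pairs[pairs$label == 1, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) stop("no pairs to analyze", call. = FALSE)
  vocab <- build_vocabulary(k)
  n_tok <- PAIR_LEN - k + 1L
  enc <- encode_pairs(pairs, k = k)
  tok <- do.call(rbind, enc$tokens)  # n x n_tok, 0-based
  counts <- matrix(0L, nrow = vocab$size, ncol = n_tok,
                   dimnames = list(vocab$tokens, seq_len(n_tok)))
  for (p in seq_len(n_tok)) {
    tab <- tabulate(tok[, p] + 1L, nbins = vocab$size)
    counts[, p] <- tab
  }
  if (mismatch_only) {
    half <- nchar(vocab$tokens) %/% 2L
    matched <- substr(vocab$tokens, 1L, half) ==
      substr(vocab$tokens, half + 1L, 2L * half)
    counts[matched, ] <- 0L
  }
  structure(counts, class = c("crispr_doublet_matrix", class(counts)),
            n_pairs = nrow(pairs), k = k, mismatch_only = mismatch_only)
}

#' Render a token string as a "guide to target" label
#'
#' @param token Character vector of `2k`-letter token strings.
#' @return Labels such as `"GG to TC"`.
#' @export
token_label <- function(token) {
  half <- nchar(token) %/% 2L
  paste(substr(token, 1L, half), "to",
        substr(token, half + 1L, 2L * half))
}

#' Top tokens by total positional frequency
#'
#' @param mat A [positional_frequency()] matrix.
#' @param n How many tokens to return (default 50).
#' @return A tibble `token`, `label`, `total`, ranked descending with
#'   lexicographic tie-break; at most the number of nonzero tokens.
#' @export
top_doublets <- function(mat, n = 50) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  totals <- rowSums(mat)
  keep <- totals > 0
  tokens <- rownames(mat)[keep]
  totals <- totals[keep]
  ord <- order(-totals, tokens)
  sel <- head(ord, n)
  tibble::tibble(
    token = tokens[sel],
    label = token_label(tokens[sel]),
    total = as.integer(totals[sel])
  )
}

#' Overlap between two top-token lists
#'
#' @param a,b Character vectors of tokens (or tibbles from [top_doublets()]).
#' @return List with `n_shared` and `shared` (sorted member tokens).
#' @export
shared_top_doublets <- function(a, b) {
  if (is.data.frame(a)) a <- a$token
  if (is.data.frame(b)) b <- b$token
  shared <- sort(intersect(a, b))
  list(n_shared = length(shared), shared = shared)
}

#' Export a positional-frequency heatmap and its table
#'
#' Writes the numeric table (rows labelled "XY to ZW", columns positions) as
#' CSV and a heatmap image (darker = more frequent) as PNG.
#'
#' @param mat A [positional_frequency()] matrix.
#' @param tokens Character vector of tokens to show (e.g.
#'   `top_doublets(mat)$token`); must be non-empty.
#' @param prefix Output path prefix; writes `<prefix>.csv` and `<prefix>.png`.
#' @param width,height Image size in inches.
#' @return Paths of the written files, invisibly.
#' @export
export_heatmap <- function(mat, tokens, prefix, width = 7, height = 7) {
  if (length(tokens) == 0L) stop("empty token selection", call. = FALSE)
  miss <- setdiff(tokens, rownames(mat))
  if (length(miss)) stop("tokens not in matrix: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  sub <- mat[tokens, , drop = FALSE]
  tbl <- tibble::as_tibble(as.data.frame(unclass(sub)), .name_repair = "minimal")
  names(tbl) <- colnames(mat)
  tbl <- dplyr::bind_cols(tibble::tibble(doublet = token_label(tokens)), tbl)
  csv_path <- paste0(prefix, ".csv")
  png_path <- paste0(prefix, ".png")
  readr::write_csv(tbl, csv_path, progress = FALSE)
  p <- autoplot.crispr_doublet_matrix(mat, tokens = tokens)
  ggplot2::ggsave(png_path, p, width = width, height = height, dpi = 150)
  invisible(c(table = csv_path, image = png_path))
}

#' Heatmap of a positional doublet-frequency matrix
#'
#' @param object A `crispr_doublet_matrix`.
#' @param tokens Tokens (rows) to display; default the top 50.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crispr_doublet_matrix
#' @export
autoplot.crispr_doublet_matrix <- function(object, tokens = NULL, ...) {
  if (is.null(tokens)) tokens <- top_doublets(object, 50)$token
  sub <- object[tokens, , drop = FALSE]
  df <- tibble::tibble(
    doublet = factor(rep(token_label(tokens), ncol(sub)),
                     levels = rev(token_label(tokens))),
    position = rep(as.integer(colnames(sub)), each = length(tokens)),
    count = as.vector(unclass(sub))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$doublet,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10") +
    ggplot2::scale_x_continuous(breaks = as.integer(colnames(sub))) +
    ggplot2::labs(x = "position along the duplex", y = NULL,
                  fill = "count") +
    ggplot2::theme_minimal(base_size = 9)
}
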