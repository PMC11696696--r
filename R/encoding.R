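#' @importFrom rlang .data
#' @importFrom stats predict rnorm runif setNames
#' @importFrom utils head
NULL

BASES <- c("A", "C", "G", "T")

#' Normalize a nucleotide sequence
#'
#' Uppercases, converts RNA `U` to `T`, and validates the alphabet. Gap
#' characters (`-`) are allowed through so that indel-containing alignment rows
#' can be recognized (and dropped) downstream by [filter_pairs()].
#'
#' @param x Character vector of raw sequences.
#' @return Character vector of normalized sequences over `{A,C,G,T,-}`.
#' @examples
#' normalize_sequence("acgu")
#' @export
normalize_sequence <- function(x) {
  if (!is.character(x) || any(is.na(x)) || any(!nzchar(x))) {
    stop("sequences must be non-empty strings", call. = FALSE)
  }
  out <- chartr("U", "T", toupper(x))
  bad <- gregexpr("[^ACGT-]", out)
  for (i in seq_along(out)) {
    pos <- bad[[i]]
    if (pos[1L] != -1L) {
      stop(sprintf(
        "invalid character '%s' at position %d in sequence '%s'",
        substr(out[i], pos[1L], pos[1L]), pos[1L], x[i]
      ), call. = FALSE)
    }
  }
  out
}

#' Build the stack-encoding vocabulary
#'
#' The order-`k` stack vocabulary contains every concatenation of a `k`-mer
#' from the guide with the aligned `k`-mer from the target, `4^(2k)` tokens in
#' all (256 doublets for the default `k = 2`). Indices are lexicographic over
#' the concatenated `2k`-letter string with `A=0, C=1, G=2, T=3`, so the map
#' is reconstructible without a stored table.
#'
#' @param k Encoding order: 1 (singlet), 2 (doublet) or 3 (triplet).
#' @return A `crispr_vocab` object: list with `k`, `size` and `tokens` (token
#'   strings ordered by index; token `i` is `tokens[i + 1]`, indices 0-based).
#' @examples
#' v <- build_vocabulary(2)
#' v$size
#' vocab_index(v, "GGTC")
#' @export
build_vocabulary <- function(k = 2) {
  k <- check_order(k)
  n <- 2L * k
  grid <- do.call(expand.grid, c(
    rep(list(BASES), n),
    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ))
  # expand.grid varies the first factor fastest; reverse columns for
  # lexicographic order on the concatenated string
  tokens <- do.call(paste0, rev(grid))
  structure(
    list(k = k, size = 4L^n, tokens = tokens),
    class = "crispr_vocab"
  )
}

#' @export
print.crispr_vocab <- function(x, ...) {
  cat(sprintf(
    "<crispr_vocab> order k = %d, %d tokens ('%s' ... '%s')\n",
    x$k, x$size, x$tokens[1L], x$tokens[x$size]
  ))
  invisible(x)
}

#' Look up token indices in a vocabulary
#'
#' @param vocab A `crispr_vocab`.
#' @param token Character vector of `2k`-letter token strings.
#' @return Integer 0-based indices.
#' @export
vocab_index <- function(vocab, token) {
  idx <- match(token, vocab$tokens)
  if (anyNA(idx)) {
    stop("unknown token(s): ", paste(token[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx - 1L
}

#' Decode token indices back to token strings
#'
#' @param vocab A `crispr_vocab`.
#' @param index Integer vector of 0-based indices.
#' @return Character vector of token strings.
#' @export
vocab_token <- function(vocab, index) {
  if (any(index < 0L | index >= vocab$size)) {
    stop("token index out of range [0, ", vocab$size, ")", call. = FALSE)
  }
  vocab$tokens[index + 1L]
}

check_order <- function(k) {
  if (length(k) != 1L || !k %in% c(1, 2, 3)) {
    stop("encoding order k must be 1, 2 or 3", call. = FALSE)
  }
  as.integer(k)
}

PAIR_LEN <- 23L

check_pair_seqs <- function(guide_seq, target_seq) {
  guide_seq <- normalize_sequence(guide_seq)
  target_seq <- normalize_sequence(target_seq)
  if (any(grepl("-", guide_seq, fixed = TRUE)) ||
      any(grepl("-", target_seq, fixed = TRUE))) {
    stop("gapped (indel) sequences cannot be tokenized; drop them with filter_pairs()",
         call. = FALSE)
  }
  if (any(nchar(guide_seq) != PAIR_LEN) || any(nchar(target_seq) != PAIR_LEN)) {
    stop("guide and target sequences must be exactly ", PAIR_LEN, " bp",
         call. = FALSE)
  }
  list(guide = guide_seq, target = target_seq)
}

#' Stack-encode one aligned guide/target pair
#'
#' Slides a `k`-base window along the 23-bp duplex with a step of one base,
#' 5' to 3'. Window `i` yields the token `guide[i..i+k-1] + target[i..i+k-1]`,
#' giving `23 - k + 1` tokens per pair (22 doublets at `k = 2`).
#'
#' @param guide_seq,target_seq Single 23-character sequences.
#' @param k Encoding order.
#' @param vocab Optional prebuilt vocabulary (must have matching `k`).
#' @return Integer vector of 0-based token indices, length `23 - k + 1`.
#' @examples
#' tokenize_pair(strrep("A", 23), strrep("A", 23))
#' @export
tokenize_pair <- function(guide_seq, target_seq, k = 2, vocab = NULL) {
  k <- check_order(k)
  seqs <- check_pair_seqs(guide_seq, target_seq)
  if (!is.null(vocab) && vocab$k != k) {
    stop("vocabulary order (", vocab$k, ") does not match k = ", k, call. = FALSE)
  }
  tokenize_base4(seqs$guide, seqs$target, k)[[1L]]
}

# integer encoding without string table: token value of window i is the
# base-4 number of the concatenated 2k letters, guide half most significant
tokenize_base4 <- function(guides, targets, k) {
  n_tok <- PAIR_LEN - k + 1L
  g_dig <- base4_digits(guides)   # n x 23
  t_dig <- base4_digits(targets)
  out <- vector("list", length(guides))
  g_val <- matrix(0L, nrow = length(guides), ncol = n_tok)
  t_val <- g_val
  for (j in seq_len(k)) {
    cols <- j:(j + n_tok - 1L)
    g_val <- g_val * 4L + g_dig[, cols, drop = FALSE]
    t_val <- t_val * 4L + t_dig[, cols, drop = FALSE]
  }
  tok <- g_val * 4L^k + t_val
  for (i in seq_along(out)) out[[i]] <- tok[i, ]
  out
}

base4_digits <- function(seqs) {
  m <- matrix(
    match(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE), BASES) - 1L,
    nrow = length(seqs), byrow = TRUE
  )
  m
}

#' Stack-encode a table of guide/target pairs
#'
#' Takes a pair table (columns `guide_id`, `guide_seq`, `target_seq` and
#' optionally `label`) and adds a `tokens` list-column of 0-based integer
#' token indices, one vector of `23 - k + 1` entries per row.
#'
#' @param pairs Data frame of aligned pairs.
#' @param k Encoding order (default 2, doublets).
#' @return A tibble: the input columns plus `tokens`.
#' @examples
#' pairs <- tibble::tibble(
#'   guide_id = "g1", guide_seq = strrep("A", 23),
#'   target_seq = strrep("A", 23), label = 0L
#' )
#' encode_pairs(pairs)$tokens[[1]]
#' @export
encode_pairs <- function(pairs, k = 2) {
  k <- check_order(k)
  pairs <- as_pair_tbl(pairs)
  seqs <- check_pair_seqs(pairs$guide_seq, pairs$target_seq)
  out <- tibble::as_tibble(pairs)
  out$guide_seq <- seqs$guide
  out$target_seq <- seqs$target
  out$tokens <- if (nrow(out) == 0L) list() else
    tokenize_base4(seqs$guide, seqs$target, k)
  attr(out, "k") <- k
  out
}

as_pair_tbl <- function(pairs) {
  req <- c("guide_id", "guide_seq", "target_seq")
  missing_cols <- setdiff(req, names(pairs))
  if (length(missing_cols)) {
    stop("pair table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(pairs)
}

#' Positions at which guide and target disagree
#'
#' Under the same-strand alignment convention a match is the identical letter,
#' so mismatches are simply positions where the two 23-mers differ.
#'
#' @param guide_seq,target_seq Character vectors of equal length.
#' @return A list of sorted 1-based integer position vectors, one per pair.
#' @examples
#' mismatch_positions("GGAAAAAAAAAAAAAAAAAAAGG", "TCAAAAAAAAAAAAAAAAAAAGG")
#' @export
mismatch_positions <- function(guide_seq, target_seq) {
  seqs <- check_pair_seqs(guide_seq, target_seq)
  g <- base4_digits(seqs$guide)
  t <- base4_digits(seqs$target)
  lapply(seq_len(nrow(g)), function(i) which(g[i, ] != t[i, ]))
}

#' Count mismatches per pair
#'
#' @inheritParams mismatch_positions
#' @return Integer vector of mismatch counts in `[0, 23]`.
#' @export
mismatch_count <- function(guide_seq, target_seq) {
  lengths(mismatch_positions(guide_seq, target_seq))
}

#' Apply the dataset filters to a raw pair table
#'
#' Reproduces the standard cleanup for substitution-only off-target modelling:
#' rows whose alignment contains a gap character or whose sequences are not
#' 23 bp are dropped (indel rows), rows containing ambiguity codes such as `N`
#' are dropped, and the table is deduplicated on the `(guide_seq, target_seq)`
#' sequence key regardless of genomic position. Duplicate groups whose labels
#' conflict resolve to label 1 (positive evidence wins) and are reported.
#'
#' @param pairs Raw pair table with columns `guide_id`, `guide_seq`,
#'   `target_seq`, `label`.
#' @return A tibble of kept pairs with a `filter_report` attribute; retrieve it
#'   with [filter_report()]. The report counts rows dropped as `indel`,
#'   `ambiguous` and `duplicate`, plus `label_conflicts` resolved.
#' @examples
#' raw <- tibble::tibble(
#'   guide_id = c("g", "g"), guide_seq = rep(strrep("A", 23), 2),
#'   target_seq = rep(strrep("A", 23), 2), label = c(0L, 1L)
#' )
#' kept <- filter_pairs(raw)
#' filter_report(kept)
#' @export
filter_pairs <- function(pairs) {
  pairs <- as_pair_tbl(pairs)
  if (!"label" %in% names(pairs)) pairs$label <- NA_integer_
  n0 <- nrow(pairs)
  if (n0 == 0L) {
    return(with_report(pairs, indel = 0L, ambiguous = 0L, duplicate = 0L,
                       label_conflicts = 0L))
  }

  gs <- chartr("U", "T", toupper(pairs$guide_seq))
  ts <- chartr("U", "T", toupper(pairs$target_seq))
  is_indel <- grepl("-", gs, fixed = TRUE) | grepl("-", ts, fixed = TRUE) |
    nchar(gs) != PAIR_LEN | nchar(ts) != PAIR_LEN
  is_ambig <- !is_indel & (grepl("[^ACGT]", gs) | grepl("[^ACGT]", ts))
  keep <- !is_indel & !is_ambig
  pairs <- pairs[keep, , drop = FALSE]
  pairs$guide_seq <- gs[keep]
  pairs$target_seq <- ts[keep]

  key <- paste(pairs$guide_seq, pairs$target_seq, sep = "|")
  first <- !duplicated(key)
  grp_max <- tapply(pairs$label, key, function(l) {
    if (all(is.na(l))) NA_integer_ else max(l, na.rm = TRUE)
  })
  conflicts <- sum(tapply(pairs$label, key, function(l) {
    l <- l[!is.na(l)]
    length(unique(l)) > 1L
  }))
  kept <- pairs[first, , drop = FALSE]
  kept$label <- as.integer(grp_max[key[first]])
  if (conflicts > 0L) {
    message(conflicts, " duplicate sequence group(s) had conflicting labels; resolved to 1")
  }
  with_report(kept,
    indel = sum(is_indel), ambiguous = sum(is_ambig),
    duplicate = sum(!first), label_conflicts = as.integer(conflicts)
  )
}

with_report <- function(kept, ...) {
  counts <- c(...)
  attr(kept, "filter_report") <- tibble::tibble(
    stage = names(counts), dropped = as.integer(counts)
  )
  kept
}

#' Retrieve the filter report attached by [filter_pairs()]
#'
#' @param pairs A tibble returned by [filter_pairs()].
#' @return A tibble with columns `stage` and `dropped`.
#' @export
filter_report <- function(pairs) {
  rep <- attr(pairs, "filter_report")
  if (is.null(rep)) stop("no filter report attached; run filter_pairs() first",
                         call. = FALSE)
  rep
}
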