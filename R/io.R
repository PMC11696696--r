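#' Read a guide/target pair table
#'
#' Comma-separated UTF-8 text with header
#' `guide_id,guide_seq,target_seq,label`. Extra columns are kept but trigger a
#' warning; `label` must be 0/1 when present.
#'
#' @param path File path.
#' @return A tibble of pairs.
#' @export
read_pair_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("guide_id", "guide_seq", "target_seq")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("pair table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), c(req, "label", "tokens", "n_mismatch"))
  if (length(extra)) {
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  if ("label" %in% names(df)) {
    if (!all(df$label %in% c(0L, 1L))) {
      stop("label column must be 0/1", call. = FALSE)
    }
    df$label <- as.integer(df$label)
  }
  if ("tokens" %in% names(df) && is.character(df$tokens)) {
    df$tokens <- lapply(strsplit(df$tokens, " ", fixed = TRUE), as.integer)
  }
  df$guide_id <- as.character(df$guide_id)
  tibble::as_tibble(df)
}

#' Write a guide/target pair table
#'
#' Inverse of [read_pair_table()]. A `tokens` list-column is flattened to
#' space-separated integers.
#'
#' @param pairs Pair tibble.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  out <- tibble::as_tibble(pairs)
  if ("tokens" %in% names(out) && is.list(out$tokens)) {
    out$tokens <- vapply(out$tokens, paste, character(1), collapse = " ")
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
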