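# shared fixture builders: everything is generated in code at test time

base_seq <- function(letter = "A") strrep(letter, 23)

# plant substitutions at given 1-based positions of a 23-mer
mutate_at <- function(seq, positions, to) {
  s <- strsplit(seq, "")[[1]]
  s[positions] <- to
  paste(s, collapse = "")
}

toy_pair_tbl <- function(guide_id, guide_seq, target_seq, label = 0L) {
  tibble::tibble(guide_id = guide_id, guide_seq = guide_seq,
                 target_seq = target_seq, label = as.integer(label))
}

# small model configurations used across training tests
tiny_config <- function(variant = "contextual", seed = 1, ...) {
  model_config(
    variant = variant, k = 2, embed_dim = 8, n_layers = 1, n_heads = 2,
    lstm_units = 4, dense_units = c(8, 4), dropout = 0,
    learning_rate = 2e-3, batch_size = 16, epochs = 3, seed = seed, ...
  )
}

reduced_config <- function(variant = "contextual", seed = 11, epochs = 6) {
  model_config(
    variant = variant, k = 2, embed_dim = 16, n_layers = 2, n_heads = 2,
    lstm_units = 16, dense_units = c(32, 16), dropout = 0.1,
    learning_rate = 1e-3, batch_size = 64, epochs = epochs, seed = seed
  )
}

# labels that depend deterministically on the first token (a purine-starting
# guide reads positive): a linearly separable toy set
separable_set <- function(n = 120, seed = 5) {
  set.seed(seed)
  guides <- replicate(n, paste(sample(c("A", "C", "G", "T"), 23, replace = TRUE),
                               collapse = ""))
  labels <- as.integer(substr(guides, 1, 1) %in% c("A", "G"))
  encode_pairs(toy_pair_tbl(sprintf("g%03d", seq_len(n)), guides, guides,
                            labels))
}

# independent brute-force ROC oracle: enumerate positive-negative pairs
roc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# independent average-precision oracle: walk the sorted order once per
# distinct threshold and accumulate precision * delta-recall
ap_oracle <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_rec <- 0
  ap <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / n_pos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}
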