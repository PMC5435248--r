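# Independent brute-force oracles used across tests.

# One synchronous update step, written as plain nested loops over nodes and
# edges with no shared code with advance_state() (noise-free path only).
brute_force_step <- function(activities, net, exponent = 0.15,
                             decay_rates = NULL, apply_decay = FALSE,
                             pinned = NULL) {
  out <- activities
  for (node in net$nodes) {
    x <- 0
    for (k in seq_len(nrow(net$edges))) {
      if (net$edges$target[k] == node) {
        x <- x + net$edges$weight[k] * activities[[net$edges$source[k]]] / 50
      }
    }
    delta <- 100 / (1 + exp(-exponent * x)) - 50
    if (apply_decay) {
      delta <- delta + 100 / (1 + exp(exponent * decay_rates[[node]])) - 50
    }
    v <- activities[[node]] + delta
    out[[node]] <- min(max(v, 0), 100)
  }
  if (!is.null(pinned)) for (nm in names(pinned)) out[[nm]] <- pinned[[nm]]
  out
}

# Exhaustive set-arithmetic confusion counts over unique directed edges
# (no 'binds' handling; used with sign-carrying truth sets only).
brute_force_confusion <- function(truth_pairs, pred_pairs) {
  truth_pairs <- unique(truth_pairs)
  pred_pairs <- unique(pred_pairs)
  tp <- sum(pred_pairs %in% truth_pairs)
  list(
    tp = tp,
    fp = length(pred_pairs) - tp,
    fn = sum(!truth_pairs %in% pred_pairs)
  )
}

random_edge_table <- function(n_nodes, n_edges, terms = NULL) {
  nodes <- LETTERS[seq_len(n_nodes)]
  if (is.null(terms)) terms <- interaction_vocabulary()$term
  data.frame(
    source = sample(nodes, n_edges, replace = TRUE),
    interaction = sample(terms, n_edges, replace = TRUE),
    target = sample(nodes, n_edges, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
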