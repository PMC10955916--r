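# Independent oracles and small fixture builders used across tests.

# Brute-force evaluation of the two pruning rules, term by term.
oracle_filter_keep <- function(weights, tau_total = 0.5, tau_ratio = 0.1) {
  keep <- logical(ncol(weights))
  for (j in seq_len(ncol(weights))) {
    total <- sum(weights[, j])
    mx <- max(weights[, j])
    keep[j] <- (total >= tau_total) && (total > 0) && (mx / total >= tau_ratio)
  }
  keep
}

# Naive O(n^3) agglomerative complete-linkage clustering. Ties broken by
# the smallest member indices of the candidate pair.
oracle_complete_linkage <- function(d, k) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- NULL
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        cd <- max(d[clusters[[i]], clusters[[j]]])
        if (cd < best_d) {
          best_d <- cd
          best <- c(i, j)
        }
      }
    }
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
  }
  part <- integer(n)
  for (i in seq_along(clusters)) part[clusters[[i]]] <- i
  part
}

# Two partitions are the same up to relabeling iff they induce the same
# co-membership relation.
same_partition <- function(a, b) {
  identical(outer(a, a, `==`), outer(b, b, `==`))
}

# Plug-in mutual information (bits) between two binary vectors, via the
# entropy identity MI = H(X) + H(Y) - H(X, Y).
oracle_mi <- function(x, y) {
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  n <- length(x)
  ent(table(x) / n) + ent(table(y) / n) - ent(table(x, y) / n)
}

# A small tokenized corpus from a list of token vectors.
toy_corpus <- function(tokens, label = NULL) {
  corpus(id = sprintf("d%d", seq_along(tokens)),
         text = vapply(tokens, paste, character(1), collapse = " "),
         tokens = tokens, label = label)
}

# A tfidf-shaped object from an explicit weight matrix, for rule-level
# unit tests that specify weights directly.
tfidf_from_weights <- function(w) {
  colnames(w) <- colnames(w) %||% sprintf("t%02d", seq_len(ncol(w)))
  rownames(w) <- rownames(w) %||% sprintf("d%02d", seq_len(nrow(w)))
  structure(
    list(weights = w, vocabulary = colnames(w), doc_ids = rownames(w),
         idf = rep(1, ncol(w)), df = colSums(w > 0),
         total_weight = colSums(w), max_weight = apply(w, 2, max)),
    class = "tfidf")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A quick small-scale synthetic corpus for pipeline-level tests.
small_synth <- function(seed, n_per_group = 15, doc_length = 100,
                        separation = 1.0) {
  suppressWarnings(generate_corpus(generator_config(
    n_per_group = n_per_group, doc_length = doc_length,
    separation = separation, seed = seed)))
}

matched_accuracy <- function(assignment, labels) {
  compute_metrics(match_clusters_to_labels(assignment, labels))$accuracy
}
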