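# Two-phase topic ensemble.
#
# Phase 1 removes the random effect inherent in NMF topic modelling by
# refitting under many seeds: with the defaults, 70 runs of 10 topics
# each contribute 700 pooled ensemble members. Phase 2 is the consensus
# function: complete-linkage hierarchical clustering of the pooled,
# L2-normalized topic vectors under cosine distance, cut at two clusters.
# Documents are then scored against the two topic clusters through their
# run-level loadings.

#' Generate the NMF topic ensemble
#'
#' Runs [fit_nmf()] with seeds `seed_base, ..., seed_base + n_runs - 1`.
#' Each H row (topic) is L2-normalized into the pool. To make loadings
#' comparable across runs despite NMF's scale indeterminacy, each run's W
#' columns are first multiplied by the norm of the matching H row (so the
#' product W H is unchanged), then each document's loading row is
#' L1-normalized within the run, so every run contributes one unit of
#' loading mass per document.
#'
#' @param tfidf a `"tfidf"` object (typically after [filter_terms()]).
#' @param k topics per run (default 10).
#' @param n_runs number of seeded runs (default 70).
#' @param seed_base first seed (default 0).
#' @param max_iter,tol passed to [fit_nmf()].
#' @return An object of class `"topic_pool"`: `topics`
#'   ((n_runs * k) x terms matrix of unit rows), `loadings` (list of
#'   per-run documents x k matrices), `provenance` (run, seed, topic),
#'   `vocabulary`, `doc_ids`, `k`, `n_runs`.
#' @export
generate_ensemble <- function(tfidf, k = 10L, n_runs = 70L, seed_base = 0L,
                              max_iter = 200L, tol = 1e-4) {
  stopifnot(inherits(tfidf, "tfidf"), n_runs >= 1L)
  seeds <- as.integer(seed_base) + seq_len(n_runs) - 1L
  topics <- matrix(0, n_runs * k, ncol(tfidf$weights),
                   dimnames = list(NULL, tfidf$vocabulary))
  loadings <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run <- tryCatch(
      fit_nmf(tfidf, k = k, seed = seeds[r], max_iter = max_iter, tol = tol),
      error = function(e) stop("ensemble run with seed ", seeds[r],
                               " failed: ", conditionMessage(e)))
    hn <- sqrt(rowSums(run$H^2))
    hn[hn == 0] <- 1
    topics[(r - 1L) * k + seq_len(k), ] <- run$H / hn
    w <- sweep(run$W, 2L, hn, `*`)
    rs <- rowSums(w)
    rs[rs == 0] <- 1
    loadings[[r]] <- w / rs
  }
  structure(
    list(topics = topics, loadings = loadings,
         provenance = data.frame(run = rep(seq_len(n_runs), each = k),
                                 seed = rep(seeds, each = k),
                                 topic = rep(seq_len(k), n_runs)),
         vocabulary = tfidf$vocabulary, doc_ids = tfidf$doc_ids,
         k = as.integer(k), n_runs = as.integer(n_runs)),
    class = "topic_pool"
  )
}

#' @export
print.topic_pool <- function(x, ...) {
  cat(sprintf("<topic_pool: %d topics (%d runs x %d), %d terms>\n",
              nrow(x$topics), x$n_runs, x$k, ncol(x$topics)))
  invisible(x)
}

#' Consensus clustering of pooled topics
#'
#' Agglomerative hierarchical clustering of the pooled topic vectors with
#' complete linkage under cosine distance, cut at `n_clusters`. Cluster
#' ids are 1-based, numbered by first appearance in pool order.
#'
#' @param pool a [generate_ensemble()] result.
#' @param n_clusters number of consensus clusters (default 2).
#' @return An object of class `"topic_partition"`: `topic_cluster`
#'   (integer per pooled topic), `n_clusters`, `linkage` (the `hclust`
#'   merge record).
#' @export
consensus_cluster <- function(pool, n_clusters = 2L) {
  stopifnot(inherits(pool, "topic_pool"))
  n <- nrow(pool$topics)
  if (n_clusters < 2L || n_clusters > n)
    stop("n_clusters must be between 2 and the pool size")
  d <- cosine_distance_rows(pool$topics)
  if (max(d) < 1e-12)
    stop("degenerate pool: all topics identical; cannot form ",
         n_clusters, " clusters")
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  cl <- stats::cutree(hc, k = n_clusters)
  structure(list(topic_cluster = as.integer(cl),
                 n_clusters = as.integer(n_clusters), linkage = hc),
            class = "topic_partition")
}

#' Assign documents to consensus topic clusters
#'
#' Each document's score for a cluster is the sum, over all pooled topics
#' in that cluster, of the document's run-normalized loading on the
#' topic. Since each run contributes one unit of loading mass per
#' document, score rows sum to the number of runs. The assignment is the
#' argmax, with the lower cluster id on exact ties.
#'
#' @param pool a [generate_ensemble()] result.
#' @param partition a [consensus_cluster()] result (or an integer vector
#'   of per-topic cluster ids).
#' @return An object of class `"consensus_result"`: `topic_cluster`,
#'   `doc_scores` (documents x clusters), `assignment` (named integer),
#'   `linkage`, `n_runs`.
#' @export
assign_documents <- function(pool, partition) {
  stopifnot(inherits(pool, "topic_pool"))
  linkage <- NULL
  if (inherits(partition, "topic_partition")) {
    linkage <- partition$linkage
    cl <- partition$topic_cluster
  } else cl <- as.integer(partition)
  if (length(cl) != nrow(pool$topics))
    stop("partition must cover every pooled topic")
  ncl <- max(cl)
  scores <- matrix(0, length(pool$doc_ids), ncl,
                   dimnames = list(pool$doc_ids, NULL))
  k <- pool$k
  for (r in seq_len(pool$n_runs)) {
    run_cl <- cl[(r - 1L) * k + seq_len(k)]
    for (c_ in seq_len(ncl)) {
      j <- run_cl == c_
      if (any(j))
        scores[, c_] <- scores[, c_] +
          rowSums(pool$loadings[[r]][, j, drop = FALSE])
    }
  }
  assignment <- max.col(scores, ties.method = "first")
  names(assignment) <- pool$doc_ids
  structure(
    list(topic_cluster = cl, doc_scores = scores,
         assignment = assignment, linkage = linkage,
         n_runs = pool$n_runs),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  sizes <- table(x$assignment)
  cat(sprintf("<consensus_result: %d documents in %d clusters (%s)>\n",
              length(x$assignment), ncol(x$doc_scores),
              paste(sprintf("cluster %s: %d", names(sizes), sizes),
                    collapse = ", ")))
  invisible(x)
}

#' Top keywords of a topic vector
#'
#' @param topic numeric vector of term weights (an H row or pooled topic).
#' @param vocabulary character vector naming the weights.
#' @param n how many keywords (default 10).
#' @return Character vector of the `n` heaviest terms, descending weight,
#'   ties broken in byte order.
#' @export
top_keywords <- function(topic, vocabulary, n = 10L) {
  stopifnot(length(topic) == length(vocabulary), n <= length(vocabulary))
  key <- match(vocabulary, sort_c(vocabulary))
  vocabulary[order(-topic, key)][seq_len(n)]
}

# Per-cluster keyword tables from a representative run (the first run of
# the pool): for each of that run's k topics, the top-n keywords, grouped
# by the consensus cluster the topic belongs to.
keyword_tables <- function(pool, topic_cluster, n = 10L, run = 1L) {
  stopifnot(inherits(pool, "topic_pool"))
  k <- pool$k
  idx <- (run - 1L) * k + seq_len(k)
  out <- list()
  for (c_ in sort(unique(topic_cluster))) {
    rows <- list()
    for (j in seq_len(k)) {
      if (topic_cluster[idx[j]] != c_) next
      tv <- pool$topics[idx[j], ]
      kw <- top_keywords(tv, pool$vocabulary, n = n)
      rows[[length(rows) + 1L]] <- data.frame(
        topic = j, rank = seq_len(n), term = kw,
        weight = tv[match(kw, pool$vocabulary)],
        stringsAsFactors = FALSE, row.names = NULL)
    }
    out[[paste0("cluster", c_)]] <-
      if (length(rows)) do.call(rbind, rows)
      else data.frame(topic = integer(), rank = integer(),
                      term = character(), weight = numeric())
  }
  out
}
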