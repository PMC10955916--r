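#' Fit the full topic-ensemble consensus model
#'
#' The main entry point: takes a corpus of transcripts (or a prepared
#' TF-IDF matrix), builds TF-IDF features, prunes common and rare words
#' with the two threshold rules, generates the seeded NMF topic ensemble,
#' consensus-clusters the pooled topics with complete linkage, and
#' assigns every document to a consensus cluster. The whole fit is
#' deterministic given the corpus and `seed_base`.
#'
#' @param x a [corpus()] (tokenized, or raw text — then `tokenizer` is
#'   applied), or a `"tfidf"` object (used as-is, no pruning).
#' @param k topics per NMF run (default 10).
#' @param n_runs number of seeded NMF runs (default 70).
#' @param n_clusters number of consensus clusters (default 2).
#' @param seed_base first NMF seed (default 0).
#' @param tau_total,tau_ratio pruning thresholds, see [filter_terms()].
#' @param max_iter,tol NMF stopping controls, see [fit_nmf()].
#' @param tokenizer a [tokenizer_spec()] used when `x` has no tokens yet.
#' @return An object of class `"topic_consensus"` with components
#'   `tfidf` (pruned), `pool`, `partition`, `consensus`, `assignment`,
#'   `labels` (if the corpus carried them), `config`, `call`.
#' @examples
#' syn <- generate_corpus(generator_config(n_per_group = 15,
#'                                         doc_length = 80, seed = 1))
#' fit <- topic_consensus(syn$corpus, n_runs = 5)
#' fit
#' table(fit$assignment, syn$corpus$label)
#' @export
topic_consensus <- function(x, k = 10L, n_runs = 70L, n_clusters = 2L,
                            seed_base = 0L, tau_total = 0.5, tau_ratio = 0.1,
                            max_iter = 200L, tol = 1e-4,
                            tokenizer = tokenizer_spec()) {
  cl <- match.call()
  labels <- NULL
  if (inherits(x, "corpus")) {
    labels <- x$label
    if (is.null(x$tokens)) x <- preprocess(x, tokenizer)
    tf <- filter_terms(compute_tfidf(term_document_matrix(x)),
                       tau_total = tau_total, tau_ratio = tau_ratio)
  } else if (inherits(x, "tfidf")) {
    tf <- x
  } else stop("`x` must be a corpus or a tfidf object")
  pool <- generate_ensemble(tf, k = k, n_runs = n_runs,
                            seed_base = seed_base, max_iter = max_iter,
                            tol = tol)
  part <- consensus_cluster(pool, n_clusters = n_clusters)
  cons <- assign_documents(pool, part)
  structure(
    list(tfidf = tf, pool = pool, partition = part, consensus = cons,
         assignment = cons$assignment, labels = labels,
         config = list(k = k, n_runs = n_runs, n_clusters = n_clusters,
                       seed_base = seed_base, tau_total = tau_total,
                       tau_ratio = tau_ratio, max_iter = max_iter,
                       tol = tol),
         call = cl),
    class = "topic_consensus"
  )
}

#' @export
print.topic_consensus <- function(x, ...) {
  cat("Topic-ensemble consensus clustering\n\n")
  cat(sprintf("  documents:        %d\n", length(x$assignment)))
  cat(sprintf("  retained terms:   %d (%d pruned)\n",
              ncol(x$tfidf$weights),
              if (is.null(x$tfidf$removed)) 0L else nrow(x$tfidf$removed)))
  cat(sprintf("  ensemble members: %d (%d runs x %d topics)\n",
              nrow(x$pool$topics), x$pool$n_runs, x$pool$k))
  sizes <- table(x$assignment)
  cat(sprintf("  clusters:         %s\n",
              paste(sprintf("%s (n = %d)", names(sizes), sizes),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.topic_consensus <- function(object, n_keywords = 10L, ...) {
  kw <- keyword_tables(object$pool, object$consensus$topic_cluster,
                       n = n_keywords)
  metrics <- NULL
  if (!is.null(object$labels))
    metrics <- compute_metrics(
      match_clusters_to_labels(object$assignment, object$labels))
  structure(list(fit = object, keywords = kw, metrics = metrics),
            class = "summary.topic_consensus")
}

#' @export
print.summary.topic_consensus <- function(x, ...) {
  print(x$fit)
  topic_cl <- x$fit$consensus$topic_cluster
  cat(sprintf("\n  topic-cluster sizes: %s\n",
              paste(sprintf("%d", as.integer(table(topic_cl))),
                    collapse = " / ")))
  for (nm in names(x$keywords)) {
    tab <- x$keywords[[nm]]
    if (!nrow(tab)) next
    cat(sprintf("\n  %s keywords (representative run):\n", nm))
    for (tp in unique(tab$topic))
      cat(sprintf("    topic %2d: %s\n", tp,
                  paste(tab$term[tab$topic == tp], collapse = " ")))
  }
  if (!is.null(x$metrics)) {
    cat("\n  evaluation against labels:\n")
    print(x$metrics, indent = "    ")
  }
  invisible(x)
}

#' Plot a fitted consensus model as an MDS scatter
#'
#' Embeds the document consensus profiles with classical MDS and draws
#' the scatter colored by cluster; if labels are present, plotting
#' symbols distinguish them. An arrow between cluster centroids marks the
#' discriminative direction.
#'
#' @param x a `"topic_consensus"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.topic_consensus <- function(x, ...) {
  emb <- mds_embed(document_distance_matrix(x$consensus))
  asg <- x$assignment
  pch <- if (is.null(x$labels)) 19L else ifelse(x$labels == 0L, 24L, 25L)
  graphics::plot(emb$points, col = asg + 1L, pch = pch,
                 xlab = "MDS 1", ylab = "MDS 2",
                 main = "Consensus clusters (classical MDS)", ...)
  cent <- apply(emb$points, 2L, function(v) tapply(v, asg, mean))
  if (nrow(cent) == 2L)
    graphics::arrows(cent[1, 1], cent[1, 2], cent[2, 1], cent[2, 2],
                     col = "red", lwd = 2, length = 0.1)
  legend_lab <- sprintf("cluster %s", sort(unique(asg)))
  graphics::legend("topleft", legend = legend_lab,
                   col = sort(unique(asg)) + 1L, pch = 19L, bty = "n")
  invisible(emb)
}
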