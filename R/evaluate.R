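# Evaluation against external binary stress labels.
#
# Cluster ids carry no semantics, so clusters are matched to labels by
# the accuracy-maximizing permutation before any rate is computed.
# Naming convention (deliberately following the source study's tables,
# and opposite to the usual clinical one): "positive" means LOW stress
# and "negative" means HIGH stress. `tpr_low` is the fraction of
# low-stress documents recovered, `tnr_high` the fraction of high-stress
# documents recovered.

#' Match two clusters to binary labels
#'
#' Evaluates both cluster-to-label permutations and keeps the one with
#' the higher accuracy (identity on ties). The confusion matrix is
#' emitted under that mapping: rows are clusters ordered so that row 1 is
#' the cluster mapped to label 0 (low) and row 2 the cluster mapped to
#' label 1 (high); columns are labels (low, high).
#'
#' @param assignment integer cluster ids (exactly 2 distinct values), or
#'   a fitted [topic_consensus()] object.
#' @param labels binary 0/1 vector, one per document (defaults to the
#'   labels stored in the fit when `assignment` is a fit).
#' @return An object of class `"cluster_matching"`: `confusion` (2x2
#'   integer matrix), `mapping` (named vector cluster -> label).
#' @export
match_clusters_to_labels <- function(assignment, labels = NULL) {
  if (inherits(assignment, "topic_consensus")) {
    if (is.null(labels)) labels <- assignment$labels
    assignment <- assignment$assignment
  }
  if (is.null(labels))
    stop("labels are required")
  labels <- as.integer(labels)
  assignment <- as.integer(assignment)
  if (length(labels) != length(assignment))
    stop("assignment and labels must have the same length")
  if (anyNA(labels) || anyNA(assignment))
    stop("labels missing for some assigned documents")
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  cl_ids <- sort(unique(assignment))
  if (length(cl_ids) != 2L)
    stop("exactly 2 clusters must be present, got ", length(cl_ids))
  cm <- matrix(0L, 2, 2,
               dimnames = list(cluster = as.character(cl_ids),
                               label = c("low", "high")))
  for (i in 1:2) for (j in 1:2)
    cm[i, j] <- sum(assignment == cl_ids[i] & labels == (j - 1L))
  acc_id <- cm[1, 1] + cm[2, 2]
  acc_sw <- cm[2, 1] + cm[1, 2]
  if (acc_sw > acc_id) {
    cm <- cm[2:1, , drop = FALSE]
    mapping <- stats::setNames(c(1L, 0L), as.character(cl_ids))
  } else {
    mapping <- stats::setNames(c(0L, 1L), as.character(cl_ids))
  }
  structure(list(confusion = cm, mapping = mapping),
            class = "cluster_matching")
}

#' @export
print.cluster_matching <- function(x, ...) {
  cat("cluster-to-label matching (rows: clusters; cols: labels)\n")
  print(x$confusion)
  invisible(x)
}

#' Accuracy and class-wise rates from a matched confusion matrix
#'
#' For a matched 2x2 matrix with rows = clusters (mapped to low, high)
#' and columns = labels (low, high): accuracy is the diagonal sum over
#' the total, the true-positive (low-stress) rate is the recovered
#' fraction of the low-stress column, and the true-negative (high-stress)
#' rate the recovered fraction of the high-stress column. All values are
#' percentages; serialized output rounds to 2 decimals.
#'
#' @param cm a `"cluster_matching"`, or a 2x2 count matrix already under
#'   the desired mapping.
#' @return An object of class `"metrics_report"`: `accuracy`, `tpr_low`,
#'   `tnr_high` (percent, full precision), `confusion`, `mapping`, `n`.
#' @export
compute_metrics <- function(cm) {
  mapping <- NULL
  if (inherits(cm, "cluster_matching")) {
    mapping <- cm$mapping
    cm <- cm$confusion
  }
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(2L, 2L)) || any(cm < 0))
    stop("`cm` must be a nonnegative 2x2 matrix")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  if (sum(cm[, 1]) == 0)
    stop("no low-stress documents: true-positive rate undefined")
  if (sum(cm[, 2]) == 0)
    stop("no high-stress documents: true-negative rate undefined")
  structure(
    list(accuracy = 100 * (cm[1, 1] + cm[2, 2]) / total,
         tpr_low = 100 * cm[1, 1] / sum(cm[, 1]),
         tnr_high = 100 * cm[2, 2] / sum(cm[, 2]),
         confusion = cm, mapping = mapping, n = total),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, indent = "", ...) {
  cat(sprintf("%saccuracy:                      %.2f%%\n", indent, x$accuracy))
  cat(sprintf("%strue-positive (low-stress):    %.2f%%\n", indent, x$tpr_low))
  cat(sprintf("%strue-negative (high-stress):   %.2f%%\n", indent, x$tnr_high))
  invisible(x)
}

#' Accuracy as a function of the retained word fraction
#'
#' Ranks the pruned vocabulary by mutual information with the labels,
#' then, for each fraction, keeps only the top-ranked words and reruns
#' the complete pipeline (ensemble, consensus, assignment, matching) with
#' the same `seed_base`, recording the matched accuracy. A fraction
#' leaving fewer documents with any nonzero weight than `n_clusters` is
#' recorded as a missing point rather than aborting.
#'
#' @param x a labeled, tokenized [corpus()].
#' @param fractions increasing values in (0, 1] (default 0.1, ..., 1.0).
#' @param k,n_runs,n_clusters,seed_base,tau_total,tau_ratio,max_iter,tol
#'   pipeline settings, as in [topic_consensus()].
#' @return An object of class `"fraction_curve"`: a data frame with
#'   columns `fraction`, `n_terms`, `accuracy` (percent; `NA` for missing
#'   points).
#' @export
word_fraction_experiment <- function(x, fractions = seq(0.1, 1, by = 0.1),
                                     k = 10L, n_runs = 70L, n_clusters = 2L,
                                     seed_base = 0L, tau_total = 0.5,
                                     tau_ratio = 0.1, max_iter = 200L,
                                     tol = 1e-4) {
  stopifnot(inherits(x, "corpus"))
  if (is.null(x$label)) stop("corpus must be labeled")
  if (is.null(x$tokens)) stop("corpus must be tokenized")
  if (any(diff(fractions) <= 0) || any(fractions <= 0 | fractions > 1))
    stop("fractions must be strictly increasing values in (0, 1]")
  tf <- filter_terms(compute_tfidf(term_document_matrix(x)),
                     tau_total = tau_total, tau_ratio = tau_ratio)
  ranking <- rank_terms_by_mutual_information(tf, x$label)
  acc <- n_terms <- numeric(length(fractions))
  for (i in seq_along(fractions)) {
    terms <- select_top_fraction(ranking, fractions[i])
    tfi <- restrict_terms(tf, terms)
    n_terms[i] <- ncol(tfi$weights)
    nonzero <- sum(rowSums(tfi$weights) > 0)
    if (nonzero < n_clusters || ncol(tfi$weights) < k) {
      acc[i] <- NA_real_
      next
    }
    pool <- generate_ensemble(tfi, k = k, n_runs = n_runs,
                              seed_base = seed_base, max_iter = max_iter,
                              tol = tol)
    cons <- assign_documents(pool, consensus_cluster(pool, n_clusters))
    m <- compute_metrics(match_clusters_to_labels(cons$assignment, x$label))
    acc[i] <- m$accuracy
  }
  structure(
    data.frame(fraction = fractions, n_terms = n_terms, accuracy = acc),
    class = c("fraction_curve", "data.frame")
  )
}
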