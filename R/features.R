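#' Term-document count matrix
#'
#' Counts token occurrences per document over the vocabulary (the union
#' of all tokens, in byte order so the column layout is reproducible).
#'
#' @param x a tokenized [corpus()].
#' @return An object of class `"term_document_matrix"` with components
#'   `counts` (documents x terms integer matrix), `vocabulary`, `doc_ids`.
#' @export
term_document_matrix <- function(x) {
  stopifnot(inherits(x, "corpus"))
  if (is.null(x$tokens))
    stop("corpus has no tokens; run preprocess() first")
  all_tok <- unlist(x$tokens, use.names = FALSE)
  if (!length(all_tok))
    stop("corpus contains no tokens at all")
  vocab <- sort_c(unique(all_tok))
  di <- rep.int(seq_along(x$tokens), lengths(x$tokens))
  tj <- match(all_tok, vocab)
  counts <- matrix(0L, nrow = length(x$id), ncol = length(vocab),
                   dimnames = list(x$id, vocab))
  tab <- table(di, tj)
  counts[cbind(as.integer(rownames(tab))[row(tab)],
               as.integer(colnames(tab))[col(tab)])] <- as.integer(tab)
  structure(list(counts = counts, vocabulary = vocab, doc_ids = x$id),
            class = "term_document_matrix")
}

#' @export
print.term_document_matrix <- function(x, ...) {
  cat(sprintf("<term_document_matrix: %d documents x %d terms, %d tokens>\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' TF-IDF weights with the per-term statistics used by the pruning rules
#'
#' Term frequency is the raw count; inverse document frequency uses the
#' smoothed form idf(t) = ln((1 + N) / (1 + df(t))) + 1, and each document
#' row is scaled to unit Euclidean length. The per-term column sum
#' (`total_weight`) and column maximum (`max_weight`) of the normalized
#' weights drive [filter_terms()].
#'
#' @param tdm a [term_document_matrix()].
#' @return An object of class `"tfidf"` with components `weights`,
#'   `vocabulary`, `doc_ids`, `idf`, `df`, `total_weight`, `max_weight`.
#' @export
compute_tfidf <- function(tdm) {
  stopifnot(inherits(tdm, "term_document_matrix"))
  n <- nrow(tdm$counts)
  df <- colSums(tdm$counts > 0L)
  idf <- log((1 + n) / (1 + df)) + 1
  w <- sweep(tdm$counts, 2L, idf, `*`)
  w <- l2_normalize_rows(w)
  structure(
    list(weights = w, vocabulary = tdm$vocabulary, doc_ids = tdm$doc_ids,
         idf = idf, df = df,
         total_weight = colSums(w), max_weight = apply(w, 2L, max)),
    class = "tfidf"
  )
}

#' @export
print.tfidf <- function(x, ...) {
  cat(sprintf("<tfidf: %d documents x %d terms>\n",
              nrow(x$weights), ncol(x$weights)))
  if (!is.null(x$removed))
    cat(sprintf("  pruned: %d rare, %d common\n",
                sum(x$removed$reason == "rare"),
                sum(x$removed$reason == "common")))
  invisible(x)
}

# Restrict a tfidf object to a term subset without renormalizing.
restrict_terms <- function(tfidf, terms) {
  keep <- tfidf$vocabulary %in% terms
  out <- tfidf
  out$weights <- tfidf$weights[, keep, drop = FALSE]
  out$vocabulary <- tfidf$vocabulary[keep]
  out$idf <- tfidf$idf[keep]
  out$df <- tfidf$df[keep]
  out$total_weight <- tfidf$total_weight[keep]
  out$max_weight <- tfidf$max_weight[keep]
  out
}

#' Prune common and rare terms from a TF-IDF matrix
#'
#' A term survives iff (i) its total TF-IDF weight across documents is at
#' least `tau_total`, and (ii) the ratio of its maximum weight to its
#' total weight is at least `tau_ratio`. Rule (i) removes rare words (low
#' total contribution); rule (ii) removes common words, whose weights are
#' spread nearly uniformly so the max/total ratio is about 1/N. Surviving
#' columns are kept as-is (no renormalization).
#'
#' @param tfidf a [compute_tfidf()] result.
#' @param tau_total minimum total weight (default 0.5).
#' @param tau_ratio minimum max/total weight ratio (default 0.1).
#' @return The restricted `"tfidf"`, with a `removed` data frame
#'   (`term`, `reason` in `"rare"`/`"common"`) recording discards.
#' @export
filter_terms <- function(tfidf, tau_total = 0.5, tau_ratio = 0.1) {
  stopifnot(inherits(tfidf, "tfidf"), tau_total >= 0,
            tau_ratio >= 0, tau_ratio <= 1)
  rare <- tfidf$total_weight < tau_total
  ratio <- ifelse(tfidf$total_weight > 0,
                  tfidf$max_weight / tfidf$total_weight, 0)
  common <- !rare & ratio < tau_ratio
  keep <- !rare & !common
  if (!any(keep))
    stop("all terms were discarded; relax tau_total/tau_ratio")
  out <- restrict_terms(tfidf, tfidf$vocabulary[keep])
  out$removed <- data.frame(
    term = tfidf$vocabulary[!keep],
    reason = ifelse(rare[!keep], "rare", "common"),
    stringsAsFactors = FALSE)
  out$thresholds <- c(tau_total = tau_total, tau_ratio = tau_ratio)
  out
}

#' Rank terms by mutual information with a binary label
#'
#' Each term's TF-IDF feature is binarized to presence (weight > 0) /
#' absence, and the plug-in (maximum-likelihood) mutual information in
#' bits is computed from the 2x2 contingency table with the label. Ties
#' are broken lexicographically (byte order) so the ranking is
#' reproducible.
#'
#' @param tfidf a `"tfidf"` object.
#' @param labels binary 0/1 vector, one per document; both classes must be
#'   present.
#' @return An object of class `"feature_ranking"`: a data frame with
#'   columns `term` and `score` (bits), sorted by decreasing score.
#' @export
rank_terms_by_mutual_information <- function(tfidf, labels) {
  stopifnot(inherits(tfidf, "tfidf"))
  labels <- as.integer(labels)
  if (length(labels) != nrow(tfidf$weights))
    stop("labels length must equal the number of documents")
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1 with no missing values")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the labels")
  pres <- tfidf$weights > 0
  n <- length(labels)
  n1 <- sum(labels == 1L)
  a11 <- colSums(pres[labels == 1L, , drop = FALSE])  # present & class 1
  a10 <- colSums(pres[labels == 0L, , drop = FALSE])  # present & class 0
  mi_term <- function(nxy, nx, ny) {
    p <- nxy / n
    out <- ifelse(nxy > 0, p * log2(n * nxy / (nx * ny)), 0)
    out
  }
  npres <- a11 + a10
  score <- mi_term(a11, npres, n1) + mi_term(a10, npres, n - n1) +
    mi_term(n1 - a11, n - npres, n1) + mi_term((n - n1) - a10, n - npres, n - n1)
  score <- pmax(score, 0)  # clip tiny negative rounding
  # tie-break lexicographically in byte order, independent of locale
  key <- match(tfidf$vocabulary, sort_c(tfidf$vocabulary))
  ord <- order(-score, key)
  structure(
    data.frame(term = tfidf$vocabulary[ord], score = score[ord],
               stringsAsFactors = FALSE),
    class = c("feature_ranking", "data.frame")
  )
}

#' Select the top fraction of a feature ranking
#'
#' @param ranking a `"feature_ranking"`.
#' @param fraction in (0, 1]; the `ceiling(fraction * n)` highest-scoring
#'   terms are returned.
#' @return Character vector of terms, best first.
#' @export
select_top_fraction <- function(ranking, fraction) {
  stopifnot(inherits(ranking, "feature_ranking"), nrow(ranking) > 0)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("`fraction` must be a single number in (0, 1]")
  ranking$term[seq_len(ceiling(fraction * nrow(ranking)))]
}
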