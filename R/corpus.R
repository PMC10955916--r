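#' Construct a corpus of respondent-level documents
#'
#' A corpus holds one document per respondent: an identifier, the raw
#' transcript text, optionally a token sequence produced by
#' [preprocess()], and optionally a binary stress label (0 = low,
#' 1 = high). Labels are all-or-none: either every document carries one or
#' none does.
#'
#' @param id character vector of unique, nonempty document identifiers.
#' @param text character vector of raw UTF-8 transcripts, same length as
#'   `id`.
#' @param tokens optional list of character vectors (one per document), as
#'   produced by [preprocess()].
#' @param label optional integer/numeric vector of 0/1 labels, no missing
#'   values.
#' @param metadata free-form named list (source path, tokenizer name, ...).
#' @return An object of class `"corpus"`.
#' @seealso [read_corpus()], [preprocess()]
#' @export
corpus <- function(id, text, tokens = NULL, label = NULL, metadata = list()) {
  id <- as.character(id)
  text <- as.character(text)
  if (length(id) != length(text))
    stop("`id` and `text` must have the same length")
  if (any(!nzchar(id)) || anyNA(id))
    stop("document ids must be nonempty strings")
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate document id(s): ", paste(dup, collapse = ", "))
  if (!is.null(tokens)) {
    if (!is.list(tokens) || length(tokens) != length(id))
      stop("`tokens` must be a list with one entry per document")
    tokens <- lapply(tokens, as.character)
  }
  if (!is.null(label)) {
    if (length(label) != length(id) || anyNA(label))
      stop("labels must be all-or-none: one non-missing value per document")
    label <- as.integer(label)
    if (!all(label %in% c(0L, 1L)))
      stop("labels must be binary (0 = low stress, 1 = high stress)")
  }
  structure(
    list(id = id, text = text, tokens = tokens, label = label,
         metadata = metadata),
    class = "corpus"
  )
}

#' @export
length.corpus <- function(x) length(x$id)

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus: %d documents%s%s>\n", length(x),
              if (is.null(x$tokens)) "" else ", tokenized",
              if (is.null(x$label)) "" else
                sprintf(", labeled (%d low / %d high)",
                        sum(x$label == 0L), sum(x$label == 1L))))
  invisible(x)
}

#' @export
as.data.frame.corpus <- function(x, ...) {
  d <- data.frame(id = x$id, text = x$text, stringsAsFactors = FALSE)
  if (!is.null(x$label)) d$label <- x$label
  d
}

#' Read a corpus from disk
#'
#' Supported formats: `"jsonl"` (one JSON object per line with fields
#' `id`, `text`, optional `label`), `"csv"` (header `id,text[,label]`),
#' and `"txt-dir"` (a directory of UTF-8 `.txt` files; the id is the file
#' name without extension). Input order is preserved; `txt-dir` files are
#' taken in byte-order of their names.
#'
#' @param path file (jsonl, csv) or directory (txt-dir).
#' @param format one of `"jsonl"`, `"csv"`, `"txt-dir"`.
#' @return A [corpus()] with raw text populated and no tokens.
#' @export
read_corpus <- function(path, format = c("jsonl", "csv", "txt-dir")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("path does not exist: ", path)
  out <- switch(format,
    "jsonl" = {
      lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      rows <- lapply(seq_along(lines), function(i) {
        obj <- jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE)
        if (is.null(obj$id)) stop("line ", i, ": missing 'id' field")
        if (is.null(obj$text)) stop("line ", i, ": missing 'text' field")
        obj
      })
      lab <- lapply(rows, `[[`, "label")
      has <- !vapply(lab, is.null, logical(1))
      if (any(has) && !all(has))
        stop("labels must be all-or-none across documents")
      corpus(
        id = vapply(rows, function(r) as.character(r$id), character(1)),
        text = vapply(rows, function(r) as.character(r$text), character(1)),
        label = if (all(has)) vapply(rows, function(r) as.numeric(r$label),
                                     numeric(1)),
        metadata = list(source = path, format = "jsonl")
      )
    },
    "csv" = {
      d <- utils::read.csv(path, colClasses = "character",
                           encoding = "UTF-8", stringsAsFactors = FALSE)
      if (!all(c("id", "text") %in% names(d)))
        stop("csv must have columns 'id' and 'text'")
      miss <- which(is.na(d$text))
      if (length(miss))
        stop("missing text in row ", miss[1])
      corpus(
        id = d$id, text = d$text,
        label = if ("label" %in% names(d)) as.numeric(d$label),
        metadata = list(source = path, format = "csv")
      )
    },
    "txt-dir" = {
      files <- sort_c(list.files(path, pattern = "\\.txt$"))
      if (!length(files)) stop("no .txt files found in ", path)
      txt <- vapply(files, function(f) {
        paste(readLines(file.path(path, f), encoding = "UTF-8",
                        warn = FALSE), collapse = "\n")
      }, character(1))
      corpus(id = sub("\\.txt$", "", files), text = unname(txt),
             metadata = list(source = path, format = "txt-dir"))
    })
  out
}

#' Read a stopword list
#'
#' One token per line, UTF-8; lines whose first non-blank character is `#`
#' are comments. Tokens are normalized the same way document tokens are
#' (Unicode NFC, ASCII lowercased) so matching is deterministic.
#'
#' @param path file path.
#' @return Character vector of stopwords.
#' @export
read_stopwords <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(normalize_token(lines))
}

#' Write clustering results (and optional metrics) to disk
#'
#' Writes `assignments.csv` with one row per document
#' (`id,cluster,score_cluster1,...,score_clusterC`) and, when `metrics` is
#' supplied, `metrics.json`. Output is byte-stable for identical inputs.
#'
#' @param consensus a `"consensus_result"` (see [assign_documents()]) or a
#'   fitted [topic_consensus()] object.
#' @param metrics optional `"metrics_report"` from [compute_metrics()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(consensus, metrics = NULL, dir) {
  if (inherits(consensus, "topic_consensus")) consensus <- consensus$consensus
  stopifnot(inherits(consensus, "consensus_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scores <- consensus$doc_scores
  d <- data.frame(id = rownames(scores),
                  cluster = as.integer(consensus$assignment),
                  stringsAsFactors = FALSE)
  for (c_ in seq_len(ncol(scores)))
    d[[sprintf("score_cluster%d", c_)]] <- sprintf("%.10g", scores[, c_])
  csv <- file.path(dir, "assignments.csv")
  utils::write.csv(d, csv, row.names = FALSE, quote = FALSE)
  paths <- csv
  if (!is.null(metrics)) {
    stopifnot(inherits(metrics, "metrics_report"))
    js <- file.path(dir, "metrics.json")
    jsonlite::write_json(
      list(accuracy = round(metrics$accuracy, 2),
           tpr_low = round(metrics$tpr_low, 2),
           tnr_high = round(metrics$tnr_high, 2),
           n = metrics$n,
           mapping = as.list(metrics$mapping),
           confusion = unclass(metrics$confusion)),
      js, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, js)
  }
  invisible(paths)
}
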