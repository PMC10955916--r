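# Tokenization and text cleaning.
#
# Cantonese (and written Chinese generally) has no spaces between words,
# and multi-character segments carry meanings their characters do not
# ("family members" vs "family" + "person"), so segmentation quality
# matters. The package treats the segmenter as a plug-in: any function
# mapping a string to a token vector can be injected, e.g. a wrapper
# around a dedicated Cantonese segmenter. The built-in default splits on
# whitespace and falls back to one token per Han character, which keeps
# the pipeline usable without language resources.

# Normalization applied to both tokens and stopwords: Unicode NFC, ASCII
# letters lowercased, CJK left untouched.
normalize_token <- function(x) {
  x <- stringi::stri_trans_nfc(x)
  chartr("ABCDEFGHIJKLMNOPQRSTUVWXYZ", "abcdefghijklmnopqrstuvwxyz", x)
}

#' Default segmenter: whitespace split with per-Han-character fallback
#'
#' Splits on whitespace; within each piece, every Han character becomes
#' its own token while maximal runs of non-Han characters stay whole.
#'
#' @param x a single string.
#' @return Character vector of tokens (possibly empty).
#' @export
default_segmenter <- function(x) {
  if (!nzchar(x)) return(character(0))
  toks <- stringi::stri_extract_all_regex(x, "\\p{Han}|[^\\p{Han}\\s]+")[[1]]
  toks[!is.na(toks)]
}

#' Tokenizer specification
#'
#' Bundles a deterministic segmenter with the cleaning rules applied after
#' segmentation: stopword removal, and removal of purely numeric (ASCII or
#' fullwidth digits) and purely punctuation/symbol tokens.
#'
#' @param name short label recorded in corpus metadata.
#' @param segmenter function mapping a raw string to a character vector of
#'   tokens; must be deterministic. Defaults to [default_segmenter()].
#' @param stopwords character vector of stopwords (normalized internally).
#' @param drop_numeric drop tokens consisting only of digits.
#' @param drop_punctuation drop tokens whose every character is Unicode
#'   punctuation or symbol.
#' @return An object of class `"tokenizer_spec"`.
#' @export
tokenizer_spec <- function(name = "default", segmenter = default_segmenter,
                           stopwords = character(0), drop_numeric = TRUE,
                           drop_punctuation = TRUE) {
  stopifnot(is.function(segmenter))
  structure(
    list(name = name, segmenter = segmenter,
         stopwords = unique(normalize_token(as.character(stopwords))),
         drop_numeric = isTRUE(drop_numeric),
         drop_punctuation = isTRUE(drop_punctuation)),
    class = "tokenizer_spec"
  )
}

clean_tokens <- function(toks, spec) {
  toks <- normalize_token(toks)
  toks <- toks[nzchar(trimws(toks))]
  if (spec$drop_punctuation && length(toks))
    toks <- toks[!grepl("^[\\p{P}\\p{S}]+$", toks, perl = TRUE)]
  if (spec$drop_numeric && length(toks))
    toks <- toks[!grepl("^[0-9０-９]+$", toks)]
  if (length(spec$stopwords) && length(toks))
    toks <- toks[!toks %in% spec$stopwords]
  toks
}

#' Tokenize and clean a corpus
#'
#' Runs the segmenter on each document's raw text, then removes
#' whitespace-only, punctuation-only and numeric-only tokens and
#' stopwords, preserving the remaining token order. Re-running on an
#' already-preprocessed corpus yields the same token sequences
#' (preprocessing is idempotent).
#'
#' @param x a [corpus()].
#' @param spec a [tokenizer_spec()].
#' @return The corpus with `tokens` populated; raw text is unchanged.
#' @export
preprocess <- function(x, spec = tokenizer_spec()) {
  stopifnot(inherits(x, "corpus"), inherits(spec, "tokenizer_spec"))
  toks <- vector("list", length(x))
  for (i in seq_along(x$id)) {
    raw <- tryCatch(spec$segmenter(x$text[[i]]),
                    error = function(e) stop("segmenter failed on document '",
                                             x$id[[i]], "': ",
                                             conditionMessage(e)))
    toks[[i]] <- clean_tokens(as.character(raw), spec)
  }
  x$tokens <- toks
  x$metadata$tokenizer <- spec$name
  x
}
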