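test_that("jsonl ingestion preserves order, ids and labels", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"id": "d1", "text": "alpha beta", "label": 0}',
    '{"id": "d2", "text": "gamma", "label": 1}',
    '{"id": "d3", "text": "delta epsilon", "label": 0}'
  ), f)
  cc <- read_corpus(f, "jsonl")
  expect_s3_class(cc, "corpus")
  expect_equal(cc$id, c("d1", "d2", "d3"))
  expect_equal(cc$text[2], "gamma")
  expect_equal(cc$label, c(0L, 1L, 0L))
  expect_null(cc$tokens)
})

test_that("duplicate and missing fields are hard errors naming the culprit", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,text", "a,one", "b,two", "c7,three", "d,four", "c7,five"),
             f)
  expect_error(read_corpus(f, "csv"), "c7")

  f2 <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"id": "x", "text": "ok"}', '{"id": "y"}'), f2)
  expect_error(read_corpus(f2, "jsonl"), "line 2.*text")

  expect_error(read_corpus(f, "parquet"))
  expect_error(read_corpus(file.path(tempdir(), "nope-missing"), "csv"),
               "does not exist")
})

test_that("a directory of txt files becomes an unlabeled corpus keyed by stem", {
  d <- withr::local_tempdir()
  for (i in 1:100)
    writeLines(sprintf("text of file %d", i),
               file.path(d, sprintf("resp%03d.txt", i)))
  cc <- read_corpus(d, "txt-dir")
  expect_length(cc, 100)
  expect_equal(cc$id, sprintf("resp%03d", 1:100))
  expect_null(cc$label)
  expect_equal(cc$text[42], "text of file 42")
})

test_that("corpus constructor enforces its invariants", {
  expect_error(corpus(c("a", ""), c("x", "y")), "nonempty")
  expect_error(corpus(c("a", "a"), c("x", "y")), "duplicate")
  expect_error(corpus(c("a", "b"), c("x", "y"), label = c(0, NA)),
               "all-or-none")
  expect_error(corpus(c("a", "b"), c("x", "y"), label = c(0, 2)), "binary")
})

test_that("preprocess drops stopwords, punctuation and numerals, keeps segments whole", {
  # multi-character segments from the segmenter must survive intact
  seg <- function(x) c("家人", "，", "好")  # 家人 ， 好
  spec <- tokenizer_spec(segmenter = seg, stopwords = "好")
  cc <- preprocess(corpus("d1", "irrelevant"), spec)
  expect_equal(cc$tokens[[1]], "家人")

  spec2 <- tokenizer_spec(stopwords = "the")
  cc2 <- preprocess(corpus("d1", "go out 123 the"), spec2)
  expect_equal(cc2$tokens[[1]], c("go", "out"))

  expect_equal(preprocess(corpus("e", ""))$tokens[[1]], character(0))

  # fullwidth digits and symbol-only tokens are removed too
  cc3 <- preprocess(corpus("d", "ok １２ ++ %"), tokenizer_spec())
  expect_equal(cc3$tokens[[1]], "ok")
})

test_that("default segmenter splits Han per character and keeps ASCII runs", {
  toks <- default_segmenter("abc 家人 ok")
  expect_equal(toks, c("abc", "家", "人", "ok"))
})

test_that("preprocessing is idempotent and order-preserving", {
  spec <- tokenizer_spec(stopwords = c("the", "a"))
  cc <- corpus(c("d1", "d2"),
               c("The quick 99 fox , jumps the fence",
                 "a b c ... c b a"))
  once <- preprocess(cc, spec)
  twice <- preprocess(once, spec)
  expect_identical(once$tokens, twice$tokens)
  expect_equal(once$tokens[[1]], c("quick", "fox", "jumps", "fence"))
  expect_equal(once$tokens[[2]], c("b", "c", "c", "b"))
  # raw text untouched
  expect_identical(once$text, cc$text)
})

test_that("segmenter failures carry the document id", {
  boom <- function(x) if (grepl("bad", x)) stop("kaput") else c("ok")
  cc <- corpus(c("good1", "bad7"), c("fine", "bad input"))
  expect_error(preprocess(cc, tokenizer_spec(segmenter = boom)), "bad7")
})

test_that("stopword files support comments and share token normalization", {
  f <- withr::local_tempfile()
  writeLines(c("# comment line", "THE", "  好  ", ""), f)
  sw <- read_stopwords(f)
  expect_setequal(sw, c("the", "好"))
  spec <- tokenizer_spec(stopwords = sw)
  cc <- preprocess(corpus("d", "The 好 ok"), spec)
  expect_equal(cc$tokens[[1]], "ok")
})

test_that("write_results round-trips assignments and only emits metrics when given", {
  cons <- structure(list(
    topic_cluster = c(1L, 2L),
    doc_scores = matrix(c(2, 1.5, 0.2, 0.1, 0.5, 1.9, 1.8, 2.2), 4, 2,
                        dimnames = list(sprintf("d%d", 1:4), NULL)),
    assignment = stats::setNames(c(1L, 1L, 2L, 2L), sprintf("d%d", 1:4)),
    linkage = NULL, n_runs = 2L), class = "consensus_result")
  d <- withr::local_tempdir()
  write_results(cons, metrics = NULL, dir = d)
  expect_false(file.exists(file.path(d, "metrics.json")))
  back <- utils::read.csv(file.path(d, "assignments.csv"),
                          colClasses = c("character", "integer",
                                         "numeric", "numeric"))
  expect_equal(nrow(back), 4L)
  expect_equal(back$id, sprintf("d%d", 1:4))
  expect_equal(back$cluster, c(1L, 1L, 2L, 2L))
  expect_equal(back$score_cluster1, unname(cons$doc_scores[, 1]))

  m <- compute_metrics(matrix(c(2, 0, 0, 2), 2, 2))
  write_results(cons, metrics = m, dir = d)
  js <- jsonlite::read_json(file.path(d, "metrics.json"))
  expect_equal(js$accuracy, 100)
  expect_equal(js$n, 4)

  # byte-stable on identical inputs
  d2 <- withr::local_tempdir()
  write_results(cons, metrics = m, dir = d2)
  expect_identical(readLines(file.path(d, "assignments.csv")),
                   readLines(file.path(d2, "assignments.csv")))
})
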