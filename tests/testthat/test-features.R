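test_that("term-document counts match direct enumeration", {
  tdm <- term_document_matrix(toy_corpus(list(c("a", "b", "a"),
                                              c("b", "c"))))
  expect_equal(tdm$vocabulary, c("a", "b", "c"))
  expect_equal(unname(tdm$counts), rbind(c(2L, 1L, 0L), c(0L, 1L, 1L)))

  one <- term_document_matrix(toy_corpus(list("x")))
  expect_equal(unname(one$counts), matrix(1L, 1, 1))

  expect_error(term_document_matrix(toy_corpus(list(character(0)))),
               "no tokens")
})

test_that("permuting document order permutes rows only", {
  toks <- list(c("a", "b"), c("b", "c", "c"), c("a", "d"))
  t1 <- term_document_matrix(toy_corpus(toks))
  t2 <- term_document_matrix(toy_corpus(toks[c(3, 1, 2)]))
  expect_equal(t2$vocabulary, t1$vocabulary)
  expect_equal(unname(t2$counts), unname(t1$counts[c(3, 1, 2), ]))
})

test_that("tfidf follows the smoothed-idf, row-normalized formula", {
  # single document: every idf = ln(2/2) + 1 = 1 and the row has unit norm
  tf1 <- compute_tfidf(term_document_matrix(toy_corpus(list(c("a", "b", "b")))))
  expect_equal(unname(tf1$idf), c(1, 1))
  expect_equal(sum(tf1$weights^2), 1, tolerance = 1e-12)

  # three documents, computed by hand from the stated formula
  tf <- compute_tfidf(term_document_matrix(
    toy_corpus(list(c("a", "a", "b"), c("b", "c"), c("c")))))
  expect_equal(unname(tf$idf),
               c(log(4 / 2) + 1, log(4 / 3) + 1, log(4 / 3) + 1),
               tolerance = 1e-12)
  pre <- c(2 * (log(2) + 1), 1 * (log(4 / 3) + 1), 0)
  expect_equal(unname(tf$weights[1, ]), pre / sqrt(sum(pre^2)),
               tolerance = 1e-12)
  expect_equal(unname(tf$weights[1, 1]), 0.9347, tolerance = 1e-4)

  # column statistics agree with their definitions
  expect_equal(tf$total_weight, colSums(tf$weights))
  expect_true(all(tf$max_weight <= tf$total_weight + 1e-12))
})

test_that("tfidf rows have unit norm and the map is deterministic", {
  set.seed(7)
  for (rep in 1:5) {
    toks <- replicate(8, sample(letters[1:12], sample(3:20, 1), TRUE),
                      simplify = FALSE)
    tf <- compute_tfidf(term_document_matrix(toy_corpus(toks)))
    expect_equal(unname(rowSums(tf$weights^2)), rep(1, 8),
                 tolerance = 1e-9)
    tf2 <- compute_tfidf(term_document_matrix(toy_corpus(toks)))
    expect_identical(tf$weights, tf2$weights)
  }
})

test_that("the two pruning rules fire as specified on crafted weights", {
  # uniform spread over 25 docs: total 1.0 passes rule (i), ratio 1/25
  # fails rule (ii) -> common
  w_common <- matrix(0.04, 25, 1)
  # a single occurrence of weight 0.3: total below 0.5 -> rare
  w_rare <- matrix(c(0.3, rep(0, 24)), 25, 1)
  # two occurrences 0.4/0.3: total 0.7, ratio 0.571 -> kept
  w_keep <- matrix(c(0.4, 0.3, rep(0, 23)), 25, 1)
  tf <- tfidf_from_weights(cbind(w_common, w_rare, w_keep))
  out <- filter_terms(tf)
  expect_equal(out$vocabulary, "t03")
  expect_equal(out$removed$reason[out$removed$term == "t01"], "common")
  expect_equal(out$removed$reason[out$removed$term == "t02"], "rare")
  # no renormalization of surviving columns
  expect_equal(unname(out$weights[, 1]), c(0.4, 0.3, rep(0, 23)))
})

test_that("filtering equals the brute-force rule oracle and is monotone", {
  set.seed(11)
  for (rep in 1:5) {
    toks <- replicate(10, sample(sprintf("w%02d", 1:25),
                                 sample(5:40, 1), TRUE),
                      simplify = FALSE)
    tf <- compute_tfidf(term_document_matrix(toy_corpus(toks)))
    # data-dependent thresholds so that some but not all terms survive
    tt <- unname(stats::quantile(tf$total_weight, 0.3))
    tr <- unname(stats::quantile(tf$max_weight / tf$total_weight, 0.3))
    keep <- oracle_filter_keep(tf$weights, tt, tr)
    out <- filter_terms(tf, tau_total = tt, tau_ratio = tr)
    expect_setequal(out$vocabulary, tf$vocabulary[keep])

    # raising either threshold never adds a survivor
    out2 <- filter_terms(tf, tau_total = tt * 1.2, tau_ratio = tr)
    expect_true(all(out2$vocabulary %in% out$vocabulary))
    out3 <- filter_terms(tf, tau_total = tt, tau_ratio = min(1, tr * 1.2))
    expect_true(all(out3$vocabulary %in% out$vocabulary))
  }
  expect_error(filter_terms(tfidf_from_weights(matrix(0.01, 30, 2)),
                            tau_total = 5),
               "relax")
})

test_that("mutual-information ranking matches the plug-in oracle", {
  # constant feature -> 0 bits; perfect balanced association -> 1 bit
  w <- cbind(everywhere = rep(0.2, 6),
             perfect = c(0, 0, 0, 0.5, 0.4, 0.3),
             noise = c(0.1, 0, 0.2, 0.3, 0, 0.1))
  labels <- c(0, 0, 0, 1, 1, 1)
  r <- rank_terms_by_mutual_information(tfidf_from_weights(w), labels)
  expect_equal(r$score[r$term == "everywhere"], 0)
  expect_equal(r$score[r$term == "perfect"], 1)
  expect_equal(r$term[1], "perfect")

  # present in 3 of 5 docs in each class: independent -> 0
  w2 <- matrix(c(rep(0.3, 3), 0, 0, rep(0.3, 3), 0, 0), ncol = 1)
  r2 <- rank_terms_by_mutual_information(tfidf_from_weights(w2),
                                         rep(c(0, 1), each = 5))
  expect_equal(r2$score, 0, tolerance = 1e-12)

  # random features agree with the entropy-identity oracle
  set.seed(3)
  wr <- matrix(stats::runif(12 * 6) * (stats::runif(12 * 6) > 0.5), 12, 6)
  lab <- rep(c(0, 1), 6)
  rr <- rank_terms_by_mutual_information(tfidf_from_weights(wr), lab)
  for (j in seq_len(ncol(wr))) {
    expected <- oracle_mi(as.integer(wr[, j] > 0), lab)
    expect_equal(rr$score[rr$term == sprintf("t%02d", j)], expected,
                 tolerance = 1e-12)
  }
})

test_that("MI scores are invariant to label swap and document order", {
  set.seed(4)
  wr <- matrix(stats::runif(40) * (stats::runif(40) > 0.4), 10, 4)
  lab <- c(0, 1, 1, 0, 0, 1, 0, 1, 1, 0)
  tf <- tfidf_from_weights(wr)
  r1 <- rank_terms_by_mutual_information(tf, lab)
  r2 <- rank_terms_by_mutual_information(tf, 1 - lab)
  expect_equal(r1, r2, tolerance = 1e-12)
  perm <- sample(10)
  r3 <- rank_terms_by_mutual_information(tfidf_from_weights(wr[perm, ]),
                                         lab[perm])
  expect_equal(r1, r3, tolerance = 1e-12)

  expect_error(rank_terms_by_mutual_information(tf, rep(0, 10)),
               "both classes")
  expect_error(rank_terms_by_mutual_information(tf, lab[-1]), "length")
})

test_that("top-fraction selection uses ceiling and is nested", {
  r <- structure(data.frame(term = sprintf("t%02d", 1:10),
                            score = seq(1, 0.1, by = -0.1)),
                 class = c("feature_ranking", "data.frame"))
  expect_length(select_top_fraction(r, 1.0), 10)
  expect_length(select_top_fraction(r, 0.25), 3)
  expect_true(all(select_top_fraction(r, 0.2) %in%
                  select_top_fraction(r, 0.4)))
  expect_error(select_top_fraction(r, 0), "fraction")
  expect_error(select_top_fraction(r, 1.5), "fraction")
})
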