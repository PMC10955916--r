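# Synthetic two-group corpus generator.
#
# Emulates the structure the clustering method assumes: two respondent
# groups whose word distributions differ in discriminative vocabulary
# while sharing a common background vocabulary, plus injected singleton
# rare words. Within a group, each document draws its group words from a
# document-specific Dirichlet preference mixed with a uniform
# within-group floor: respondents emphasize a handful of personally
# salient themes on top of a lexicon shared by their group. The
# concentration makes discriminative words weight-concentrated in a few
# documents (so the max/total pruning rule retains them) while the floor
# keeps every pair of same-group documents correlated (so the consensus
# clustering can assemble each group); background words are spread
# near-uniformly over all documents (removed as common) and rare words
# occur exactly once (removed as rare).

#' Configuration for the synthetic corpus generator
#'
#' @param n_per_group documents per group (default 50, i.e. 100 total).
#' @param doc_length tokens per document (default 200).
#' @param n_background shared background vocabulary size (default 60).
#' @param n_group_words discriminative words per group (default 40).
#' @param n_rare size of the singleton rare-word pool (default 30).
#' @param p_background,p_group,p_rare per-token role probabilities; must
#'   sum to 1 (defaults 0.5, 0.45, 0.05).
#' @param separation in \[0, 1\]: how exclusive group vocabularies are. A
#'   group-word draw uses the document's own group vocabulary with
#'   probability `(1 + separation) / 2` and the other group's otherwise,
#'   so 1 gives fully exclusive vocabularies and 0 makes both groups draw
#'   group words from one common distribution (indistinguishable limit).
#' @param group_concentration Dirichlet concentration of each document's
#'   preference over its group vocabulary (default 0.1; smaller is more
#'   concentrated; `Inf` gives uniform usage).
#' @param group_floor weight of the uniform within-group floor mixed into
#'   the per-document preference (default 0.2).
#' @param seed RNG seed (default 0).
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(n_per_group = 50L, doc_length = 200L,
                             n_background = 60L, n_group_words = 40L,
                             n_rare = 30L, p_background = 0.5,
                             p_group = 0.45, p_rare = 0.05,
                             separation = 1.0, group_concentration = 0.1,
                             group_floor = 0.2, seed = 0L) {
  p <- c(p_background, p_group, p_rare)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("mixing weights must be nonnegative and sum to 1")
  if (separation < 0 || separation > 1)
    stop("separation must be in [0, 1]")
  if (any(c(n_per_group, doc_length, n_background, n_group_words,
            n_rare) < 0))
    stop("sizes must be nonnegative")
  if (group_concentration <= 0)
    stop("group_concentration must be positive")
  if (group_floor < 0 || group_floor > 1)
    stop("group_floor must be in [0, 1]")
  structure(
    list(n_per_group = as.integer(n_per_group),
         doc_length = as.integer(doc_length),
         n_background = as.integer(n_background),
         n_group_words = as.integer(n_group_words),
         n_rare = as.integer(n_rare),
         p_background = p_background, p_group = p_group, p_rare = p_rare,
         separation = separation,
         group_concentration = group_concentration,
         group_floor = group_floor, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Generate a labeled synthetic corpus with ground-truth word roles
#'
#' Documents are drawn token by token: a background word with probability
#' `p_background` (uniform over the shared background vocabulary), a
#' group word with probability `p_group` (own group's vocabulary with
#' probability `(1 + separation) / 2`, the other group's otherwise;
#' own-group words follow the document's Dirichlet-plus-floor
#' preference, other-group draws are uniform), or a
#' rare word with probability `p_rare`. Each rare word is used exactly
#' once corpus-wide and then retired; once the pool is exhausted the
#' draw falls back to a background word (with a one-time warning).
#' Labels are 0 for group 1 and 1 for group 2. Identical seeds give
#' byte-identical corpora.
#'
#' @param config a [generator_config()].
#' @return An object of class `"synthetic_corpus"`: `corpus` (labeled,
#'   tokenized), `roles` (data frame `term`, `role` in
#'   background/group1/group2/rare), `config`.
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  v_bg <- if (cfg$n_background) sprintf("bg_%03d", seq_len(cfg$n_background))
          else character(0)
  v_g <- list(sprintf("g1_%03d", seq_len(cfg$n_group_words)),
              sprintf("g2_%03d", seq_len(cfg$n_group_words)))
  v_rare <- if (cfg$n_rare) sprintf("rare_%03d", seq_len(cfg$n_rare))
            else character(0)
  n_docs <- 2L * cfg$n_per_group
  group <- rep(1:2, each = cfg$n_per_group)
  probs <- c(cfg$p_background, cfg$p_group, cfg$p_rare)
  rare_used <- 0L
  exhausted_warned <- FALSE
  tokens <- vector("list", n_docs)
  with_seed(cfg$seed, {
    for (d in seq_len(n_docs)) {
      # per-document preference over the own-group vocabulary
      if (is.finite(cfg$group_concentration)) {
        pref <- stats::rgamma(cfg$n_group_words, cfg$group_concentration)
        if (sum(pref) == 0) pref <- rep(1, cfg$n_group_words)
        pref <- pref / sum(pref)
      } else pref <- rep(1 / cfg$n_group_words, cfg$n_group_words)
      pref <- cfg$group_floor / cfg$n_group_words +
        (1 - cfg$group_floor) * pref
      roles <- sample.int(3L, cfg$doc_length, replace = TRUE, prob = probs)
      toks <- character(cfg$doc_length)
      # rare draws: consume the next unused rare words, overflow to bg
      i_rare <- which(roles == 3L)
      if (length(i_rare)) {
        n_avail <- min(length(i_rare), cfg$n_rare - rare_used)
        if (n_avail > 0) {
          toks[i_rare[seq_len(n_avail)]] <-
            v_rare[rare_used + seq_len(n_avail)]
          rare_used <- rare_used + n_avail
        }
        if (n_avail < length(i_rare)) {
          if (!exhausted_warned) {
            warning("rare vocabulary exhausted at document ", d,
                    "; substituting background words", call. = FALSE)
            exhausted_warned <- TRUE
          }
          over <- if (n_avail > 0) i_rare[-seq_len(n_avail)] else i_rare
          roles[over] <- 1L
        }
      }
      i_bg <- which(roles == 1L)
      if (length(i_bg))
        toks[i_bg] <- v_bg[sample.int(cfg$n_background, length(i_bg),
                                      replace = TRUE)]
      i_grp <- which(roles == 2L)
      if (length(i_grp)) {
        own <- stats::runif(length(i_grp)) < (1 + cfg$separation) / 2
        g_own <- group[d]
        g_oth <- 3L - g_own
        if (any(own))
          toks[i_grp[own]] <-
            v_g[[g_own]][sample.int(cfg$n_group_words, sum(own),
                                    replace = TRUE, prob = pref)]
        if (any(!own))
          toks[i_grp[!own]] <-
            v_g[[g_oth]][sample.int(cfg$n_group_words, sum(!own),
                                    replace = TRUE)]
      }
      tokens[[d]] <- toks
    }
  })
  ids <- sprintf("doc_%03d", seq_len(n_docs))
  corp <- corpus(id = ids,
                 text = vapply(tokens, paste, character(1), collapse = " "),
                 tokens = tokens, label = group - 1L,
                 metadata = list(generator = unclass(cfg)))
  roles <- data.frame(
    term = c(v_bg, v_g[[1]], v_g[[2]], v_rare),
    role = c(rep("background", length(v_bg)),
             rep("group1", cfg$n_group_words),
             rep("group2", cfg$n_group_words),
             rep("rare", length(v_rare))),
    stringsAsFactors = FALSE)
  structure(list(corpus = corp, roles = roles, config = cfg),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf(
    "<synthetic_corpus: %d documents (%d per group), separation %.2f>\n",
    length(x$corpus), x$config$n_per_group, x$config$separation))
  invisible(x)
}

#' Filter behavior per ground-truth word role
#'
#' Runs the TF-IDF pruning rules on a generated corpus and reports, for
#' each word role, how many words appear in the corpus and what fraction
#' is retained, removed by the total-weight (rare) rule, or removed by
#' the max/total ratio (common) rule — for assertion in tests of the
#' generator/filter contract.
#'
#' @param x a [generate_corpus()] result.
#' @param tau_total,tau_ratio thresholds, as in [filter_terms()].
#' @return Data frame with columns `role`, `n`, `retained`,
#'   `removed_rare`, `removed_common` (fractions).
#' @export
ground_truth_filter_expectations <- function(x, tau_total = 0.5,
                                             tau_ratio = 0.1) {
  stopifnot(inherits(x, "synthetic_corpus"))
  tf <- compute_tfidf(term_document_matrix(x$corpus))
  rare <- tf$total_weight < tau_total
  ratio <- ifelse(tf$total_weight > 0, tf$max_weight / tf$total_weight, 0)
  common <- !rare & ratio < tau_ratio
  role <- x$roles$role[match(tf$vocabulary, x$roles$term)]
  out <- do.call(rbind, lapply(unique(x$roles$role), function(rl) {
    i <- which(role == rl)
    if (!length(i))
      return(data.frame(role = rl, n = 0L, retained = NA_real_,
                        removed_rare = NA_real_, removed_common = NA_real_))
    data.frame(role = rl, n = length(i),
               retained = mean(!rare[i] & !common[i]),
               removed_rare = mean(rare[i]),
               removed_common = mean(common[i]))
  }))
  rownames(out) <- NULL
  out
}
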