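# Variation of information between naming systems, and the two-level
# (speakers within language, then languages) corpus averaging used to
# compare transmission chains with a reference naming corpus.
#
# All information quantities are in nats. Pairs of systems are compared
# over the chips labelled by both, so partial (aggregate) systems are
# handled by restriction to the common chip set.

#' Construct a speaker corpus
#'
#' A corpus maps language ids to speakers to naming systems, all over a
#' shared chip grid; it models both WCS-style reference data and control
#' corpora.
#'
#' @param languages named list: `languages[[language_id]][[speaker_id]]`
#'   is a [naming_system()].
#' @return an object of class `speaker_corpus`.
#' @export
speaker_corpus <- function(languages) {
  if (!length(languages) || is.null(names(languages))) {
    stop("a corpus needs at least one named language")
  }
  for (lang in names(languages)) {
    if (!length(languages[[lang]]) || is.null(names(languages[[lang]]))) {
      stop("language '", lang, "' needs at least one named speaker")
    }
    for (ns in languages[[lang]]) stopifnot(inherits(ns, "naming_system"))
  }
  structure(list(languages = languages), class = "speaker_corpus")
}

#' @export
print.speaker_corpus <- function(x, ...) {
  ns <- lengths(x$languages)
  cat(sprintf("<speaker_corpus: %d languages, %d speakers>\n",
              length(ns), sum(ns)))
  invisible(x)
}

# Integer-coded labels aligned to grid order (NA where unlabelled), for
# the fast contingency path.
label_codes <- function(ns) {
  al <- aligned_labels(ns)
  f <- factor(al, levels = sort(unique(al[!is.na(al)])))
  list(code = as.integer(f), k = nlevels(f))
}

# VI and MI from two code vectors over their common support.
# VI = 2 H(A,B) - H(A) - H(B); MI = H(A) + H(B) - H(A,B).
info_pair <- function(ca, cb) {
  keep <- !is.na(ca$code) & !is.na(cb$code)
  n <- sum(keep)
  if (n == 0L) stop("systems share no labelled chips")
  a <- ca$code[keep]
  b <- cb$code[keep]
  joint <- tabulate((a - 1L) * cb$k + b, ca$k * cb$k) / n
  ha <- -sum(xlogx(tabulate(a, ca$k) / n))
  hb <- -sum(xlogx(tabulate(b, cb$k) / n))
  hab <- -sum(xlogx(joint))
  c(ha = ha, hb = hb, mi = ha + hb - hab, vi = 2 * hab - ha - hb, n = n)
}

#' Entropy of a naming system
#'
#' `H(C) = -sum_k P(k) log P(k)` over the used terms, where `P(k)` is
#' the fraction of labelled chips carrying term `k` (0 log 0 = 0).
#' Measured in nats.
#'
#' @param ns a [naming_system()] with at least one labelled chip.
#' @return non-negative entropy, at most `log(#used terms)`.
#' @export
entropy <- function(ns) {
  if (!length(ns$labels)) stop("entropy of an empty labelling is undefined")
  p <- table(ns$labels) / length(ns$labels)
  -sum(xlogx(as.numeric(p)))
}

#' Mutual information between two naming systems
#'
#' `I(C, C') = sum_{k,k'} P(k, k') log( P(k, k') / (P(k) P(k')) )`,
#' with the joint distribution given by co-assignment counts over the
#' chips labelled in both systems. In nats.
#'
#' @param a,b [naming_system()]s over the same grid with at least one
#'   commonly labelled chip.
#' @return mutual information, between 0 and `min(H(a), H(b))`.
#' @export
mutual_information <- function(a, b) {
  unname(info_pair(label_codes(a), label_codes(b))["mi"])
}

#' Variation of information between two naming systems
#'
#' `VI(C, C') = H(C) + H(C') - 2 I(C, C')`, the information-theoretic
#' distance between two partitions of the same chip set. It is a true
#' metric: non-negative, symmetric, zero exactly for partitions that are
#' identical up to term renaming, and satisfying the triangle
#' inequality. For partial systems it is computed over the commonly
#' labelled chips. In nats; bounded by `log(n)` for `n` common chips.
#'
#' @inheritParams mutual_information
#' @return the VI distance.
#' @export
variation_of_information <- function(a, b) {
  unname(info_pair(label_codes(a), label_codes(b))["vi"])
}

# Precompute code vectors for every speaker of a corpus (flat list with
# language/speaker bookkeeping), so repeated corpus comparisons avoid
# re-factoring labels.
corpus_codes <- function(corpus) {
  langs <- names(corpus$languages)
  out <- lapply(langs, function(lang)
    lapply(corpus$languages[[lang]], label_codes))
  names(out) <- langs
  out
}

# mean VI of one coded system against each language (mean over that
# language's speakers); returns named per-language means
per_language_vi <- function(code, codes) {
  vapply(codes, function(spk) {
    mean(vapply(spk, function(cb) info_pair(code, cb)["vi"], numeric(1)))
  }, numeric(1))
}

#' Mean VI from a system to a reference corpus
#'
#' The two-level averaging procedure used throughout the analyses: the
#' VI between `ns` and every speaker of every language is computed, then
#' averaged across speakers within each language, then (unweighted)
#' across languages, so a heavily sampled language counts no more than a
#' sparsely sampled one.
#'
#' @param ns a [naming_system()].
#' @param corpus a [speaker_corpus()].
#' @param language_filter optional predicate `function(language_id,
#'   speakers)` returning `TRUE` for languages to keep (e.g. restrict to
#'   languages using the same number of terms as `ns`).
#' @return the mean VI (nats).
#' @export
mean_vi_to_corpus <- function(ns, corpus, language_filter = NULL) {
  langs <- corpus$languages
  if (!is.null(language_filter)) {
    keep <- vapply(names(langs),
                   function(l) isTRUE(language_filter(l, langs[[l]])),
                   logical(1))
    langs <- langs[keep]
    if (!length(langs)) stop("language_filter removed every language")
  }
  codes <- lapply(langs, function(spk) lapply(spk, label_codes))
  mean(per_language_vi(label_codes(ns), codes))
}

#' Mean pairwise VI between the languages of a corpus
#'
#' For each unordered pair of distinct languages, the VI is averaged
#' over all cross-language speaker pairs; the result is the unweighted
#' mean over language pairs. This is the corpus-internal baseline
#' against which converged chains are judged.
#'
#' @param corpus a [speaker_corpus()] with at least two languages.
#' @return the mean cross-language VI (nats).
#' @export
corpus_pairwise_vi <- function(corpus) {
  M <- language_vi_matrix(corpus_codes(corpus))
  mean(M[upper.tri(M)])
}

# Symmetric matrix of language-pair mean VIs: entry (i, j) is the mean
# VI over all cross-language speaker pairs of languages i and j.
language_vi_matrix <- function(codes) {
  L <- length(codes)
  if (L < 2) stop("need at least two languages")
  M <- matrix(NA_real_, L, L, dimnames = list(names(codes), names(codes)))
  for (i in seq_len(L - 1)) {
    for (j in seq(i + 1, L)) {
      vis <- vapply(codes[[i]], function(ca)
        vapply(codes[[j]], function(cb) info_pair(ca, cb)["vi"], numeric(1)),
        numeric(length(codes[[j]])))
      M[i, j] <- M[j, i] <- mean(vis)
    }
  }
  M
}

# Per-language mean VI of each language against all other languages
# (used for corpus-side samples in two-sample comparisons).
per_language_cross_vi <- function(corpus) {
  M <- language_vi_matrix(corpus_codes(corpus))
  rowMeans(M, na.rm = TRUE)
}

#' Closest reference language to a transmission chain
#'
#' Averages, over a window of chain iterations (default 4-13, skipping
#' the early iterations still dominated by the initial partition) and
#' over each language's speakers, the VI between the chain's systems and
#' that language; returns the language with the smallest mean, breaking
#' ties lexicographically.
#'
#' @param chain a [chain_record()].
#' @param corpus a [speaker_corpus()].
#' @param iteration_window inclusive iteration range, default `c(4, 13)`
#'   (iteration 0 is the initial partition).
#' @return a language id.
#' @export
closest_language <- function(chain, corpus, iteration_window = c(4, 13)) {
  lo <- iteration_window[1]
  hi <- iteration_window[2]
  n_iter <- length(chain$generations) - 1L
  if (lo < 0 || hi > n_iter) {
    stop("iteration window ", lo, "-", hi,
         " exceeds chain length (", n_iter, " iterations)")
  }
  codes <- corpus_codes(corpus)
  means <- rowMeans(vapply(seq(lo, hi), function(it) {
    per_language_vi(label_codes(chain$generations[[it + 1L]]), codes)
  }, numeric(length(codes))))
  names(means)[order(means, names(means))][1] # ties: lexicographic id
}
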