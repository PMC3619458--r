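grid <- build_wcs_array()

split_system <- function(n_first, term1 = "a", term2 = "b") {
  labels <- rep(term2, 330)
  labels[seq_len(n_first)] <- term1
  naming_system(grid, stats::setNames(labels, grid$chip_id))
}

test_that("entropy matches closed forms", {
  expect_equal(entropy(split_system(165)), log(2), tolerance = 1e-12)
  expect_equal(entropy(split_system(330)), 0)
  expect_equal(entropy(split_system(300)),
               -(10 / 11) * log(10 / 11) - (1 / 11) * log(1 / 11),
               tolerance = 1e-12)
  expect_equal(entropy(split_system(300)), 0.3046, tolerance = 1e-3)
  expect_error(entropy(naming_system(grid, character())), "empty")
})

test_that("mutual information: identical, independent, and bounded", {
  ns <- random_partition(grid, 3, seed = 1)
  expect_equal(mutual_information(ns, ns), entropy(ns), tolerance = 1e-12)

  # independent crossing on 4 items: {1,2 | 3,4} vs {1,3 | 2,4}
  g4 <- chip_grid(c("c1", "c2", "c3", "c4"), c(1, 1, 2, 2), c(1, 2, 1, 2))
  a <- naming_system(g4, c(c1 = "x", c2 = "x", c3 = "y", c4 = "y"))
  b <- naming_system(g4, c(c1 = "x", c3 = "x", c2 = "y", c4 = "y"))
  expect_equal(mutual_information(a, b), 0, tolerance = 1e-14)
  expect_equal(variation_of_information(a, b), 2 * log(2), tolerance = 1e-12)

  for (seed in 1:5) {
    p <- random_partition(grid, 3, seed = seed)
    q <- random_partition(grid, 5, seed = seed + 100)
    expect_gte(mutual_information(p, q), -1e-14)
    expect_lte(mutual_information(p, q), min(entropy(p), entropy(q)) + 1e-12)
  }
})

test_that("VI and MI agree with the brute-force contingency oracle", {
  for (seed in 1:10) {
    p <- random_partition(grid, sample(2:6, 1), seed = seed)
    q <- random_partition(grid, sample(2:6, 1), seed = seed + 50)
    o <- info_oracle(p$labels, q$labels)
    expect_equal(mutual_information(p, q), o$mi, tolerance = 1e-12)
    expect_equal(variation_of_information(p, q), o$vi, tolerance = 1e-12)
  }
})

test_that("VI is invariant under term renaming", {
  p <- random_partition(grid, 4, seed = 3)
  renamed <- naming_system(grid, stats::setNames(
    paste0("renamed_", p$labels), names(p$labels)))
  expect_equal(variation_of_information(p, renamed), 0, tolerance = 1e-12)
  q <- random_partition(grid, 3, seed = 4)
  expect_equal(variation_of_information(p, q),
               variation_of_information(renamed, q), tolerance = 1e-12)
})

test_that("VI satisfies the metric axioms on random partition triples", {
  set.seed(20240301)
  for (i in 1:60) {
    p <- random_partition(grid, sample(2:6, 1), seed = 3 * i)
    q <- random_partition(grid, sample(2:6, 1), seed = 3 * i + 1)
    r <- random_partition(grid, sample(2:6, 1), seed = 3 * i + 2)
    vpq <- variation_of_information(p, q)
    vqr <- variation_of_information(q, r)
    vpr <- variation_of_information(p, r)
    expect_gte(vpq, 0)
    expect_equal(vpq, variation_of_information(q, p), tolerance = 1e-12)
    expect_lte(vpr, vpq + vqr + 1e-12)
    expect_lte(vpq, log(330))
  }
})

test_that("VI equals the conditional-entropy decomposition H(A|B) + H(B|A)", {
  for (seed in 1:5) {
    p <- random_partition(grid, 4, seed = seed)
    q <- random_partition(grid, 3, seed = seed + 10)
    o <- info_oracle(p$labels, q$labels)
    hab_given <- (o$ha - o$mi) + (o$hb - o$mi)
    expect_equal(variation_of_information(p, q), hab_given, tolerance = 1e-12)
  }
})

test_that("VI is invariant under joint rotation of both systems", {
  p <- hue_partition(grid, 4, seed = 2)
  q <- random_partition(grid, 3, seed = 6)
  v0 <- variation_of_information(p, q)
  for (s in c(3, 11, 20)) {
    expect_equal(variation_of_information(rotate_hue(p, s), rotate_hue(q, s)),
                 v0, tolerance = 1e-12)
  }
})

test_that("partial systems are compared over commonly labelled chips only", {
  ids <- grid$chip_id
  p <- naming_system(grid, stats::setNames(rep(c("a", "b"), c(100, 100)),
                                           ids[1:200]))
  q <- naming_system(grid, stats::setNames(rep(c("x", "y"), c(75, 75)),
                                           ids[101:250]))
  # common support: ids 101..200
  o <- info_oracle(p$labels, q$labels)
  expect_equal(variation_of_information(p, q), o$vi, tolerance = 1e-12)
  disjoint <- naming_system(grid, stats::setNames(rep("z", 50), ids[281:330]))
  expect_error(variation_of_information(p, disjoint), "no labelled chips|share no")
})

test_that("mean VI to a corpus averages speakers within languages first", {
  ns <- random_partition(grid, 3, seed = 1)
  one <- speaker_corpus(list(l1 = list(s1 = ns)))
  expect_equal(mean_vi_to_corpus(ns, one), 0, tolerance = 1e-12)

  # unbalanced speaker counts must not tilt the language mean
  a1 <- random_partition(grid, 3, seed = 11)
  b1 <- random_partition(grid, 4, seed = 12)
  b2 <- random_partition(grid, 4, seed = 13)
  b3 <- random_partition(grid, 4, seed = 14)
  corpus <- speaker_corpus(list(A = list(s1 = a1),
                                B = list(s1 = b1, s2 = b2, s3 = b3)))
  mean_a <- variation_of_information(ns, a1)
  mean_b <- mean(c(variation_of_information(ns, b1),
                   variation_of_information(ns, b2),
                   variation_of_information(ns, b3)))
  expect_equal(mean_vi_to_corpus(ns, corpus), (mean_a + mean_b) / 2,
               tolerance = 1e-12)

  expect_error(mean_vi_to_corpus(ns, corpus,
                                 language_filter = function(l, spk) FALSE),
               "removed every language")
  expect_equal(mean_vi_to_corpus(ns, corpus,
                                 language_filter = function(l, spk) l == "A"),
               mean_a, tolerance = 1e-12)
})

test_that("corpus pairwise VI matches exhaustive enumeration", {
  corpus <- make_tiny_corpus(grid, k = 3, n_lang = 3, n_spk = 2)
  langs <- corpus$languages
  pair_means <- c()
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    vis <- c()
    for (sa in langs[[pair[1]]]) {
      for (sb in langs[[pair[2]]]) {
        vis <- c(vis, variation_of_information(sa, sb))
      }
    }
    pair_means <- c(pair_means, mean(vis))
  }
  expect_equal(corpus_pairwise_vi(corpus), mean(pair_means), tolerance = 1e-12)

  ns <- random_partition(grid, 3, seed = 5)
  same <- speaker_corpus(list(l1 = list(s1 = ns, s2 = ns),
                              l2 = list(s1 = ns)))
  expect_equal(corpus_pairwise_vi(same), 0, tolerance = 1e-12)
  expect_error(corpus_pairwise_vi(speaker_corpus(list(l1 = list(s1 = ns)))),
               "two languages")

  two <- speaker_corpus(list(l1 = list(s1 = ns),
                             l2 = list(s1 = random_partition(grid, 4, seed = 6))))
  expect_equal(corpus_pairwise_vi(two),
               variation_of_information(ns, two$languages$l2$s1),
               tolerance = 1e-12)
})

test_that("closest_language averages the iteration window per language", {
  set.seed(1)
  learner <- make_exemplar_learner(tau = 0.3, warp = 0.8)
  init <- random_partition(grid, 3, seed = 2)
  chain <- run_chain(init, learner, generations = 13, seed = 3)

  # a language holding the chain's own final system always wins
  final <- chain$generations[[14]]
  corpus <- make_tiny_corpus(grid, k = 3, n_lang = 2, n_spk = 1)
  corpus$languages$self <- list(s1 = final)
  # window of just the final iteration makes the check exact
  expect_equal(closest_language(chain, corpus, iteration_window = c(13, 13)),
               "self")

  # two-language corpus: the smaller window mean wins (hand-checkable)
  c2 <- make_tiny_corpus(grid, k = 4, n_lang = 2, n_spk = 2, seed = 7)
  means <- sapply(names(c2$languages), function(l) {
    mean(sapply(4:13, function(it) {
      mean(sapply(c2$languages[[l]], function(sp)
        variation_of_information(chain$generations[[it + 1]], sp)))
    }))
  })
  expect_equal(closest_language(chain, c2), names(which.min(means)))
  expect_error(closest_language(chain, c2, iteration_window = c(4, 20)),
               "exceeds chain length")
})
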