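grid <- build_wcs_array()

test_that("training sets hold 6k distinct chips with the teacher's labels", {
  ns <- hue_partition(grid, 5, seed = 1)
  ex <- sample_training_set(ns, 5, seed = 2)
  expect_equal(nrow(ex), 30)
  expect_false(anyDuplicated(ex$chip_id) > 0)
  expect_identical(unname(ns$labels[ex$chip_id]), ex$term)

  ex2 <- sample_training_set(ns, 2, seed = 9)
  expect_equal(length(unique(ex2$chip_id)), 12)

  expect_identical(sample_training_set(ns, 3, seed = 7),
                   sample_training_set(ns, 3, seed = 7))
  small <- chip_grid(c("a", "b"), c(1, 1), c(1, 2))
  ns_small <- naming_system(small, c(a = "t1", b = "t2"))
  expect_error(sample_training_set(ns_small, 2), "cannot sample")
})

test_that("the zero-temperature exemplar learner is the nearest-exemplar rule", {
  ns <- hue_partition(grid, 2, seed = 1)
  ex <- sample_training_set(ns, 2, seed = 3)
  learned <- exemplar_learner(ex, grid, ns$terms, tau = 0, seed = 4)
  oracle <- nearest_term_oracle(ex, grid)
  # agreement wherever the oracle has a unique nearest term
  emb <- perceptual_embedding(grid)
  ex_emb <- emb[ex$chip_id, , drop = FALSE]
  unique_nearest <- vapply(seq_len(nrow(grid)), function(i) {
    d <- sqrt(colSums((t(ex_emb) - emb[i, ])^2))
    length(unique(ex$term[d <= min(d) + 1e-12])) == 1
  }, logical(1))
  expect_gt(mean(unique_nearest), 0.9)
  expect_identical(learned$labels[unique_nearest][order(names(learned$labels[unique_nearest]))],
                   oracle[unique_nearest][order(names(oracle[unique_nearest]))])
})

test_that("reconstruction from a 2-band hue partition errs only near boundaries", {
  ns <- hue_partition(grid, 2, seed = 5)
  # one exemplar per term per row keeps every chip close to its band
  ex_ids <- c(chip_id(1:8, 10), chip_id(1:8, 30))
  ex <- data.frame(chip_id = ex_ids, term = unname(ns$labels[ex_ids]))
  learned <- exemplar_learner(ex, grid, ns$terms, tau = 0, seed = 1)
  mism <- names(learned$labels)[learned$labels[names(ns$labels)] != ns$labels]
  mism_cols <- grid$col[match(mism, grid$chip_id)]
  # band boundaries fall after columns 20 and 40
  boundary_cols <- c(20, 21, 40, 1)
  expect_true(all(mism_cols %in% c(0, boundary_cols)))
})

test_that("equidistant exemplars of different terms tie-break uniformly", {
  g4 <- chip_grid(c("left", "right", "mid"), c(4, 4, 4), c(10, 12, 11))
  ex <- data.frame(chip_id = c("left", "right"), term = c("A", "B"))
  picks <- vapply(1:400, function(s) {
    exemplar_learner(ex, g4, c("A", "B"), tau = 0, seed = s)$labels[["mid"]]
  }, character(1))
  expect_gt(mean(picks == "A"), 0.4)
  expect_lt(mean(picks == "A"), 0.6)
})

test_that("a chip coincident with its only nearby example takes its term", {
  ex <- data.frame(chip_id = c("R410", "R425"), term = c("near", "far"))
  learned <- exemplar_learner(ex, grid, c("near", "far"), tau = 0, seed = 1)
  expect_equal(learned$labels[["R410"]], "near")
  expect_error(exemplar_learner(ex[0, ], grid, "t"), "at least one example")
})

test_that("chains record every generation and reproduce bit-for-bit", {
  init <- random_partition(grid, 3, seed = 1)
  learner <- make_exemplar_learner(tau = 0.3, warp = 0.8)
  ch <- run_chain(init, learner, generations = 13, seed = 5, chain_id = "c1")
  expect_length(ch$generations, 14)
  expect_length(ch$training_sets, 13)
  for (g in 1:13) {
    expect_equal(nrow(ch$training_sets[[g]]), 6 * 3)
    expect_true(is_complete(ch$generations[[g + 1]]))
    expect_lte(length(unique(ch$generations[[g + 1]]$labels)), 3)
    # generation g trains on labels from generation g - 1
    prev <- ch$generations[[g]]$labels
    expect_identical(unname(prev[ch$training_sets[[g]]$chip_id]),
                     ch$training_sets[[g]]$term)
  }
  ch2 <- run_chain(init, learner, generations = 13, seed = 5, chain_id = "c1")
  expect_identical(ch, ch2)
  ch3 <- run_chain(init, learner, generations = 13, seed = 6, chain_id = "c1")
  expect_false(identical(ch$generations[[14]]$labels,
                         ch3$generations[[14]]$labels))
})

test_that("a degenerate copy learner gives closed-form dynamics", {
  copy_learner <- function(examples, grid, inventory, seed = NULL) {
    labels <- stats::setNames(rep(inventory[1], nrow(grid)), grid$chip_id)
    labels[examples$chip_id] <- examples$term
    naming_system(grid, labels, inventory)
  }
  init <- hue_partition(grid, 4, seed = 1)
  ch <- run_chain(init, copy_learner, generations = 3, seed = 2)
  for (g in 1:3) {
    ex <- ch$training_sets[[g]]
    sys <- ch$generations[[g + 1]]$labels
    expect_identical(unname(sys[ex$chip_id]), ex$term)
    others <- setdiff(grid$chip_id, ex$chip_id)
    expect_true(all(sys[others] == init$terms[1]))
  }
})

test_that("the experiment design has 30 chains: 20 random + 5 hue + 5 lightness", {
  design <- build_experiment_design(seed = 1)
  expect_equal(nrow(design), 30)
  expect_equal(sum(design$initial_kind == "random"), 20)
  expect_equal(sum(design$initial_kind == "hue"), 5)
  expect_equal(sum(design$initial_kind == "lightness"), 5)
  expect_equal(sum(design$k == 3), 6)
  for (k in 2:6) {
    expect_equal(sum(design$k == k & design$initial_kind == "random"), 4)
    expect_equal(sum(design$k == k & design$initial_kind == "hue"), 1)
  }
  expect_false(anyDuplicated(design$chain_id) > 0)
  expect_true(all(design$seed >= 0 & design$seed < 2^31))
  expect_identical(design, build_experiment_design(seed = 1))
})

test_that("synthetic corpora respect their parameters", {
  corpus <- generate_synthetic_corpus(n_languages = 8, k_range = 2:6,
                                      speakers_per_language = 3,
                                      noise_eps = 0.05, seed = 4)
  expect_length(corpus$languages, 8)
  for (lang in corpus$languages) {
    expect_length(lang, 3)
    terms <- lang[[1]]$terms
    expect_gte(length(terms), 2)
    expect_lte(length(terms), 6)
    for (sp in lang) {
      expect_true(is_complete(sp))
      expect_identical(sp$terms, terms)
    }
  }
  expect_error(generate_synthetic_corpus(noise_eps = 0.7, n_languages = 1),
               "noise_eps")
})

test_that("zero label noise makes all speakers of a language identical", {
  corpus <- generate_synthetic_corpus(n_languages = 3, speakers_per_language = 4,
                                      noise_eps = 0, seed = 11)
  for (lang in corpus$languages) {
    for (sp in lang[-1]) expect_identical(sp$labels, lang[[1]]$labels)
  }
})

test_that("within-language speaker variation is below cross-language distance", {
  corpus <- generate_synthetic_corpus(n_languages = 10, speakers_per_language = 4,
                                      noise_eps = 0.05, seed = 21)
  within <- mean(sapply(corpus$languages, function(lang) {
    pairs <- utils::combn(length(lang), 2)
    mean(apply(pairs, 2, function(p)
      variation_of_information(lang[[p[1]]], lang[[p[2]]])))
  }))
  between <- corpus_pairwise_vi(corpus)
  expect_lt(within, between)
})

test_that("corpus generation is reproducible and seed-sensitive", {
  a <- generate_synthetic_corpus(n_languages = 3, speakers_per_language = 2,
                                 seed = 5)
  b <- generate_synthetic_corpus(n_languages = 3, speakers_per_language = 2,
                                 seed = 5)
  expect_identical(a, b)
  d <- generate_synthetic_corpus(n_languages = 3, speakers_per_language = 2,
                                 seed = 6)
  expect_false(identical(a, d))
})
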