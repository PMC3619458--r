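# Iterated-learning chain simulation. Each generation sees 6*k labelled
# example chips sampled from the previous generation's system, learns
# from them, and labels the full array; the resulting system trains the
# next generation. A parameterised exemplar learner stands in for human
# participants, and a corpus generator emulates WCS-scale reference
# data, so the whole analysis pipeline is testable end to end without
# human data.

#' Construct a chain record
#'
#' Stores the full history of one transmission chain: the initial
#' partition (iteration 0), every learner generation's complete system,
#' and the training examples passed between generations.
#'
#' @param chain_id identifier string.
#' @param k term-inventory size (2-6).
#' @param initial_kind one of `"hue"`, `"lightness"`, `"random"` (or
#'   `"custom"`).
#' @param generations list of [naming_system()]s, element 1 = iteration 0.
#' @param training_sets list of training-example data frames
#'   (`chip_id`, `term`), one per learner generation.
#' @param seed the seed the chain was run with.
#' @return an object of class `chain_record`.
#' @export
chain_record <- function(chain_id, k, initial_kind, generations,
                         training_sets, seed = NA_integer_) {
  structure(list(chain_id = as.character(chain_id), k = as.integer(k),
                 initial_kind = initial_kind, generations = generations,
                 training_sets = training_sets, seed = seed),
            class = "chain_record")
}

#' @export
print.chain_record <- function(x, ...) {
  cat(sprintf("<chain_record '%s': k=%d, %s initial, %d learner generations>\n",
              x$chain_id, x$k, x$initial_kind, length(x$generations) - 1L))
  invisible(x)
}

#' Sample a training set from a naming system
#'
#' Draws `6 * k` distinct chips uniformly at random without replacement
#' from the full array and pairs each with its label under `ns` -- the
#' data one generation passes to the next.
#'
#' @param ns a complete [naming_system()].
#' @param k term-inventory size; the sample has `6 * k` examples.
#' @param seed integer seed.
#' @return a data frame with columns `chip_id`, `term`.
#' @export
sample_training_set <- function(ns, k, seed = NULL) {
  if (!is_complete(ns)) stop("training data require a complete labelling")
  n <- 6L * as.integer(k)
  if (n > nrow(ns$grid)) {
    stop("cannot sample ", n, " distinct chips from a grid of ", nrow(ns$grid))
  }
  ids <- with_seed(seed, sample(ns$grid$chip_id, n))
  data.frame(chip_id = ids, term = unname(ns$labels[ids]),
             stringsAsFactors = FALSE)
}

#' Exemplar-based learner
#'
#' Labels every chip of the grid by similarity to the training
#' exemplars in perceptual space: chip `c` takes term `t` with
#' probability proportional to
#' `sum over examples e with term t of exp(-d(c, e) / tau)`,
#' where `d` is Euclidean distance in the [perceptual_embedding()] with
#' parameters `rho` and `warp`. As `tau -> 0` this becomes the
#' deterministic nearest-exemplar rule (distance ties broken uniformly
#' at random); `tau = 0` selects that rule exactly. Only terms present
#' in the examples can appear in the output, so the inventory is an
#' upper bound and terms may die out along a chain.
#'
#' @param examples data frame with columns `chip_id`, `term`.
#' @param grid a [chip_grid()].
#' @param inventory allowed term inventory.
#' @param tau softmax temperature in perceptual-distance units
#'   (default 0.3).
#' @param rho,warp embedding parameters, see [perceptual_embedding()].
#' @param seed integer seed.
#' @return a complete [naming_system()].
#' @export
exemplar_learner <- function(examples, grid, inventory, tau = 0.3,
                             rho = 3, warp = 0, seed = NULL) {
  if (!nrow(examples)) stop("exemplar learner needs at least one example")
  if (length(setdiff(examples$term, inventory))) {
    stop("examples use terms outside the inventory")
  }
  emb <- perceptual_embedding(grid, rho = rho, warp = warp)
  ex_emb <- emb[examples$chip_id, , drop = FALSE]
  # n_chip x n_example Euclidean distances
  d2 <- outer(rowSums(emb^2), rowSums(ex_emb^2), `+`) -
    2 * tcrossprod(emb, ex_emb)
  D <- sqrt(pmax(d2, 0))
  terms_used <- sort(unique(examples$term))
  tf <- factor(examples$term, levels = terms_used)
  labels <- with_seed(seed, {
    if (tau > 0) {
      # per-chip softmax over exemplars, aggregated by term; row minimum
      # subtracted for numerical stability (softmax-invariant)
      W <- exp(-(D - apply(D, 1, min)) / tau)
      score <- W %*% outer(as.integer(tf), seq_along(terms_used), `==`)
      idx <- apply(score, 1, function(p) sample.int(length(p), 1, prob = p))
    } else {
      idx <- apply(D, 1, function(d) {
        cand <- unique(as.integer(tf)[d <= min(d) + 1e-12])
        if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
      })
    }
    terms_used[idx]
  })
  naming_system(grid, stats::setNames(labels, grid$chip_id), inventory)
}

#' Build a learner function with fixed parameters
#'
#' Convenience factory returning a learner of the signature expected by
#' [run_chain()]: `function(examples, grid, inventory, seed)`.
#'
#' @inheritParams exemplar_learner
#' @return a learner function.
#' @export
make_exemplar_learner <- function(tau = 0.3, rho = 3, warp = 0) {
  function(examples, grid, inventory, seed = NULL) {
    exemplar_learner(examples, grid, inventory,
                     tau = tau, rho = rho, warp = warp, seed = seed)
  }
}

#' Run one iterated-learning chain
#'
#' Starting from a complete initial partition, repeatedly samples a
#' `6 * k` training set from the current system and hands it to the
#' learner, whose complete response becomes the next generation.
#' Sub-seeds for each sampling and learning step are derived from
#' `seed` and the chain id, so every chain is independently
#' reproducible.
#'
#' @param initial a complete [naming_system()] (iteration 0).
#' @param learner `function(examples, grid, inventory, seed)` returning
#'   a complete [naming_system()], e.g. from [make_exemplar_learner()].
#' @param generations number of learner generations (default 13).
#' @param seed integer master seed.
#' @param chain_id identifier (default `"chain"`).
#' @param initial_kind stored metadata (default `"custom"`).
#' @return a [chain_record()] holding `generations + 1` systems.
#' @export
run_chain <- function(initial, learner, generations = 13, seed = NULL,
                      chain_id = "chain", initial_kind = "custom") {
  if (!is_complete(initial)) stop("the initial partition must be complete")
  stopifnot(generations >= 1)
  k <- length(initial$terms)
  systems <- vector("list", generations + 1L)
  systems[[1]] <- initial
  training <- vector("list", generations)
  current <- initial
  for (g in seq_len(generations)) {
    ex <- sample_training_set(current, k,
                              seed = derive_seed(seed %||% 0L, chain_id, g, "sample"))
    current <- learner(ex, initial$grid, initial$terms,
                       seed = derive_seed(seed %||% 0L, chain_id, g, "learn"))
    if (!is_complete(current)) stop("learner returned an incomplete system")
    training[[g]] <- ex
    systems[[g + 1L]] <- current
  }
  chain_record(chain_id, k, initial_kind, systems, training,
               seed %||% NA_integer_)
}

#' The 30-chain experimental design
#'
#' For each inventory size k = 2, ..., 6: four chains with random
#' initial partitions, one with a hue partition and one with a
#' lightness partition -- 30 chains in all, 20 of them random. Each
#' configuration carries its own seed derived from the master seed.
#'
#' @param seed integer master seed.
#' @return a data frame with columns `chain_id`, `k`, `initial_kind`,
#'   `seed` (30 rows).
#' @export
build_experiment_design <- function(seed = NULL) {
  rows <- list()
  for (k in 2:6) {
    for (r in 1:4) {
      rows[[length(rows) + 1L]] <-
        data.frame(chain_id = sprintf("random-k%d-%d", k, r), k = k,
                   initial_kind = "random", stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(chain_id = sprintf("hue-k%d", k), k = k,
                 initial_kind = "hue", stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(chain_id = sprintf("lightness-k%d", k), k = k,
                 initial_kind = "lightness", stringsAsFactors = FALSE)
  }
  design <- do.call(rbind, rows)
  design$seed <- vapply(design$chain_id,
                        function(id) derive_seed(seed %||% 0L, "design", id),
                        integer(1))
  rownames(design) <- NULL
  design
}

#' Simulate chains for a design table
#'
#' Builds each row's initial partition ([random_partition()],
#' [hue_partition()] or [lightness_partition()]) and runs the chain.
#'
#' @param design a design data frame, see [build_experiment_design()].
#' @param grid a [chip_grid()].
#' @param learner learner function, see [run_chain()].
#' @param generations learner generations per chain (default 13).
#' @return a named list of [chain_record()]s.
#' @export
simulate_design <- function(design, grid, learner, generations = 13) {
  chains <- lapply(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    initial <- switch(row$initial_kind,
      random = random_partition(grid, row$k, seed = row$seed),
      hue = hue_partition(grid, row$k, seed = row$seed),
      lightness = lightness_partition(grid, row$k),
      stop("unknown initial_kind: ", row$initial_kind))
    run_chain(initial, learner, generations = generations, seed = row$seed,
              chain_id = row$chain_id, initial_kind = row$initial_kind)
  })
  names(chains) <- design$chain_id
  chains
}

# neighbour indices (grid rows) for every chip: hue neighbours wrap
# around the 40-column circle; lightness neighbours stay in range;
# achromatic chips neighbour each other along the lightness column
grid_neighbours <- function(grid) {
  idx <- stats::setNames(seq_len(nrow(grid)), grid$chip_id)
  lapply(seq_len(nrow(grid)), function(i) {
    r <- grid$row[i]; h <- grid$col[i]
    ids <- character(0)
    if (h >= 1L) {
      ids <- c(ids, chip_id(r, (h %% N_HUES) + 1L),
               chip_id(r, ((h - 2L) %% N_HUES) + 1L))
      if (r > 1L) ids <- c(ids, chip_id(r - 1L, h))
      if (r < 8L) ids <- c(ids, chip_id(r + 1L, h))
    } else {
      if (r > 0L) ids <- c(ids, chip_id(r - 1L, 0L))
      if (r < 9L) ids <- c(ids, chip_id(r + 1L, 0L))
    }
    unname(idx[ids])
  })
}

# k near-evenly spread anchor boundaries (of the 6 defined alongside
# the warped embedding), starting from a given anchor
pick_anchor_boundaries <- function(k, start) {
  n <- length(ANCHOR_BOUNDARIES)
  sort(ANCHOR_BOUNDARIES[((start - 1L + floor(n * (seq_len(k) - 1) / k)) %% n) + 1L])
}

# template: k contiguous hue bands with boundaries on anchor columns,
# optionally reserving one term for the darkest rows
anchored_template <- function(grid, k, lightness_split, seed) {
  with_seed(seed, {
    terms <- default_terms(k)
    kb <- if (lightness_split && k > 2) k - 1L else k
    bounds <- pick_anchor_boundaries(kb, sample.int(length(ANCHOR_BOUNDARIES), 1))
    # band index of each chromatic column: boundary b separates col b and b+1
    band_of_col <- findInterval(seq_len(N_HUES), bounds + 1L) %% kb + 1L
    band <- ifelse(grid$col == 0L,
                   sample.int(kb, 1), band_of_col[pmax(grid$col, 1L)])
    labels <- terms[band]
    if (lightness_split) {
      labels[grid$row >= 7L] <- terms[k] # darkest rows get their own term
    }
    naming_system(grid, stats::setNames(labels, grid$chip_id), terms)
  })
}

#' Generate a synthetic multi-language naming corpus
#'
#' Emulates a WCS-scale reference corpus. Each language draws a term
#' count from `k_range` and a template system made of contiguous hue
#' bands whose boundaries sit on the perceptual anchor columns of the
#' warped hue circle (see [perceptual_embedding()]); with probability
#' `p_lightness` one term instead covers the darkest lightness rows
#' (a dark/light stripe). Each speaker then reproduces the template
#' with per-chip label noise: with probability `noise_eps` a chip takes
#' the template label of a uniformly chosen neighbouring chip, so
#' speaker variation concentrates on category boundaries.
#'
#' @param n_languages number of languages (default 110, the WCS scale).
#' @param k_range candidate term counts (default 2:6).
#' @param speakers_per_language speakers per language (default 10).
#' @param noise_eps per-chip boundary-noise probability in `[0, 0.5)`
#'   (default 0.05).
#' @param seed integer master seed.
#' @param grid a [chip_grid()] (default the 330-chip array).
#' @param p_lightness probability a language reserves a term for the
#'   darkest rows (default 0.3).
#' @param anchor_offset rotate every template's hue bands by this many
#'   columns; lets a second corpus be built with disjoint anchor
#'   structure (default 0).
#' @return a [speaker_corpus()].
#' @export
generate_synthetic_corpus <- function(n_languages = 110, k_range = 2:6,
                                      speakers_per_language = 10,
                                      noise_eps = 0.05, seed = NULL,
                                      grid = build_wcs_array(),
                                      p_lightness = 0.3,
                                      anchor_offset = 0) {
  if (noise_eps < 0 || noise_eps >= 0.5) stop("noise_eps must be in [0, 0.5)")
  stopifnot(n_languages >= 1, speakers_per_language >= 1,
            all(k_range >= 2), all(k_range <= 6))
  nb <- grid_neighbours(grid)
  nchip <- nrow(grid)
  languages <- list()
  for (li in seq_len(n_languages)) {
    lang_seed <- derive_seed(seed %||% 0L, "corpus", li)
    template <- with_seed(lang_seed, {
      k <- if (length(k_range) == 1) k_range else sample(k_range, 1)
      light <- stats::runif(1) < p_lightness
      anchored_template(grid, k, light, seed = NULL)
    })
    if (anchor_offset != 0) template <- rotate_hue(template, anchor_offset)
    tmpl_labels <- aligned_labels(template)
    speakers <- list()
    for (si in seq_len(speakers_per_language)) {
      labels <- with_seed(derive_seed(lang_seed, "speaker", si), {
        out <- tmpl_labels
        flip <- which(stats::runif(nchip) < noise_eps)
        if (length(flip)) {
          pick <- vapply(nb[flip], function(v) v[sample.int(length(v), 1)],
                         integer(1))
          out[flip] <- tmpl_labels[pick]
        }
        out
      })
      speakers[[sprintf("s%02d", si)]] <-
        naming_system(grid, stats::setNames(labels, grid$chip_id),
                      template$terms)
    }
    languages[[sprintf("L%03d", li)]] <- speakers
  }
  speaker_corpus(languages)
}
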