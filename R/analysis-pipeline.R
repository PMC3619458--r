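# Orchestration of the three analyses: convergence of chains towards a
# reference corpus, the rotation null control along the hue dimension,
# and the comparison against a second (control) corpus; plus the t
# statistics reported for each.

#' Paired t test
#'
#' Standard paired t on two equal-length samples, returning the
#' statistic, degrees of freedom (`n - 1`) and two-sided p value. The
#' degenerate case of identical samples returns `t = 0`; a non-zero
#' constant difference (zero variance, non-zero mean) is an error.
#'
#' @param a,b paired numeric vectors, `n >= 2`.
#' @return a list with elements `t`, `df`, `p`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = length(d) - 1L, p = 1))
    stop("degenerate paired sample: constant non-zero differences")
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Two-sample t test with pooled variance
#'
#' By default uses the classical pooled-variance statistic with
#' `df = n1 + n2 - 2` (so samples of 20 chains and 110 languages give
#' 128 degrees of freedom); set `welch = TRUE` for the Welch
#' correction.
#'
#' @param a,b numeric samples, each `n >= 2`.
#' @param welch use Welch's unequal-variance correction (default
#'   `FALSE`).
#' @return a list with elements `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1))
    }
    stop("degenerate two-sample input: both samples constant")
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Convergence of chains towards a reference corpus
#'
#' For every chain and every iteration (0 = the initial partition), the
#' two-level mean VI to the reference corpus is computed
#' ([mean_vi_to_corpus()]); the curve of per-iteration means across
#' chains is returned together with a paired first-versus-last t test,
#' a Spearman trend test on the averaged curve, and (optionally) the
#' corpus-internal baseline [corpus_pairwise_vi()] plus a pooled
#' two-sample t comparing the final systems' VI scores with the
#' per-language corpus scores.
#'
#' @param chains list of [chain_record()]s sharing a generation count.
#' @param reference a [speaker_corpus()].
#' @param language_filter optional language predicate, see
#'   [mean_vi_to_corpus()].
#' @param baseline also compute the corpus-internal baseline and the
#'   final-versus-corpus two-sample test (quadratic in corpus size;
#'   default `TRUE`).
#' @param welch Welch correction for the two-sample test (default
#'   `FALSE`).
#' @return an object of class `convergence_curve`: list with `curve`
#'   (data frame `iteration`, `mean_vi`, `sd_vi`, `n`), `per_chain`
#'   (chains x iterations matrix), `first_vs_last`, `trend`, and if
#'   requested `baseline` and `final_vs_corpus`.
#' @export
convergence_analysis <- function(chains, reference, language_filter = NULL,
                                 baseline = TRUE, welch = FALSE) {
  if (!length(chains)) stop("no chains supplied")
  n_gen <- unique(vapply(chains, function(ch) length(ch$generations), integer(1)))
  if (length(n_gen) != 1) stop("chains must share a generation count")
  langs <- reference$languages
  if (!is.null(language_filter)) {
    keep <- vapply(names(langs),
                   function(l) isTRUE(language_filter(l, langs[[l]])),
                   logical(1))
    langs <- langs[keep]
    if (!length(langs)) stop("language_filter removed every language")
  }
  codes <- lapply(langs, function(spk) lapply(spk, label_codes))
  V <- t(vapply(chains, function(ch) {
    vapply(ch$generations, function(ns)
      mean(per_language_vi(label_codes(ns), codes)), numeric(1))
  }, numeric(n_gen)))
  rownames(V) <- vapply(chains, `[[`, character(1), "chain_id")
  colnames(V) <- seq_len(n_gen) - 1L
  curve <- data.frame(iteration = seq_len(n_gen) - 1L,
                      mean_vi = colMeans(V),
                      sd_vi = apply(V, 2, stats::sd),
                      n = nrow(V))
  rownames(curve) <- NULL
  trend_ct <- suppressWarnings(
    stats::cor.test(curve$iteration, curve$mean_vi, method = "spearman"))
  out <- list(curve = curve, per_chain = V,
              first_vs_last = if (nrow(V) >= 2) paired_t(V[, 1], V[, n_gen]),
              trend = list(rho = unname(trend_ct$estimate),
                           p = trend_ct$p.value))
  if (baseline) {
    M <- language_vi_matrix(codes)
    out$baseline <- mean(M[upper.tri(M)])
    out$final_vs_corpus <- two_sample_t(V[, n_gen],
                                        rowMeans(M, na.rm = TRUE),
                                        welch = welch)
  }
  class(out) <- "convergence_curve"
  out
}

#' @export
print.convergence_curve <- function(x, ...) {
  n <- nrow(x$curve)
  cat(sprintf("<convergence_curve: %d chains, iterations 0-%d>\n",
              x$curve$n[1], x$curve$iteration[n]))
  cat(sprintf("  mean VI: %.4f (iteration 0) -> %.4f (iteration %d)\n",
              x$curve$mean_vi[1], x$curve$mean_vi[n], x$curve$iteration[n]))
  if (!is.null(x$first_vs_last)) {
    cat(sprintf("  first vs last: t(%d) = %.3f, p = %.3g; Spearman rho = %.3f\n",
                x$first_vs_last$df, x$first_vs_last$t, x$first_vs_last$p,
                x$trend$rho))
  }
  if (!is.null(x$baseline)) {
    cat(sprintf("  corpus-internal baseline VI: %.4f; final vs corpus t(%d) = %.3f, p = %.3g\n",
                x$baseline, x$final_vs_corpus$df, x$final_vs_corpus$t,
                x$final_vs_corpus$p))
  }
  invisible(x)
}

#' @export
plot.convergence_curve <- function(x, ...) {
  with(x$curve, {
    graphics::plot(iteration, mean_vi, type = "b", pch = 16,
                   xlab = "iteration", ylab = "mean VI to reference (nats)",
                   ylim = range(mean_vi - sd_vi, mean_vi + sd_vi), ...)
    graphics::arrows(iteration, mean_vi - sd_vi, iteration, mean_vi + sd_vi,
                     angle = 90, code = 3, length = 0.03)
  })
  if (!is.null(x$baseline)) graphics::abline(h = x$baseline, lty = 2)
  invisible(x)
}

#' Rotation null control
#'
#' Rotates each final system 0 to `max_steps` columns along the hue
#' circle and recomputes its mean VI to the reference corpus. A genuine
#' hue-structure match is destroyed by rotation, so the profile should
#' be minimised at offset 0; paired t tests compare offset 0 against
#' the landmark offsets (defaults: quarter 5, three-quarter 15, and
#' maximum 20 of the tested range).
#'
#' @param finals list of complete [naming_system()]s (chain finals).
#' @param reference a [speaker_corpus()].
#' @param max_steps largest rotation offset (default 20).
#' @param landmarks named offsets tested against offset 0.
#' @param language_filter optional language predicate.
#' @return an object of class `rotation_profile`: list with `profile`
#'   (data frame `offset`, `mean_vi`, `sd_vi`), `per_system` (systems x
#'   offsets matrix) and `tests` (named list of paired t results; a
#'   negative t means offset 0 fits better).
#' @export
rotation_analysis <- function(finals, reference, max_steps = 20,
                              landmarks = c(quarter = 5, three_quarter = 15,
                                            maximum = 20),
                              language_filter = NULL) {
  if (!length(finals)) stop("no final systems supplied")
  langs <- reference$languages
  if (!is.null(language_filter)) {
    keep <- vapply(names(langs),
                   function(l) isTRUE(language_filter(l, langs[[l]])),
                   logical(1))
    langs <- langs[keep]
    if (!length(langs)) stop("language_filter removed every language")
  }
  codes <- lapply(langs, function(spk) lapply(spk, label_codes))
  offsets <- 0:max_steps
  V <- t(vapply(finals, function(ns) {
    vapply(offsets, function(s)
      mean(per_language_vi(label_codes(rotate_hue(ns, s)), codes)),
      numeric(1))
  }, numeric(length(offsets))))
  colnames(V) <- offsets
  landmarks <- landmarks[landmarks >= 1 & landmarks <= max_steps]
  tests <- if (nrow(V) >= 2) {
    lapply(landmarks, function(s) paired_t(V[, 1], V[, s + 1]))
  } else {
    list()
  }
  out <- list(profile = data.frame(offset = offsets,
                                   mean_vi = colMeans(V),
                                   sd_vi = apply(V, 2, stats::sd)),
              per_system = V, tests = tests)
  class(out) <- "rotation_profile"
  out
}

#' @export
print.rotation_profile <- function(x, ...) {
  cat(sprintf("<rotation_profile: %d systems, offsets 0-%d>\n",
              nrow(x$per_system), max(x$profile$offset)))
  cat(sprintf("  mean VI at offset 0: %.4f; minimum at offset %d\n",
              x$profile$mean_vi[1],
              x$profile$offset[which.min(x$profile$mean_vi)]))
  for (nm in names(x$tests)) {
    cat(sprintf("  offset 0 vs %s: t(%d) = %.3f, p = %.3g\n", nm,
                x$tests[[nm]]$df, x$tests[[nm]]$t, x$tests[[nm]]$p))
  }
  invisible(x)
}

#' @export
plot.rotation_profile <- function(x, ...) {
  with(x$profile, graphics::plot(offset, mean_vi, type = "b", pch = 16,
                                 xlab = "rotation offset (hue columns)",
                                 ylab = "mean VI to reference (nats)", ...))
  invisible(x)
}

#' Compare chain finals against a second (control) corpus
#'
#' Computes each final system's mean VI to the control corpus and each
#' control speaker's mean VI to the other control speakers, then runs
#' a pooled two-sample t test between the two sets of scores (degrees
#' of freedom `n_finals + n_speakers - 2`). A significantly positive t
#' says the chains remained farther from the control corpus than its
#' own speakers are from each other.
#'
#' @param finals list of complete [naming_system()]s.
#' @param corpus the control [speaker_corpus()].
#' @param welch Welch correction (default `FALSE`).
#' @return a list with `final_vi` (per final), `internal_vi` (per
#'   control speaker), `internal_mean`, and `test`.
#' @export
second_corpus_comparison <- function(finals, corpus, welch = FALSE) {
  codes <- lapply(corpus$languages, function(spk) lapply(spk, label_codes))
  final_vi <- vapply(finals, function(ns)
    mean(per_language_vi(label_codes(ns), codes)), numeric(1))
  flat <- unlist(codes, recursive = FALSE)
  S <- length(flat)
  if (S < 2) stop("control corpus needs at least two speakers")
  D <- matrix(0, S, S)
  for (i in seq_len(S - 1)) {
    for (j in seq(i + 1, S)) {
      D[i, j] <- D[j, i] <- info_pair(flat[[i]], flat[[j]])["vi"]
    }
  }
  internal <- rowSums(D) / (S - 1)
  list(final_vi = final_vi, internal_vi = internal,
       internal_mean = mean(D[upper.tri(D)]),
       test = two_sample_t(final_vi, internal, welch = welch))
}

#' Default configuration for a full study
#'
#' Returns the study conditions as a named list; any element can be
#' overridden via `...`. The learner is the exemplar learner with a
#' warped (perceptually anchored) hue circle, the reference corpus is
#' generated at WCS scale (110 languages, 10 speakers), and the control
#' corpus is a single tightly coherent 6-term language of 9 speakers
#' with offset anchor structure.
#'
#' @param ... overrides of individual defaults.
#' @return a named list.
#' @export
study_config <- function(...) {
  cfg <- list(
    n_languages = 110, speakers_per_language = 10, noise_eps = 0.05,
    k_range = 2:6, p_lightness = 0.3,
    tau = 0.3, rho = 3, warp = 0.8,
    generations = 13, max_steps = 20,
    second_n_speakers = 9, second_k = 6, second_noise_eps = 0.02,
    second_anchor_offset = 2,
    welch = FALSE)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full study
#'
#' Generates the reference and control corpora, simulates the 30-chain
#' design, and runs the three analyses on the 20 random-initial chains:
#' convergence to the reference corpus, the rotation null control of
#' the finals, and the second-corpus comparison. Everything is
#' reproducible from `(config, seed)`; if `out` is given, the chain
#' systems, curves, profile and a JSON summary are also written there.
#'
#' @param config a [study_config()] list.
#' @param seed integer master seed.
#' @param out optional output directory.
#' @return an object of class `study_report`.
#' @export
run_full_study <- function(config = study_config(), seed = 1, out = NULL) {
  grid <- build_wcs_array()
  reference <- generate_synthetic_corpus(
    n_languages = config$n_languages, k_range = config$k_range,
    speakers_per_language = config$speakers_per_language,
    noise_eps = config$noise_eps, seed = derive_seed(seed, "reference"),
    grid = grid, p_lightness = config$p_lightness)
  control <- generate_synthetic_corpus(
    n_languages = 1, k_range = config$second_k,
    speakers_per_language = config$second_n_speakers,
    noise_eps = config$second_noise_eps, seed = derive_seed(seed, "control"),
    grid = grid, p_lightness = 0,
    anchor_offset = config$second_anchor_offset)
  design <- build_experiment_design(seed)
  learner <- make_exemplar_learner(tau = config$tau, rho = config$rho,
                                   warp = config$warp)
  chains <- simulate_design(design, grid, learner,
                            generations = config$generations)
  random_chains <- chains[design$chain_id[design$initial_kind == "random"]]
  finals <- lapply(random_chains, function(ch)
    ch$generations[[length(ch$generations)]])
  convergence <- convergence_analysis(random_chains, reference,
                                      welch = config$welch)
  rotation <- rotation_analysis(finals, reference,
                                max_steps = config$max_steps)
  second <- second_corpus_comparison(finals, control, welch = config$welch)
  report <- structure(list(config = config, seed = seed, design = design,
                           chains = chains, reference = reference,
                           control = control, convergence = convergence,
                           rotation = rotation, second = second),
                      class = "study_report")
  if (!is.null(out)) write_study_report(report, out)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report: %d chains (%d random), seed %d>\n",
              nrow(x$design), sum(x$design$initial_kind == "random"), x$seed))
  print(x$convergence)
  print(x$rotation)
  cat(sprintf("  control corpus: final VI %.4f vs internal %.4f, t(%d) = %.3f, p = %.3g\n",
              mean(x$second$final_vi), x$second$internal_mean,
              x$second$test$df, x$second$test$t, x$second$test$p))
  invisible(x)
}

#' Write study outputs to a directory
#'
#' Emits `convergence.tsv` (per-chain, per-iteration mean VI),
#' `rotation.tsv` (per-system, per-offset VI), `chains.tsv` (every
#' generation's labelling) with `manifest.json`, and `summary.json`
#' holding the headline statistics.
#'
#' @param report a `study_report`.
#' @param out output directory (created if absent).
#' @return `out`, invisibly.
#' @export
write_study_report <- function(report, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  V <- report$convergence$per_chain
  conv <- data.frame(chain_id = rownames(V)[row(V)],
                     iteration = as.integer(colnames(V))[col(V)],
                     mean_vi = as.vector(V))
  conv <- conv[order(conv$chain_id, conv$iteration), ]
  utils::write.table(conv, file.path(out, "convergence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  R <- report$rotation$per_system
  rot <- data.frame(chain_id = rownames(R)[row(R)],
                    offset = as.integer(colnames(R))[col(R)],
                    mean_vi = as.vector(R))
  rot <- rot[order(rot$chain_id, rot$offset), ]
  utils::write.table(rot, file.path(out, "rotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_chain_table(report$chains, file.path(out, "chains.tsv"),
                    manifest = file.path(out, "manifest.json"))
  summary <- list(
    seed = report$seed,
    n_chains = nrow(report$design),
    n_random_chains = sum(report$design$initial_kind == "random"),
    generations = report$config$generations,
    convergence = list(
      first_mean_vi = report$convergence$curve$mean_vi[1],
      last_mean_vi = utils::tail(report$convergence$curve$mean_vi, 1),
      baseline = report$convergence$baseline,
      first_vs_last = report$convergence$first_vs_last,
      final_vs_corpus = report$convergence$final_vs_corpus,
      trend = report$convergence$trend),
    rotation = list(profile = report$rotation$profile$mean_vi,
                    tests = report$rotation$tests),
    second_corpus = list(final_mean = mean(report$second$final_vi),
                         internal_mean = report$second$internal_mean,
                         test = report$second$test))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Read / write chain tables
#'
#' Chains serialize as a TSV with header
#' `chain_id<TAB>iteration<TAB>chip_id<TAB>term` plus a JSON manifest
#' recording each chain's `k`, `initial_kind` and seed. Training sets
#' are not serialized; re-reading reconstructs every generation's
#' system with empty training records.
#'
#' @param chains named list of [chain_record()]s.
#' @param path TSV path.
#' @param manifest JSON manifest path (default alongside `path`).
#' @return `read_chain_table`: a named list of [chain_record()]s.
#' @export
write_chain_table <- function(chains, path,
                              manifest = paste0(path, ".manifest.json")) {
  rows <- list()
  for (ch in chains) {
    for (g in seq_along(ch$generations)) {
      ns <- ch$generations[[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        chain_id = ch$chain_id, iteration = g - 1L,
        chip_id = names(ns$labels), term = unname(ns$labels),
        stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- lapply(chains, function(ch)
    list(chain_id = ch$chain_id, k = ch$k, initial_kind = ch$initial_kind,
         seed = ch$seed, generations = length(ch$generations) - 1L))
  names(meta) <- vapply(chains, `[[`, character(1), "chain_id")
  jsonlite::write_json(meta, manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @param grid the [chip_grid()] the chains label.
#' @rdname write_chain_table
#' @export
read_chain_table <- function(path, grid,
                             manifest = paste0(path, ".manifest.json")) {
  tab <- utils::read.delim(path, colClasses = c("character", "integer",
                                                "character", "character"))
  meta <- jsonlite::read_json(manifest)
  chains <- lapply(meta, function(m) {
    ctab <- tab[tab$chain_id == m$chain_id, ]
    terms <- default_terms(m$k)
    gens <- lapply(sort(unique(ctab$iteration)), function(it) {
      gt <- ctab[ctab$iteration == it, ]
      naming_system(grid, stats::setNames(gt$term, gt$chip_id), terms)
    })
    chain_record(m$chain_id, m$k, m$initial_kind, gens,
                 vector("list", length(gens) - 1L),
                 m$seed %||% NA_integer_)
  })
  names(chains) <- names(meta)
  chains
}
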