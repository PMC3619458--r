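# Naming systems: partitions (possibly partial) of a chip grid into
# colour-term categories, plus the initial-partition generators used to
# seed transmission chains, the hue-rotation operator, and the
# minority-term rule.

#' Construct a naming system
#'
#' A naming system assigns a colour term to each (labelled) chip of a
#' grid; it is a clustering of the chip set. Partial labellings are
#' allowed, to represent aggregate field data where some chips were
#' never named.
#'
#' @param grid a [chip_grid()].
#' @param labels named character vector, names are chip ids of `grid`,
#'   values are terms.
#' @param terms the allowed term inventory; defaults to the terms used.
#' @return an object of class `naming_system`.
#' @export
naming_system <- function(grid, labels, terms = NULL) {
  stopifnot(inherits(grid, "chip_grid"))
  labels <- labels[!is.na(labels)]
  if (length(labels) && is.null(names(labels))) {
    stop("labels must be a named character vector (names = chip ids)")
  }
  unknown <- setdiff(names(labels), grid$chip_id)
  if (length(unknown)) {
    stop("labels refer to chips absent from the grid: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  used <- unique(unname(labels))
  terms <- as.character(terms %||% sort(used))
  if (length(setdiff(used, terms))) {
    stop("labels use terms outside the inventory: ",
         paste(setdiff(used, terms), collapse = ", "))
  }
  structure(list(grid = grid,
                 labels = vapply(labels, as.character, character(1)),
                 terms = terms),
            class = "naming_system")
}

#' @export
print.naming_system <- function(x, ...) {
  cat(sprintf("<naming_system: %d/%d chips labelled, %d-term inventory (%d used)>\n",
              length(x$labels), nrow(x$grid), length(x$terms),
              length(unique(x$labels))))
  invisible(x)
}

#' Is every chip of the grid labelled?
#'
#' @param ns a [naming_system()].
#' @return logical flag.
#' @export
is_complete <- function(ns) {
  length(ns$labels) == nrow(ns$grid) && setequal(names(ns$labels), ns$grid$chip_id)
}

# labels aligned to grid order; NA for unlabelled chips
aligned_labels <- function(ns) {
  unname(ns$labels[ns$grid$chip_id])
}

# balanced contiguous allocation of n items into k groups; remainder
# goes to the leftmost groups, so sizes are deterministic
balanced_sizes <- function(n, k) {
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  as.integer(sizes)
}

check_k <- function(k) {
  if (length(k) != 1 || k < 2 || k > 6) {
    stop("term count k must be between 2 and 6")
  }
  as.integer(k)
}

default_terms <- function(k) paste0("t", seq_len(k))

#' Hue (vertical) initial partition
#'
#' Splits the 40 chromatic hue columns into `k` contiguous bands of
#' near-equal width (widths differ by at most one column; wider bands
#' leftmost), labelling every chip in a band with that band's term. The
#' 10 achromatic chips, which have no hue, are grouped with one band
#' chosen uniformly at random.
#'
#' @param grid a [chip_grid()].
#' @param k number of terms, 2-6.
#' @param seed integer seed (selects the achromatic band).
#' @return a complete [naming_system()].
#' @export
hue_partition <- function(grid, k, seed = NULL) {
  k <- check_k(k)
  terms <- default_terms(k)
  band_of_col <- rep(seq_len(k), times = balanced_sizes(N_HUES, k))
  achro_band <- with_seed(seed, sample.int(k, 1))
  band <- ifelse(grid$col == 0L, achro_band, band_of_col[pmax(grid$col, 1L)])
  labels <- stats::setNames(terms[band], grid$chip_id)
  naming_system(grid, labels, terms)
}

#' Lightness (horizontal) initial partition
#'
#' Splits the 10 lightness rows into `k` contiguous groups of near-equal
#' size (sizes differ by at most one; larger groups at the light end),
#' labelling every chip by its row group. Deterministic.
#'
#' @inheritParams hue_partition
#' @return a complete [naming_system()].
#' @export
lightness_partition <- function(grid, k) {
  k <- check_k(k)
  terms <- default_terms(k)
  group_of_row <- rep(seq_len(k), times = balanced_sizes(10L, k))
  labels <- stats::setNames(terms[group_of_row[grid$row + 1L]], grid$chip_id)
  naming_system(grid, labels, terms)
}

#' Random initial partition
#'
#' Assigns terms to chips by a seeded uniform shuffle with balanced term
#' counts: every term labels the same number of chips, up to a
#' difference of one when `k` does not divide the grid size (330 chips
#' into 4 terms gives counts 83, 83, 82, 82 in shuffled positions).
#'
#' @inheritParams hue_partition
#' @return a complete [naming_system()].
#' @export
random_partition <- function(grid, k, seed = NULL) {
  k <- check_k(k)
  terms <- default_terms(k)
  n <- nrow(grid)
  pool <- rep(terms, times = balanced_sizes(n, k))
  labels <- with_seed(seed, sample(pool))
  naming_system(grid, stats::setNames(labels, grid$chip_id), terms)
}

#' Rotate a naming system along the hue dimension
#'
#' Shifts the labelling of chromatic chips `steps` columns to the right
#' around the 40-column hue circle: the chip at (row r, col h) receives
#' the label previously at (r, h - steps), wrapping cyclically.
#' Achromatic chips (col 0) have no hue and are left unchanged. `steps`
#' is taken modulo 40, so 0 and 40 are the identity; term frequencies
#' over chromatic chips are preserved.
#'
#' @param ns a complete [naming_system()].
#' @param steps integer rotation offset.
#' @return the rotated [naming_system()].
#' @export
rotate_hue <- function(ns, steps) {
  if (!is_complete(ns)) stop("rotate_hue requires a complete labelling")
  steps <- as.integer(steps) %% N_HUES
  if (steps == 0L) return(ns)
  g <- ns$grid
  src_col <- ifelse(g$col == 0L, 0L, ((g$col - 1L - steps) %% N_HUES) + 1L)
  src_id <- ifelse(g$col == 0L, g$chip_id, chip_id(g$row, src_col))
  labels <- stats::setNames(unname(ns$labels[src_id]), g$chip_id)
  naming_system(g, labels, ns$terms)
}

#' Minority terms of a naming system
#'
#' Terms used for strictly fewer than `threshold` of all chips (default
#' 5%): in a 330-chip system a term covering 16 chips (4.8%) is a
#' minority term, one covering 17 (5.2%) is not.
#'
#' @param ns a complete [naming_system()].
#' @param threshold fraction of chips below which a term is a minority
#'   term (default 0.05).
#' @return character vector of minority terms (possibly empty).
#' @export
minority_terms <- function(ns, threshold = 0.05) {
  if (!is_complete(ns)) stop("minority_terms requires a complete labelling")
  counts <- table(ns$labels)
  names(counts)[counts < threshold * nrow(ns$grid)]
}

#' Read / write naming tables
#'
#' Naming tables are TSV files with header
#' `language_id<TAB>speaker_id<TAB>chip_id<TAB>term`, one row per
#' labelled chip; unlabelled chips are simply absent. A file may hold a
#' whole multi-language corpus or a single system (fixed language and
#' speaker ids).
#'
#' @param path file path.
#' @param grid the [chip_grid()] the systems label.
#' @return `read_naming_table`: a [speaker_corpus()].
#' @export
read_naming_table <- function(path, grid) {
  tab <- utils::read.delim(path, colClasses = "character")
  need <- c("language_id", "speaker_id", "chip_id", "term")
  if (!identical(names(tab), need)) {
    stop("naming table must have header '",
         paste(need, collapse = "\t"), "'")
  }
  languages <- list()
  for (lang in unique(tab$language_id)) {
    ltab <- tab[tab$language_id == lang, ]
    speakers <- list()
    for (sp in unique(ltab$speaker_id)) {
      stab <- ltab[ltab$speaker_id == sp, ]
      speakers[[sp]] <- naming_system(
        grid, stats::setNames(stab$term, stab$chip_id))
    }
    languages[[lang]] <- speakers
  }
  speaker_corpus(languages)
}

#' @param corpus a [speaker_corpus()], or a single [naming_system()]
#'   (written with `language_id` and `speaker_id` both `"s1"`).
#' @rdname read_naming_table
#' @export
write_naming_table <- function(corpus, path) {
  if (inherits(corpus, "naming_system")) {
    corpus <- speaker_corpus(list(s1 = list(s1 = corpus)))
  }
  rows <- list()
  for (lang in names(corpus$languages)) {
    for (sp in names(corpus$languages[[lang]])) {
      ns <- corpus$languages[[lang]][[sp]]
      rows[[paste(lang, sp)]] <- data.frame(
        language_id = lang, speaker_id = sp,
        chip_id = names(ns$labels), term = unname(ns$labels),
        stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
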