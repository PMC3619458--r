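# The World Color Survey stimulus array and its geometry.
#
# The canonical array has 330 chips: 40 equally spaced Munsell hues at 8
# lightness levels (rows 1-8) plus a 10-level achromatic column (col 0,
# rows 0-9). Hue is circular: column 40 is adjacent to column 1.

N_HUES <- 40L
CHROMATIC_ROWS <- 1:8
ACHROMATIC_ROWS <- 0:9

# Hue columns after which the warped perceptual circle is stretched
# ("fault" zones where category boundaries are cheap). The set is
# aperiodic: no non-zero cyclic shift maps more than one anchor onto
# another, so rotating an anchored system misaligns it at every tested
# offset. Gaps: 6, 8, 10, 5, 4, 7.
ANCHOR_BOUNDARIES <- c(6L, 14L, 24L, 29L, 33L, 40L)

#' Construct a chip grid
#'
#' A chip grid is a data frame with columns `chip_id`, `row` (lightness
#' level, 0 = lightest) and `col` (0 = achromatic, 1-40 = chromatic hue).
#'
#' @param chip_id character vector of unique chip identifiers.
#' @param row integer lightness rows in 0-9.
#' @param col integer hue columns in 0-40.
#' @return an object of class `chip_grid` (a data frame).
#' @export
chip_grid <- function(chip_id, row, col) {
  row <- as.integer(row)
  col <- as.integer(col)
  chip_id <- as.character(chip_id)
  bad <- col < 0L | col > N_HUES | row < 0L | row > 9L |
    (col > 0L & !(row %in% CHROMATIC_ROWS))
  if (any(bad)) {
    stop("invalid chip coordinates at position(s) ",
         paste(which(bad), collapse = ", "),
         ": chromatic chips (col 1-40) need row 1-8; achromatic row 0-9")
  }
  if (anyDuplicated(chip_id)) stop("duplicate chip_id in grid")
  if (anyDuplicated(cbind(row, col))) stop("duplicate (row, col) in grid")
  g <- data.frame(chip_id = chip_id, row = row, col = col,
                  stringsAsFactors = FALSE)
  class(g) <- c("chip_grid", "data.frame")
  g
}

#' Chip identifier convention
#'
#' Identifiers follow `"R<row><col>"` with the row a single digit and the
#' column zero-padded to two digits, e.g. `R305` for row 3, hue column 5.
#'
#' @param row,col integer coordinates.
#' @return character ids.
#' @export
chip_id <- function(row, col) sprintf("R%d%02d", as.integer(row), as.integer(col))

#' Build the canonical 330-chip WCS array
#'
#' Deterministically constructs the standard stimulus grid: 40 hues x 8
#' lightness rows (320 chromatic chips) plus 10 achromatic chips in
#' column 0 spanning rows 0-9.
#'
#' @return a [chip_grid()] with 330 chips.
#' @examples
#' g <- build_wcs_array()
#' nrow(g)                 # 330
#' sum(g$col == 0)         # 10 achromatic chips
#' @export
build_wcs_array <- function() {
  achro <- data.frame(row = ACHROMATIC_ROWS, col = 0L)
  chrom <- expand.grid(col = seq_len(N_HUES), row = CHROMATIC_ROWS)
  coords <- rbind(achro, chrom[, c("row", "col")])
  chip_grid(chip_id(coords$row, coords$col), coords$row, coords$col)
}

#' Circular distance between two hue columns
#'
#' The hue dimension is a 40-step circle, so the distance between columns
#' `h1` and `h2` is `min(|h1 - h2|, 40 - |h1 - h2|)`, at most 20.
#' Achromatic chips (column 0) carry no hue and are rejected.
#'
#' @param c1,c2 single-row subsets of a chip grid (or any list/data frame
#'   with a `col` field).
#' @return a non-negative integer in 0-20.
#' @export
circular_hue_distance <- function(c1, c2) {
  h1 <- as.integer(c1$col)
  h2 <- as.integer(c2$col)
  if (any(h1 < 1L) || any(h2 < 1L)) {
    stop("circular_hue_distance is defined for chromatic chips only (col >= 1)")
  }
  d <- abs(h1 - h2)
  pmin(d, N_HUES - d)
}

#' Embed chips in a 3-D perceptual space
#'
#' Chromatic chips are placed on a cylinder: hue on a circle of radius
#' `rho` (in lightness-row units), lightness along the axis. Achromatic
#' chips sit on the axis itself. With the default `rho = 3`, adjacent
#' hues are about 0.47 row units apart, finer than the unit spacing of
#' adjacent lightness rows, so hue-contiguous categories are the easiest
#' to generalise.
#'
#' An optional warp makes the hue circle non-uniform, modelling a
#' shared perceptual bias. With `warp > 0` the angular step between a
#' column and its successor is widened by a factor `1 / (1 - warp)` at
#' six irregularly spaced anchor boundaries (after columns 6, 14, 24,
#' 29, 33 and 40), then all steps are renormalised to a full turn.
#' Category boundaries are perceptually cheap to maintain in these
#' stretched "fault" zones, so exemplar learners sharing the warp drift
#' towards systems whose category edges sit on the anchors. The anchor
#' set is aperiodic: no non-zero rotation maps it onto itself, so
#' rotation misaligns anchored systems at every offset. `warp = 0`
#' (the default) is the uniform circle with `theta(h) = 2*pi*h/40`.
#'
#' @param chips a chip grid or subset of one.
#' @param rho hue-circle radius in row units (default 3).
#' @param warp amplitude in `[0, 1)` of the hue-circle warp (default 0).
#' @return a numeric matrix with one row per chip and columns x, y, z.
#' @export
perceptual_embedding <- function(chips, rho = 3, warp = 0) {
  stopifnot(warp >= 0, warp < 1)
  h <- as.integer(chips$col)
  r <- as.integer(chips$row)
  if (warp > 0) {
    w <- rep(1, N_HUES)
    # step w[j] spans columns j-1 -> j, so the gap after anchor column b
    # is step b + 1 (wrapping: the gap after column 40 is step 1)
    w[(ANCHOR_BOUNDARIES %% N_HUES) + 1L] <- 1 / (1 - warp)
    theta_col <- 2 * pi * cumsum(w) / sum(w)
    theta <- c(0, theta_col)[h + 1L] # h = 0 never used for chromatic chips
  } else {
    theta <- 2 * pi * h / N_HUES
  }
  chrom <- h >= 1L
  out <- cbind(x = ifelse(chrom, rho * cos(theta), 0),
               y = ifelse(chrom, rho * sin(theta), 0),
               z = as.numeric(r))
  rownames(out) <- chips$chip_id
  out
}

#' Read / write a chip table
#'
#' Chip tables are UTF-8 TSV files with header `chip_id<TAB>row<TAB>col`,
#' one chip per line. `read_chip_table(write_chip_table(g, f))`
#' reproduces `g` exactly.
#'
#' @param path file path.
#' @return `read_chip_table`: a [chip_grid()].
#' @export
read_chip_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = c("character", "integer", "integer"))
  if (!identical(names(tab), c("chip_id", "row", "col"))) {
    stop("chip table must have header 'chip_id\trow\tcol', got: ",
         paste(names(tab), collapse = ", "))
  }
  if (nrow(tab) == 0L) return(chip_grid(character(), integer(), integer()))
  bad <- tab$col < 0L | tab$col > N_HUES | tab$row < 0L | tab$row > 9L |
    (tab$col > 0L & !(tab$row %in% CHROMATIC_ROWS))
  if (any(bad)) {
    stop("invalid chip coordinates at line ", which(bad)[1] + 1L,
         " of ", path)
  }
  dup <- duplicated(tab[, c("row", "col")])
  if (any(dup)) {
    stop("duplicate (row, col) at line ", which(dup)[1] + 1L, " of ", path)
  }
  chip_grid(tab$chip_id, tab$row, tab$col)
}

#' @param grid a [chip_grid()].
#' @rdname read_chip_table
#' @export
write_chip_table <- function(grid, path) {
  utils::write.table(as.data.frame(grid)[, c("chip_id", "row", "col")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
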