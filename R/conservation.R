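#' Convert normalized evolutionary rates to 1-9 conservation grades
#'
#' Site-specific evolutionary rates (mean roughly 0 over positions, more
#' negative = more conserved) are discretized into nine conservation grades
#' by equal-width binning of the observed rate range: the most-negative bin
#' receives grade 9 (most conserved), the most-positive grade 1. This is a
#' documented convention standing in for the ConSurf partition; grades
#' computed externally can be imported with [read_position_scores()] and
#' used directly instead. A degenerate (constant or single-position) input
#' yields the middle grade 5 everywhere.
#'
#' @param rates Either a numeric vector of per-position rates (positions
#'   taken as `seq_along(rates)`) or a data frame with columns `position`
#'   and `rate`.
#' @return A tibble with columns `position`, `rate`, `grade` (integer 1-9).
#' @export
grades_from_rates <- function(rates) {
  if (is.data.frame(rates)) {
    stopifnot(all(c("position", "rate") %in% names(rates)))
    position <- as.integer(rates$position)
    rate <- as.numeric(rates$rate)
  } else {
    rate <- as.numeric(rates)
    position <- seq_along(rate)
  }
  if (length(rate) == 0L) abort("no rates supplied")
  if (anyNA(rate)) abort("rates must be finite")
  rng <- range(rate)
  if (diff(rng) == 0) {
    grade <- rep(5L, length(rate))
  } else {
    width <- diff(rng) / 9
    bin <- pmin(floor((rate - rng[1]) / width) + 1L, 9L)
    grade <- as.integer(10L - bin)
  }
  tibble(position = position, rate = rate, grade = grade)
}

shannon_entropy <- function(x) {
  p <- table(x)
  p <- as.numeric(p) / sum(p)
  -sum(p * log(p))
}

#' Correlated-mutation scores from an alignment
#'
#' Scores each query position for co-variation with any other position,
#' using normalized mutual information (MI divided by the smaller of the two
#' column entropies) as an explicit, documented stand-in for dedicated
#' correlated-mutation tools whose output can instead be imported with
#' [read_position_scores()]. Only rows where both columns are non-gap,
#' non-wildcard enter each pairwise computation; constant columns score 0 by
#' convention. The per-position score is the maximum over all partner
#' positions and lies in `[0, 1]`.
#'
#' @param aln An `aa_msa` alignment.
#' @param mask Query positions to exclude.
#' @return A tibble with columns `position`, `score`. With fewer than three
#'   sequences the statistic is meaningless; a warning is issued and all
#'   scores are 0.
#' @export
correlation_scores <- function(aln, mask = integer(0)) {
  pos <- alignment_positions(aln)
  pos <- pos[!(pos$query_position %in% mask), ]
  if (nrow(pos) < 2L) abort("need at least two unmasked query positions")
  if (nrow(aln) < 3L) {
    warn("fewer than 3 sequences: correlation scores degenerate to 0")
    return(tibble(position = pos$query_position, score = 0))
  }
  m <- aln_matrix(aln)[, pos$column, drop = FALSE]
  k <- ncol(m)
  usable <- !(m %in% c(GAP_CHARS, AA_WILDCARD))
  dim(usable) <- dim(m)
  score <- numeric(k)
  nmi <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      ok <- usable[, i] & usable[, j]
      if (sum(ok) < 2L) next
      a <- m[ok, i]
      b <- m[ok, j]
      ha <- shannon_entropy(a)
      hb <- shannon_entropy(b)
      if (ha == 0 || hb == 0) next
      hab <- shannon_entropy(paste(a, b))
      mi <- max(ha + hb - hab, 0)
      nmi[i, j] <- nmi[j, i] <- min(mi / min(ha, hb), 1)
    }
  }
  for (i in seq_len(k)) score[i] <- max(nmi[i, ], 0)
  tibble(position = pos$query_position, score = score)
}

#' Read or write per-position score tables
#'
#' Externally computed conservation rates, grades or correlation scores are
#' exchanged as two-column TSV (`position`, `value`); imported values take
#' precedence over the package's internal stand-ins.
#'
#' @param path File path.
#' @param value_name Name to give the value column, e.g. `"rate"`,
#'   `"grade"` or `"score"`.
#' @return A tibble with columns `position` and `value_name`.
#' @export
read_position_scores <- function(path, value_name = "value") {
  out <- readr::read_tsv(path,
    col_names = c("position", "value"), comment = "#",
    col_types = "id", progress = FALSE, skip = guess_header_skip(path)
  )
  names(out)[2] <- value_name
  as_tibble(out)
}

guess_header_skip <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^position\\b", first, ignore.case = TRUE)) 1L else 0L
}

#' @rdname read_position_scores
#' @param scores A tibble whose first two columns are position and value.
#' @export
write_position_scores <- function(scores, path) {
  readr::write_tsv(scores[, 1:2], path)
  invisible(path)
}
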