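#' Build a position mask from ranges
#'
#' Poorly aligned regions are excluded from consensus analysis as ranges of
#' query positions, e.g. `mask_ranges(c(1, 131, 279), c(18, 179, 293))`.
#'
#' @param from,to Integer vectors of inclusive range bounds (recycled
#'   pairwise).
#' @return Sorted integer vector of masked query positions.
#' @export
mask_ranges <- function(from, to) {
  stopifnot(length(from) == length(to), all(from <= to))
  sort(unique(unlist(purrr::map2(from, to, seq))))
}

# Consensus residue of a frequency vector: the most frequent residue, ties
# broken in favour of a non-wild-type residue, then alphabetically.
consensus_residue <- function(freqs, wt) {
  if (length(freqs) == 0L) {
    return(NULL)
  }
  best <- names(freqs)[freqs == max(freqs)]
  best <- best[order(best == wt, best)]
  list(residue = best[1], freq = unname(freqs[best[1]]))
}

consensus_scan <- function(aln, mask, gap_policy, emit) {
  if (nrow(aln) == 0L) abort("empty alignment")
  pos <- alignment_positions(aln)
  pos <- pos[!(pos$query_position %in% mask) & pos$wt != AA_WILDCARD, ]
  m <- aln_matrix(aln)
  rows <- purrr::pmap(pos, function(query_position, column, wt) {
    cf <- column_freqs(m[, column], gap_policy)
    cons <- consensus_residue(cf$freqs, wt)
    if (is.null(cons) || cons$residue == wt) {
      return(NULL)
    }
    wt_freq <- unname(cf$freqs[wt])
    if (is.na(wt_freq)) wt_freq <- 0
    emit(query_position, wt, cons$residue, cons$freq, wt_freq)
  })
  out <- bind_rows(purrr::compact(rows))
  if (nrow(out) == 0L) {
    return(tibble(
      position = integer(0), wt = character(0), proposed = character(0),
      method = character(0), consensus_freq = numeric(0),
      wt_freq = numeric(0), mutation = character(0)
    ))
  }
  out
}

candidate_row <- function(position, wt, proposed, method,
                          consensus_freq, wt_freq) {
  tibble(
    position = position, wt = wt, proposed = proposed, method = method,
    consensus_freq = consensus_freq, wt_freq = wt_freq,
    mutation = format_mutation(wt, position, proposed)
  )
}

#' Simple-consensus back-to-consensus candidates
#'
#' Proposes the substitution of a query residue by the consensus residue of
#' its alignment column whenever the consensus differs from the wild type
#' and is present in at least `cutoff` of the analysed sequences (the
#' comparison is inclusive, so an exact 50% consensus passes the default
#' cutoff). Frequency ties at the consensus prefer the non-wild-type
#' residue, then alphabetical order.
#'
#' @param aln An `aa_msa` alignment.
#' @param cutoff Minimum consensus-residue frequency in (0, 1]; default 0.5.
#' @param mask Integer vector of query positions excluded from analysis
#'   (e.g. poorly aligned regions; see [mask_ranges()]).
#' @param gap_policy Denominator convention for frequencies; see
#'   [column_profile()].
#' @return A tibble of candidates: `position`, `wt`, `proposed`, `method`,
#'   `consensus_freq`, `wt_freq`, `mutation`.
#' @export
simple_consensus <- function(aln, cutoff = 0.5, mask = integer(0),
                             gap_policy = c("exclude_gaps", "count_gaps")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(cutoff > 0, cutoff <= 1)
  consensus_scan(aln, mask, gap_policy, function(p, wt, cons, cf, wf) {
    if (cf >= cutoff) {
      candidate_row(p, wt, cons, "simple_consensus", cf, wf)
    } else {
      NULL
    }
  })
}

#' Frequency-ratio back-to-consensus candidates
#'
#' A stricter back-to-consensus variant: the consensus residue must reach a
#' minimal frequency (`min_consensus_freq`, default 0.4) and the ratio of
#' the wild-type ("target") residue frequency to the consensus frequency
#' must not exceed `ratio_cutoff` (default 0.2), so only positions where
#' the query residue is rare relative to a strong consensus are proposed.
#'
#' @inheritParams simple_consensus
#' @param ratio_cutoff Maximum allowed wild-type/consensus frequency ratio.
#' @param min_consensus_freq Minimum frequency of the consensus residue.
#' @return A candidate tibble as in [simple_consensus()].
#' @export
frequency_ratio <- function(aln, ratio_cutoff = 0.2,
                            min_consensus_freq = 0.4, mask = integer(0),
                            gap_policy = c("exclude_gaps", "count_gaps")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(
    ratio_cutoff > 0, ratio_cutoff <= 1,
    min_consensus_freq > 0, min_consensus_freq <= 1
  )
  consensus_scan(aln, mask, gap_policy, function(p, wt, cons, cf, wf) {
    if (cf >= min_consensus_freq && wf / cf <= ratio_cutoff) {
      candidate_row(p, wt, cons, "frequency_ratio", cf, wf)
    } else {
      NULL
    }
  })
}

#' Write or read candidate tables
#'
#' Candidates are exchanged as TSV with columns `position`, `wt`,
#' `proposed`, `method`, `consensus_freq`, `wt_freq`.
#'
#' @param candidates A candidate tibble.
#' @param path File path.
#' @return `write_candidates()` returns `path` invisibly;
#'   `read_candidates()` returns the candidate tibble (with the `mutation`
#'   column reconstructed).
#' @export
write_candidates <- function(candidates, path) {
  readr::write_tsv(
    candidates[, c(
      "position", "wt", "proposed", "method",
      "consensus_freq", "wt_freq"
    )],
    path
  )
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  out$position <- as.integer(out$position)
  out$mutation <- format_mutation(out$wt, out$position, out$proposed)
  as_tibble(out)
}
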