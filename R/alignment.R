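#' Construct a protein multiple sequence alignment object
#'
#' An alignment is a tibble with one row per sequence (columns `id`, `seq`)
#' plus a `query_id` attribute naming the target protein whose gap-free
#' coordinates anchor all downstream positions. Residues are upper-cased,
#' `.` gaps are normalised to `-`, and characters outside the 20-letter
#' amino-acid alphabet are mapped to the wildcard `X`, which never enters
#' frequency counts.
#'
#' @param ids Character vector of sequence identifiers.
#' @param seqs Character vector of aligned sequences (equal lengths).
#' @param query_id Identifier of the query sequence; must occur in `ids`.
#' @return A tibble of class `aa_msa` with columns `id` and `seq`.
#' @export
new_alignment <- function(ids, seqs, query_id) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) {
    abort("ids and seqs must have the same length")
  }
  if (length(ids) == 0L) abort("alignment has no sequences")
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  seqs <- vapply(seqs, sanitize_seq, character(1), USE.NAMES = FALSE)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    abort("ragged alignment: rows have unequal lengths")
  }
  if (!query_id %in% ids) {
    abort(paste0("query_id '", query_id, "' not found among sequence ids"))
  }
  qseq <- seqs[match(query_id, ids)]
  if (!grepl("[^-]", qseq)) abort("query row contains only gaps")
  out <- tibble(id = ids, seq = seqs)
  attr(out, "query_id") <- query_id
  class(out) <- c("aa_msa", class(tibble()))
  out
}

sanitize_seq <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- !(ch %in% c(AA_ALPHABET, "-"))
  if (any(bad)) ch[bad] <- AA_WILDCARD
  paste(ch, collapse = "")
}

#' @export
print.aa_msa <- function(x, ...) {
  cat(
    "Amino-acid alignment: ", nrow(x), " sequences x ",
    nchar(x$seq[1]), " columns (query: ", attr(x, "query_id"), ")\n",
    sep = ""
  )
  NextMethod()
}

#' Read a protein multiple sequence alignment
#'
#' Reads an aligned FASTA or Clustal file into an [new_alignment()] object.
#' FASTA parsing goes through [Biostrings::readBStringSet()]; Clustal through
#' [Biostrings::readAAMultipleAlignment()].
#'
#' @param path Path to the alignment file.
#' @param query_id Identifier of the query sequence.
#' @param format `"fasta"` (default) or `"clustal"`.
#' @return An `aa_msa` tibble.
#' @export
read_alignment <- function(path, query_id, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(set))
    seqs <- as.character(set)
  } else {
    msa <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    ids <- names(Biostrings::unmasked(msa))
    seqs <- as.character(Biostrings::unmasked(msa))
  }
  new_alignment(ids, seqs, query_id)
}

#' Write an alignment as unwrapped aligned FASTA
#'
#' One header line and one sequence line per record, so a written file
#' re-read with [read_alignment()] reproduces the object exactly.
#'
#' @param aln An `aa_msa` alignment.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  writeLines(paste0(">", aln$id, "\n", aln$seq), path, sep = "\n")
  invisible(path)
}

aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(m) <- aln$id
  m
}

query_row <- function(aln) {
  aln$seq[match(attr(aln, "query_id"), aln$id)]
}

#' Map alignment columns to query positions
#'
#' @param aln An `aa_msa` alignment.
#' @return A tibble with one row per non-gap query column: `query_position`
#'   (1-based over the gap-free query sequence), `column` (1-based alignment
#'   column) and `wt` (the query residue).
#' @export
alignment_positions <- function(aln) {
  q <- strsplit(query_row(aln), "", fixed = TRUE)[[1]]
  keep <- which(!(q %in% GAP_CHARS))
  tibble(
    query_position = seq_along(keep),
    column = keep,
    wt = q[keep]
  )
}

column_freqs <- function(col_chars, gap_policy) {
  is_gap <- col_chars %in% GAP_CHARS
  res <- col_chars[!is_gap & col_chars != AA_WILDCARD]
  gap_fraction <- mean(is_gap)
  denom <- switch(gap_policy,
    exclude_gaps = length(res),
    count_gaps = length(col_chars)
  )
  if (length(res) == 0L || denom == 0L) {
    return(list(freqs = numeric(0), gap_fraction = gap_fraction))
  }
  tab <- table(res)
  list(
    freqs = setNames(as.numeric(tab) / denom, names(tab)),
    gap_fraction = gap_fraction
  )
}

#' Residue frequency profile of one alignment column
#'
#' Computes per-residue frequencies for a single alignment column. Under
#' `exclude_gaps` the denominator is the number of non-gap, non-wildcard
#' residues (frequencies sum to 1); under `count_gaps` it is the number of
#' sequences (frequencies sum to 1 minus the gap fraction).
#'
#' @param aln An `aa_msa` alignment.
#' @param column 1-based alignment column index. The column must map to a
#'   non-gap query position.
#' @param gap_policy `"exclude_gaps"` (default) or `"count_gaps"`.
#' @return A tibble with columns `query_position`, `column`, `residue`,
#'   `freq`, `gap_fraction`, `n_sequences`.
#' @export
column_profile <- function(aln, column,
                           gap_policy = c("exclude_gaps", "count_gaps")) {
  gap_policy <- match.arg(gap_policy)
  width <- nchar(aln$seq[1])
  if (column < 1L || column > width) {
    abort(paste0("column ", column, " outside alignment width ", width))
  }
  pos <- alignment_positions(aln)
  hit <- pos[pos$column == column, ]
  if (nrow(hit) == 0L) {
    abort(paste0(
      "column ", column,
      " has a gap in the query: no query position is defined"
    ))
  }
  m <- aln_matrix(aln)
  cf <- column_freqs(m[, column], gap_policy)
  tibble(
    query_position = hit$query_position,
    column = column,
    residue = names(cf$freqs) %||% character(0),
    freq = as.numeric(cf$freqs),
    gap_fraction = cf$gap_fraction,
    n_sequences = nrow(aln)
  )
}

#' Residue frequency profiles for all query positions
#'
#' @inheritParams column_profile
#' @return A long tibble: one row per (query position, residue) with
#'   `query_position`, `column`, `wt`, `residue`, `freq`, `gap_fraction`,
#'   `n_sequences`.
#' @export
column_profiles <- function(aln,
                            gap_policy = c("exclude_gaps", "count_gaps")) {
  gap_policy <- match.arg(gap_policy)
  pos <- alignment_positions(aln)
  m <- aln_matrix(aln)
  purrr::pmap_dfr(pos, function(query_position, column, wt) {
    cf <- column_freqs(m[, column], gap_policy)
    if (length(cf$freqs) == 0L) {
      return(tibble(
        query_position = query_position, column = column, wt = wt,
        residue = character(0), freq = numeric(0),
        gap_fraction = cf$gap_fraction, n_sequences = nrow(m)
      ))
    }
    tibble(
      query_position = query_position, column = column, wt = wt,
      residue = names(cf$freqs), freq = as.numeric(cf$freqs),
      gap_fraction = cf$gap_fraction, n_sequences = nrow(m)
    )
  })
}

#' Greedy identity-based redundancy reduction
#'
#' Walks the alignment with the query first, then the remaining sequences in
#' input order, and drops a sequence when its pairwise identity (matching
#' residues over columns where both sequences are non-gap) to any already
#' kept sequence exceeds `identity_cutoff`. The query is always kept.
#'
#' @param aln An `aa_msa` alignment.
#' @param identity_cutoff Identity fraction in (0, 1]; sequences more similar
#'   than this to a kept sequence are dropped.
#' @return A reduced `aa_msa` alignment.
#' @export
reduce_redundancy <- function(aln, identity_cutoff) {
  stopifnot(identity_cutoff > 0, identity_cutoff <= 1)
  m <- aln_matrix(aln)
  qi <- match(attr(aln, "query_id"), aln$id)
  order_idx <- c(qi, setdiff(seq_len(nrow(aln)), qi))
  kept <- integer(0)
  for (i in order_idx) {
    drop <- FALSE
    for (j in kept) {
      if (pairwise_identity(m[i, ], m[j, ]) > identity_cutoff) {
        drop <- TRUE
        break
      }
    }
    if (!drop) kept <- c(kept, i)
  }
  kept <- sort(kept)
  new_alignment(aln$id[kept], aln$seq[kept], attr(aln, "query_id"))
}

pairwise_identity <- function(a, b) {
  shared <- !(a %in% GAP_CHARS) & !(b %in% GAP_CHARS)
  if (!any(shared)) {
    return(0)
  }
  mean(a[shared] == b[shared])
}
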