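#' Amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes used throughout the package.
#' Unknown residues are represented by the wildcard `"X"`, which is excluded
#' from all frequency counts; `"-"` and `"."` are treated as gap symbols.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

GAP_CHARS <- c("-", ".")
AA_WILDCARD <- "X"

#' Parse mutations in wtPOSsub notation
#'
#' Parses mutation strings such as `"C128F"` (wild-type residue, 1-based
#' position in the gap-free query sequence, substituting residue) into a
#' tidy table. The canonical text form is reproduced in the `mutation`
#' column so parsing and formatting round-trip.
#'
#' @param x Character vector of mutation strings, e.g. `c("C128F", "T148L")`.
#' @return A tibble with columns `mutation`, `wt`, `position`, `sub`.
#' @examples
#' parse_mutations(c("C128F", "T148L"))
#' @export
parse_mutations <- function(x) {
  x <- toupper(trimws(as.character(x)))
  m <- stringr::str_match(x, "^([A-Z])([0-9]+)([A-Z])$")
  bad <- is.na(m[, 1])
  if (any(bad)) {
    abort(paste0(
      "invalid mutation token(s): ",
      paste(unique(x[bad]), collapse = ", "),
      " (expected wtPOSsub, e.g. C128F)"
    ))
  }
  wt <- m[, 2]
  sub <- m[, 4]
  if (any(wt == sub)) {
    abort(paste0(
      "wild-type equals substitution in: ",
      paste(unique(x[wt == sub]), collapse = ", ")
    ))
  }
  ok_aa <- c(AA_ALPHABET, AA_WILDCARD)
  if (any(!wt %in% ok_aa) || any(!sub %in% ok_aa)) {
    abort("mutation residues must be standard one-letter amino-acid codes")
  }
  tibble(
    mutation = x,
    wt = wt,
    position = as.integer(m[, 3]),
    sub = sub
  )
}

#' Format mutations back to wtPOSsub notation
#'
#' @param wt,position,sub Vectors of wild-type residues, positions and
#'   substitutions (recycled to common length).
#' @return Character vector like `"C128F"`.
#' @export
format_mutation <- function(wt, position, sub) {
  paste0(wt, as.integer(position), sub)
}
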