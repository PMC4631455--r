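#' Default stability-call thresholds per prediction tool
#'
#' A mutation is called stabilizing when its mean ddG is strictly below the
#' tool's stabilizing threshold and destabilizing when strictly above the
#' destabilizing threshold (kcal/mol, negative = stabilizing): FoldX uses
#' (-1.0, +0.5), Rosetta the stricter (-2.0, +0.5).
#'
#' @param tool `"foldx"`, `"rosetta"` or `"generic"`.
#' @return Named numeric vector with elements `stabilizing` and
#'   `destabilizing`; `NA` for `"generic"` (thresholds must be supplied).
#' @export
default_thresholds <- function(tool) {
  switch(tool,
    foldx = c(stabilizing = -1.0, destabilizing = 0.5),
    rosetta = c(stabilizing = -2.0, destabilizing = 0.5),
    generic = c(stabilizing = NA_real_, destabilizing = NA_real_),
    abort(paste0("unknown tool: ", tool))
  )
}

ddg_record_tbl <- function(mutation, structure_id, tool, ddg, replicate) {
  parsed <- parse_mutations(mutation)
  if (any(!is.finite(ddg))) abort("non-finite ddG value encountered")
  tibble(
    mutation = parsed$mutation, wt = parsed$wt,
    position = parsed$position, sub = parsed$sub,
    structure_id = as.character(structure_id), tool = tool,
    ddg = as.numeric(ddg), replicate = as.integer(replicate)
  )
}

#' Parse per-structure ddG prediction tables
#'
#' Ingests folding free-energy change predictions from external calculators
#' into a tidy record table (one row per mutation x structure x replicate).
#' Three dialects are recognised:
#'
#' * `generic_tsv`: tab-separated `mutation`, `structure_id`, `ddg` and
#'   optional `replicate` columns, with or without a header line.
#' * `foldx_buildmodel`: a BuildModel-style "Dif" energy file; header lines
#'   are skipped and data rows look like `C128F_2.pdb<TAB>-1.40<TAB>...`
#'   (mutation tag and replicate number in the model name, the first energy
#'   column is the ddG). The structure is taken from `structure_id`.
#' * `rosetta_ddg_monomer`: a ddg-predictions file whose data rows start
#'   with `ddG:` followed by the mutation description and the total ddG.
#'
#' @param path Path to the table.
#' @param dialect One of `"generic_tsv"`, `"foldx_buildmodel"`,
#'   `"rosetta_ddg_monomer"`.
#' @param tool Tool label stored in the records; defaults to the dialect's
#'   native tool (`generic_tsv` defaults to `"generic"`).
#' @param structure_id Structure identifier for dialects whose files do not
#'   carry one (required for the FoldX and Rosetta dialects).
#' @return Tibble of records: `mutation`, `wt`, `position`, `sub`,
#'   `structure_id`, `tool`, `ddg`, `replicate`.
#' @export
parse_ddg_table <- function(path,
                            dialect = c(
                              "generic_tsv", "foldx_buildmodel",
                              "rosetta_ddg_monomer"
                            ),
                            tool = NULL, structure_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(paste0("empty ddG table: ", path))
  switch(dialect,
    generic_tsv = parse_generic_tsv(lines, tool %||% "generic"),
    foldx_buildmodel = parse_foldx_dif(
      lines, tool %||% "foldx",
      structure_id
    ),
    rosetta_ddg_monomer = parse_rosetta_ddg(
      lines, tool %||% "rosetta",
      structure_id
    )
  )
}

parse_generic_tsv <- function(lines, tool) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- grepl("^mutation\\b", lines[1], ignore.case = TRUE)
  if (header) {
    cols <- tolower(fields[[1]])
    fields <- fields[-1]
  } else {
    cols <- c("mutation", "structure_id", "ddg", "replicate")
  }
  if (length(fields) == 0L) abort("ddG table has a header but no rows")
  want <- function(name, i, default = NULL) {
    idx <- if (header) match(name, cols) else i
    vapply(seq_along(fields), function(r) {
      row <- fields[[r]]
      if (is.na(idx) || idx > length(row)) {
        if (is.null(default)) {
          abort(paste0("missing field '", name, "' on data line ", r))
        }
        default
      } else {
        row[idx]
      }
    }, character(1))
  }
  mutation <- want("mutation", 1)
  structure <- want("structure_id", 2)
  ddg <- suppressWarnings(as.numeric(want("ddg", 3)))
  if (anyNA(ddg)) {
    abort(paste0(
      "non-numeric ddG on data line ",
      which(is.na(ddg))[1]
    ))
  }
  repl <- suppressWarnings(as.integer(want("replicate", 4, default = "1")))
  tool_col <- if (header && "tool" %in% cols) {
    want("tool", NA_integer_)
  } else {
    rep(tool, length(mutation))
  }
  out <- ddg_record_tbl(mutation, structure, tool, ddg, repl)
  out$tool <- tool_col
  out
}

parse_foldx_dif <- function(lines, tool, structure_id) {
  if (is.null(structure_id)) {
    abort("structure_id is required for the foldx_buildmodel dialect")
  }
  data <- grep("^[A-Z][0-9]+[A-Z](_[0-9]+)?\\.pdb\t", lines, value = TRUE)
  if (length(data) == 0L) {
    abort("no BuildModel data rows found (expected '<mut>_<rep>.pdb<TAB>ddg')")
  }
  fields <- strsplit(data, "\t", fixed = TRUE)
  name <- sub("\\.pdb$", "", vapply(fields, `[[`, character(1), 1))
  mutation <- sub("_[0-9]+$", "", name)
  repl <- ifelse(grepl("_[0-9]+$", name),
    as.integer(sub("^.*_", "", name)), 1L
  )
  ddg <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  if (anyNA(ddg)) abort("non-numeric energy in BuildModel data row")
  ddg_record_tbl(mutation, structure_id, tool, ddg, repl)
}

parse_rosetta_ddg <- function(lines, tool, structure_id) {
  if (is.null(structure_id)) {
    abort("structure_id is required for the rosetta_ddg_monomer dialect")
  }
  data <- grep("^ddG:", lines, value = TRUE)
  data <- data[!grepl("description", data)]
  if (length(data) == 0L) abort("no 'ddG:' data rows found")
  fields <- strsplit(trimws(sub("^ddG:", "", data)), "\\s+")
  mutation <- vapply(fields, `[[`, character(1), 1)
  ddg <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  if (anyNA(ddg)) abort("non-numeric total ddG in 'ddG:' row")
  ddg_record_tbl(mutation, structure_id, tool, ddg, 1L)
}

#' Write ddG records as generic TSV
#'
#' @param records A ddG record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ddg_table <- function(records, path) {
  readr::write_tsv(
    records[, c("mutation", "structure_id", "ddg", "replicate")], path
  )
  invisible(path)
}

#' Average ddG records per mutation and tool
#'
#' Averages replicates within each structure first, then averages the
#' per-structure means across structures, mirroring the convention of
#' averaging predictions over all analysed structures (or chains). With
#' `require_all_structures = TRUE` (default) a mutation missing any expected
#' structure for its tool is excluded; the exclusions are attached as the
#' `"excluded"` attribute and reported via a message. With `FALSE`,
#' available structures are averaged with a warning.
#'
#' @param records A ddG record tibble from [parse_ddg_table()].
#' @param require_all_structures Logical; see above.
#' @param expected_structures Optional character vector of structure ids a
#'   complete mutation must cover; defaults to all structures observed for
#'   the record's tool.
#' @return Tibble with `mutation`, `wt`, `position`, `sub`, `tool`,
#'   `mean_ddg`, `n_structures`, `n_replicates`.
#' @export
summarize_ddg <- function(records, require_all_structures = TRUE,
                          expected_structures = NULL) {
  if (nrow(records) == 0L) abort("no ddG records supplied")
  per_struct <- records %>%
    group_by(.data$mutation, .data$wt, .data$position, .data$sub,
      .data$tool, .data$structure_id) %>%
    summarise(
      struct_mean = mean(.data$ddg), n_repl = n(),
      .groups = "drop"
    )
  out <- per_struct %>%
    group_by(.data$mutation, .data$wt, .data$position, .data$sub,
      .data$tool) %>%
    summarise(
      mean_ddg = mean(.data$struct_mean),
      n_structures = n(),
      n_replicates = as.integer(max(.data$n_repl)),
      .groups = "drop"
    )
  expected <- expected_structures %||% NULL
  n_expected <- per_struct %>%
    group_by(.data$tool) %>%
    summarise(
      n_exp = length(unique(.data$structure_id)),
      .groups = "drop"
    )
  if (!is.null(expected)) n_expected$n_exp <- length(expected)
  out <- left_join(out, n_expected, by = "tool")
  incomplete <- out$n_structures < out$n_exp
  if (any(incomplete)) {
    if (require_all_structures) {
      excluded <- out[incomplete, c("mutation", "tool", "n_structures")]
      message(
        sum(incomplete), " mutation(s) excluded: predictions missing for ",
        "one or more expected structures (",
        paste(utils::head(excluded$mutation, 5), collapse = ", "),
        if (nrow(excluded) > 5) ", ..." else "", ")"
      )
      out <- out[!incomplete, ]
      attr(out, "excluded") <- excluded
    } else {
      warn(paste0(
        sum(incomplete),
        " mutation(s) averaged over fewer structures than expected"
      ))
    }
  }
  out$n_exp <- NULL
  out
}

#' Classify mean ddG values as stabilizing / neutral / destabilizing
#'
#' Calls are strict on both sides: stabilizing iff `mean_ddg` is strictly
#' below the stabilizing threshold, destabilizing iff strictly above the
#' destabilizing threshold, neutral otherwise. Values exactly at a
#' threshold are therefore neutral. Defaults come from
#' [default_thresholds()] per tool.
#'
#' @param summaries A summary tibble from [summarize_ddg()].
#' @param stabilizing_threshold,destabilizing_threshold Optional numeric
#'   overrides (kcal/mol) applied to every row; by default each row uses its
#'   tool's thresholds.
#' @return The input with added columns `call` (factor-like character) and
#'   `stab_threshold`, `destab_threshold`.
#' @export
call_stability <- function(summaries, stabilizing_threshold = NULL,
                           destabilizing_threshold = NULL) {
  thr <- purrr::map(summaries$tool, default_thresholds)
  stab <- stabilizing_threshold %||%
    vapply(thr, `[[`, numeric(1), "stabilizing")
  destab <- destabilizing_threshold %||%
    vapply(thr, `[[`, numeric(1), "destabilizing")
  if (anyNA(stab) || anyNA(destab)) {
    abort("thresholds must be supplied for tool 'generic'")
  }
  if (any(stab >= destab)) {
    abort("stabilizing threshold must be below destabilizing threshold")
  }
  summaries %>%
    mutate(
      stab_threshold = stab,
      destab_threshold = destab,
      call = dplyr::case_when(
        .data$mean_ddg < stab ~ "stabilizing",
        .data$mean_ddg > destab ~ "destabilizing",
        TRUE ~ "neutral"
      )
    )
}

#' Energy-based candidate selection
#'
#' Intersects the stabilizing calls of two prediction tools and removes
#' mutations at evolutionarily conserved (grade >= `grade_cutoff`,
#' inclusive) or correlated (score >= `correlation_cutoff`, inclusive)
#' positions. A mutation present in only one tool's calls is excluded with a
#' logged reason, as is one vetoed by a destabilizing call from either tool
#' (when `veto_destabilizing`, the default). In the pipeline driver the
#' conservation/correlation filter is applied before the energy evaluation
#' to save ddG computation; the resulting set is identical either way.
#'
#' @param calls_a,calls_b Called summaries from [call_stability()] for the
#'   two tools (e.g. FoldX and Rosetta).
#' @param conservation Optional tibble with `position`, `grade`.
#' @param correlation Optional tibble with `position`, `score`.
#' @param grade_cutoff Positions with grade at or above this are immutable
#'   (default 8).
#' @param correlation_cutoff Positions with correlation score at or above
#'   this are excluded (default 0.8).
#' @param veto_destabilizing If `TRUE`, a destabilizing call by either tool
#'   excludes the mutation outright.
#' @return Tibble of kept mutations with per-tool mean ddGs
#'   (`mean_ddg_a`, `mean_ddg_b`); excluded mutations and their reasons are
#'   attached as the `"excluded"` attribute.
#' @export
energy_candidates <- function(calls_a, calls_b, conservation = NULL,
                              correlation = NULL, grade_cutoff = 8L,
                              correlation_cutoff = 0.8,
                              veto_destabilizing = TRUE) {
  a <- calls_a[, c("mutation", "wt", "position", "sub", "mean_ddg", "call")]
  b <- calls_b[, c("mutation", "mean_ddg", "call")]
  merged <- dplyr::full_join(a, b,
    by = "mutation",
    suffix = c("_a", "_b")
  )
  reason <- rep(NA_character_, nrow(merged))
  reason[is.na(merged$call_a) | is.na(merged$call_b)] <- "single_tool_only"
  both_stab <- !is.na(merged$call_a) & !is.na(merged$call_b) &
    merged$call_a == "stabilizing" & merged$call_b == "stabilizing"
  reason[is.na(reason) & !both_stab] <- "not_stabilizing_by_both"
  if (veto_destabilizing) {
    veto <- (!is.na(merged$call_a) & merged$call_a == "destabilizing") |
      (!is.na(merged$call_b) & merged$call_b == "destabilizing")
    reason[veto] <- "destabilizing_veto"
  }
  if (!is.null(conservation)) {
    hi <- merged$position %in%
      conservation$position[conservation$grade >= grade_cutoff]
    reason[is.na(reason) & hi] <- "conserved_position"
  }
  if (!is.null(correlation)) {
    corr <- merged$position %in%
      correlation$position[correlation$score >= correlation_cutoff]
    reason[is.na(reason) & corr] <- "correlated_position"
  }
  kept <- merged[is.na(reason), ]
  excluded <- merged[!is.na(reason), c("mutation")]
  excluded$reason <- reason[!is.na(reason)]
  if (nrow(excluded) > 0L) {
    message(
      nrow(excluded), " mutation(s) excluded from energy candidates (",
      paste(sprintf(
        "%s: %d", names(table(excluded$reason)),
        as.integer(table(excluded$reason))
      ), collapse = ", "), ")"
    )
  }
  out <- kept[, c(
    "mutation", "wt", "position", "sub",
    "mean_ddg_a", "mean_ddg_b"
  )]
  attr(out, "excluded") <- excluded
  out
}
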