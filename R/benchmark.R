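#' Read experimental stability records
#'
#' Reads a ProTherm-style TSV of experimentally determined folding
#' free-energy changes with columns `protein_id`, `mutation`, `ddg_exp`,
#' `pH`, `temperature`, `record_id`. Because databases differ in sign
#' convention, each file (or call) must declare whether a negative
#' `ddg_exp` means stabilizing (`"stabilizing_negative"`, the internal
#' convention shared with the ddG calculators) or the opposite; a
#' `# sign_convention: ...` comment line in the file takes precedence.
#'
#' @param path Path to the TSV file.
#' @param sign_convention `"stabilizing_negative"` or
#'   `"stabilizing_positive"`; optional if declared in the file header.
#' @return Tibble of records with a `sign_convention` attribute.
#' @export
read_stability_records <- function(path, sign_convention = NULL) {
  lines <- readLines(path, n = 5L)
  decl <- grep("^#\\s*sign_convention:", lines, value = TRUE)
  if (length(decl) > 0L) {
    sign_convention <- trimws(sub("^#\\s*sign_convention:", "", decl[1]))
  }
  if (is.null(sign_convention)) {
    abort("sign_convention must be declared (file comment or argument)")
  }
  out <- readr::read_tsv(path,
    comment = "#", show_col_types = FALSE,
    progress = FALSE
  )
  need <- c("protein_id", "mutation", "ddg_exp", "record_id")
  stopifnot(all(need %in% names(out)))
  if (!"pH" %in% names(out)) out$pH <- NA_real_
  if (!"temperature" %in% names(out)) out$temperature <- NA_real_
  attr(out, "sign_convention") <- match.arg(
    sign_convention,
    c("stabilizing_negative", "stabilizing_positive")
  )
  as_tibble(out)
}

#' Curate experimental stability records into a benchmark dataset
#'
#' Applies the validation-dataset rules: records with `|ddg_exp|` below
#' `min_abs_ddg` (default 0.5 kcal/mol, about the experimental error of
#' ddG measurement; the comparison keeps values at exactly 0.5) are
#' dropped, and when several records exist for one (protein, mutation) only
#' the one measured closest to `target_pH` (default 7) is retained. pH ties
#' prefer the lower pH, then the smaller temperature deviation from 25 C,
#' then the lexicographically smaller record id; a record with missing pH
#' always loses to one with a pH. Signs are canonicalized so that negative
#' means stabilizing, and each mutation is labelled accordingly. Curation
#' is idempotent.
#'
#' @param records Record tibble from [read_stability_records()] (or any
#'   tibble with the same columns and a declared sign convention).
#' @param min_abs_ddg Minimum absolute experimental ddG (inclusive).
#' @param target_pH pH whose nearest measurement wins deduplication.
#' @param sign_convention Convention override if `records` carries none.
#' @return A tibble of class `benchmark_dataset` (one row per protein x
#'   mutation) with canonical `ddg_exp` and a `label` column
#'   (`"stabilizing"` / `"destabilizing"`).
#' @export
curate <- function(records, min_abs_ddg = 0.5, target_pH = 7.0,
                   sign_convention = NULL) {
  conv <- attr(records, "sign_convention") %||% sign_convention
  if (is.null(conv)) {
    abort("sign_convention must be declared (attribute or argument)")
  }
  out <- as_tibble(records)
  if (conv == "stabilizing_positive") out$ddg_exp <- -out$ddg_exp
  out <- out[abs(out$ddg_exp) >= min_abs_ddg, ]
  if (nrow(out) == 0L) abort("no records survive the |ddG| filter")
  ph_dev <- abs(out$pH - target_pH)
  ph_dev[is.na(ph_dev)] <- Inf
  t_dev <- abs(out$temperature - 25)
  t_dev[is.na(t_dev)] <- Inf
  ph_rank <- out$pH
  ph_rank[is.na(ph_rank)] <- Inf
  ord <- order(
    out$protein_id, out$mutation, ph_dev, ph_rank, t_dev,
    out$record_id
  )
  out <- out[ord, ]
  out <- out[!duplicated(paste(out$protein_id, out$mutation)), ]
  out <- out %>%
    mutate(label = ifelse(.data$ddg_exp < 0, "stabilizing",
      "destabilizing"
    )) %>%
    arrange(.data$protein_id, .data$mutation)
  attr(out, "sign_convention") <- "stabilizing_negative"
  attr(out, "min_abs_ddg") <- min_abs_ddg
  attr(out, "target_pH") <- target_pH
  class(out) <- c("benchmark_dataset", class(tibble()))
  out
}

#' Confusion counts for stabilizing-mutation prediction
#'
#' @param predicted_stabilizing Logical vector: prediction per record.
#' @param truly_stabilizing Logical vector: label per record.
#' @return Tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(predicted_stabilizing, truly_stabilizing) {
  stopifnot(length(predicted_stabilizing) == length(truly_stabilizing))
  tibble(
    tp = sum(predicted_stabilizing & truly_stabilizing),
    fp = sum(predicted_stabilizing & !truly_stabilizing),
    tn = sum(!predicted_stabilizing & !truly_stabilizing),
    fn = sum(!predicted_stabilizing & truly_stabilizing)
  )
}

#' Precision of stabilizing-mutation predictions
#'
#' The fraction of mutations predicted as stabilizing that are truly
#' stabilizing: `tp / (tp + fp)`. Undefined (`NA`) when nothing is
#' predicted stabilizing.
#'
#' @param counts A one-row tibble or named list with `tp`, `fp` (and
#'   optionally `tn`, `fn`).
#' @return A single numeric in `[0, 1]`, or `NA_real_` when undefined.
#' @export
precision <- function(counts) {
  denom <- counts$tp + counts$fp
  ifelse(denom == 0, NA_real_, counts$tp / denom)
}

#' False positive rate of stabilizing-mutation predictions
#'
#' The fraction of truly destabilizing mutations incorrectly predicted as
#' stabilizing: `fp / (fp + tn)`. Undefined (`NA`) when there are no truly
#' destabilizing mutations.
#'
#' @inheritParams precision
#' @return A single numeric in `[0, 1]`, or `NA_real_` when undefined.
#' @export
false_positive_rate <- function(counts) {
  denom <- counts$fp + counts$tn
  ifelse(denom == 0, NA_real_, counts$fp / denom)
}

#' Round a proportion to whole percent, half away from zero
#'
#' Report-level rounding only; metrics are stored at full precision.
#'
#' @param p Proportion in `[0, 1]` (or `NA`).
#' @return Integer percent.
#' @export
round_percent <- function(p) {
  as.integer(sign(p) * floor(abs(p) * 100 + 0.5))
}

#' Sweep stability-call thresholds over a benchmark dataset
#'
#' For each tool and each threshold `t` of the grid (default -2.5 to +2.5
#' kcal/mol in steps of 0.5, 11 thresholds), predicts a mutation as
#' stabilizing iff its mean predicted ddG is strictly below `t`, scores the
#' predictions against the dataset labels and reports precision and false
#' positive rate.
#'
#' @param summaries Summary tibble from [summarize_ddg()] (any number of
#'   tools); predictions are matched to dataset rows by `mutation` (and by
#'   `protein_id` too when the summaries carry that column).
#' @param dataset A `benchmark_dataset` from [curate()].
#' @param grid Numeric vector of thresholds.
#' @param missing `"error"` (default) to fail when a dataset mutation lacks
#'   a prediction, or `"skip"` to drop such rows with a message.
#' @return A tibble of class `metric_sweep`: `tool`, `threshold`, `tp`,
#'   `fp`, `tn`, `fn`, `n_predicted_stabilizing`, `precision`, `fpr`.
#' @export
threshold_sweep <- function(summaries, dataset,
                            grid = seq(-2.5, 2.5, by = 0.5),
                            missing = c("error", "skip")) {
  missing <- match.arg(missing)
  if (nrow(dataset) == 0L) abort("empty benchmark dataset")
  by <- if ("protein_id" %in% names(summaries)) {
    c("protein_id", "mutation")
  } else {
    "mutation"
  }
  out <- purrr::map_dfr(unique(summaries$tool), function(tl) {
    preds <- summaries[summaries$tool == tl, ]
    joined <- left_join(as_tibble(dataset),
      preds[, c(by, "mean_ddg")],
      by = by
    )
    if (anyNA(joined$mean_ddg)) {
      if (missing == "error") {
        abort(paste0(
          "no ", tl, " prediction for: ",
          paste(utils::head(
            joined$mutation[is.na(joined$mean_ddg)], 5
          ), collapse = ", ")
        ))
      }
      message(
        sum(is.na(joined$mean_ddg)), " dataset mutation(s) without ",
        tl, " prediction skipped"
      )
      joined <- joined[!is.na(joined$mean_ddg), ]
    }
    truly <- joined$label == "stabilizing"
    purrr::map_dfr(grid, function(t) {
      cc <- confusion_counts(joined$mean_ddg < t, truly)
      tibble(
        tool = tl, threshold = t, tp = cc$tp, fp = cc$fp, tn = cc$tn,
        fn = cc$fn, n_predicted_stabilizing = cc$tp + cc$fp,
        precision = precision(cc), fpr = false_positive_rate(cc)
      )
    })
  })
  class(out) <- c("metric_sweep", class(tibble()))
  out
}

#' Evaluate the combined two-tool design rule on a benchmark dataset
#'
#' Applies the full energy-arm decision rule to a labelled dataset: a
#' mutation is predicted stabilizing only if both tools call it stabilizing
#' at their thresholds and its position is not conserved (grade below
#' `grade_cutoff`), then scores the predictions. The combined prediction
#' set is by construction a subset of each tool's own stabilizing set.
#'
#' @param calls_a,calls_b Called summaries from [call_stability()].
#' @param dataset A `benchmark_dataset`.
#' @param conservation Optional tibble with `position`, `grade`.
#' @param grade_cutoff Immutability grade cutoff (inclusive, default 8).
#' @return A one-row tibble: `tool = "combined"`, confusion counts,
#'   `n_predicted_stabilizing`, `precision`, `fpr`.
#' @export
evaluate_pipeline <- function(calls_a, calls_b, dataset,
                              conservation = NULL, grade_cutoff = 8L) {
  cand <- energy_candidates(calls_a, calls_b,
    conservation = conservation,
    grade_cutoff = grade_cutoff
  )
  missing <- setdiff(dataset$mutation, c(
    calls_a$mutation,
    calls_b$mutation
  ))
  if (length(missing) > 0L) {
    abort(paste0(
      "dataset mutation(s) without predictions: ",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  predicted <- dataset$mutation %in% cand$mutation
  truly <- dataset$label == "stabilizing"
  cc <- confusion_counts(predicted, truly)
  tibble(
    tool = "combined", tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
    n_predicted_stabilizing = cc$tp + cc$fp,
    precision = precision(cc), fpr = false_positive_rate(cc)
  )
}

#' @describeIn threshold_sweep One row per tool: the threshold maximising
#'   precision (ties: lower FPR, then lower threshold).
#' @param x A `metric_sweep`.
#' @param ... Unused.
#' @export
glance.metric_sweep <- function(x, ...) {
  x %>%
    group_by(.data$tool) %>%
    arrange(
      dplyr::desc(.data$precision), .data$fpr, .data$threshold,
      .by_group = TRUE
    ) %>%
    slice(1) %>%
    ungroup()
}

#' Write a metric table as TSV
#'
#' @param sweep A `metric_sweep` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(sweep, path) {
  readr::write_tsv(as_tibble(sweep), path)
  invisible(path)
}
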