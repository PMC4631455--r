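#' Plot precision and false positive rate across thresholds
#'
#' @param object A `metric_sweep` from [threshold_sweep()].
#' @param ... Unused.
#' @return A ggplot: precision and FPR versus decision threshold, one
#'   panel per metric, coloured by tool.
#' @export
autoplot.metric_sweep <- function(object, ...) {
  long <- object %>%
    select("tool", "threshold", "precision", "fpr") %>%
    tidyr::pivot_longer(c("precision", "fpr"),
      names_to = "metric", values_to = "value"
    ) %>%
    mutate(metric = ifelse(.data$metric == "fpr",
      "false positive rate", .data$metric
    ))
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$threshold, .data$value, colour = .data$tool)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "stabilizing-call threshold (kcal/mol)", y = NULL,
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the per-mutation ddG profile of a design plan
#'
#' @param object A `design_plan` whose candidates carry mean ddG columns
#'   (joined via `ddg`), or any plan combined with a summary table.
#' @param ddg Optional summary tibble (from [summarize_ddg()]) supplying
#'   `mean_ddg` per mutation.
#' @param ... Unused.
#' @return A ggplot: admitted mutations in admission order with their mean
#'   predicted ddG.
#' @export
autoplot.design_plan <- function(object, ddg = NULL, ...) {
  df <- tidy(object)
  if (!is.null(ddg)) {
    df <- left_join(df, ddg[, c("mutation", "mean_ddg")], by = "mutation")
  }
  if (!"mean_ddg" %in% names(df)) {
    abort("supply `ddg` summaries to plot a plan's ddG profile")
  }
  df$mutation <- factor(df$mutation, levels = df$mutation[order(df$order)])
  ggplot2::ggplot(
    df,
    ggplot2::aes(.data$mutation, .data$mean_ddg, fill = .data$provenance)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = NULL, y = "mean predicted ddG (kcal/mol)",
      fill = NULL,
      title = paste0("Design ", attr(object, "name"))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
      hjust = 1))
}

#' Plot consensus candidates along the query sequence
#'
#' @param candidates Candidate tibble from [simple_consensus()] /
#'   [frequency_ratio()] (rows from both methods may be bound together).
#' @return A ggplot of candidate positions versus consensus and wild-type
#'   frequencies.
#' @export
plot_consensus_candidates <- function(candidates) {
  ggplot2::ggplot(
    candidates,
    ggplot2::aes(.data$position, .data$consensus_freq)
  ) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$position, y = .data$wt_freq,
        yend = .data$consensus_freq),
      colour = "grey60"
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$method)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$wt_freq), shape = 1) +
    ggplot2::labs(
      x = "query position", y = "residue frequency", colour = NULL,
      title = "Back-to-consensus candidates",
      subtitle = "filled: consensus residue, open: wild type"
    ) +
    ggplot2::theme_minimal()
}
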