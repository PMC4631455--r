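#' Assess mutation pairs for antagonistic epistasis
#'
#' Two individually stabilizing mutations are antagonistic when the
#' predicted ddG of their double-point mutant fails the additivity
#' criterion: strictly greater than `threshold` (default -3.0 kcal/mol).
#' A double mutant at exactly the threshold is additive.
#'
#' @param pairs Tibble with columns `mutation_a`, `mutation_b`,
#'   `double_ddg` (mean over structures, kcal/mol).
#' @param threshold Antagonism threshold in kcal/mol.
#' @return The input with `antagonistic` (logical) and `threshold_used`
#'   columns added.
#' @export
assess_pairs <- function(pairs, threshold = -3.0) {
  a <- parse_mutations(pairs$mutation_a)
  b <- parse_mutations(pairs$mutation_b)
  same <- a$position == b$position
  if (any(same)) {
    abort(paste0(
      "same-position pair(s) are not valid double mutants: ",
      paste(pairs$mutation_a[same], pairs$mutation_b[same],
        sep = "/", collapse = ", "
      )
    ))
  }
  if (any(!is.finite(pairs$double_ddg))) abort("double_ddg must be finite")
  pairs %>%
    mutate(
      antagonistic = .data$double_ddg > threshold,
      threshold_used = threshold
    )
}

#' Keep the most favourable mutation per position
#'
#' When several stabilizing candidates target one position, only the most
#' favourable (lowest mean ddG) is retained; exact ties are broken
#' alphabetically by substituting residue.
#'
#' @param candidates Tibble with `mutation`, `position`, `sub` and a ddG
#'   ranking column.
#' @param ddg_col Name of the ddG column used for ranking (default
#'   `"mean_ddg"`).
#' @return Candidate tibble with one row per position.
#' @export
best_per_position <- function(candidates, ddg_col = "mean_ddg") {
  stopifnot(ddg_col %in% names(candidates))
  if (any(!is.finite(candidates[[ddg_col]]))) {
    abort("candidates must carry finite ddG values")
  }
  candidates %>%
    arrange(.data$position, .data[[ddg_col]], .data$sub) %>%
    group_by(.data$position) %>%
    slice(1) %>%
    ungroup()
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Greedily assemble an additive multiple-point design
#'
#' Scans candidates from most to least stabilizing (ascending `ddg_col`,
#' ties broken by a secondary ddG column when present, then by position) and
#' admits each candidate only if it is non-antagonistic with every mutation
#' already admitted. Candidates must be one-per-position (see
#' [best_per_position()]); an assessment must exist for every pair that
#' needs testing.
#'
#' @param candidates Candidate tibble with `mutation`, `position`, `sub`
#'   and the ranking column(s).
#' @param assessments Pair tibble from [assess_pairs()].
#' @param ddg_col Primary ranking column (default `"mean_ddg"`).
#' @param tie_col Optional secondary ranking column (e.g. the other tool's
#'   mean ddG); used only to break exact ties.
#' @param provenance Provenance label for admitted mutations (`"energy"`,
#'   `"evolution"` or `"manual"`).
#' @param name Name of the resulting design.
#' @return A `design_plan` object (see [new_design_plan()]) whose rows are
#'   the admitted mutations in admission order. Rejected candidates and the
#'   admitted mutation each conflicted with are attached as the
#'   `"rejected"` attribute.
#' @export
greedy_combine <- function(candidates, assessments, ddg_col = "mean_ddg",
                           tie_col = NULL, provenance = "energy",
                           name = "design") {
  if (nrow(candidates) == 0L) {
    return(new_design_plan(character(0), provenance = character(0),
      name = name))
  }
  if (anyDuplicated(candidates$position)) {
    abort("candidates must contain at most one mutation per position")
  }
  ord <- order(
    candidates[[ddg_col]],
    if (!is.null(tie_col)) candidates[[tie_col]] else candidates$position,
    candidates$position
  )
  cand <- candidates[ord, ]
  keyed <- setNames(
    assessments$antagonistic,
    pair_key(assessments$mutation_a, assessments$mutation_b)
  )
  admitted <- character(0)
  rejected <- tibble(
    mutation = character(0),
    conflicts_with = character(0)
  )
  for (i in seq_len(nrow(cand))) {
    mut <- cand$mutation[i]
    conflict <- NA_character_
    for (adm in admitted) {
      k <- pair_key(mut, adm)
      if (!k %in% names(keyed)) {
        abort(paste0("missing pair assessment for ", mut, " / ", adm))
      }
      if (keyed[[k]]) {
        conflict <- adm
        break
      }
    }
    if (is.na(conflict)) {
      admitted <- c(admitted, mut)
    } else {
      rejected <- bind_rows(
        rejected,
        tibble(mutation = mut, conflicts_with = conflict)
      )
    }
  }
  plan <- new_design_plan(admitted,
    provenance = rep(provenance, length(admitted)), name = name
  )
  attr(plan, "rejected") <- rejected
  plan
}

#' Create a multiple-point design plan
#'
#' A design plan is an ordered set of single-point mutations (admission
#' order preserved) with at most one mutation per position, printed in the
#' conventional `"+"`-joined notation (`C128F + T148L + ...`).
#'
#' @param mutations Character vector of mutations in wtPOSsub notation.
#' @param provenance Per-mutation origin: `"energy"`, `"evolution"` or
#'   `"manual"` (recycled if length 1).
#' @param name Design name.
#' @return A tibble of class `design_plan` with columns `order`,
#'   `mutation`, `wt`, `position`, `sub`, `provenance`.
#' @export
new_design_plan <- function(mutations, provenance = "manual",
                            name = "design") {
  if (length(mutations) == 0L) {
    out <- tibble(
      order = integer(0), mutation = character(0), wt = character(0),
      position = integer(0), sub = character(0), provenance = character(0)
    )
  } else {
    parsed <- parse_mutations(mutations)
    if (anyDuplicated(parsed$position)) {
      abort("design plan has two mutations at one position")
    }
    if (length(provenance) == 1L) {
      provenance <- rep(provenance, nrow(parsed))
    }
    stopifnot(all(provenance %in% c("energy", "evolution", "manual")))
    out <- tibble(
      order = seq_len(nrow(parsed)), mutation = parsed$mutation,
      wt = parsed$wt, position = parsed$position, sub = parsed$sub,
      provenance = provenance
    )
  }
  attr(out, "name") <- name
  class(out) <- c("design_plan", class(tibble()))
  out
}

#' @export
print.design_plan <- function(x, ...) {
  cat("Design plan '", attr(x, "name"), "': ", nrow(x), " mutation(s)\n",
    sep = ""
  )
  if (nrow(x) > 0L) cat("  ", plan_notation(x), "\n", sep = "")
  invisible(x)
}

#' Mutation notation of a design plan
#'
#' @param plan A `design_plan`.
#' @param by_position Join mutations in position order (the conventional
#'   report style) rather than admission order.
#' @return A single string like `"C128F + T148L + A172I"`.
#' @export
plan_notation <- function(plan, by_position = TRUE) {
  muts <- if (by_position) {
    plan$mutation[order(plan$position)]
  } else {
    plan$mutation
  }
  paste(muts, collapse = " + ")
}

#' Merge two design plans into a hybrid
#'
#' Takes the union of the two mutation sets (e.g. combining the best
#' energy-based and the best evolution-based design into one hybrid
#' mutant). A position mutated differently in both plans is an error by
#' default; `conflict_policy = "prefer_A"` keeps plan A's mutation instead.
#'
#' @param plan_a,plan_b `design_plan` objects.
#' @param conflict_policy `"error"` (default) or `"prefer_A"`.
#' @param name Name of the merged design.
#' @return A merged `design_plan`; provenance of each mutation is
#'   preserved.
#' @export
merge_designs <- function(plan_a, plan_b,
                          conflict_policy = c("error", "prefer_A"),
                          name = NULL) {
  conflict_policy <- match.arg(conflict_policy)
  both <- intersect(plan_a$position, plan_b$position)
  clash <- both[plan_a$mutation[match(both, plan_a$position)] !=
    plan_b$mutation[match(both, plan_b$position)]]
  if (length(clash) > 0L && conflict_policy == "error") {
    abort(paste0(
      "plans mutate position(s) ", paste(clash, collapse = ", "),
      " differently"
    ))
  }
  b_keep <- plan_b[!(plan_b$position %in% plan_a$position), ]
  muts <- c(plan_a$mutation, b_keep$mutation)
  prov <- c(plan_a$provenance, b_keep$provenance)
  new_design_plan(muts,
    provenance = prov,
    name = name %||% paste0(
      attr(plan_a, "name"), "+",
      attr(plan_b, "name")
    )
  )
}

#' @describeIn new_design_plan Tidy a design plan into a plain tibble.
#' @param x A `design_plan`.
#' @param ... Unused.
#' @export
tidy.design_plan <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @describeIn new_design_plan One-row summary: name, size, notation and
#'   provenance breakdown.
#' @export
glance.design_plan <- function(x, ...) {
  tibble(
    name = attr(x, "name"),
    n_mutations = nrow(x),
    n_energy = sum(x$provenance == "energy"),
    n_evolution = sum(x$provenance == "evolution"),
    notation = plan_notation(x)
  )
}
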