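# Independent pseudo-random streams per generator: each generator derives
# its own seed from the master seed and a fixed label, so adding a
# generator never perturbs the draws of another.
stream_seed <- function(seed, label) {
  offsets <- c(msa = 101L, ddg = 202L, structure = 303L, benchmark = 404L)
  stopifnot(label %in% names(offsets))
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[label]]
}

#' Simulate a multiple sequence alignment with planted consensus deviations
#'
#' Generates an alignment that emulates the input of back-to-consensus
#' analysis. Background columns carry the query residue as a strong
#' majority (plus low-frequency noise spread over several other residues),
#' so they never produce candidates. At each planted site the query carries
#' `wt` while a deterministic, rounded count of sequences carries the
#' consensus residue at `consensus_freq` and the wild type at `wt_freq`;
#' the remainder is spread thinly over other residues so the planted
#' consensus is always the column's most frequent residue. The realized
#' (post-rounding) counts are emitted as ground truth.
#'
#' @param n_sequences Number of sequences including the query (default 50).
#' @param length Query length in residues (default 60).
#' @param planted Tibble with columns `position`, `wt`, `consensus`
#'   (residues differ), and optionally `consensus_freq` (default 0.8) and
#'   `wt_freq` (default 0.05).
#' @param background_noise Fraction of non-query rows carrying a non-wt
#'   residue in background columns (default 0.2, spread over >= 3
#'   residues).
#' @param seed Master seed; fixed seed gives byte-identical output.
#' @return A list with `alignment` (an `aa_msa`, query id `"query"`) and
#'   `truth` (tibble of planted candidates with realized frequencies).
#' @export
simulate_msa <- function(n_sequences = 50L, length = 60L,
                         planted = NULL, background_noise = 0.2,
                         seed = 1L) {
  set.seed(stream_seed(seed, "msa"))
  if (is.null(planted)) {
    planted <- tibble(
      position = integer(0), wt = character(0),
      consensus = character(0)
    )
  }
  planted <- as_tibble(planted)
  if (nrow(planted) > 0L) {
    if (!"consensus_freq" %in% names(planted)) planted$consensus_freq <- 0.8
    if (!"wt_freq" %in% names(planted)) planted$wt_freq <- 0.05
    stopifnot(
      all(planted$wt != planted$consensus),
      all(planted$position >= 1), all(planted$position <= length),
      all(planted$consensus_freq + planted$wt_freq <= 1)
    )
  }
  query <- sample(AA_ALPHABET, length, replace = TRUE)
  query[planted$position] <- planted$wt
  mat <- matrix("", nrow = n_sequences, ncol = length)
  mat[1, ] <- query
  truth_rows <- list()
  for (j in seq_len(length)) {
    p_idx <- match(j, planted$position)
    others <- seq(2L, n_sequences)
    if (is.na(p_idx)) {
      n_noise <- round(background_noise * (n_sequences - 1L))
      col <- rep(query[j], n_sequences - 1L)
      if (n_noise > 0L) {
        noise_res <- sample(setdiff(AA_ALPHABET, query[j]), 4L)
        col[sample.int(n_sequences - 1L, n_noise)] <-
          sample(noise_res, n_noise, replace = TRUE)
      }
      mat[others, j] <- col
    } else {
      n_cons <- round(planted$consensus_freq[p_idx] * n_sequences)
      # query is one wild-type copy; realized wt count is at least 1
      n_wt <- max(round(planted$wt_freq[p_idx] * n_sequences), 1L)
      stopifnot(n_cons + n_wt <= n_sequences)
      n_fill <- n_sequences - n_cons - n_wt
      filler_pool <- setdiff(
        AA_ALPHABET,
        c(planted$wt[p_idx], planted$consensus[p_idx])
      )
      # spread filler over many residues so none rivals the consensus
      filler <- rep(sample(filler_pool, min(8L, max(n_fill, 1L))),
        length.out = max(n_fill, 0L)
      )
      col <- c(
        rep(planted$consensus[p_idx], n_cons),
        rep(planted$wt[p_idx], n_wt - 1L),
        filler
      )
      mat[others, j] <- sample(col)
      truth_rows[[length(truth_rows) + 1L]] <- tibble(
        position = j, wt = planted$wt[p_idx],
        proposed = planted$consensus[p_idx],
        consensus_freq = n_cons / n_sequences,
        wt_freq = n_wt / n_sequences,
        mutation = format_mutation(
          planted$wt[p_idx], j,
          planted$consensus[p_idx]
        )
      )
    }
  }
  ids <- c("query", sprintf("homolog_%03d", seq_len(n_sequences - 1L)))
  aln <- new_alignment(ids, apply(mat, 1, paste, collapse = ""), "query")
  truth <- if (length(truth_rows) > 0L) {
    bind_rows(truth_rows)
  } else {
    tibble(
      position = integer(0), wt = character(0), proposed = character(0),
      consensus_freq = numeric(0), wt_freq = numeric(0),
      mutation = character(0)
    )
  }
  list(alignment = aln, truth = truth)
}

#' Simulate single- and double-mutant ddG prediction tables
#'
#' Emulates the output of external ddG calculators over a mutation
#' universe: true single-mutant effects are drawn from a mixture of a
#' stabilizing tail (uniform on `[-4, -2]` kcal/mol, for a configurable
#' fraction of mutations) and a near-neutral bulk (normal, mean +0.5, sd
#' 0.8); per-structure, per-replicate records add Gaussian noise of sd
#' `noise_sd`. Double-mutant ddGs are the sum of the two true singles plus
#' an epistasis offset, zero except for the planted antagonistic pairs,
#' whose offset is chosen to push the double mutant above the antagonism
#' threshold (default -3). Ground truth (true effects, planted pairs) is
#' returned alongside.
#'
#' @param mutations Character vector of single mutations (wtPOSsub).
#' @param frac_stabilizing Fraction of the universe drawn from the
#'   stabilizing tail (default 0.3).
#' @param antagonistic_pairs Optional tibble with `mutation_a`,
#'   `mutation_b` (both must be in `mutations`) and optionally `offset`
#'   (kcal/mol added to the pair's additive ddG; computed automatically to
#'   land 0.5 above the threshold when absent).
#' @param structures Character vector of structure ids (default three).
#' @param n_replicates Replicates per structure (default 3).
#' @param noise_sd Per-record Gaussian noise sd in kcal/mol (default 0.1).
#' @param tools Tool labels to emit tables for (default foldx + rosetta;
#'   each tool gets independent noise around the same true effect).
#' @param antagonism_threshold Threshold used to auto-size offsets.
#' @param seed Master seed.
#' @return List with `singles` (ddG record tibble across tools),
#'   `doubles` (pair records: `mutation_a`, `mutation_b`, `structure_id`,
#'   `tool`, `ddg`), and `truth` (list with `effects` and `pairs`).
#' @export
simulate_ddg <- function(mutations, frac_stabilizing = 0.3,
                         antagonistic_pairs = NULL,
                         structures = c("struct1", "struct2", "struct3"),
                         n_replicates = 3L, noise_sd = 0.1,
                         tools = c("foldx", "rosetta"),
                         antagonism_threshold = -3.0, seed = 1L) {
  set.seed(stream_seed(seed, "ddg"))
  parsed <- parse_mutations(mutations)
  n <- nrow(parsed)
  stab <- runif(n) < frac_stabilizing
  true_eff <- ifelse(stab, runif(n, -4, -2), rnorm(n, 0.5, 0.8))
  effects <- tibble(
    mutation = parsed$mutation, true_ddg = true_eff,
    truly_stabilizing = stab
  )
  if (is.null(antagonistic_pairs)) {
    antagonistic_pairs <- tibble(
      mutation_a = character(0),
      mutation_b = character(0)
    )
  }
  antagonistic_pairs <- as_tibble(antagonistic_pairs)
  if (nrow(antagonistic_pairs) > 0L) {
    unknown <- setdiff(
      c(
        antagonistic_pairs$mutation_a,
        antagonistic_pairs$mutation_b
      ),
      effects$mutation
    )
    if (length(unknown) > 0L) {
      abort(paste0(
        "antagonistic pair references unknown mutation(s): ",
        paste(unknown, collapse = ", ")
      ))
    }
    if (!"offset" %in% names(antagonistic_pairs)) {
      add <- effects$true_ddg[match(
        antagonistic_pairs$mutation_a,
        effects$mutation
      )] +
        effects$true_ddg[match(
          antagonistic_pairs$mutation_b,
          effects$mutation
        )]
      antagonistic_pairs$offset <- pmax(
        antagonism_threshold + 0.5 - add, 0.5
      )
    }
  }
  singles <- tidyr::expand_grid(
    mutation = effects$mutation, tool = tools,
    structure_id = structures, replicate = seq_len(n_replicates)
  ) %>%
    left_join(effects[, c("mutation", "true_ddg")], by = "mutation") %>%
    mutate(ddg = .data$true_ddg +
      rnorm(dplyr::n(), 0, noise_sd)) %>%
    select(-"true_ddg")
  singles <- dplyr::bind_cols(
    parse_mutations(singles$mutation),
    singles[, c("structure_id", "tool", "ddg", "replicate")]
  )
  all_pairs <- utils::combn(effects$mutation, 2L)
  pair_tbl <- tibble(
    mutation_a = all_pairs[1, ], mutation_b = all_pairs[2, ]
  )
  pk <- pair_key(pair_tbl$mutation_a, pair_tbl$mutation_b)
  off <- rep(0, nrow(pair_tbl))
  if (nrow(antagonistic_pairs) > 0L) {
    idx <- match(
      pair_key(
        antagonistic_pairs$mutation_a,
        antagonistic_pairs$mutation_b
      ), pk
    )
    off[idx] <- antagonistic_pairs$offset
  }
  pair_true <- effects$true_ddg[match(pair_tbl$mutation_a,
    effects$mutation)] +
    effects$true_ddg[match(pair_tbl$mutation_b, effects$mutation)] + off
  doubles <- tidyr::expand_grid(
    idx = seq_len(nrow(pair_tbl)), tool = tools,
    structure_id = structures
  ) %>%
    mutate(
      mutation_a = pair_tbl$mutation_a[.data$idx],
      mutation_b = pair_tbl$mutation_b[.data$idx],
      ddg = pair_true[.data$idx] + rnorm(dplyr::n(), 0, noise_sd)
    ) %>%
    select("mutation_a", "mutation_b", "structure_id", "tool", "ddg")
  list(
    singles = singles, doubles = doubles,
    truth = list(
      effects = effects,
      pairs = dplyr::bind_cols(pair_tbl,
        offset = off,
        true_double_ddg = pair_true
      )
    )
  )
}

#' Average simulated double-mutant records into pair assessments
#'
#' Convenience wrapper: averages `doubles` records (over structures, per
#' tool) and runs [assess_pairs()].
#'
#' @param doubles Double-mutant record tibble from [simulate_ddg()] (or the
#'   same layout from external tables).
#' @param tool Which tool's records to use (default `"rosetta"`).
#' @param threshold Antagonism threshold (default -3).
#' @return A pair-assessment tibble.
#' @export
summarize_pairs <- function(doubles, tool = "rosetta", threshold = -3.0) {
  doubles %>%
    filter(.data$tool == !!tool) %>%
    group_by(.data$mutation_a, .data$mutation_b) %>%
    summarise(double_ddg = mean(.data$ddg), .groups = "drop") %>%
    assess_pairs(threshold = threshold)
}

#' Emit a toy PDB structure with salt bridges at controlled distances
#'
#' Writes minimal but valid PDB ATOM records for pairs of residues (an
#' acidic and a basic residue per requested bridge) whose charged-group
#' atoms are placed at exactly the requested nitrogen-oxygen distances.
#' Pairs are spaced 50 Angstrom apart so no unintended contacts arise.
#'
#' @param bridges Tibble with one row per requested pair: `distance`
#'   (Angstrom, > 0) and optionally `res_a`/`res_b` (residue numbers;
#'   defaults 2k-1, 2k) and `acidic`/`basic` residue names (defaults
#'   `"ASP"`, `"LYS"`).
#' @param path Optional output path; when `NULL` the PDB text is returned.
#' @param structure_id Identifier recorded in the HEADER line.
#' @param chain Chain identifier.
#' @return The PDB text (character vector of lines), invisibly when written
#'   to `path`.
#' @export
simulate_structure <- function(bridges, path = NULL,
                               structure_id = "toy", chain = "A") {
  bridges <- as_tibble(bridges)
  if (any(bridges$distance <= 0)) abort("requested distance must be > 0")
  n <- nrow(bridges)
  if (!"res_a" %in% names(bridges)) bridges$res_a <- 2L * seq_len(n) - 1L
  if (!"res_b" %in% names(bridges)) bridges$res_b <- 2L * seq_len(n)
  if (!"acidic" %in% names(bridges)) bridges$acidic <- "ASP"
  if (!"basic" %in% names(bridges)) bridges$basic <- "LYS"
  lines <- paste0("HEADER    TOY STRUCTURE ", structure_id)
  serial <- 0L
  atom_line <- function(name, res, resno, x, y, z) {
    serial <<- serial + 1L
    sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      serial, paste0(" ", name), res, chain, resno, x, y, z, 1, 0
    )
  }
  for (k in seq_len(n)) {
    ox <- 50 * (k - 1)
    acid <- bridges$acidic[k]
    base <- bridges$basic[k]
    o_name <- if (acid == "GLU") "OE1" else "OD1"
    n_name <- switch(base, LYS = "NZ", ARG = "NH1", HIS = "ND1")
    lines <- c(
      lines,
      atom_line("N", acid, bridges$res_a[k], ox - 3, 3, 0),
      atom_line("CA", acid, bridges$res_a[k], ox - 2, 2, 0),
      atom_line("C", acid, bridges$res_a[k], ox - 3, 1, 0),
      atom_line("CB", acid, bridges$res_a[k], ox - 1, 1, 0),
      atom_line(o_name, acid, bridges$res_a[k], ox, 0, 0),
      atom_line("N", base, bridges$res_b[k], ox + 3, -3, 0),
      atom_line("CA", base, bridges$res_b[k], ox + 2, -2, 0),
      atom_line("C", base, bridges$res_b[k], ox + 3, -1, 0),
      atom_line(n_name, base, bridges$res_b[k], ox + bridges$distance[k],
        0, 0)
    )
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Simulate a complete design project
#'
#' Bundles the generators into one seeded project emulating a full study:
#' an alignment with planted consensus deviations, single- and
#' double-mutant ddG tables over a mutation universe containing planted
#' stabilizing mutations and planted antagonistic pairs, and a toy
#' structure. The ground truth includes the additive clique the greedy
#' combiner should recover.
#'
#' @param seed Master seed.
#' @param n_sequences,length Alignment dimensions.
#' @return A list: `msa`, `ddg`, `structure_lines`, and `truth` (combined
#'   ground-truth list with `consensus`, `effects`, `pairs`,
#'   `expected_plan`).
#' @export
simulate_project <- function(seed = 1L, n_sequences = 50L, length = 60L) {
  planted <- tibble(
    position = c(10L, 25L, 40L),
    wt = c("V", "A", "T"), consensus = c("L", "P", "I")
  )
  msa <- simulate_msa(
    n_sequences = n_sequences, length = length,
    planted = planted, seed = seed
  )
  pos <- alignment_positions(msa$alignment)
  wt_at <- function(p) pos$wt[match(p, pos$query_position)]
  mut_at <- function(p, pref) {
    wt <- wt_at(p)
    sub <- if (pref == wt) setdiff(c("W", "F", "K"), wt)[1] else pref
    format_mutation(wt, p, sub)
  }
  universe <- c(
    mut_at(5, "W"), mut_at(12, "F"), mut_at(18, "L"), mut_at(30, "I"),
    mut_at(33, "Y"), mut_at(47, "M"), mut_at(52, "F"), mut_at(58, "W")
  )
  # plant: first five strongly stabilizing, last three neutral; one
  # antagonistic pair among the stabilizing five
  effects <- tibble(
    mutation = universe,
    true_ddg = c(-3.6, -3.1, -2.8, -2.4, -2.2, 0.4, 0.8, 1.2),
    truly_stabilizing = c(rep(TRUE, 5), rep(FALSE, 3))
  )
  # offset sized so the planted pair's true double (-3.6 + -2.8 + offset)
  # lands at -2.5, clearly above the -3.0 antagonism threshold
  pairs <- tibble(
    mutation_a = universe[1], mutation_b = universe[3], offset = 3.9
  )
  ddg <- simulate_ddg(universe,
    antagonistic_pairs = pairs,
    noise_sd = 0.05, seed = seed
  )
  # overwrite mixture draws with the planted effect sizes (deterministic
  # truth, noisy records)
  ddg <- replant_effects(ddg, effects, pairs, seed = seed)
  structure_lines <- simulate_structure(
    tibble(distance = c(3.5, 4.5)),
    structure_id = "toy1"
  )
  # greedy over the five stabilizing candidates: universe[1] admitted
  # first, universe[3] rejected (antagonistic with it), rest admitted
  expected_plan <- sort(universe[c(1, 2, 4, 5)])
  list(
    msa = msa, ddg = ddg, structure_lines = structure_lines,
    truth = list(
      consensus = msa$truth, effects = effects,
      pairs = ddg$truth$pairs[ddg$truth$pairs$offset > 0, ],
      expected_plan = expected_plan
    )
  )
}

replant_effects <- function(ddg, effects, pairs, seed) {
  set.seed(stream_seed(seed, "ddg") + 7L)
  old <- ddg$truth$effects$true_ddg[match(
    ddg$singles$mutation,
    ddg$truth$effects$mutation
  )]
  new <- effects$true_ddg[match(ddg$singles$mutation, effects$mutation)]
  ddg$singles$ddg <- ddg$singles$ddg - old + new
  add_new <- effects$true_ddg[match(
    ddg$doubles$mutation_a,
    effects$mutation
  )] +
    effects$true_ddg[match(ddg$doubles$mutation_b, effects$mutation)]
  pk_all <- pair_key(ddg$doubles$mutation_a, ddg$doubles$mutation_b)
  pk_truth <- pair_key(
    ddg$truth$pairs$mutation_a,
    ddg$truth$pairs$mutation_b
  )
  off <- ddg$truth$pairs$offset[match(pk_all, pk_truth)]
  off[is.na(off)] <- 0
  old_d <- ddg$truth$pairs$true_double_ddg[match(pk_all, pk_truth)]
  ddg$doubles$ddg <- ddg$doubles$ddg - old_d + add_new + off
  ddg$truth$effects <- effects
  ddg$truth$pairs$true_double_ddg <- add_new[match(pk_truth, pk_all)] +
    ddg$truth$pairs$offset
  ddg
}
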