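# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's internal code paths: they operate on raw
# character matrices / vectors with direct counting, so agreement with the
# package is a genuine cross-check.

AAS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Build an alignment from explicit rows; first row is the query by default.
make_aln <- function(..., query_id = NULL) {
  seqs <- c(...)
  if (is.null(names(seqs))) {
    names(seqs) <- c("query", paste0("s", seq_len(length(seqs) - 1)))
  }
  new_alignment(names(seqs), unname(seqs), query_id %||% names(seqs)[1])
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Build a column of an alignment from residue counts, shuffling row order
# deterministically is not needed because column statistics are order-free.
col_from_counts <- function(counts) {
  unlist(mapply(rep, names(counts), counts, SIMPLIFY = FALSE),
    use.names = FALSE
  )
}

# Alignment whose query row is `query` and whose remaining rows realize the
# given per-column residue vectors (list of character vectors, one per
# column, each of length n_other).
aln_from_columns <- function(query, columns) {
  n_other <- length(columns[[1]])
  stopifnot(all(lengths(columns) == n_other))
  mat <- do.call(cbind, columns)
  rows <- apply(mat, 1, paste, collapse = "")
  make_aln(paste(query, collapse = ""), rows)
}

# Random gapped alignment for property tests.
random_alignment <- function(n_seq, n_col, gap_prob = 0.1) {
  mat <- matrix(
    sample(AAS, n_seq * n_col, replace = TRUE),
    nrow = n_seq
  )
  gaps <- matrix(runif(n_seq * n_col) < gap_prob, nrow = n_seq)
  gaps[1, ] <- FALSE # keep the query gap-free for simplicity
  mat[gaps] <- "-"
  new_alignment(
    c("query", paste0("s", seq_len(n_seq - 1))),
    apply(mat, 1, paste, collapse = ""),
    "query"
  )
}

# Brute-force per-column consensus oracle. Direct counting: frequencies
# over non-gap residues, consensus = max frequency with non-wt-then-
# alphabetical tie-break.
oracle_consensus <- function(aln, method, cutoff = 0.5, ratio_cutoff = 0.2,
                             min_freq = 0.4, mask = integer(0)) {
  m <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  qi <- match(attr(aln, "query_id"), aln$id)
  q <- m[qi, ]
  hits <- character(0)
  qpos <- 0L
  for (j in seq_len(ncol(m))) {
    if (q[j] %in% c("-", ".")) next
    qpos <- qpos + 1L
    if (qpos %in% mask || q[j] == "X") next
    col <- m[, j]
    col <- col[!(col %in% c("-", ".", "X"))]
    if (length(col) == 0) next
    tab <- table(col) / length(col)
    best <- names(tab)[tab == max(tab)]
    best <- best[order(best == q[j], best)][1]
    f_cons <- as.numeric(tab[best])
    f_wt <- if (q[j] %in% names(tab)) as.numeric(tab[q[j]]) else 0
    ok <- if (method == "simple") {
      best != q[j] && f_cons >= cutoff
    } else {
      best != q[j] && f_cons >= min_freq && (f_wt / f_cons) <= ratio_cutoff
    }
    if (ok) hits <- c(hits, paste0(q[j], qpos, best))
  }
  hits
}

# Independent greedy-admission oracle: sorted scan over an explicit
# antagonism lookup function. Ties in ddG break by sequence position, the
# documented convention.
oracle_greedy <- function(muts, ddg, antag_fun) {
  pos <- as.numeric(gsub("[^0-9]", "", muts))
  ord <- order(ddg, pos)
  admitted <- character(0)
  for (i in ord) {
    ok <- TRUE
    for (a in admitted) {
      if (antag_fun(muts[i], a)) {
        ok <- FALSE
        break
      }
    }
    if (ok) admitted <- c(admitted, muts[i])
  }
  admitted
}

# Direct-counting precision / false-positive-rate oracle.
oracle_metrics <- function(predicted, truly) {
  tp <- sum(predicted & truly)
  fp <- sum(predicted & !truly)
  tn <- sum(!predicted & !truly)
  list(
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    fpr = if (fp + tn == 0) NA_real_ else fp / (fp + tn)
  )
}

# All-pairs distance oracle for salt bridges on an atom table.
oracle_salt_bridges <- function(atoms, cutoff = 4.0) {
  acid_names <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  base_names <- list(
    LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
    HIS = c("ND1", "NE2")
  )
  is_in <- function(row, sets) {
    row$residue_name %in% names(sets) &&
      row$atom_name %in% sets[[row$residue_name]]
  }
  found <- list()
  for (i in seq_len(nrow(atoms))) {
    ai <- atoms[i, ]
    if (!is_in(ai, acid_names)) next
    for (j in seq_len(nrow(atoms))) {
      aj <- atoms[j, ]
      if (!is_in(aj, base_names)) next
      if (ai$chain == aj$chain && ai$residue_number == aj$residue_number) {
        next
      }
      if (ai$chain != aj$chain) next
      d <- sqrt((ai$x - aj$x)^2 + (ai$y - aj$y)^2 + (ai$z - aj$z)^2)
      if (d <= cutoff) {
        key <- paste(ai$chain, ai$residue_number, aj$chain,
          aj$residue_number,
          sep = "_"
        )
        found[[key]] <- min(found[[key]] %||% Inf, d)
      }
    }
  }
  found
}

pair_strings <- function(pairs) {
  paste(
    pmin(pairs$mutation_a, pairs$mutation_b),
    pmax(pairs$mutation_a, pairs$mutation_b)
  )
}

# Labelled benchmark fixture with matched predictions for two tools.
sweep_fixture <- function(seed = 17, n = 40) {
  set.seed(seed)
  wt <- sample(AAS, n, replace = TRUE)
  sub <- vapply(wt, function(w) sample(setdiff(AAS, w), 1), character(1))
  muts <- sprintf("%s%d%s", wt, seq_len(n), sub)
  truth <- runif(n) < 0.25
  recs <- tibble::tibble(
    protein_id = "p1", mutation = muts,
    ddg_exp = ifelse(truth, runif(n, -3, -0.5), runif(n, 0.5, 3)),
    pH = 7, temperature = 25, record_id = sprintf("r%03d", seq_len(n))
  )
  ds <- curate(recs, sign_convention = "stabilizing_negative")
  summaries <- dplyr::bind_rows(lapply(c("foldx", "rosetta"), function(tl) {
    p <- parse_mutations(muts)
    p$tool <- tl
    p$mean_ddg <- ifelse(truth, rnorm(n, -2, 1), rnorm(n, 1, 1))
    p$n_structures <- 3L
    p$n_replicates <- 1L
    p
  }))
  list(ds = ds, summaries = summaries, truth = truth)
}

# Random charged-residue toy structure: n residues, one charged atom each,
# in a box small enough that contacts occur.
random_charged_structure <- function(n = 30, box = 15) {
  res <- sample(c("ASP", "GLU", "LYS", "ARG", "HIS"), n, replace = TRUE)
  atom <- vapply(res, function(r) {
    switch(r,
      ASP = sample(c("OD1", "OD2"), 1),
      GLU = sample(c("OE1", "OE2"), 1),
      LYS = "NZ",
      ARG = sample(c("NH1", "NH2", "NE"), 1),
      HIS = sample(c("ND1", "NE2"), 1)
    )
  }, character(1))
  new_structure_model(
    data.frame(
      chain = "A", residue_number = seq_len(n), residue_name = res,
      atom_name = atom,
      x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box)
    ),
    structure_id = "rand"
  )
}
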