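# Side-chain charged-group atoms used by the salt-bridge criterion.
# His is counted as positively charged, following the convention of
# salt-bridge servers that include it.
ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASIC_ATOMS <- list(
  LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
  HIS = c("ND1", "NE2")
)

#' Read a protein structure from a PDB file
#'
#' Loads the first model of a PDB file via [bio3d::read.pdb()], keeps the
#' highest-occupancy alternate location of each atom, and drops hetero atoms
#' and waters (structures are consumed after ligand/water removal). Atoms
#' are returned as a tidy table.
#'
#' @param path Path to a PDB file.
#' @param structure_id Identifier stored with the model; defaults to the
#'   file name without extension.
#' @return A tibble of class `structure_model` with columns `chain`,
#'   `residue_number`, `residue_name`, `atom_name`, `x`, `y`, `z` and a
#'   `structure_id` attribute.
#' @export
read_structure <- function(path, structure_id = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) abort(paste0("cannot parse PDB file ", path, ": ",
      conditionMessage(e)))
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ]
  if (nrow(at) == 0L) abort(paste0("no protein atoms in ", path))
  # keep highest-occupancy altloc per (chain, residue, atom)
  o <- at$o
  o[is.na(o)] <- 1
  key <- paste(at$chain, at$resno, at$elety)
  ord <- order(key, -o)
  at <- at[ord[!duplicated(key[ord])], ]
  out <- tibble(
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    residue_number = as.integer(at$resno),
    residue_name = at$resid,
    atom_name = at$elety,
    x = at$x, y = at$y, z = at$z
  )
  out <- arrange(out, .data$chain, .data$residue_number)
  attr(out, "structure_id") <- structure_id %||%
    sub("\\.[^.]*$", "", basename(path))
  class(out) <- c("structure_model", class(tibble()))
  out
}

#' Construct a structure model from an atom table
#'
#' @param atoms Data frame with columns `chain`, `residue_number`,
#'   `residue_name`, `atom_name`, `x`, `y`, `z`.
#' @param structure_id Identifier for the model.
#' @return A `structure_model` tibble.
#' @export
new_structure_model <- function(atoms, structure_id) {
  need <- c(
    "chain", "residue_number", "residue_name", "atom_name",
    "x", "y", "z"
  )
  stopifnot(all(need %in% names(atoms)))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("atom coordinates must be finite")
  }
  out <- as_tibble(atoms[, need])
  out$residue_number <- as.integer(out$residue_number)
  attr(out, "structure_id") <- structure_id
  class(out) <- c("structure_model", class(tibble()))
  out
}

#' Detect intra-molecular salt bridges
#'
#' Flags every Asp/Glu side-chain carboxyl oxygen lying within `cutoff`
#' (default 4.0 Angstrom, a conventional salt-bridge criterion) of an
#' Arg/Lys/His side-chain nitrogen. Only intra-chain pairs are considered
#' by default ("intra-molecular" contacts); with `intra_chain_only = FALSE`
#' inter-chain pairs are reported too. The minimum heavy-atom distance per
#' residue pair is reported.
#'
#' @param structure A `structure_model`.
#' @param cutoff Distance cutoff in Angstrom (inclusive).
#' @param intra_chain_only Restrict to pairs within one chain.
#' @return Tibble of interaction records: `kind` (`"salt_bridge"`),
#'   `chain_a`, `res_a`, `chain_b`, `res_b`, `min_distance`,
#'   `structure_id`. Pair members are ordered with the acidic residue
#'   first.
#' @export
find_salt_bridges <- function(structure, cutoff = 4.0,
                              intra_chain_only = TRUE) {
  acid <- charged_atoms(structure, ACIDIC_ATOMS)
  base <- charged_atoms(structure, BASIC_ATOMS)
  empty <- interaction_tbl()
  if (nrow(acid) == 0L || nrow(base) == 0L) {
    return(empty)
  }
  d <- sqrt(outer(acid$x, base$x, "-")^2 +
    outer(acid$y, base$y, "-")^2 +
    outer(acid$z, base$z, "-")^2)
  hits <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hits) == 0L) {
    return(empty)
  }
  rec <- tibble(
    chain_a = acid$chain[hits[, 1]],
    res_a = acid$residue_number[hits[, 1]],
    chain_b = base$chain[hits[, 2]],
    res_b = base$residue_number[hits[, 2]],
    dist = d[hits]
  )
  rec <- rec[!(rec$chain_a == rec$chain_b & rec$res_a == rec$res_b), ]
  if (intra_chain_only) rec <- rec[rec$chain_a == rec$chain_b, ]
  if (nrow(rec) == 0L) {
    return(empty)
  }
  rec %>%
    group_by(.data$chain_a, .data$res_a, .data$chain_b, .data$res_b) %>%
    summarise(min_distance = min(.data$dist), .groups = "drop") %>%
    mutate(
      kind = "salt_bridge",
      structure_id = attr(structure, "structure_id") %||% NA_character_
    ) %>%
    select(
      "kind", "chain_a", "res_a", "chain_b", "res_b",
      "min_distance", "structure_id"
    ) %>%
    arrange(.data$chain_a, .data$res_a, .data$res_b)
}

charged_atoms <- function(structure, atom_sets) {
  keep <- rep(FALSE, nrow(structure))
  for (res in names(atom_sets)) {
    keep <- keep | (structure$residue_name == res &
      structure$atom_name %in% atom_sets[[res]])
  }
  structure[keep, ]
}

interaction_tbl <- function() {
  tibble(
    kind = character(0), chain_a = character(0), res_a = integer(0),
    chain_b = character(0), res_b = integer(0),
    min_distance = numeric(0), structure_id = character(0)
  )
}

# Aliphatic side-chain carbons and aromatic ring atoms for the optional
# interaction classes.
ALIPHATIC_RES <- c("ALA", "VAL", "LEU", "ILE", "MET", "PRO")
AROMATIC_RING <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

#' Detect hydrophobic side-chain contacts
#'
#' Optional interaction class (off by default in the pipeline): flags
#' pairs of aliphatic residues (Ala, Val, Leu, Ile, Met, Pro) with any two
#' side-chain carbons within `cutoff` (default 5.0 Angstrom). Intra-chain
#' only by default, like [find_salt_bridges()].
#'
#' @inheritParams find_salt_bridges
#' @param cutoff Distance cutoff in Angstrom (inclusive).
#' @return Interaction tibble with `kind = "hydrophobic"`.
#' @export
find_hydrophobic_contacts <- function(structure, cutoff = 5.0,
                                      intra_chain_only = TRUE) {
  sc <- structure[structure$residue_name %in% ALIPHATIC_RES &
    grepl("^C", structure$atom_name) &
    !structure$atom_name %in% c("C", "CA"), ]
  pairwise_contacts(sc, sc, cutoff, "hydrophobic", intra_chain_only,
    structure_id = attr(structure, "structure_id")
  )
}

#' Detect aromatic ring-stacking contacts
#'
#' Optional interaction class (off by default in the pipeline): computes
#' ring centroids of Phe/Tyr/Trp/His side chains and flags pairs whose
#' centroid distance lies within `range` (default 4.5-7.0 Angstrom, the
#' conventional stacking window).
#'
#' @inheritParams find_salt_bridges
#' @param range Length-2 numeric: inclusive centroid-distance window.
#' @return Interaction tibble with `kind = "aromatic"`; `min_distance` is
#'   the centroid-centroid distance.
#' @export
find_aromatic_contacts <- function(structure, range = c(4.5, 7.0),
                                   intra_chain_only = TRUE) {
  ring <- structure[
    structure$residue_name %in% names(AROMATIC_RING) &
      mapply(
        function(rn, an) an %in% AROMATIC_RING[[rn]],
        structure$residue_name, structure$atom_name
      ),
  ]
  empty <- interaction_tbl()
  if (nrow(ring) == 0L) {
    return(empty)
  }
  cent <- ring %>%
    group_by(.data$chain, .data$residue_number) %>%
    summarise(
      x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
      .groups = "drop"
    )
  if (nrow(cent) < 2L) {
    return(empty)
  }
  out <- pairwise_contacts(cent, cent, range[2], "aromatic",
    intra_chain_only,
    structure_id = attr(structure, "structure_id")
  )
  out[out$min_distance >= range[1], ]
}

pairwise_contacts <- function(a, b, cutoff, kind, intra_chain_only,
                              structure_id) {
  empty <- interaction_tbl()
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(empty)
  }
  d <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
    outer(a$z, b$z, "-")^2)
  hits <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hits) == 0L) {
    return(empty)
  }
  rec <- tibble(
    chain_a = a$chain[hits[, 1]],
    res_a = a$residue_number[hits[, 1]],
    chain_b = b$chain[hits[, 2]],
    res_b = b$residue_number[hits[, 2]],
    dist = d[hits]
  )
  # distinct residues, each unordered pair once
  rec <- rec[paste(rec$chain_a, sprintf("%09d", rec$res_a)) <
    paste(rec$chain_b, sprintf("%09d", rec$res_b)), ]
  if (intra_chain_only) rec <- rec[rec$chain_a == rec$chain_b, ]
  if (nrow(rec) == 0L) {
    return(empty)
  }
  rec %>%
    group_by(.data$chain_a, .data$res_a, .data$chain_b, .data$res_b) %>%
    summarise(min_distance = min(.data$dist), .groups = "drop") %>%
    mutate(kind = kind, structure_id = structure_id %||% NA_character_) %>%
    select(
      "kind", "chain_a", "res_a", "chain_b", "res_b",
      "min_distance", "structure_id"
    ) %>%
    arrange(.data$chain_a, .data$res_a, .data$res_b)
}

#' Union of interactions across structures or chains
#'
#' An interaction is considered important if present in at least one of the
#' analysed structures or chains. Records are deduplicated by kind and
#' unordered residue pair; the contributing structures are kept as a
#' provenance column and the smallest observed distance is retained.
#'
#' @param ... Interaction tibbles (from [find_salt_bridges()]), or a single
#'   list of them.
#' @return Deduplicated interaction tibble with `structures` (comma-joined
#'   provenance) and `n_structures` columns.
#' @export
union_interactions <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1L && is.list(inputs[[1]]) &&
    !is.data.frame(inputs[[1]])) {
    inputs <- inputs[[1]]
  }
  if (length(inputs) == 0L) abort("no interaction sets supplied")
  all <- bind_rows(inputs)
  if (nrow(all) == 0L) {
    out <- interaction_tbl()
    out$structure_id <- NULL
    out$structures <- character(0)
    out$n_structures <- integer(0)
    return(out)
  }
  # canonical unordered pair: lexicographically smaller (chain, res) first
  flip <- paste(all$chain_a, sprintf("%09d", all$res_a)) >
    paste(all$chain_b, sprintf("%09d", all$res_b))
  tmp_c <- all$chain_a[flip]
  tmp_r <- all$res_a[flip]
  all$chain_a[flip] <- all$chain_b[flip]
  all$res_a[flip] <- all$res_b[flip]
  all$chain_b[flip] <- tmp_c
  all$res_b[flip] <- tmp_r
  all %>%
    group_by(.data$kind, .data$chain_a, .data$res_a, .data$chain_b,
      .data$res_b) %>%
    summarise(
      min_distance = min(.data$min_distance),
      structures = paste(unique(.data$structure_id), collapse = ","),
      n_structures = length(unique(.data$structure_id)),
      .groups = "drop"
    ) %>%
    arrange(.data$chain_a, .data$res_a, .data$res_b)
}

#' Discard candidates whose wild-type side chains form interactions
#'
#' A candidate mutation is discarded when its wild-type residue participates
#' in any interaction of the set (e.g. a salt bridge that the substitution
#' would disrupt). Positions are matched to structure residue numbers
#' through an identity mapping by default; supply `position_map` (tibble
#' with `position`, `residue_number`) for structures with offset author
#' numbering.
#'
#' @param candidates Tibble with at least `mutation` and `position` columns.
#' @param interactions Interaction set from [union_interactions()] (or a
#'   single structure's records).
#' @param position_map Optional tibble mapping sequence `position` to
#'   structure `residue_number`.
#' @param structure Optional `structure_model` used to verify that every
#'   candidate position resolves to a residue; unresolvable positions are an
#'   error.
#' @return The candidate tibble with added `decision` (`"kept"` /
#'   `"discarded"`) and `reason` columns (machine-readable, `NA` for kept).
#' @export
filter_interacting <- function(candidates, interactions,
                               position_map = NULL, structure = NULL) {
  res_num <- candidates$position
  if (!is.null(position_map)) {
    idx <- match(candidates$position, position_map$position)
    if (anyNA(idx)) {
      abort(paste0(
        "position(s) not resolvable to structure residues: ",
        paste(candidates$position[is.na(idx)], collapse = ", ")
      ))
    }
    res_num <- position_map$residue_number[idx]
  }
  if (!is.null(structure)) {
    known <- unique(structure$residue_number)
    if (any(!res_num %in% known)) {
      abort(paste0(
        "position(s) absent from structure: ",
        paste(candidates$position[!res_num %in% known], collapse = ", ")
      ))
    }
  }
  hit_kind <- rep(NA_character_, nrow(candidates))
  if (nrow(interactions) > 0L) {
    for (i in seq_along(res_num)) {
      j <- which(interactions$res_a == res_num[i] |
        interactions$res_b == res_num[i])
      if (length(j) > 0L) hit_kind[i] <- interactions$kind[j[1]]
    }
  }
  candidates %>%
    mutate(
      decision = ifelse(is.na(hit_kind), "kept", "discarded"),
      reason = hit_kind
    )
}
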