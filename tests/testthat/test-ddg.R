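test_that("generic ddG tables parse, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("C128F\t1BN6\t-1.4", path)
  rec <- parse_ddg_table(path, "generic_tsv")
  expect_equal(rec$mutation, "C128F")
  expect_equal(rec$ddg, -1.4)
  expect_equal(rec$replicate, 1L)
  expect_equal(rec$position, 128L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("C128C\t1BN6\t-1.4", bad)
  expect_error(parse_ddg_table(bad, "generic_tsv"), "wild-type equals")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(parse_ddg_table(empty, "generic_tsv"), "empty")

  # 100 random records survive a write/read cycle unchanged
  set.seed(5)
  wt <- sample(AAS, 100, replace = TRUE)
  sub <- vapply(wt, function(w) sample(setdiff(AAS, w), 1), character(1))
  recs <- parse_ddg_table(
    {
      p <- withr::local_tempfile(fileext = ".tsv")
      writeLines(sprintf(
        "%s%d%s\t%s\t%.4f\t%d", wt, 101:200, sub,
        sample(c("s1", "s2"), 100, TRUE),
        round(rnorm(100), 4), sample(1:5, 100, TRUE)
      ), p)
      p
    },
    "generic_tsv"
  )
  out <- withr::local_tempfile(fileext = ".tsv")
  write_ddg_table(recs, out)
  again <- parse_ddg_table(out, "generic_tsv")
  expect_equal(again, recs)
})

test_that("FoldX- and Rosetta-style output files are parsed leniently", {
  fx <- withr::local_tempfile(fileext = ".fxout")
  writeLines(c(
    "BuildModel run on struct1",
    "Pdb\ttotal energy\tBackbone Hbond",
    "C128F_1.pdb\t-1.40\t0.2",
    "C128F_2.pdb\t-1.20\t0.2",
    "T148L_1.pdb\t0.65\t0.1"
  ), fx)
  rec <- parse_ddg_table(fx, "foldx_buildmodel", structure_id = "1BN6")
  expect_equal(rec$mutation, c("C128F", "C128F", "T148L"))
  expect_equal(rec$replicate, c(1L, 2L, 1L))
  expect_equal(rec$tool, rep("foldx", 3))
  expect_equal(rec$structure_id, rep("1BN6", 3))
  expect_error(
    parse_ddg_table(fx, "foldx_buildmodel"),
    "structure_id"
  )

  rs <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "ddG: description total fa_atr fa_rep",
    "ddG: C128F -2.134 -1.0 0.2",
    "ddG: T148L -2.950 -1.2 0.1"
  ), rs)
  rec2 <- parse_ddg_table(rs, "rosetta_ddg_monomer", structure_id = "1CQW")
  expect_equal(rec2$ddg, c(-2.134, -2.950))
  expect_equal(rec2$tool, rep("rosetta", 2))
})

make_records <- function(mutation, structure_id, ddg, tool = "foldx",
                         replicate = 1L) {
  p <- parse_mutations(mutation)
  tibble::tibble(
    mutation = p$mutation, wt = p$wt, position = p$position, sub = p$sub,
    structure_id = structure_id, tool = tool, ddg = ddg,
    replicate = replicate
  )
}

test_that("ddG summaries average replicates within, then across structures", {
  rec <- make_records(rep("C128F", 3), c("s1", "s2", "s3"), c(-1, -2, -3))
  expect_equal(summarize_ddg(rec)$mean_ddg, -2)

  one <- make_records("C128F", "s1", -1.5)
  expect_equal(summarize_ddg(one)$mean_ddg, -1.5)
  expect_equal(summarize_ddg(one)$n_structures, 1L)

  # replicate-first averaging: s1 has replicates (0, -2) -> -1; s2 has -3
  rep_rec <- make_records(
    rep("C128F", 3), c("s1", "s1", "s2"), c(0, -2, -3),
    replicate = c(1L, 2L, 1L)
  )
  expect_equal(summarize_ddg(rep_rec)$mean_ddg, mean(c(-1, -3)))
})

test_that("mutations missing an expected structure are excluded or warned", {
  rec <- rbind(
    make_records(rep("C128F", 3), c("s1", "s2", "s3"), c(-1, -2, -3)),
    make_records(rep("T148L", 2), c("s1", "s2"), c(-1, -2))
  )
  expect_message(s <- summarize_ddg(rec), "excluded")
  expect_equal(s$mutation, "C128F")
  expect_equal(attr(s, "excluded")$mutation, "T148L")

  expect_warning(
    s2 <- summarize_ddg(rec, require_all_structures = FALSE),
    "fewer structures"
  )
  expect_equal(nrow(s2), 2L)
  expect_equal(s2$mean_ddg[s2$mutation == "T148L"], -1.5)
})

test_that("summaries are order-invariant and shift-linear", {
  set.seed(9)
  rec <- make_records(
    rep(c("C128F", "T148L"), each = 6),
    rep(c("s1", "s2", "s3"), 4), rnorm(12),
    replicate = rep(1:2, 6)
  )
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(
    dplyr::arrange(summarize_ddg(rec), mutation),
    dplyr::arrange(summarize_ddg(shuffled), mutation),
    ignore_attr = TRUE
  )
  shifted <- rec
  shifted$ddg <- shifted$ddg + 1.7
  expect_equal(
    summarize_ddg(shifted)$mean_ddg,
    summarize_ddg(rec)$mean_ddg + 1.7
  )
})

test_that("stability calls use strict thresholds per tool", {
  s <- summarize_ddg(make_records(
    c("C128F", "T148L", "A172I", "D198W"), "s1",
    c(-1.2, -1.0, 0.6, 0.5)
  ))
  called <- call_stability(s)
  calls <- setNames(called$call, called$mutation)
  expect_equal(calls[["C128F"]], "stabilizing") # -1.2 < -1.0
  expect_equal(calls[["T148L"]], "neutral") # exactly at threshold
  expect_equal(calls[["A172I"]], "destabilizing") # 0.6 > 0.5
  expect_equal(calls[["D198W"]], "neutral") # exactly at 0.5

  # rosetta default is stricter
  s_r <- s
  s_r$tool <- "rosetta"
  calls_r <- setNames(call_stability(s_r)$call, s_r$mutation)
  expect_equal(calls_r[["C128F"]], "neutral") # -1.2 >= -2.0

  s_g <- s
  s_g$tool <- "generic"
  expect_error(call_stability(s_g), "generic")
  expect_equal(
    call_stability(s_g, -1, 0.5)$call,
    called$call
  )
})

test_that("lowering the stabilizing threshold never enlarges the set", {
  set.seed(33)
  s <- summarize_ddg(make_records(
    sprintf("A%dV", 1:40), "s1", rnorm(40, -1, 1.5)
  ))
  thresholds <- c(-0.5, -1, -1.5, -2)
  sets <- lapply(thresholds, function(t) {
    called <- call_stability(s, t, 0.5)
    called$mutation[called$call == "stabilizing"]
  })
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

energy_universe <- function(seed) {
  set.seed(seed)
  n <- 30
  wt <- sample(AAS, n, replace = TRUE)
  sub <- vapply(wt, function(w) sample(setdiff(AAS, w), 1), character(1))
  muts <- sprintf("%s%d%s", wt, seq_len(n), sub)
  fx <- call_stability(summarize_ddg(
    make_records(muts, "s1", rnorm(n, -1, 1), tool = "foldx")
  ))
  rs <- call_stability(summarize_ddg(
    make_records(muts, "s1", rnorm(n, -1.5, 1.5), tool = "rosetta")
  ))
  cons <- tibble::tibble(
    position = seq_len(n),
    grade = sample(1:9, n, replace = TRUE)
  )
  corr <- tibble::tibble(
    position = seq_len(n),
    score = runif(n)
  )
  list(fx = fx, rs = rs, cons = cons, corr = corr)
}

test_that("energy candidates require agreement and mutable positions", {
  fx <- call_stability(summarize_ddg(make_records(
    c("C128F", "T148L", "A172I", "V219W"), "s1", c(-1.5, -1.4, -1.3, -0.2)
  )))
  rs <- call_stability(summarize_ddg(make_records(
    c("C128F", "T148L", "A172I"), "s1", c(-2.5, -2.4, -2.3),
    tool = "rosetta"
  )))
  cons <- tibble::tibble(position = c(128, 148, 172, 219),
    grade = c(5, 8, 3, 2))
  corr <- tibble::tibble(position = c(128, 148, 172, 219),
    score = c(0.3, 0.1, 0.85, 0.2))
  expect_message(
    cand <- energy_candidates(fx, rs, cons, corr),
    "excluded"
  )
  # T148L: grade 8 immutable; A172I: correlated 0.85; V219W: one tool only
  expect_equal(cand$mutation, "C128F")
  ex <- attr(cand, "excluded")
  expect_equal(
    setNames(ex$reason, ex$mutation)[c("T148L", "A172I", "V219W")],
    c(
      T148L = "conserved_position", A172I = "correlated_position",
      V219W = "single_tool_only"
    )
  )
})

test_that("candidate set is unchanged by filtering before or after energy", {
  for (seed in 1:100) {
    u <- energy_universe(seed)
    after <- suppressMessages(
      energy_candidates(u$fx, u$rs, u$cons, u$corr)
    )
    # conservation-first: drop filtered positions from the calls up front
    bad_pos <- union(
      u$cons$position[u$cons$grade >= 8],
      u$corr$position[u$corr$score >= 0.8]
    )
    fx_pre <- u$fx[!u$fx$position %in% bad_pos, ]
    rs_pre <- u$rs[!u$rs$position %in% bad_pos, ]
    before <- suppressMessages(energy_candidates(fx_pre, rs_pre))
    expect_equal(sort(after$mutation), sort(before$mutation))
    # candidates are a subset of each tool's stabilizing set
    expect_true(all(
      after$mutation %in% u$fx$mutation[u$fx$call == "stabilizing"]
    ))
    expect_true(all(
      after$mutation %in% u$rs$mutation[u$rs$call == "stabilizing"]
    ))
  }
})
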