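rec_tbl <- function(...) {
  tibble::tibble(...)
}

base_records <- function() {
  rec_tbl(
    protein_id = c("p1", "p1", "p1", "p1", "p2", "p2"),
    mutation = c("A10V", "A10V", "L20I", "G30A", "F40Y", "F40Y"),
    ddg_exp = c(-1.2, -1.0, 0.4, 0.5, 2.0, 1.4),
    pH = c(6.5, 8.2, 7.0, 7.0, NA, 5.0),
    temperature = c(25, 25, 25, 25, 25, 25),
    record_id = sprintf("r%02d", 1:6)
  )
}

test_that("curation filters small effects and deduplicates by pH", {
  ds <- curate(base_records(), sign_convention = "stabilizing_negative")
  # |ddG| = 0.4 excluded, 0.5 kept (inclusive)
  expect_false("L20I" %in% ds$mutation)
  expect_true("G30A" %in% ds$mutation)
  # duplicate A10V: pH 6.5 beats 8.2
  expect_equal(ds$ddg_exp[ds$mutation == "A10V"], -1.2)
  # duplicate F40Y: missing pH loses to pH 5.0
  expect_equal(ds$ddg_exp[ds$mutation == "F40Y"], 1.4)
  expect_equal(
    setNames(ds$label, ds$mutation)[c("A10V", "G30A")],
    c(A10V = "stabilizing", G30A = "destabilizing")
  )
})

test_that("pH ties and all-missing duplicates resolve deterministically", {
  recs <- rec_tbl(
    protein_id = "p", mutation = c("A1V", "A1V"),
    ddg_exp = c(-1, -2), pH = c(6.5, 7.5),
    temperature = c(25, 25), record_id = c("r2", "r1")
  )
  ds <- curate(recs, sign_convention = "stabilizing_negative")
  expect_equal(ds$ddg_exp, -1) # |6.5-7| = |7.5-7|: lower pH wins

  recs2 <- rec_tbl(
    protein_id = "p", mutation = c("A1V", "A1V"),
    ddg_exp = c(-1, -2), pH = c(NA, NA),
    temperature = c(25, 25), record_id = c("r2", "r1")
  )
  ds2 <- curate(recs2, sign_convention = "stabilizing_negative")
  expect_equal(ds2$record_id, "r1") # first by record id
})

test_that("sign conventions canonicalize to stabilizing-negative", {
  recs <- rec_tbl(
    protein_id = "p", mutation = "A1V", ddg_exp = 1.5,
    pH = 7, temperature = 25, record_id = "r1"
  )
  ds <- curate(recs, sign_convention = "stabilizing_positive")
  expect_equal(ds$ddg_exp, -1.5)
  expect_equal(ds$label, "stabilizing")
  expect_error(curate(recs), "sign_convention")
})

test_that("curation is idempotent", {
  ds <- curate(base_records(), sign_convention = "stabilizing_negative")
  again <- curate(ds)
  expect_equal(as.data.frame(again), as.data.frame(ds))
})

test_that("stability record files round-trip with declared convention", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# sign_convention: stabilizing_negative",
    "protein_id\tmutation\tddg_exp\tpH\ttemperature\trecord_id",
    "p1\tA10V\t-1.2\t6.5\t25\tr01",
    "p1\tL20I\t0.8\t7.0\t25\tr02"
  ), path)
  recs <- read_stability_records(path)
  expect_equal(attr(recs, "sign_convention"), "stabilizing_negative")
  expect_equal(nrow(recs), 2L)
  ds <- curate(recs)
  expect_equal(nrow(ds), 2L)
})

test_that("precision and FPR follow their confusion-count definitions", {
  expect_equal(
    precision(list(tp = 16, fp = 5)), 16 / 21,
    tolerance = 1e-12
  )
  expect_equal(round_percent(precision(list(tp = 16, fp = 5))), 76L)
  expect_equal(round_percent(precision(list(tp = 20, fp = 10))), 67L)
  expect_true(is.na(precision(list(tp = 0, fp = 0))))

  expect_equal(round_percent(false_positive_rate(
    list(fp = 5, tn = 532)
  )), 1L)
  expect_equal(round_percent(false_positive_rate(
    list(fp = 10, tn = 527)
  )), 2L)
  expect_equal(false_positive_rate(list(fp = 0, tn = 100)), 0)
  expect_true(is.na(false_positive_rate(list(fp = 0, tn = 0))))
  # half-away-from-zero report rounding
  expect_equal(round_percent(0.005), 1L)
  expect_equal(round_percent(0.675), 68L)
})

test_that("metrics agree with a direct-counting oracle on random sets", {
  set.seed(303)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    predicted <- runif(n) < runif(1)
    truly <- runif(n) < runif(1)
    cc <- confusion_counts(predicted, truly)
    want <- oracle_metrics(predicted, truly)
    expect_equal(precision(cc), want$precision)
    expect_equal(false_positive_rate(cc), want$fpr)
    expect_equal(cc$tp + cc$fn, sum(truly))
    expect_equal(cc$fp + cc$tn, sum(!truly))
  }
})

test_that("threshold sweep covers the grid with monotone prediction counts", {
  fx <- sweep_fixture()
  sw <- threshold_sweep(fx$summaries, fx$ds)
  expect_equal(nrow(sw), 22L) # 11 thresholds x 2 tools
  for (tl in unique(sw$tool)) {
    rows <- sw[sw$tool == tl, ]
    expect_equal(rows$threshold, seq(-2.5, 2.5, by = 0.5))
    expect_true(all(diff(rows$n_predicted_stabilizing) >= 0))
  }
  # undefined precision marker when nothing is predicted stabilizing
  all_destab <- fx$summaries
  all_destab$mean_ddg <- abs(all_destab$mean_ddg) + 1
  destab_ds <- fx$ds[fx$ds$label == "destabilizing", ]
  sw2 <- threshold_sweep(all_destab, destab_ds)
  row <- sw2[sw2$threshold == -2.5 & sw2$tool == "foldx", ]
  expect_true(is.na(row$precision))
  expect_equal(row$fpr, 0)

  # missing predictions: error by default, droppable on request
  gap <- fx$summaries[fx$summaries$mutation != fx$ds$mutation[1], ]
  expect_error(threshold_sweep(gap, fx$ds), "no foldx prediction")
  expect_message(
    sw3 <- threshold_sweep(gap, fx$ds, missing = "skip"),
    "skipped"
  )
  expect_equal(nrow(sw3), 22L)
})

test_that("glance picks the highest-precision threshold per tool", {
  fx <- sweep_fixture()
  sw <- threshold_sweep(fx$summaries, fx$ds)
  g <- glance(sw)
  expect_equal(nrow(g), 2L)
  for (tl in g$tool) {
    expect_equal(
      g$precision[g$tool == tl],
      max(sw$precision[sw$tool == tl], na.rm = TRUE)
    )
  }
})

test_that("the combined rule is at least as precise as either tool alone", {
  fx <- sweep_fixture(seed = 23)
  calls <- call_stability(fx$summaries)
  fx_calls <- calls[calls$tool == "foldx", ]
  rs_calls <- calls[calls$tool == "rosetta", ]
  combined <- suppressMessages(
    evaluate_pipeline(fx_calls, rs_calls, fx$ds)
  )
  # combined predictions are a subset of each tool's stabilizing calls
  for (one in list(fx_calls, rs_calls)) {
    stab <- one$mutation[one$call == "stabilizing"]
    n_pred <- combined$n_predicted_stabilizing
    expect_true(n_pred <= length(stab))
    expect_true(combined$fp <= sum(
      fx$ds$label[fx$ds$mutation %in% stab] == "destabilizing"
    ))
  }
})

test_that("the pipeline rule scores constructed universes exactly", {
  muts <- c("A10V", "L20I", "G30A", "F40Y")
  mk_calls <- function(tool, ddg) {
    p <- parse_mutations(muts)
    p$tool <- tool
    p$mean_ddg <- ddg
    p$n_structures <- 3L
    call_stability(p)
  }
  # both tools call A10V and L20I stabilizing; G30A/F40Y not
  fx <- mk_calls("foldx", c(-1.5, -1.6, 0.2, 0.8))
  rs <- mk_calls("rosetta", c(-2.5, -2.6, 0.2, 0.8))
  ds <- curate(
    rec_tbl(
      protein_id = "p", mutation = muts,
      ddg_exp = c(-1.5, 1.0, 0.9, 1.1), # L20I is a false positive
      pH = 7, temperature = 25, record_id = sprintf("r%d", 1:4)
    ),
    sign_convention = "stabilizing_negative"
  )
  no_filter <- suppressMessages(evaluate_pipeline(fx, rs, ds))
  expect_equal(no_filter$tp, 1L)
  expect_equal(no_filter$fp, 1L)
  expect_equal(no_filter$precision, 0.5)

  # conservation filtering removes the grade-8 false positive
  cons <- tibble::tibble(position = c(10, 20, 30, 40),
    grade = c(3, 8, 1, 1))
  filtered <- suppressMessages(evaluate_pipeline(fx, rs, ds, cons))
  expect_equal(filtered$precision, 1.0)
  expect_equal(filtered$fpr, 0.0)

  # empty intersection -> undefined precision
  rs_none <- mk_calls("rosetta", c(0, 0, 0, 0))
  none <- suppressMessages(evaluate_pipeline(fx, rs_none, ds))
  expect_true(is.na(none$precision))

  # predictions must cover the dataset
  expect_error(
    suppressMessages(
      evaluate_pipeline(fx[-1, ], rs[-1, ], ds)
    ),
    "A10V"
  )
})
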