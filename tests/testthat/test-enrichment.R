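fake_prediction_set <- function(events, grouping = "condition") {
  if (nrow(events) == 0) {
    return(structure(list(events = events,
                          counts = data.frame(group = character(0),
                                              protease_id = character(0),
                                              n_events = integer(0)),
                          totals = integer(0), grouping = grouping,
                          skipped = character(0), protease_ids = character(0)),
                     class = "prediction_set"))
  }
  counts <- aggregate(list(n_events = events$key),
                      by = list(group = events$group,
                                protease_id = events$protease_id),
                      FUN = length)
  totals <- tapply(events$key, events$group, length)
  structure(list(events = events,
                 counts = counts,
                 totals = setNames(as.integer(totals), names(totals)),
                 grouping = grouping, skipped = character(0),
                 protease_ids = unique(events$protease_id)),
            class = "prediction_set")
}

events_df <- function(keys, proteases, group = "all", terminus = "N") {
  data.frame(key = keys, peptide_id = keys, uniprot = "P", terminus = terminus,
             cut_position = 1L, window = "AAAAAAAA",
             protease_id = proteases, group = group, stringsAsFactors = FALSE)
}

test_that("the reference library tallies events per protease, order-invariantly", {
  ev <- events_df(c("p1", "p2", "p3"), c("A", "A", "B"))
  ref <- build_reference(fake_prediction_set(ev, "all"))
  expect_equal(ref$N, 3)
  expect_equal(unname(ref$K[c("A", "B")]), c(2, 1))
  ref2 <- build_reference(fake_prediction_set(ev[c(3, 1, 2), ], "all"))
  expect_identical(ref, ref2)
  expect_error(build_reference(fake_prediction_set(ev[0, ], "all")),
               class = "urodegradome_empty_error")
})

test_that("reference N equals an independent event recount on synthetic health data", {
  study <- generate_study(small_study_config(), seed = 13)
  hp <- predict_degradome(study$health, study$rules, study$proteome,
                          grouping = "all")
  ref <- build_reference(hp)
  manual <- length(unique(paste(hp$events$key, hp$events$terminus,
                                hp$events$protease_id)))
  expect_equal(ref$N, manual)
  expect_equal(sum(ref$K), ref$N)
})

test_that("hypergeometric upper tail matches hand combinatorics", {
  expect_identical(hypergeom_upper_tail(0, 5, 2, 10), 1)
  expect_equal(hypergeom_upper_tail(2, 5, 2, 10), 10 / 45, tolerance = 1e-15)
  expect_identical(hypergeom_upper_tail(3, 2, 5, 10), 0)
  expect_error(hypergeom_upper_tail(3, 2, 1, 10),
               class = "urodegradome_argument_error")
  expect_error(hypergeom_upper_tail(1, 11, 2, 10),
               class = "urodegradome_argument_error")
})

test_that("enrichment folds, flags and Bonferroni arithmetic behave", {
  # disease: 2 of 4 events are A; reference: 10 of 20 are A -> fold 1.0
  ev <- events_df(sprintf("d%d", 1:4), c("A", "A", "B", "C"), group = "g1")
  href <- structure(list(N = 20, K = c(A = 10, B = 5, C = 5)),
                    class = "reference_library")
  res <- enrich(fake_prediction_set(ev), href)
  rowA <- res[res$protease_id == "A", ]
  expect_equal(rowA$fold_enrichment, 1.0)
  expect_equal(attr(res, "m"), 3)
  expect_true(all(res$p_adj >= res$p_raw, na.rm = TRUE))
  expect_true(all(res$p_adj <= 1, na.rm = TRUE))

  # K = 0, k > 0: disease-only, fold undefined, no test
  ev2 <- events_df(sprintf("d%d", 1:3), c("A", "X", "X"), group = "g1")
  res2 <- enrich(fake_prediction_set(ev2), href)
  rowX <- res2[res2$protease_id == "X", ]
  expect_true(rowX$disease_only)
  expect_true(is.na(rowX$fold_enrichment))
  expect_true(is.na(rowX$p_raw))
  expect_equal(attr(res2, "m"), 3) # A, B, C testable; X not
  # k = 0 rows are reported with p_raw = 1
  rowB <- res2[res2$protease_id == "B", ]
  expect_equal(rowB$k, 0)
  expect_equal(rowB$p_raw, 1)

  # Bonferroni: p_raw 0.01 with m = 10 is not significant at 0.05
  expect_equal(min(1, 0.01 * 10), 0.1) # the arithmetic enrich() applies
  expect_error(enrich(fake_prediction_set(ev), href, alpha = 1.2),
               class = "urodegradome_argument_error")
  # unknown protease vs rule registry
  rules <- specificity_rules(data.frame(
    protease_id = "A", catalytic_class = "serine", human = TRUE,
    P4 = "*", P3 = "*", P2 = "*", P1 = "K",
    P1p = "*", P2p = "*", P3p = "*", P4p = "*"))
  expect_error(enrich(fake_prediction_set(ev), href, rules = rules),
               class = "urodegradome_rule_error")
})

test_that("fold enrichment is invariant to scaling all disease counts", {
  ev <- events_df(sprintf("d%d", 1:6), rep(c("A", "B", "C"), 2), group = "g1")
  href <- structure(list(N = 60, K = c(A = 10, B = 20, C = 30)),
                    class = "reference_library")
  res1 <- enrich(fake_prediction_set(ev), href)
  ev3 <- events_df(sprintf("d%d", 1:18), rep(c("A", "B", "C"), 6), group = "g1")
  res3 <- enrich(fake_prediction_set(ev3), href)
  m1 <- res1[order(res1$protease_id), "fold_enrichment"]
  m3 <- res3[order(res3$protease_id), "fold_enrichment"]
  expect_equal(m1, m3)
})

test_that("fold bins follow the heatmap convention and output carries metadata", {
  expect_equal(as.character(fold_bins(c(0.5, 5, 15, 25, 40))),
               c("0-1", "1-10", "10-20", "20-30", ">30"))
  ev <- events_df(sprintf("d%d", 1:4), c("A", "A", "B", "C"), group = "g1")
  href <- structure(list(N = 20, K = c(A = 10, B = 5, C = 5)),
                    class = "reference_library")
  res <- enrich(fake_prediction_set(ev), href)
  f <- tempfile(fileext = ".tsv")
  write_enrichment(res, f)
  lines <- readLines(f)
  expect_true(any(grepl("^# alpha=0.05", lines)))
  expect_true(any(grepl("^# m=3", lines)))
  body <- read.delim(f, comment.char = "#")
  expect_true("fold_bin" %in% names(body))
})

test_that("a group larger than the reference library is rejected", {
  ev <- events_df(sprintf("d%d", 1:5), rep("A", 5), group = "g1")
  href <- structure(list(N = 3, K = c(A = 3)), class = "reference_library")
  expect_error(enrich(fake_prediction_set(ev), href),
               class = "urodegradome_argument_error")
})

test_that("the significance matrix mirrors the significant flags", {
  res <- structure(
    data.frame(group = c("c1", "c1", "c2"), protease_id = c("A", "B", "A"),
               k = c(5, 1, 1), n = c(6, 6, 4), K = c(2, 8, 2), N = c(20, 20, 20),
               fold_enrichment = c(8, 0.4, 2.5), p_raw = c(1e-5, 0.9, 0.2),
               p_adj = c(3e-5, 1, 0.6), significant = c(TRUE, FALSE, FALSE),
               disease_only = FALSE),
    class = c("enrichment_results", "data.frame"))
  mat <- significance_matrix(res)
  expect_true(mat["c1", "A"])
  expect_false(mat["c2", "A"])
  expect_false(mat["c1", "B"])
})
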