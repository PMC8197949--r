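demo_rules <- function() {
  read_specificity_rules(system.file("extdata", "rules", "demo_proteases.tsv",
                                     package = "urodegradome"))
}

random_rules <- function(n, wildcard_prob = 0.5, set_size = 2:6) {
  rows <- lapply(seq_len(n), function(i) {
    repeat {
      pos <- vapply(1:8, function(j) {
        if (runif(1) < wildcard_prob) "*" else
          paste(sort(sample(canonical_residues(),
                            sample(set_size, 1))), collapse = "")
      }, character(1))
      if (any(pos != "*")) break
    }
    c(list(protease_id = sprintf("R%02d", i),
           catalytic_class = sample(c("serine", "metallo", "cysteine",
                                      "aspartic", "threonine"), 1),
           human = sample(c(TRUE, TRUE, TRUE, FALSE), 1)),
      setNames(as.list(pos), c("P4", "P3", "P2", "P1", "P1p", "P2p", "P3p", "P4p")))
  })
  specificity_rules(do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE)))
}

# Random window with gaps only at the outer edges (P1/P1' never gap),
# mirroring how windows arise near protein termini.
random_window <- function() {
  res <- sample(canonical_residues(), 8, replace = TRUE)
  gl <- sample(0:3, 1, prob = c(8, 1, 1, 1))
  gr <- sample(0:3, 1, prob = c(8, 1, 1, 1))
  if (gl > 0) res[seq_len(gl)] <- "-"
  if (gr > 0) res[8 - seq_len(gr) + 1] <- "-"
  paste(res, collapse = "")
}

test_that("cleavage sites are reconstructed with correct windows and padding", {
  parent <- "MAAAKLLLGDEF"
  sites <- reconstruct_cleavage_sites(5, 8, parent)
  expect_equal(sites$terminus, c("N", "C"))
  expect_equal(sites$cut_position, c(4L, 8L))
  expect_equal(sites$window, c("MAAAKLLL", "KLLLGDEF"))

  # start = 1: the peptide begins at the intact protein N-terminus
  s1 <- reconstruct_cleavage_sites(1, 8, parent)
  expect_equal(s1$terminus, "C")

  # end = parent length: no C-terminal cleavage either
  s2 <- reconstruct_cleavage_sites(5, nchar(parent), parent)
  expect_equal(s2$terminus, "N")

  # start = 3: window padded with gaps at P4, P3
  s3 <- reconstruct_cleavage_sites(3, 8, parent)
  n_win <- s3$window[s3$terminus == "N"]
  expect_equal(substr(n_win, 1, 2), "--")
  expect_equal(n_win, "--MAAAKL")

  expect_error(reconstruct_cleavage_sites(5, 99, parent),
               class = "urodegradome_validation_error")
})

test_that("window matching agrees with a position-by-position oracle on 1000 random pairs", {
  set.seed(61)
  rules <- random_rules(40)
  for (i in 1:1000) {
    rule <- rules[sample(nrow(rules), 1), ]
    win <- random_window()
    expect_identical(match_site(win, rule), oracle_match(win, rule),
                     label = paste(win, "vs rule", rule$protease_id))
  }
  # strict gap mode: a gap fails even wildcard positions
  set.seed(62)
  for (i in 1:100) {
    rule <- rules[sample(nrow(rules), 1), ]
    win <- random_window()
    expect_identical(match_site(win, rule, gap_satisfies_wildcard = FALSE),
                     oracle_match(win, rule, gap_satisfies_wildcard = FALSE))
  }
})

test_that("single-position rules behave as expected and gaps never satisfy residue sets", {
  rule <- specificity_rules(data.frame(
    protease_id = "TRYP", catalytic_class = "serine", human = TRUE,
    P4 = "*", P3 = "*", P2 = "*", P1 = "KR",
    P1p = "*", P2p = "*", P3p = "*", P4p = "*"))[1, ]
  expect_true(match_site("AAAKAAAA", rule))
  expect_false(match_site("AAALAAAA", rule))
  expect_false(match_site("AAA-AAAA", rule))
})

test_that("degradome prediction equals brute-force enumeration on random toy studies", {
  set.seed(63)
  for (rep_i in 1:20) {
    cfg <- synthetic_config(n_proteins = 4, protein_length = c(80, 120),
                            n_proteases = sample(4:8, 1), n_conditions = 2,
                            peptides_per_condition = sample(5:25, 1),
                            planted_per_condition = 1, health_peptides = 5,
                            min_rule_sites = 1)
    study <- generate_study(cfg, seed = rep_i)
    rules <- study$rules
    # mix in a non-human rule to exercise the human filter
    rules$human[1] <- FALSE
    ps <- predict_degradome(study$disease, rules, study$proteome, grouping = "all")
    got <- sort(unique(paste(ps$events$key, ps$events$terminus,
                             ps$events$protease_id, sep = "~")))
    want <- oracle_degradome_events(study$disease, rules, study$proteome)
    expect_identical(got, want)
    expect_false(any(ps$events$protease_id == rules$protease_id[1]))
  }
})

test_that("grouping semantics: per condition vs pooled counting", {
  df <- data.frame(
    peptide_id = c("p1", "p1"), sequence = c("SKVGG", "SKVGG"),
    uniprot = "PA", gene = "G", start = 3L, end = 7L,
    condition = c("ckd", "t2dn"), class = "renal",
    stringsAsFactors = FALSE)
  tab <- association_table(df)
  prot <- proteome(c(PA = "MASKVGGLQAW"))
  rules <- specificity_rules(data.frame(
    protease_id = "ANY_A", catalytic_class = "metallo", human = TRUE,
    P4 = "*", P3 = "*", P2 = "*", P1 = "A",
    P1p = "*", P2p = "*", P3p = "*", P4p = "*"))
  by_cond <- predict_degradome(tab, rules, prot, grouping = "condition")
  pooled <- predict_degradome(tab, rules, prot, grouping = "all")
  # the peptide N-terminus (cut after A at position 2) matches in both conditions
  expect_equal(unname(by_cond$totals[c("ckd", "t2dn")]), c(1L, 1L))
  expect_equal(unname(pooled$totals[["all"]]), 1L)
})

test_that("widening an allowed set or adding a wildcard never loses events", {
  set.seed(64)
  cfg <- synthetic_config(n_proteins = 4, protein_length = c(80, 120),
                          n_proteases = 5, n_conditions = 2,
                          peptides_per_condition = 15,
                          planted_per_condition = 1, health_peptides = 5,
                          min_rule_sites = 1)
  study <- generate_study(cfg, seed = 99)
  rules <- study$rules
  base <- predict_degradome(study$disease, rules, study$proteome, grouping = "all")
  # widen: add a residue to every non-wildcard set of rule 2
  wide <- rules
  for (pp in c("P4", "P3", "P2", "P1", "P1p", "P2p", "P3p", "P4p")) {
    v <- wide[[pp]][2]
    if (v != "*") {
      extra <- setdiff(canonical_residues(), strsplit(v, "")[[1]])[1]
      wide[[pp]][2] <- paste(sort(c(strsplit(v, "")[[1]], extra)), collapse = "")
    }
  }
  wider <- predict_degradome(study$disease, wide, study$proteome, grouping = "all")
  expect_gte(nrow(wider$events), nrow(base$events))
  # wildcard one non-wildcard position of rule 3 (keep at least one specific)
  wc <- rules
  specific <- which(unlist(wc[3, c("P4", "P3", "P2", "P1", "P1p", "P2p", "P3p", "P4p")]) != "*")
  if (length(specific) > 1) {
    pos_name <- c("P4", "P3", "P2", "P1", "P1p", "P2p", "P3p", "P4p")[specific[1]]
    wc[[pos_name]][3] <- "*"
    freer <- predict_degradome(study$disease, wc, study$proteome, grouping = "all")
    expect_gte(nrow(freer$events), nrow(base$events))
  }
})

test_that("every emitted event window re-derives from the parent at the cut position", {
  study <- generate_study(small_study_config(), seed = 3)
  ps <- predict_degradome(study$disease, study$rules, study$proteome,
                          grouping = "condition")
  ev <- ps$events
  idx <- sample(nrow(ev), min(nrow(ev), 200))
  rederived <- vapply(idx, function(i) {
    cleavage_window(study$proteome[[ev$uniprot[i]]], ev$cut_position[i])
  }, character(1))
  expect_equal(ev$window[idx], rederived)
})

test_that("rule files parse strictly, round-trip, and errors are line-addressed", {
  rules <- demo_rules()
  expect_s3_class(rules, "specificity_rules")
  expect_equal(nrow(rules), 8)
  expect_false(all(rules$human))
  f <- tempfile(fileext = ".tsv")
  write_specificity_rules(rules, f)
  back <- read_specificity_rules(f)
  expect_equal(as.data.frame(back), as.data.frame(rules))

  bad <- as.data.frame(rules)
  bad$P1[2] <- "KX9"
  f2 <- write_toy_file(bad)
  err <- tryCatch(read_specificity_rules(f2), error = identity)
  expect_s3_class(err, "urodegradome_rule_error")
  expect_match(conditionMessage(err), "rule 2")

  allwild <- as.data.frame(rules)[1, ]
  allwild[c("P4", "P3", "P2", "P1", "P1p", "P2p", "P3p", "P4p")] <- "*"
  expect_error(specificity_rules(allwild), class = "urodegradome_rule_error")

  nonhuman_only <- specificity_rules(as.data.frame(rules)[!rules$human, ])
  study <- generate_study(small_study_config(), seed = 5)
  expect_error(predict_degradome(study$disease, nonhuman_only, study$proteome),
               class = "urodegradome_rule_error")
})

test_that("peptides without a parent protein are skipped with a warning", {
  tab <- toy_table()
  prot <- proteome(c(PA = "MASKVGGLQ"))
  rules <- demo_rules()
  expect_warning(ps <- predict_degradome(tab, rules, prot, grouping = "all"),
                 "skipped")
  expect_length(ps$skipped, 1)
})
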