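test_that("proteome generation is deterministic and honours the config", {
  cfg <- synthetic_config(n_proteins = 5, protein_length = 50)
  p1 <- generate_proteome(cfg, seed = 5)
  p2 <- generate_proteome(cfg, seed = 5)
  expect_identical(p1, p2)
  expect_length(p1, 5)
  expect_true(all(nchar(p1) == 50))
  expect_true(all(.is_canonical <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", p1)))
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_proteome(p1, f1); write_proteome(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
  p3 <- generate_proteome(cfg, seed = 6)
  expect_false(identical(p1, p3))
})

test_that("residue frequencies track the configured profile", {
  cfg <- synthetic_config(n_proteins = 30, protein_length = 350)
  prot <- generate_proteome(cfg, seed = 8)
  res <- table(factor(strsplit(paste(prot, collapse = ""), "")[[1]],
                      levels = canonical_residues()))
  chi <- chisq.test(res)
  expect_gt(chi$p.value, 1e-4) # consistent with uniform at 10k+ residues
  skew <- setNames(c(rep(1, 19), 20), canonical_residues()) # heavy Tyr
  cfg2 <- synthetic_config(n_proteins = 10, protein_length = 300,
                           residue_freq = skew)
  prot2 <- generate_proteome(cfg2, seed = 8)
  comp <- table(strsplit(paste(prot2, collapse = ""), "")[[1]])
  expect_gt(comp[["Y"]] / sum(comp), 0.3)
})

test_that("generated rules are valid, human, class-balanced and seed-stable", {
  cfg <- synthetic_config(n_proteases = 12)
  r1 <- generate_specificity_matrices(cfg, seed = 2)
  r2 <- generate_specificity_matrices(cfg, seed = 2)
  expect_identical(r1, r2)
  expect_s3_class(r1, "specificity_rules")
  expect_equal(nrow(r1), 12)
  expect_true(all(r1$human))
  expect_equal(unname(table(r1$catalytic_class)[c("aspartic", "cysteine",
                                                  "metallo", "serine")]),
               rep(3L, 4), ignore_attr = TRUE)
  # fully specific rules when wildcards are disabled
  cfg2 <- synthetic_config(n_proteases = 4, wildcard_prob = 0,
                           allowed_set_size = 1, planted_per_condition = 2)
  r3 <- generate_specificity_matrices(cfg2, seed = 3)
  pos <- as.matrix(as.data.frame(r3)[, c("P4", "P3", "P2", "P1",
                                         "P1p", "P2p", "P3p", "P4p")])
  expect_true(all(nchar(pos) == 1 & pos != "*"))
})

test_that("allowed-set sizes track the configured distribution", {
  cfg <- synthetic_config(n_proteases = 200, allowed_set_size = c(2, 8))
  r <- generate_specificity_matrices(cfg, seed = 4)
  pos <- unlist(as.data.frame(r)[, c("P4", "P3", "P2", "P1",
                                     "P1p", "P2p", "P3p", "P4p")])
  sizes <- nchar(pos[pos != "*"])
  expect_equal(mean(sizes), 5, tolerance = 0.1)
  expect_true(all(sizes >= 2 & sizes <= 8))
})

test_that("generated studies are deterministic and internally consistent", {
  cfg <- small_study_config()
  s1 <- generate_study(cfg, seed = 17)
  s2 <- generate_study(cfg, seed = 17)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$disease$records, s2$disease$records)
  expect_identical(unclass(s1$proteome), unclass(s2$proteome))

  # every record validates against the proteome (coordinates and sequences)
  expect_equal(validate_against_proteome(s1$disease, s1$proteome)$n_mismatch, 0)
  # peptide lengths within the configured band
  lens <- nchar(s1$disease$records$sequence)
  expect_true(all(lens >= 6 & lens <= 40))
  # per-condition peptide counts match the config
  per_cond <- table(s1$disease$records$condition)
  expect_true(all(per_cond == cfg$peptides_per_condition))
})

test_that("planted signatures are exactly the degree-1 peptides", {
  for (seed in c(5, 23, 91)) {
    study <- generate_study(small_study_config(), seed = seed)
    sig <- extract_signatures(build_network(study$disease))
    planted <- study$manifest$signature_keys
    expect_setequal(unlist(sig$by_condition, use.names = FALSE),
                    unlist(planted, use.names = FALSE))
    for (cc in names(planted)) {
      expect_setequal(sig$by_condition[[cc]], planted[[cc]])
    }
  }
})

test_that("planted-protease termini re-match their planted rules at elevated rates", {
  cfg <- small_study_config(activity_multiplier = 8,
                            peptides_per_condition = 60)
  study <- generate_study(cfg, seed = 29)
  rules <- study$rules
  rec <- study$disease$records
  hrec <- study$health$records
  rate_for <- function(records, pr) {
    up <- records[!duplicated(records$key), ]
    hits <- 0; tot <- 0
    r <- rules[rules$protease_id == pr, ]
    for (i in seq_len(nrow(up))) {
      sites <- reconstruct_cleavage_sites(up$start[i], up$end[i],
                                          study$proteome[[up$uniprot[i]]])
      hits <- hits + sum(match_site(sites$window, r))
      tot <- tot + nrow(sites)
    }
    hits / tot
  }
  planted <- study$manifest$planted_proteases
  for (cc in names(planted)[1]) {
    sub <- rec[rec$condition == cc, ]
    for (pr in planted[[cc]]) {
      expect_gt(rate_for(sub, pr), rate_for(hrec, pr))
    }
  }
})

test_that("the full pipeline accepts generated studies end to end", {
  study <- generate_study(small_study_config(), seed = 37)
  # store -> network -> physchem -> degradome -> enrichment -> signatures
  expect_s3_class(summarize_classes(study$disease, study$health), "class_summary")
  net <- build_network(study$disease)
  sig <- extract_signatures(net)
  peps <- signature_class_peptides(sig, study$disease, study$health)
  cd <- suppressMessages(class_distributions(peps, min_peptides = 5,
                                             descriptors = c("length", "gravy")))
  expect_true(nrow(cd$summary) > 0)
  dp <- predict_degradome(study$disease, study$rules, study$proteome,
                          grouping = "condition")
  hp <- predict_degradome(study$health, study$rules, study$proteome,
                          grouping = "all")
  er <- enrich(dp, build_reference(hp), rules = study$rules)
  expect_s3_class(er, "enrichment_results")
  mat <- significance_matrix(er)
  tab <- minimal_signature_table(mat)
  expect_equal(nrow(tab), length(unique(er$group)))
})

test_that("study artefacts round-trip through the store file formats", {
  study <- generate_study(small_study_config(), seed = 41)
  d <- tempfile(); dir.create(d)
  fa <- file.path(d, "proteome.fasta")
  tsv <- file.path(d, "disease.tsv")
  rl <- file.path(d, "rules.tsv")
  mf <- file.path(d, "manifest.json")
  write_proteome(study$proteome, fa)
  write_association_table(study$disease, tsv)
  write_specificity_rules(study$rules, rl)
  write_manifest(study$manifest, mf)
  expect_identical(unclass(read_proteome(fa)), unclass(study$proteome))
  back <- load_association_table(tsv)
  expect_setequal(back$records$key, study$disease$records$key)
  expect_identical(as.data.frame(read_specificity_rules(rl)),
                   as.data.frame(study$rules))
  j <- jsonlite::read_json(mf)
  expect_equal(j$seed, 41)
  expect_length(j$planted_proteases, small_study_config()$n_conditions)
})

test_that("infeasible configurations error out distinctly", {
  expect_error(synthetic_config(peptides_per_condition = 0), "peptides_per_condition")
  expect_error(synthetic_config(activity_multiplier = 0.5), "activity_multiplier")
  expect_error(synthetic_config(protein_length = 20, peptide_length = c(6, 40)),
               "protein_length")
  # more planted proteases than rules
  expect_error(synthetic_config(planted_per_condition = 50, n_proteases = 10),
               "planted_per_condition")
})
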