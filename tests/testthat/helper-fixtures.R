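# Fixtures and independent oracles shared across the test files. The
# oracle implementations are deliberately naive (enumeration / hand
# counting) and never call the code paths they check.

toy_records <- function() {
  data.frame(
    peptide_id = c("p1", "p2", "p3"),
    sequence = c("ASK", "GGL", "ASK"),
    uniprot = c("PA", "PA", "PB"),
    gene = c("GA", "GA", "GB"),
    start = c(2L, 6L, 4L),
    end = c(4L, 8L, 6L),
    condition = c("ckd", "ckd", "bladder cancer"),
    class = c("renal", "renal", "cancer"),
    stringsAsFactors = FALSE
  )
}

toy_table <- function() association_table(toy_records())

toy_proteome <- function() {
  proteome(c(PA = "MASKVGGLQ", PB = "QWEASKPLM"))
}

write_toy_file <- function(df, path = tempfile(fileext = ".tsv"), sep = "\t") {
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# Random association table over small alphabets of conditions/peptides.
random_table <- function(n_rows = 40, n_conditions = 4, n_peptides = 15) {
  conds <- sprintf("c%02d", seq_len(n_conditions))
  peps <- sprintf("SEQ%02d", seq_len(n_peptides))
  idx <- sample(n_peptides, n_rows, replace = TRUE)
  seqs <- vapply(idx, function(i) {
    paste(rep(c("A", "G", "L", "S", "K")[(i %% 5) + 1], 5), collapse = "")
  }, character(1))
  df <- data.frame(
    peptide_id = peps[idx],
    sequence = seqs,
    uniprot = sprintf("P%02d", (idx %% 3) + 1),
    gene = "G",
    start = idx + 1L,
    end = idx + 5L,
    condition = sample(conds, n_rows, replace = TRUE),
    class = NA_character_,
    stringsAsFactors = FALSE
  )
  df$class <- rep(disease_classes(), length.out = n_conditions)[match(df$condition, conds)]
  association_table(df)
}

# Brute-force per-peptide condition recount, independent of igraph.
oracle_degrees <- function(table) {
  rec <- table$records
  d <- tapply(rec$condition, rec$key, function(x) length(unique(x)))
  setNames(as.integer(d), names(d))
}

# Exact combinatorial upper-tail hypergeometric sum.
oracle_hyper_upper <- function(k, K, n, N) {
  if (k <= 0) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  xs <- k:hi
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Position-by-position rule evaluation, independent of .match_windows.
oracle_match <- function(window, rule, gap_satisfies_wildcard = TRUE) {
  syms <- strsplit(window, "")[[1]]
  pos_names <- c("P4", "P3", "P2", "P1", "P1p", "P2p", "P3p", "P4p")
  for (j in 1:8) {
    spec <- as.character(rule[[pos_names[j]]])
    if (spec == "*") {
      if (!gap_satisfies_wildcard && syms[j] == "-") return(FALSE)
    } else {
      if (!syms[j] %in% strsplit(spec, "")[[1]]) return(FALSE)
    }
  }
  TRUE
}

# Brute-force degradome: loop over peptides, termini and rules.
oracle_degradome_events <- function(table, rules, prot) {
  rules <- rules[rules$human, , drop = FALSE]
  rec <- table$records
  up <- rec[!duplicated(rec$key), , drop = FALSE]
  out <- character(0)
  for (i in seq_len(nrow(up))) {
    pseq <- unclass(prot)[[up$uniprot[i]]]
    if (is.null(pseq) || is.na(pseq)) next
    L <- nchar(pseq)
    sites <- list()
    if (up$start[i] > 1) sites$N <- up$start[i] - 1L
    if (up$end[i] < L) sites$C <- up$end[i]
    for (term in names(sites)) {
      cut <- sites[[term]]
      # window symbols: parent residues cut-3..cut and cut+1..cut+4
      idx <- (cut - 3):(cut + 4)
      res <- strsplit(pseq, "")[[1]]
      win <- paste(ifelse(idx >= 1 & idx <= L, res[pmax(idx, 1)], "-"),
                   collapse = "")
      for (r in seq_len(nrow(rules))) {
        if (oracle_match(win, rules[r, ])) {
          out <- c(out, paste(up$key[i], term, rules$protease_id[r], sep = "~"))
        }
      }
    }
  }
  sort(unique(out))
}

# Exhaustive minimal-signature oracle: enumerate every subset up to kmax.
oracle_minimal_sets <- function(mat, condition, kmax = 3) {
  enriched <- sort(colnames(mat)[mat[condition, ]])
  others <- setdiff(rownames(mat), condition)
  identifying <- function(S) {
    for (o in others) {
      if (all(S %in% colnames(mat)[mat[o, ]])) return(FALSE)
    }
    TRUE
  }
  for (k in seq_len(min(kmax, max(length(enriched), 1)))) {
    if (length(enriched) < k) break
    sets <- combn(enriched, k, simplify = FALSE)
    hits <- Filter(identifying, sets)
    if (length(hits) > 0) return(hits)
  }
  list()
}

random_enrichment_matrix <- function(n_cond = 8, n_prot = 12, density = 0.3) {
  mat <- matrix(runif(n_cond * n_prot) < density, nrow = n_cond,
                dimnames = list(sprintf("cond%02d", seq_len(n_cond)),
                                sprintf("PRT%02d", seq_len(n_prot))))
  enrichment_matrix(mat)
}

small_study_config <- function(...) {
  args <- list(n_proteins = 6, protein_length = c(120, 200),
               n_proteases = 8, n_conditions = 3,
               peptides_per_condition = 30, planted_per_condition = 2,
               health_peptides = 60, min_rule_sites = 2)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}
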