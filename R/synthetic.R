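# Synthetic-study generator: proteome, MEROPS-style specificity rules, and
# disease/health peptide tables with planted signature peptides and planted
# condition-specific protease activity, plus a ground-truth manifest.

#' Configuration for the synthetic-study generator
#'
#' Defaults emulate the structure of a pooled urinary-peptidomics
#' meta-analysis: a modest panel of parent proteins, MEROPS-style
#' specificity rules over four catalytic classes, conditions with on the
#' order of a hundred associated peptides each, a health reference set
#' much larger than any single condition (the regime the
#' reference-library enrichment test assumes), and low-molecular-weight
#' peptides of 6-40 residues.
#'
#' @param n_proteins Number of parent proteins.
#' @param protein_length Length range `c(min, max)` (or one fixed value).
#' @param residue_freq Named residue frequency profile (default uniform
#'   over the 20 canonical residues).
#' @param n_proteases Number of specificity rules.
#' @param wildcard_prob Per-position wildcard probability of a rule.
#' @param allowed_set_size Range `c(min, max)` of allowed-set sizes at
#'   non-wildcard positions.
#' @param n_conditions Number of disease conditions.
#' @param peptides_per_condition Peptides associated with each condition.
#' @param planted_per_condition Planted active proteases per condition.
#' @param activity_multiplier Activity multiplier `m >= 1` of planted
#'   proteases; a peptide terminus is a genuine match site of a planted
#'   rule with probability proportional to `m` (capped at 1), and `m = 1`
#'   reduces exactly to the health/baseline process.
#' @param signature_fraction Fraction of each condition's peptides that are
#'   guaranteed condition-specific (degree 1); the remaining peptides are
#'   shared between at least two conditions.
#' @param health_peptides Health reference peptide count.
#' @param rule_cut_prob Probability that a terminus is protease-generated
#'   at baseline (the remainder are uniform background cuts).
#' @param max_planted_promiscuity Upper bound on the proteome match-site
#'   density of a rule eligible for planting; activity of a protease that
#'   matches more than this fraction of random sites is not attributable
#'   from event counts.
#' @param min_rule_sites Minimum number of distinct match sites a generated
#'   rule must have in the proteome (deficient rules are resampled):
#'   a protease whose whole substrate repertoire is one or two sites would
#'   re-use the same cut site across many peptides and cluster the event
#'   counts the enrichment test treats as exchangeable.
#' @param peptide_length Peptide length band `c(min, max)` in residues.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 20,
                             protein_length = c(200, 400),
                             residue_freq = NULL,
                             n_proteases = 30,
                             wildcard_prob = 0.5,
                             allowed_set_size = c(4, 6),
                             n_conditions = 5,
                             peptides_per_condition = 100,
                             planted_per_condition = 5,
                             activity_multiplier = 5,
                             signature_fraction = 0.2,
                             health_peptides = 3000,
                             rule_cut_prob = 0.9,
                             max_planted_promiscuity = 0.05,
                             min_rule_sites = 20,
                             peptide_length = c(6, 40)) {
  if (is.null(residue_freq)) {
    residue_freq <- setNames(rep(1 / 20, 20), canonical_residues())
  }
  residue_freq <- residue_freq[canonical_residues()]
  if (any(is.na(residue_freq)) || any(residue_freq < 0) || sum(residue_freq) <= 0) {
    .ud_stop("residue_freq must be a non-negative profile over the 20 canonical residues with positive mass",
             "urodegradome_argument_error")
  }
  residue_freq <- residue_freq / sum(residue_freq)
  if (length(protein_length) == 1) protein_length <- rep(protein_length, 2)
  if (length(peptide_length) == 1) peptide_length <- rep(peptide_length, 2)
  if (length(allowed_set_size) == 1) allowed_set_size <- rep(allowed_set_size, 2)
  cfg <- list(n_proteins = as.integer(n_proteins),
              protein_length = as.integer(protein_length),
              residue_freq = residue_freq,
              n_proteases = as.integer(n_proteases),
              wildcard_prob = wildcard_prob,
              allowed_set_size = as.integer(allowed_set_size),
              n_conditions = as.integer(n_conditions),
              peptides_per_condition = as.integer(peptides_per_condition),
              planted_per_condition = as.integer(planted_per_condition),
              activity_multiplier = activity_multiplier,
              signature_fraction = signature_fraction,
              health_peptides = as.integer(health_peptides),
              rule_cut_prob = rule_cut_prob,
              max_planted_promiscuity = max_planted_promiscuity,
              min_rule_sites = as.integer(min_rule_sites),
              peptide_length = as.integer(peptide_length))
  with(cfg, {
    stopifnot(n_proteins >= 1, n_proteases >= 1, n_conditions >= 1,
              peptides_per_condition >= 1, health_peptides >= 1,
              planted_per_condition >= 1, planted_per_condition <= n_proteases,
              activity_multiplier >= 1,
              wildcard_prob >= 0, wildcard_prob < 1,
              rule_cut_prob >= 0, rule_cut_prob <= 1,
              signature_fraction >= 0, signature_fraction <= 1,
              max_planted_promiscuity > 0, max_planted_promiscuity <= 1,
              min_rule_sites >= 1,
              all(allowed_set_size >= 1), all(allowed_set_size <= 20),
              peptide_length[1] >= 1, peptide_length[2] >= peptide_length[1],
              protein_length[1] > peptide_length[2] + 2)
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic parent proteome
#'
#' Sequences are drawn residue-wise from the configured frequency profile;
#' deterministic for a given seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return A [proteome()] of `n_proteins` sequences.
#' @export
generate_proteome <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  .gen_proteome(config)
}

.gen_proteome <- function(config) {
  len_range <- seq(config$protein_length[1], config$protein_length[2])
  lens <- len_range[sample.int(length(len_range), config$n_proteins,
                               replace = TRUE)]
  seqs <- vapply(lens, function(L) {
    paste(sample(canonical_residues(), L, replace = TRUE,
                 prob = config$residue_freq), collapse = "")
  }, character(1))
  proteome(setNames(seqs, sprintf("SYNP%03d", seq_len(config$n_proteins))))
}

#' Generate synthetic MEROPS-style specificity rules
#'
#' Each P4..P4' position is independently a wildcard with the configured
#' probability, otherwise an allowed set of the configured size; rules
#' that come out all-wildcard are resampled (retry cap 100). Catalytic
#' classes are assigned round-robin over aspartic, cysteine, metallo and
#' serine; all rules are human-flagged.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return A [specificity_rules()] data frame of `n_proteases` rules.
#' @export
generate_specificity_matrices <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  .gen_rules(config)
}

.gen_rule_positions <- function(config) {
  sizes <- seq(config$allowed_set_size[1], config$allowed_set_size[2])
  for (try in 1:100) {
    pos <- vapply(seq_len(8), function(j) {
      if (runif(1) < config$wildcard_prob) return("*")
      k <- sizes[sample.int(length(sizes), 1)]
      paste(sort(sample(canonical_residues(), k)), collapse = "")
    }, character(1))
    if (any(pos != "*")) {
      names(pos) <- .window_positions
      return(pos)
    }
  }
  .ud_stop("could not sample a rule with a non-wildcard position (wildcard_prob too high)",
           "urodegradome_argument_error")
}

.gen_rules <- function(config) {
  classes <- rep(c("aspartic", "cysteine", "metallo", "serine"),
                 length.out = config$n_proteases)
  rows <- lapply(seq_len(config$n_proteases), function(i) {
    pos <- .gen_rule_positions(config)
    c(list(protease_id = sprintf("PRT%02d", i),
           catalytic_class = classes[i], human = TRUE), as.list(pos))
  })
  specificity_rules(do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE)))
}

# Per-protein list of matching cut positions for each rule.
.match_positions <- function(proteome, rules) {
  rlist <- .rules_as_list(rules)
  lapply(unclass(proteome), function(seq) {
    L <- nchar(seq)
    wins <- cleavage_window(seq, seq_len(L - 1L))
    lapply(rlist, function(rule) {
      which(.match_windows(wins, rule))
    })
  })
}

# Terminus-category probabilities for a condition with `a` planted
# proteases out of `t` at multiplier m (a = 0 gives the health baseline):
# planted-rule cut, non-planted-rule cut, uniform background cut.
.terminus_probs <- function(q, a, t, m) {
  p0 <- q * a / t
  pi_p <- min(1, m * p0)
  rest <- 1 - pi_p
  denom <- q * (t - a) / t + (1 - q)
  rho <- if (denom > 0) q * (t - a) / t * rest / denom else 0
  c(planted = pi_p, rule = rho, uniform = rest - rho)
}

# Peptide sampler factory. A protease-generated terminus is anchored on a
# genuine match site of that protease, drawn uniformly over the whole
# proteome (which also selects the parent protein); the second terminus is
# then placed inside the peptide-length window, on a matching site of its
# own protease when one exists there, else uniformly. The mechanics are
# identical for planted, non-planted and baseline proteases, so a
# multiplier of 1 reduces exactly to the health process.
.make_peptide_sampler <- function(proteome, mpos, minlen, maxlen) {
  np <- length(proteome)
  plens <- nchar(unclass(proteome))
  t <- length(mpos[[1]])
  # Flattened (protein, position) site lists per rule, filtered for
  # anchoring at the N side (room for a peptide to the right) or C side.
  siteN <- vector("list", t); siteC <- vector("list", t)
  for (r in seq_len(t)) {
    prN <- integer(0); poN <- integer(0); prC <- integer(0); poC <- integer(0)
    for (p in seq_len(np)) {
      v <- mpos[[p]][[r]]
      vN <- v[v <= plens[p] - 1L - minlen]
      vC <- v[v >= minlen + 1L]
      if (length(vN)) { prN <- c(prN, rep.int(p, length(vN))); poN <- c(poN, vN) }
      if (length(vC)) { prC <- c(prC, rep.int(p, length(vC))); poC <- c(poC, vC) }
    }
    siteN[[r]] <- list(prot = prN, pos = poN)
    siteC[[r]] <- list(prot = prC, pos = poC)
  }
  pick <- function(x) x[sample.int(length(x), 1)]
  resolve <- function(cat, planted, nonplanted) {
    if (cat == 1L && length(planted) > 0) return(pick(planted))
    if (cat == 2L && length(nonplanted) > 0) return(pick(nonplanted))
    0L
  }
  gen_from_anchor <- function(anchor, rN, rC) {
    # Returns c(p, c1, c2, both_realised).
    if (anchor == "N") {
      i <- sample.int(length(siteN[[rN]]$pos), 1)
      p <- siteN[[rN]]$prot[i]; c1 <- siteN[[rN]]$pos[i]
      lo <- c1 + minlen; hi <- min(c1 + maxlen, plens[p] - 1L)
      cand <- if (rC > 0) { v <- mpos[[p]][[rC]]; v[v >= lo & v <= hi] } else integer(0)
      if (length(cand) > 0) return(c(p, c1, pick(cand), 1L))
      c(p, c1, lo - 1L + sample.int(hi - lo + 1L, 1), 0L)
    } else {
      i <- sample.int(length(siteC[[rC]]$pos), 1)
      p <- siteC[[rC]]$prot[i]; c2 <- siteC[[rC]]$pos[i]
      lo <- max(1L, c2 - maxlen); hi <- c2 - minlen
      cand <- if (rN > 0) { v <- mpos[[p]][[rN]]; v[v >= lo & v <= hi] } else integer(0)
      if (length(cand) > 0) return(c(p, pick(cand), c2, 1L))
      c(p, lo - 1L + sample.int(hi - lo + 1L, 1), c2, 0L)
    }
  }
  function(probs, planted, nonplanted) {
    cats <- sample.int(3L, 2, replace = TRUE, prob = probs)
    rN <- resolve(cats[1], planted, nonplanted)
    rC <- resolve(cats[2], planted, nonplanted)
    okN <- rN > 0 && length(siteN[[rN]]$pos) > 0
    okC <- rC > 0 && length(siteC[[rC]]$pos) > 0
    if (okN && okC) {
      # Both termini protease-generated: retry anchoring (alternating sides
      # at random) until both land on genuine match sites, else keep the
      # last anchor-only draw.
      for (try in 1:8) {
        v <- gen_from_anchor(if (runif(1) < 0.5) "N" else "C", rN, rC)
        if (v[4] == 1L) break
      }
      return(v[1:3])
    }
    if (okN) return(gen_from_anchor("N", rN, 0L)[1:3])
    if (okC) return(gen_from_anchor("C", 0L, rC)[1:3])
    p <- sample.int(np, 1)
    c1 <- sample.int(plens[p] - 1L - minlen, 1)
    lo <- c1 + minlen; hi <- min(c1 + maxlen, plens[p] - 1L)
    c(p, c1, lo - 1L + sample.int(hi - lo + 1L, 1))
  }
}

#' Generate a synthetic disease study with planted ground truth
#'
#' For each condition, peptide termini are protease-generated cut sites:
#' planted proteases generate a terminus with probability proportional to
#' the activity multiplier, the remaining termini come from the baseline
#' protease mixture or uniform background positions. A configured fraction
#' of each condition's peptides is condition-specific (planted degree-1
#' signatures); the rest are shared between at least two conditions, so
#' the disease network's degree-1 set equals the planted signature set.
#' Health peptides are generated from the baseline mixture over the same
#' proteome and rule set, so enrichment differences reflect only planted
#' activity.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param proteome,rules Optional pre-generated [proteome()] and
#'   [specificity_rules()]; generated internally when `NULL`.
#' @return A `synthetic_study` list: `disease` and `health`
#'   [association_table()]s, a `manifest` (ground truth: per-condition
#'   planted proteases and signature peptide keys, parameter echo, seed),
#'   plus the `proteome` and `rules` used.
#' @export
generate_study <- function(config, seed, proteome = NULL, rules = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  if (is.null(proteome)) proteome <- .gen_proteome(config)
  resample_rules <- is.null(rules)
  if (is.null(rules)) rules <- .gen_rules(config)
  stopifnot(nrow(rules) == config$n_proteases)
  mpos <- .match_positions(proteome, rules)
  if (resample_rules) {
    # Generated rules must have enough substrate diversity in this proteome
    # (distinct match sites) that repeated activity samples distinct
    # peptides rather than re-using one cut site; deficient rules are
    # resampled, mirroring the all-wildcard retry.
    n_sites <- function(r) sum(vapply(mpos, function(pp) length(pp[[r]]),
                                      integer(1)))
    wins_by_prot <- lapply(unclass(proteome), function(s) {
      cleavage_window(s, seq_len(nchar(s) - 1L))
    })
    for (r in seq_len(nrow(rules))) {
      for (try in 1:100) {
        if (n_sites(r) >= config$min_rule_sites) break
        pos <- .gen_rule_positions(config)
        rules[r, .window_positions] <- as.list(pos)
        new_rule <- rules[r, ]
        for (p in seq_along(mpos)) {
          mpos[[p]][[r]] <- which(.match_windows(wins_by_prot[[p]], new_rule))
        }
      }
      if (n_sites(r) < config$min_rule_sites) {
        .ud_stop("could not sample rules with enough proteome match sites; enlarge the proteome or relax rule specificity",
                 "urodegradome_argument_error")
      }
    }
  }
  plens <- nchar(unclass(proteome))
  t <- config$n_proteases
  a <- config$planted_per_condition
  nc <- config$n_conditions
  per <- config$peptides_per_condition
  minlen <- config$peptide_length[1]
  maxlen <- config$peptide_length[2]
  q <- config$rule_cut_prob
  conds <- sprintf("cond%02d", seq_len(nc))
  cond_class <- setNames(rep(disease_classes(), length.out = nc), conds)

  # Planted protease sets are sampled from the plantable rules: a planted
  # "active" protease must (i) have at least one match site usable as an
  # N- and as a C-terminal anchor somewhere in the proteome — otherwise it
  # has no substrate and its planted activity could never be observed —
  # and (ii) be informative, i.e. not match more than
  # `max_planted_promiscuity` of all cleavage sites (activity of a
  # near-indiscriminate protease is not attributable from event counts).
  # Sets are disjoint across conditions when feasible.
  n_sites_total <- sum(plens - 1L)
  plantable <- which(vapply(seq_len(t), function(r) {
    nm <- sum(vapply(seq_len(config$n_proteins),
                     function(p) length(mpos[[p]][[r]]), integer(1)))
    if (nm == 0 || nm / n_sites_total > config$max_planted_promiscuity) {
      return(FALSE)
    }
    any(vapply(seq_len(config$n_proteins), function(p) {
      v <- mpos[[p]][[r]]
      length(v[v <= plens[p] - 1L - minlen]) > 0
    }, logical(1))) &&
      any(vapply(seq_len(config$n_proteins), function(p) {
        v <- mpos[[p]][[r]]
        length(v[v >= minlen + 1L]) > 0
      }, logical(1)))
  }, logical(1)))
  if (length(plantable) < a) {
    .ud_stop("not enough plantable proteases (rules with match sites in the proteome); enlarge the proteome or relax rule specificity",
             "urodegradome_argument_error")
  }
  if (nc * a <= length(plantable)) {
    pool <- plantable[sample.int(length(plantable), nc * a)]
    planted_idx <- split(pool, rep(seq_len(nc), each = a))
  } else {
    planted_idx <- lapply(seq_len(nc), function(i) {
      plantable[sample.int(length(plantable), a)]
    })
  }
  names(planted_idx) <- conds

  disease_probs <- lapply(seq_len(nc), function(i) {
    .terminus_probs(q, a, t, config$activity_multiplier)
  })
  health_probs <- .terminus_probs(q, 0, t, 1)

  sampler <- .make_peptide_sampler(proteome, mpos, minlen, maxlen)
  used <- new.env(hash = TRUE, parent = emptyenv())
  make_one <- function(probs, planted, nonplanted) {
    for (try in 1:200) {
      v <- sampler(probs, planted, nonplanted)
      id <- paste(v[1], v[2], v[3])
      if (is.null(used[[id]])) {
        used[[id]] <- TRUE
        return(v)
      }
    }
    .ud_stop("could not generate enough distinct peptides; enlarge the proteome or reduce counts",
             "urodegradome_argument_error")
  }

  n_sig <- if (nc == 1) per else round(config$signature_fraction * per)
  if (n_sig > per) {
    .ud_stop("more planted signatures than peptides per condition",
             "urodegradome_argument_error")
  }

  pep_protein <- integer(0); pep_start <- integer(0); pep_end <- integer(0)
  pep_members <- list(); pep_origin <- integer(0); pep_sig <- logical(0)

  add_pep <- function(v, members, origin, sig) {
    pep_protein[[length(pep_protein) + 1]] <<- v[1]
    pep_start[[length(pep_start) + 1]] <<- v[2] + 1L
    pep_end[[length(pep_end) + 1]] <<- v[3]
    pep_members[[length(pep_members) + 1]] <<- members
    pep_origin[[length(pep_origin) + 1]] <<- origin
    pep_sig[[length(pep_sig) + 1]] <<- sig
  }

  for (i in seq_len(nc)) {
    planted <- planted_idx[[i]]
    nonplanted <- setdiff(seq_len(t), planted)
    for (j in seq_len(n_sig)) {
      add_pep(make_one(disease_probs[[i]], planted, nonplanted), i, i, TRUE)
    }
  }

  slots <- rep(per - n_sig, nc)
  while (sum(slots) > 0) {
    ord <- order(slots, decreasing = TRUE)
    origin <- ord[1]
    partners <- ord[slots[ord] > 0 & ord != origin]
    if (length(partners) == 0) {
      # Lone remainder: widen the membership of existing shared peptides.
      candidates <- which(!pep_sig & !vapply(pep_members, function(mm) origin %in% mm, logical(1)))
      if (length(candidates) < slots[origin]) {
        .ud_stop("cannot satisfy the shared-peptide degree constraint; lower signature_fraction or add conditions",
                 "urodegradome_argument_error")
      }
      for (ci in candidates[seq_len(slots[origin])]) {
        pep_members[[ci]] <- c(pep_members[[ci]], origin)
      }
      slots[origin] <- 0
      break
    }
    partner <- partners[1]
    planted <- planted_idx[[origin]]
    nonplanted <- setdiff(seq_len(t), planted)
    add_pep(make_one(disease_probs[[origin]], planted, nonplanted),
            c(origin, partner), origin, FALSE)
    slots[origin] <- slots[origin] - 1
    slots[partner] <- slots[partner] - 1
  }

  acc <- names(proteome)
  n_pep <- length(pep_protein)
  pep_seq <- substr(unclass(proteome)[pep_protein], pep_start, pep_end)
  pep_acc <- acc[pep_protein]
  pep_id <- sprintf("PEP%05d", seq_len(n_pep))
  reps <- lengths(pep_members)
  disease_records <- data.frame(
    peptide_id = rep(pep_id, reps),
    sequence = rep(pep_seq, reps),
    uniprot = rep(pep_acc, reps),
    gene = rep(sub("SYNP", "GENE", pep_acc), reps),
    start = rep(pep_start, reps),
    end = rep(pep_end, reps),
    condition = conds[unlist(pep_members)],
    class = unname(cond_class[conds[unlist(pep_members)]]),
    stringsAsFactors = FALSE
  )
  disease <- association_table(disease_records)

  n_h <- config$health_peptides
  h_protein <- integer(n_h); h_start <- integer(n_h); h_end <- integer(n_h)
  for (j in seq_len(n_h)) {
    v <- make_one(health_probs, integer(0), seq_len(t))
    h_protein[j] <- v[1]; h_start[j] <- v[2] + 1L; h_end[j] <- v[3]
  }
  health_records <- data.frame(
    peptide_id = sprintf("HLT%05d", seq_len(n_h)),
    sequence = substr(unclass(proteome)[h_protein], h_start, h_end),
    uniprot = acc[h_protein],
    gene = sub("SYNP", "GENE", acc[h_protein]),
    start = h_start, end = h_end,
    condition = "health", class = "health",
    stringsAsFactors = FALSE
  )
  health <- association_table(health_records)

  sig_keys <- lapply(seq_len(nc), function(i) {
    idx <- which(pep_sig & pep_origin == i)
    peptide_key(pep_seq[idx], pep_acc[idx], pep_start[idx], pep_end[idx])
  })
  names(sig_keys) <- conds

  manifest <- structure(list(
    seed = seed,
    planted_proteases = lapply(planted_idx, function(ix) rules$protease_id[ix]),
    signature_keys = sig_keys,
    condition_class = as.list(cond_class),
    parameters = unclass(config)
  ), class = "ground_truth_manifest")

  structure(list(disease = disease, health = health, manifest = manifest,
                 proteome = proteome, rules = rules),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic degradomics study (seed", x$manifest$seed, ")\n")
  cat("  disease:", length(unique(x$disease$records$key)), "peptides across",
      length(x$manifest$planted_proteases), "conditions\n")
  cat("  health:", length(unique(x$health$records$key)), "peptides\n")
  cat("  proteome:", length(x$proteome), "proteins | rules:",
      nrow(x$rules), "proteases\n")
  invisible(x)
}

#' Write the ground-truth manifest as JSON
#'
#' @param manifest A `ground_truth_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "ground_truth_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
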