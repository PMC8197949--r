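# Peptide-centric protease prediction: reconstruct P4-P4' cleavage windows
# at observed peptide termini and match them against MEROPS-style
# specificity rules.

.window_positions <- c("P4", "P3", "P2", "P1", "P1p", "P2p", "P3p", "P4p")
.catalytic_classes <- c("aspartic", "cysteine", "metallo", "serine", "threonine")

#' Construct a set of protease specificity rules
#'
#' Each rule gives, for each Schechter-Berger position P4..P4', either the
#' wildcard `"*"` or a non-empty string of allowed residues. At least one
#' position must be non-wildcard.
#'
#' @param df Data frame with columns `protease_id`, `catalytic_class`,
#'   `human`, and `P4, P3, P2, P1, P1p, P2p, P3p, P4p`.
#' @return A `specificity_rules` data frame.
#' @export
specificity_rules <- function(df) {
  req <- c("protease_id", "catalytic_class", "human", .window_positions)
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    .ud_stop(paste0("missing rule column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "urodegradome_rule_error")
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)[req]
  df$protease_id <- as.character(df$protease_id)
  df$catalytic_class <- tolower(as.character(df$catalytic_class))
  df$human <- as.logical(df$human)
  problems <- character(0)
  line <- function(i) paste0("rule ", i, " (", df$protease_id[i], ")")
  for (i in seq_len(nrow(df))) {
    if (!df$catalytic_class[i] %in% .catalytic_classes)
      problems <- c(problems, paste0(line(i), ": unknown catalytic class '",
                                     df$catalytic_class[i], "'"))
    if (is.na(df$human[i]))
      problems <- c(problems, paste0(line(i), ": human flag not TRUE/FALSE"))
    pos <- toupper(as.character(df[i, .window_positions]))
    non_wild <- pos != "*"
    if (!any(non_wild))
      problems <- c(problems, paste0(line(i), ": all positions wildcard"))
    bad <- non_wild & (!nzchar(pos) | !.is_canonical_seq(pos))
    if (any(bad))
      problems <- c(problems, paste0(line(i), ": invalid residue set at ",
                                     paste(.window_positions[bad], collapse = ", ")))
    df[i, .window_positions] <- pos
  }
  if (anyDuplicated(df$protease_id)) {
    problems <- c(problems, paste0("duplicate protease_id: ",
                                   paste(unique(df$protease_id[duplicated(df$protease_id)]),
                                         collapse = ", ")))
  }
  if (length(problems) > 0) {
    .ud_stop(paste(problems, collapse = "; "), "urodegradome_rule_error")
  }
  class(df) <- c("specificity_rules", "data.frame")
  df
}

#' Read protease specificity rules from structured text
#'
#' One record per protease: tab-separated with header `protease_id,
#' catalytic_class, human, P4..P4p`, each position `*` or a residue string.
#' Parse errors name the offending line.
#'
#' @param path File path.
#' @return A [specificity_rules()] data frame.
#' @export
read_specificity_rules <- function(path) {
  if (!file.exists(path)) {
    .ud_stop(paste0("file not found: ", path), "urodegradome_io_error")
  }
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  tryCatch(specificity_rules(df), urodegradome_rule_error = function(e) {
    .ud_stop(paste0(path, ": ", conditionMessage(e)), "urodegradome_rule_error")
  })
}

#' Write protease specificity rules to structured text
#'
#' @param rules A [specificity_rules()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_specificity_rules <- function(rules, path) {
  stopifnot(inherits(rules, "specificity_rules"))
  write.table(as.data.frame(rules), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Cleavage windows at given cut positions
#'
#' The window holds the 8 symbols at positions P4..P1 (parent residues
#' `cut-3 .. cut`) and P1'..P4' (parent residues `cut+1 .. cut+4`), with
#' `-` where the window overruns a protein terminus.
#'
#' @param parent_seq Parent protein sequence (single string).
#' @param cuts Integer vector of cut positions (`1 <= cut < nchar(parent)`);
#'   cleavage is between residues `cut` and `cut + 1`.
#' @return Character vector of 8-symbol windows.
#' @export
cleavage_window <- function(parent_seq, cuts) {
  L <- nchar(parent_seq)
  if (any(cuts < 1 | cuts >= L)) {
    .ud_stop("cut position out of range (need 1 <= cut < parent length)",
             "urodegradome_argument_error")
  }
  padded <- paste0("---", parent_seq, "----")
  substring(padded, cuts, cuts + 7L)
}

#' Reconstruct the cleavage sites evidenced by one peptide
#'
#' An observed peptide evidences up to two proteolytic events: an
#' N-terminal cleavage between parent residues `start - 1` and `start`
#' (only if `start > 1`) and a C-terminal cleavage between `end` and
#' `end + 1` (only if `end < parent length`). Termini coinciding with the
#' intact protein termini are not cleavage events.
#'
#' @param start,end 1-based inclusive peptide coordinates in the parent.
#' @param parent_seq Parent protein sequence.
#' @return Data frame with 0-2 rows: `terminus` (`"N"`/`"C"`),
#'   `cut_position`, `window`.
#' @export
reconstruct_cleavage_sites <- function(start, end, parent_seq) {
  L <- nchar(parent_seq)
  if (start < 1 || end > L || end < start) {
    .ud_stop("peptide coordinates do not fit the parent sequence",
             "urodegradome_validation_error")
  }
  terminus <- character(0); cut <- integer(0)
  if (start > 1) { terminus <- c(terminus, "N"); cut <- c(cut, start - 1L) }
  if (end < L) { terminus <- c(terminus, "C"); cut <- c(cut, as.integer(end)) }
  data.frame(terminus = terminus, cut_position = cut,
             window = if (length(cut)) cleavage_window(parent_seq, cut) else character(0),
             stringsAsFactors = FALSE)
}

# Vectorised matcher: logical vector, one entry per window. `rule` may be
# a one-row data frame or a plain list with the P4..P4p fields.
.match_windows <- function(windows, rule, gap_satisfies_wildcard = TRUE) {
  ok <- rep(TRUE, length(windows))
  for (j in seq_along(.window_positions)) {
    spec <- rule[[.window_positions[j]]]
    sym <- substr(windows, j, j)
    if (identical(spec, "*")) {
      if (!gap_satisfies_wildcard) ok <- ok & sym != "-"
    } else {
      ok <- ok & sym %in% .residues(spec)
    }
  }
  ok
}

# Rules as a plain list of lists (cheap row access in hot loops).
.rules_as_list <- function(rules) {
  lapply(seq_len(nrow(rules)), function(r) as.list(rules[r, ]))
}

#' Does a cleavage window satisfy a specificity rule?
#'
#' True iff at every non-wildcard position the window symbol is a residue
#' in the allowed set. A terminal-gap symbol `-` never satisfies a
#' non-wildcard position; by default it does satisfy a wildcard (the
#' conservative reading, switchable).
#'
#' @param window 8-symbol window (residues or `-`), or a vector of them.
#' @param rule One row of a [specificity_rules()] data frame (or a list
#'   with the `P4..P4p` fields).
#' @param gap_satisfies_wildcard If `FALSE`, a gap fails wildcard
#'   positions too.
#' @return Logical vector.
#' @export
match_site <- function(window, rule, gap_satisfies_wildcard = TRUE) {
  .match_windows(window, rule, gap_satisfies_wildcard)
}

#' Predict the degradome of an association table
#'
#' For every peptide with an available parent protein, both termini are
#' reconstructed and matched against every retained (human) specificity
#' rule. A prediction event is a (peptide, terminus, protease) triple,
#' counted once per group; under `grouping = "condition"` a peptide listed
#' under two conditions contributes its events to both groups, under
#' `"all"` once in total.
#'
#' @param table An [association_table()].
#' @param rules A [specificity_rules()] data frame; non-human rules are
#'   excluded before matching.
#' @param proteome A [proteome()].
#' @param grouping `"condition"`, `"class"`, or `"all"`.
#' @param gap_satisfies_wildcard See [match_site()].
#' @return A `prediction_set`: list with `events` (data frame `group,
#'   protease_id, peptide_id, key, terminus, cut_position, window`),
#'   `counts` (per group x protease), `totals` (per group), `grouping`,
#'   and `skipped` (peptide keys lacking a parent).
#' @export
predict_degradome <- function(table, rules, proteome,
                              grouping = c("condition", "class", "all"),
                              gap_satisfies_wildcard = TRUE) {
  stopifnot(inherits(table, "association_table"),
            inherits(rules, "specificity_rules"))
  grouping <- match.arg(grouping)
  rules <- rules[rules$human, , drop = FALSE]
  if (nrow(rules) == 0) {
    .ud_stop("no human rules left after filtering", "urodegradome_rule_error")
  }
  rec <- table$records
  up <- rec[!duplicated(rec$key),
            c("key", "peptide_id", "uniprot", "start", "end"), drop = FALSE]
  have <- up$uniprot %in% names(proteome)
  skipped <- up$key[!have]
  if (length(skipped) > 0) {
    warning(length(skipped),
            " peptide(s) lack a parent sequence and were skipped")
  }
  up <- up[have, , drop = FALSE]

  # Site table: up to two rows (N/C) per peptide.
  plen <- nchar(unclass(proteome))[up$uniprot]
  n_ok <- up$start > 1
  c_ok <- up$end < plen
  sites <- data.frame(
    key = c(up$key[n_ok], up$key[c_ok]),
    peptide_id = c(up$peptide_id[n_ok], up$peptide_id[c_ok]),
    uniprot = c(up$uniprot[n_ok], up$uniprot[c_ok]),
    terminus = c(rep("N", sum(n_ok)), rep("C", sum(c_ok))),
    cut_position = c(up$start[n_ok] - 1L, up$end[c_ok]),
    stringsAsFactors = FALSE
  )
  if (nrow(sites) > 0) {
    padded <- paste0("---", unclass(proteome), "----")[match(sites$uniprot, names(proteome))]
    sites$window <- substring(padded, sites$cut_position, sites$cut_position + 7L)
  } else {
    sites$window <- character(0)
  }

  # Match all sites against all rules; assemble events in one pass.
  rlist <- .rules_as_list(rules)
  hit_idx <- vector("list", nrow(rules))
  for (r in seq_len(nrow(rules))) {
    hit_idx[[r]] <- which(.match_windows(sites$window, rlist[[r]],
                                         gap_satisfies_wildcard))
  }
  n_hits <- lengths(hit_idx)
  if (sum(n_hits) > 0) {
    events <- sites[unlist(hit_idx), , drop = FALSE]
    events$protease_id <- rep(rules$protease_id, n_hits)
  } else {
    events <- cbind(sites[0, , drop = FALSE], protease_id = character(0))
  }

  # Expand events to groups.
  if (grouping == "all") {
    events$group <- "all"
  } else {
    gcol <- if (grouping == "condition") "condition" else "class"
    membership <- unique(rec[, c("key", gcol)])
    names(membership)[2] <- "group"
    events <- merge(events, membership, by = "key")
  }
  events <- events[order(events$group, events$protease_id, events$key,
                         events$terminus), , drop = FALSE]
  rownames(events) <- NULL

  if (nrow(events) > 0) {
    counts <- aggregate(list(n_events = events$key),
                        by = list(group = events$group,
                                  protease_id = events$protease_id),
                        FUN = length)
    totals <- tapply(events$key, events$group, length)
    totals <- setNames(as.integer(totals), names(totals))
  } else {
    counts <- data.frame(group = character(0), protease_id = character(0),
                         n_events = integer(0))
    totals <- integer(0)
  }

  structure(list(events = events, counts = counts, totals = totals,
                 grouping = grouping, skipped = skipped,
                 protease_ids = rules$protease_id),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("Degradome prediction set (grouping:", x$grouping, ")\n")
  cat("  events:", nrow(x$events), "| groups:", length(x$totals),
      "| proteases with events:", length(unique(x$events$protease_id)), "\n")
  if (length(x$skipped) > 0) cat("  skipped peptides:", length(x$skipped), "\n")
  invisible(x)
}

#' Write prediction events as delimited text
#'
#' @param x A `prediction_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(x, path) {
  stopifnot(inherits(x, "prediction_set"))
  write.table(x$events[, c("group", "protease_id", "peptide_id", "terminus",
                           "cut_position", "window")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
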