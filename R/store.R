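# Data model and I/O for disease-peptide association tables, parent
# proteomes and the health reference set.

#' Construct a disease-peptide association table
#'
#' The association table is the package's central container: one row per
#' (peptide, condition) association, plus a condition-to-class mapping.
#' Peptides are keyed by (sequence, parent accession, start, end); the same
#' key may be associated with several conditions.
#'
#' @param records Data frame with columns `peptide_id`, `sequence`,
#'   `uniprot`, `gene`, `start`, `end`, `condition`, `class`.
#' @param condition_class Optional named character vector mapping condition
#'   labels to class labels; derived from `records$class` when absent.
#' @return An object of class `association_table`: a list with elements
#'   `records` (validated, deduplicated data frame with an added `key`
#'   column) and `condition_class`.
#' @export
association_table <- function(records, condition_class = NULL) {
  req <- c("peptide_id", "sequence", "uniprot", "gene", "start", "end",
           "condition", "class")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    .ud_stop(paste0("missing required column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "urodegradome_schema_error")
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)[req]
  records$sequence <- toupper(trimws(as.character(records$sequence)))
  records$peptide_id <- as.character(records$peptide_id)
  records$uniprot <- trimws(as.character(records$uniprot))
  records$gene <- as.character(records$gene)
  records$condition <- tolower(trimws(as.character(records$condition)))
  records$class <- tolower(trimws(as.character(records$class)))
  records$start <- suppressWarnings(as.integer(records$start))
  records$end <- suppressWarnings(as.integer(records$end))

  .validate_records(records)

  # Collapse duplicate (sequence, parent, start, end, condition) rows.
  records$key <- peptide_key(records$sequence, records$uniprot,
                             records$start, records$end)
  records <- records[!duplicated(paste(records$key, records$condition, sep = "\r")), ,
                     drop = FALSE]
  rownames(records) <- NULL

  if (is.null(condition_class)) {
    cc <- unique(records[, c("condition", "class")])
    dup <- cc$condition[duplicated(cc$condition)]
    if (length(dup) > 0) {
      .ud_stop(paste0("condition(s) mapped to more than one class: ",
                      paste(unique(dup), collapse = ", ")),
               "urodegradome_schema_error")
    }
    condition_class <- setNames(cc$class, cc$condition)
  } else {
    condition_class <- setNames(tolower(trimws(as.character(condition_class))),
                                tolower(trimws(names(condition_class))))
    unmapped <- setdiff(unique(records$condition), names(condition_class))
    if (length(unmapped) > 0) {
      .ud_stop(paste0("condition(s) without a class mapping: ",
                      paste(unmapped, collapse = ", ")),
               "urodegradome_schema_error")
    }
    records$class <- unname(condition_class[records$condition])
  }
  bad_class <- setdiff(unique(condition_class), .valid_classes())
  if (length(bad_class) > 0) {
    .ud_stop(paste0("unknown disease class label(s): ",
                    paste(bad_class, collapse = ", ")),
             "urodegradome_schema_error")
  }

  structure(list(records = records, condition_class = condition_class),
            class = "association_table")
}

# Record-level validation collecting all offending row numbers.
.validate_records <- function(records) {
  n <- nrow(records)
  if (n == 0) return(invisible(TRUE))
  rows <- seq_len(n)
  noncanon <- rows[.has_noncanonical_code(records$sequence)]
  if (length(noncanon) > 0) {
    .ud_stop(paste0("sequence with non-canonical residue code (B/Z/U/O/X) in row(s): ",
                    paste(noncanon, collapse = ", ")),
             c("urodegradome_noncanonical_error", "urodegradome_validation_error"),
             rows = noncanon)
  }
  bad_seq <- rows[!.is_canonical_seq(records$sequence)]
  bad_coord <- rows[is.na(records$start) | is.na(records$end) |
                      records$start < 1 | records$end < records$start]
  bad_len <- setdiff(
    rows[!is.na(records$start) & !is.na(records$end) &
           (records$end - records$start + 1L) != nchar(records$sequence)],
    bad_coord
  )
  bad <- sort(unique(c(bad_seq, bad_coord, bad_len)))
  if (length(bad) > 0) {
    parts <- character(0)
    if (length(bad_seq) > 0)
      parts <- c(parts, paste0("invalid sequence in row(s): ",
                               paste(bad_seq, collapse = ", ")))
    if (length(bad_coord) > 0)
      parts <- c(parts, paste0("invalid coordinates (need 1 <= start <= end) in row(s): ",
                               paste(bad_coord, collapse = ", ")))
    if (length(bad_len) > 0)
      parts <- c(parts, paste0("end - start + 1 != sequence length in row(s): ",
                               paste(bad_len, collapse = ", ")))
    .ud_stop(paste(parts, collapse = "; "), "urodegradome_validation_error",
             rows = bad)
  }
  invisible(TRUE)
}

#' @export
print.association_table <- function(x, ...) {
  cat("Disease-peptide association table\n")
  cat("  associations:", nrow(x$records), "\n")
  cat("  unique peptides:", length(unique(x$records$key)), "\n")
  cat("  conditions:", length(x$condition_class),
      sprintf("(%d classes)", length(unique(x$condition_class))), "\n")
  invisible(x)
}

#' Load a disease-peptide association table from delimited text
#'
#' Reads a UTF-8 delimited file with required columns `peptide_id,
#' sequence, uniprot, gene, start, end, condition, class` (remappable via
#' `col_map`; `class` may instead be supplied as a side mapping via
#' `class_map`). Condition and class labels are case-normalised and
#' trimmed; duplicate association rows are collapsed; coordinates and the
#' 20-letter alphabet are validated, collecting all offending row numbers.
#'
#' @param path Path to the file.
#' @param delim Field delimiter; `NULL` (default) sniffs tab vs comma from
#'   the header line.
#' @param col_map Optional named character vector mapping required column
#'   names to the names actually used in the file, e.g.
#'   `c(uniprot = "accession")`.
#' @param class_map Optional named character vector mapping condition
#'   labels to class labels, used when the file has no `class` column.
#' @return An [association_table()].
#' @export
load_association_table <- function(path, delim = NULL, col_map = NULL,
                                   class_map = NULL) {
  if (!file.exists(path)) {
    .ud_stop(paste0("file not found: ", path), "urodegradome_io_error")
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  df <- read.delim(path, sep = delim, stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE,
                   fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(df)) {
        .ud_stop(paste0("mapped column not present in file: ", col_map[[std]]),
                 "urodegradome_schema_error")
      }
      names(df)[names(df) == col_map[[std]]] <- std
    }
  }
  if (!"class" %in% names(df)) {
    if (is.null(class_map)) {
      .ud_stop("no `class` column and no `class_map` supplied",
               "urodegradome_schema_error")
    }
    df$class <- NA_character_
    cm <- setNames(tolower(trimws(class_map)), tolower(trimws(names(class_map))))
    df$class <- unname(cm[tolower(trimws(df$condition))])
    return(association_table(df, condition_class = cm))
  }
  association_table(df, condition_class = class_map)
}

#' Write an association table in canonical form
#'
#' Rows are sorted by (uniprot, start, end, sequence, condition) and written
#' as tab-separated UTF-8 text, so that write-load-write round trips are
#' byte-identical.
#'
#' @param x An [association_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(x, path) {
  stopifnot(inherits(x, "association_table"))
  rec <- x$records
  ord <- order(rec$uniprot, rec$start, rec$end, rec$sequence, rec$condition)
  rec <- rec[ord, c("peptide_id", "sequence", "uniprot", "gene",
                    "start", "end", "condition", "class")]
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(rec, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a parent proteome from FASTA
#'
#' The token up to the first whitespace in each header is used as the
#' accession. Accessions must be unique and sequences non-empty.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector (accession -> uppercase sequence) of class
#'   `proteome`.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  acc <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(aa))
  proteome(setNames(seqs, acc))
}

#' Construct a proteome object from named sequences
#'
#' @param sequences Named character vector, accession -> amino-acid sequence.
#' @return Named character vector of class `proteome`.
#' @export
proteome <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    .ud_stop("proteome sequences must be named by accession",
             "urodegradome_schema_error")
  }
  if (anyDuplicated(names(sequences))) {
    .ud_stop("duplicate accession(s) in proteome", "urodegradome_schema_error")
  }
  if (any(!nzchar(sequences))) {
    .ud_stop("empty protein sequence(s)", "urodegradome_validation_error")
  }
  structure(toupper(unlist(sequences)), class = "proteome")
}

#' Write a proteome to FASTA
#'
#' @param x A [proteome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(x, path) {
  aa <- Biostrings::AAStringSet(unclass(x))
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Check peptide coordinates against parent protein sequences
#'
#' For each unique peptide with an available parent, verifies that the
#' peptide sequence equals the parent substring at the recorded 1-based
#' inclusive coordinates. Missing parents are reported, not fatal.
#'
#' @param table An [association_table()].
#' @param proteome A [proteome()].
#' @return A `validation_report`: list with counts (`n_peptides`,
#'   `n_match`, `n_mismatch`, `n_missing`) and data frames `mismatches`,
#'   `missing`.
#' @export
validate_against_proteome <- function(table, proteome) {
  stopifnot(inherits(table, "association_table"))
  rec <- table$records
  up <- rec[!duplicated(rec$key),
            c("key", "peptide_id", "sequence", "uniprot", "start", "end")]
  have <- up$uniprot %in% names(proteome)
  missing <- up[!have, , drop = FALSE]
  present <- up[have, , drop = FALSE]
  if (nrow(present) > 0) {
    parent_sub <- substr(unclass(proteome)[present$uniprot],
                         present$start, present$end)
    ok <- parent_sub == present$sequence &
      present$end <= nchar(unclass(proteome)[present$uniprot])
  } else {
    ok <- logical(0)
  }
  mism <- present[!ok, , drop = FALSE]
  if (nrow(mism) > 0) {
    mism$parent_substring <- substr(unclass(proteome)[mism$uniprot],
                                    mism$start, mism$end)
  } else {
    mism$parent_substring <- character(0)
  }
  rownames(mism) <- rownames(missing) <- NULL
  structure(list(
    n_peptides = nrow(up),
    n_match = sum(ok),
    n_mismatch = nrow(mism),
    n_missing = nrow(missing),
    mismatches = mism,
    missing = missing
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Proteome validation report\n")
  cat(sprintf("  peptides: %d | matches: %d | mismatches: %d | missing parents: %d\n",
              x$n_peptides, x$n_match, x$n_mismatch, x$n_missing))
  invisible(x)
}

#' Per-class peptide and protein counts, with optional reference overlap
#'
#' Counts unique peptides (by key) and unique parent proteins per disease
#' class. Because a peptide may be associated with conditions of several
#' classes, per-class counts can sum to more than the total unique count.
#' When a reference table (typically the health set) is given, the overlap
#' of parent proteins and of peptide sequences is also reported.
#'
#' @param table An [association_table()].
#' @param reference Optional second [association_table()].
#' @return A `class_summary`: list with `per_class` data frame (`class`,
#'   `n_peptides`, `n_proteins`), totals, and (if `reference` given) an
#'   `overlap` list with shared protein/sequence counts and fractions.
#' @export
summarize_classes <- function(table, reference = NULL) {
  stopifnot(inherits(table, "association_table"))
  rec <- table$records
  cls <- sort(unique(rec$class))
  per_class <- do.call(rbind, lapply(cls, function(cl) {
    sub <- rec[rec$class == cl, , drop = FALSE]
    data.frame(class = cl,
               n_peptides = length(unique(sub$key)),
               n_proteins = length(unique(sub$uniprot)),
               stringsAsFactors = FALSE)
  }))
  rownames(per_class) <- NULL
  out <- list(per_class = per_class,
              total_peptides = length(unique(rec$key)),
              total_proteins = length(unique(rec$uniprot)))
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "association_table"))
    ref <- reference$records
    prot <- unique(rec$uniprot)
    seqs <- unique(rec$sequence)
    shared_prot <- intersect(prot, unique(ref$uniprot))
    shared_seq <- intersect(seqs, unique(ref$sequence))
    out$overlap <- list(
      n_proteins = length(prot),
      n_shared_proteins = length(shared_prot),
      protein_fraction = length(shared_prot) / length(prot),
      n_sequences = length(seqs),
      n_shared_sequences = length(shared_seq),
      sequence_fraction = length(shared_seq) / length(seqs)
    )
  }
  structure(out, class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat("Class summary:", x$total_peptides, "unique peptides from",
      x$total_proteins, "proteins\n")
  print(x$per_class, row.names = FALSE)
  if (!is.null(x$overlap)) {
    cat(sprintf("  shared with reference: %d/%d proteins (%.1f%%), %d/%d sequences (%.1f%%)\n",
                x$overlap$n_shared_proteins, x$overlap$n_proteins,
                100 * x$overlap$protein_fraction,
                x$overlap$n_shared_sequences, x$overlap$n_sequences,
                100 * x$overlap$sequence_fraction))
  }
  invisible(x)
}

#' Export a validation report or class summary
#'
#' @param x A `validation_report` or `class_summary`.
#' @param path Output path.
#' @param format `"tsv"` (per-class / per-record rows) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  } else if (inherits(x, "class_summary")) {
    write.table(x$per_class, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (inherits(x, "validation_report")) {
    counts <- data.frame(metric = c("n_peptides", "n_match", "n_mismatch", "n_missing"),
                         value = c(x$n_peptides, x$n_match, x$n_mismatch, x$n_missing))
    write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    .ud_stop("unsupported object for write_report", "urodegradome_schema_error")
  }
  invisible(path)
}
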