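# Minimal degradome signatures: smallest protease subsets uniquely
# identifying a condition from the binary enrichment matrix.

#' Construct a binary enrichment matrix
#'
#' @param mat Logical matrix, conditions in rows, proteases in columns,
#'   entry `TRUE` iff the protease is significantly enriched in the
#'   condition. Dimnames must be unique; all-`FALSE` rows are allowed.
#' @return An `enrichment_matrix`.
#' @export
enrichment_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.logical(mat)) {
    .ud_stop("enrichment matrix must be a logical matrix",
             "urodegradome_schema_error")
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat)) ||
      anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat))) {
    .ud_stop("enrichment matrix needs unique row (condition) and column (protease) names",
             "urodegradome_schema_error")
  }
  structure(mat, class = c("enrichment_matrix", "matrix", "array"))
}

.enriched_set <- function(mat, condition) {
  sort(colnames(mat)[mat[condition, ]])
}

#' Minimal degradome signature of a condition
#'
#' Exhaustive search, in increasing cardinality, for the smallest subsets
#' of the condition's enriched proteases that are contained in no other
#' condition's enriched set. All identifying subsets at the first
#' cardinality `k*` where any exists are returned (lexicographic order);
#' if none exists up to `kmax`, the expression is empty (`k*` absent).
#'
#' @param mat An [enrichment_matrix()].
#' @param condition Condition (row) label.
#' @param kmax Largest subset size to try (default 3).
#' @param against Conditions to test uniqueness against (default all rows);
#'   restrict e.g. to one disease class via this argument.
#' @return A `signature_expression`: list with `condition`, `k_star`
#'   (`NA` if none), `minimal_sets` (list of character vectors), and
#'   `rendered` text.
#' @export
minimal_signatures <- function(mat, condition, kmax = 3, against = rownames(mat)) {
  stopifnot(inherits(mat, "enrichment_matrix"))
  if (!condition %in% rownames(mat)) {
    .ud_stop(paste0("unknown condition: ", condition),
             "urodegradome_argument_error")
  }
  if (kmax < 1) {
    .ud_stop("kmax must be >= 1", "urodegradome_argument_error")
  }
  enriched <- .enriched_set(mat, condition)
  others <- setdiff(intersect(against, rownames(mat)), condition)
  other_sets <- lapply(others, function(cc) .enriched_set(mat, cc))
  found <- list()
  k_star <- NA_integer_
  if (length(enriched) > 0) {
    for (k in seq_len(min(kmax, length(enriched)))) {
      combs <- combn(enriched, k, simplify = FALSE)
      hit <- Filter(function(S) {
        !any(vapply(other_sets, function(E) all(S %in% E), logical(1)))
      }, combs)
      if (length(hit) > 0) {
        found <- hit
        k_star <- k
        break
      }
    }
  }
  expr <- structure(list(condition = condition, k_star = k_star,
                         minimal_sets = found, rendered = NULL),
                    class = "signature_expression")
  expr$rendered <- render_expression(expr)
  expr
}

# Try to factor equally-sized minimal sets as an exact cross-product of
# per-slot alternatives; NULL if not factorable.
.factor_sets <- function(sets) {
  k <- length(sets[[1]])
  if (any(lengths(sets) != k)) return(NULL)
  canon <- function(S) paste(sort(S), collapse = "\r")
  have <- vapply(sets, canon, character(1))
  base <- sets[[1]]
  slots <- lapply(base, function(a) {
    rest <- setdiff(base, a)
    alts <- unique(unlist(sets))
    alts <- Filter(function(b) canon(c(rest, b)) %in% have, alts)
    sort(alts)
  })
  # Slots must be pairwise disjoint and their product must equal the sets.
  all_members <- unlist(slots)
  if (anyDuplicated(all_members)) return(NULL)
  if (prod(lengths(slots)) != length(sets)) return(NULL)
  grid <- expand.grid(slots, stringsAsFactors = FALSE)
  prod_keys <- apply(grid, 1, function(r) canon(as.character(r)))
  if (!setequal(prod_keys, have) || anyDuplicated(prod_keys)) return(NULL)
  # Deterministic slot order: by first alternative.
  slots[order(vapply(slots, `[[`, character(1), 1L))]
}

#' Render a signature expression as Table-style text
#'
#' Singleton alternatives are joined by `" or "`; a single multi-protease
#' set by `" + "`; when the minimal sets form an exact cross-product of
#' per-slot alternatives they are factored as `+`-joined parenthesised
#' `or`-groups; otherwise the sets are listed separated by `" | "`. An
#' empty expression renders as `"no unique degradome profile"`.
#'
#' @param expr A `signature_expression`.
#' @return Character string.
#' @export
render_expression <- function(expr) {
  sets <- lapply(expr$minimal_sets, sort)
  if (length(sets) == 0) return("no unique degradome profile")
  if (all(lengths(sets) == 1)) {
    return(paste(sort(vapply(sets, `[[`, character(1), 1L)), collapse = " or "))
  }
  if (length(sets) == 1) {
    return(paste(sets[[1]], collapse = " + "))
  }
  slots <- .factor_sets(sets)
  if (!is.null(slots)) {
    parts <- vapply(slots, function(s) {
      if (length(s) == 1) s else paste0("(", paste(s, collapse = " or "), ")")
    }, character(1))
    return(paste(parts, collapse = " + "))
  }
  canon <- vapply(sets, function(S) paste(S, collapse = " + "), character(1))
  paste(sort(canon), collapse = " | ")
}

#' Parse rendered signature text back into minimal sets
#'
#' Inverse of [render_expression()] (the cross-product factoring is
#' lossless).
#'
#' @param text Rendered signature text.
#' @return List of character vectors (sorted), empty for
#'   `"no unique degradome profile"`.
#' @export
parse_signature <- function(text) {
  text <- trimws(text)
  if (identical(text, "no unique degradome profile") || !nzchar(text)) {
    return(list())
  }
  parts <- strsplit(text, " | ", fixed = TRUE)[[1]]
  sets <- list()
  for (part in parts) {
    slots <- strsplit(trimws(part), " + ", fixed = TRUE)[[1]]
    alts <- lapply(slots, function(s) {
      s <- trimws(s)
      s <- sub("^\\(", "", s)
      s <- sub("\\)$", "", s)
      trimws(strsplit(s, " or ", fixed = TRUE)[[1]])
    })
    grid <- expand.grid(alts, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid))) {
      sets[[length(sets) + 1]] <- sort(as.character(grid[i, ]))
    }
  }
  unique(sets)
}

#' @export
print.signature_expression <- function(x, ...) {
  cat(x$condition, ": ", x$rendered,
      if (!is.na(x$k_star)) paste0("  (k* = ", x$k_star, ")") else "", "\n",
      sep = "")
  invisible(x)
}

#' Minimal degradome signatures for every condition
#'
#' @param mat An [enrichment_matrix()].
#' @param kmax Largest subset size (default 3).
#' @param classes Optional named character vector mapping conditions to
#'   disease classes, included as a column.
#' @return Data frame `condition, class, k_star, signature`.
#' @export
minimal_signature_table <- function(mat, kmax = 3, classes = NULL) {
  stopifnot(inherits(mat, "enrichment_matrix"))
  rows <- lapply(rownames(mat), function(cc) {
    e <- minimal_signatures(mat, cc, kmax = kmax)
    data.frame(condition = cc,
               class = if (is.null(classes)) NA_character_ else unname(classes[cc]),
               k_star = e$k_star,
               signature = e$rendered,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
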