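# Bipartite disease-peptide network, degree computation and signature
# (degree-1) peptide extraction.

#' Build the bipartite disease-peptide network
#'
#' Conditions are source nodes and peptides target nodes; one edge per
#' distinct (condition, peptide) association. Peptide degree is the number
#' of distinct conditions a peptide is associated with. Conditions mapped
#' to the `health` class are excluded: health is a separate reference, not
#' part of the disease network.
#'
#' @param table An [association_table()].
#' @param peptide_identity `"key"` (default) identifies a peptide node by
#'   the full (sequence, parent, start, end) key; `"sequence"` merges
#'   identical sequences from different loci/parents into one node (this
#'   can change degree and signature counts).
#' @return An `igraph` object of class `disease_peptide_network` with
#'   vertex attributes `node_type` (`"condition"`/`"peptide"`), `type`
#'   (bipartite flag: peptides are `TRUE`), `degree`, and for peptide nodes
#'   `peptide_id` and `sequence`.
#' @export
build_network <- function(table, peptide_identity = c("key", "sequence")) {
  stopifnot(inherits(table, "association_table"))
  peptide_identity <- match.arg(peptide_identity)
  rec <- table$records
  health_conditions <- names(table$condition_class)[table$condition_class == "health"]
  rec <- rec[!rec$condition %in% health_conditions, , drop = FALSE]
  if (nrow(rec) == 0) {
    .ud_stop("no disease associations to build a network from",
             "urodegradome_empty_error")
  }
  node <- if (peptide_identity == "key") rec$key else rec$sequence
  edges <- unique(data.frame(condition = rec$condition, peptide = node,
                             stringsAsFactors = FALSE))
  pep_meta <- rec[!duplicated(node), , drop = FALSE]
  pep_nodes <- if (peptide_identity == "key") pep_meta$key else pep_meta$sequence
  vertices <- rbind(
    data.frame(name = unique(edges$condition), node_type = "condition",
               peptide_id = NA_character_, sequence = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(name = pep_nodes, node_type = "peptide",
               peptide_id = pep_meta$peptide_id, sequence = pep_meta$sequence,
               stringsAsFactors = FALSE)
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  igraph::V(g)$type <- igraph::V(g)$node_type == "peptide"
  igraph::V(g)$degree <- igraph::degree(g)
  g <- igraph::set_graph_attr(g, "peptide_identity", peptide_identity)
  class(g) <- c("disease_peptide_network", class(g))
  g
}

#' Extract signature (degree-1) peptides from the network
#'
#' A signature peptide is associated with exactly one condition. Signature
#' sets of different conditions are disjoint by construction.
#'
#' @param graph A network from [build_network()].
#' @return A `signature_set`: list with `by_condition` (named list of
#'   peptide node names), `peptides` (data frame `condition, peptide,
#'   peptide_id, sequence`), and `total`.
#' @export
extract_signatures <- function(graph) {
  stopifnot(inherits(graph, "igraph"))
  v <- igraph::V(graph)
  is_pep <- v$node_type == "peptide"
  deg <- igraph::degree(graph)
  sig_idx <- which(is_pep & deg == 1)
  if (length(sig_idx) > 0) {
    cond <- vapply(sig_idx, function(i) {
      igraph::V(graph)$name[igraph::neighbors(graph, i)[1]]
    }, character(1))
    df <- data.frame(condition = cond,
                     peptide = v$name[sig_idx],
                     peptide_id = v$peptide_id[sig_idx],
                     sequence = v$sequence[sig_idx],
                     stringsAsFactors = FALSE)
    df <- df[order(df$condition, df$peptide), , drop = FALSE]
    rownames(df) <- NULL
    by_condition <- split(df$peptide, df$condition)
  } else {
    df <- data.frame(condition = character(0), peptide = character(0),
                     peptide_id = character(0), sequence = character(0),
                     stringsAsFactors = FALSE)
    by_condition <- list()
  }
  structure(list(by_condition = by_condition, peptides = df,
                 total = nrow(df)),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("Signature peptides (degree = 1):", x$total, "across",
      length(x$by_condition), "conditions\n")
  if (length(x$by_condition) > 0) {
    counts <- vapply(x$by_condition, length, integer(1))
    print(data.frame(condition = names(counts), n_signatures = unname(counts)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Write the signature peptide list as delimited text
#'
#' @param x A `signature_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(x, path) {
  stopifnot(inherits(x, "signature_set"))
  write.table(x$peptides[, c("condition", "peptide_id", "sequence")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the network as SIF or GraphML
#'
#' SIF lines read `condition<TAB>associates<TAB>peptide`. GraphML carries
#' the node attributes (`node_type`, `degree`, `peptide_id`, `sequence`).
#'
#' @param graph A network from [build_network()].
#' @param path Output path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(graph, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- graph
    class(g) <- "igraph"
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    is_cond <- igraph::V(graph)$node_type[match(el[, 1], igraph::V(graph)$name)] == "condition"
    src <- ifelse(is_cond, el[, 1], el[, 2])
    tgt <- ifelse(is_cond, el[, 2], el[, 1])
    writeLines(paste(src, "associates", tgt, sep = "\t"), path)
  }
  invisible(path)
}

#' Re-import a network exported by [export_network()]
#'
#' @param path File path.
#' @param format `"sif"` or `"graphml"`.
#' @return An igraph object with `node_type` and `degree` attributes
#'   (recomputed for SIF, which does not carry attributes).
#' @export
import_network <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    igraph::V(g)$degree <- as.integer(igraph::V(g)$degree)
    return(g)
  }
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 3L)
  if (length(bad) > 0) {
    .ud_stop(paste0("malformed SIF line(s): ", paste(bad, collapse = ", ")),
             "urodegradome_io_error")
  }
  edges <- data.frame(condition = vapply(parts, `[[`, character(1), 1L),
                      peptide = vapply(parts, `[[`, character(1), 3L),
                      stringsAsFactors = FALSE)
  vertices <- rbind(
    data.frame(name = unique(edges$condition), node_type = "condition"),
    data.frame(name = unique(edges$peptide), node_type = "peptide")
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  igraph::V(g)$type <- igraph::V(g)$node_type == "peptide"
  igraph::V(g)$degree <- igraph::degree(g)
  g
}
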