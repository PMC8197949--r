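# Shared constants and low-level helpers.

#' The 20 canonical amino-acid one-letter codes
#'
#' @return Character vector of length 20, alphabetical.
#' @export
canonical_residues <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Ambiguity/non-standard codes that get a distinct rejection error: the
# descriptor scales and specificity matching are undefined for them.
.noncanonical_codes <- c("B", "Z", "U", "O", "X")

#' The nine disease-class labels plus the health reference label
#'
#' @return Character vector of valid class labels.
#' @export
disease_classes <- function() {
  c("autoimmune", "bowel", "cancer", "cardiovascular", "infection",
    "mental", "metabolic", "renal", "respiratory")
}

.valid_classes <- function() c(disease_classes(), "health")

# Classed error helper so callers can distinguish schema errors, record
# validation errors, non-canonical alphabet errors etc. programmatically.
.ud_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "urodegradome_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

.is_canonical_seq <- function(x) {
  !is.na(x) & nzchar(x) & !grepl(paste0("[^", paste(canonical_residues(), collapse = ""), "]"), x)
}

.has_noncanonical_code <- function(x) {
  grepl(paste0("[", paste(.noncanonical_codes, collapse = ""), "]"), x)
}

#' Peptide uniqueness key
#'
#' A peptide is identified by the quadruple (sequence, parent accession,
#' start, end): the same sequence can occur at two loci or in two parents,
#' and the degradome stage needs the coordinates. Coordinates are 1-based
#' inclusive throughout the package.
#'
#' @param sequence Peptide sequence.
#' @param uniprot Parent protein accession.
#' @param start,end 1-based inclusive coordinates in the parent.
#' @return Character key, one per input element.
#' @export
peptide_key <- function(sequence, uniprot, start, end) {
  paste(sequence, uniprot, start, end, sep = "|")
}

# Split residues of one sequence into a character vector.
.residues <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

.read_scale_file <- function(name) {
  path <- system.file("extdata", "scales", name, package = "urodegradome")
  if (!nzchar(path)) {
    # During development (pkgload) fall back to the source tree.
    path <- file.path("inst", "extdata", "scales", name)
  }
  read.delim(path, stringsAsFactors = FALSE)
}
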