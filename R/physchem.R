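# Physicochemical descriptor engine: composition, amino-acid groups,
# molecular weight, GRAVY, net charge / isoelectric point, and per-class
# descriptor distribution summaries.

#' Load the bundled hydropathy scale (Kyte-Doolittle)
#'
#' @return Named numeric vector, residue -> hydropathy index.
#' @export
load_hydropathy_scale <- function() {
  df <- .read_scale_file("hydropathy_kyte_doolittle.tsv")
  setNames(df$hydropathy, df$residue)
}

#' Load a pKa scale for net-charge / pI calculation
#'
#' pKa values for the ionisable groups: the free termini plus D, E, C, Y
#' (acidic) and K, R, H (basic). Values differ across published scales, so
#' the scale used is recorded in descriptor output metadata.
#'
#' @param scale One of `"emboss"` (default), `"lehninger"`, `"bjellqvist"`.
#' @return A `pka_scale`: list with named numeric vectors `acidic` and
#'   `basic` (names `Cterm`, `D`, `E`, `C`, `Y` / `Nterm`, `K`, `R`, `H`)
#'   and the scale name.
#' @export
load_pka_scale <- function(scale = c("emboss", "lehninger", "bjellqvist")) {
  scale <- match.arg(scale)
  df <- .read_scale_file("pka_scales.tsv")
  vals <- setNames(df[[scale]], df$group)
  structure(list(
    acidic = vals[df$group[df$kind == "acidic"]],
    basic = vals[df$group[df$kind == "basic"]],
    name = scale
  ), class = "pka_scale")
}

#' Load the bundled residue mass table
#'
#' @param monoisotopic Use monoisotopic instead of average masses.
#' @return Named numeric vector of residue masses (Da).
#' @export
load_mass_table <- function(monoisotopic = FALSE) {
  df <- .read_scale_file("residue_masses.tsv")
  setNames(if (monoisotopic) df$monoisotopic else df$average, df$residue)
}

# Mass of one water molecule (Da), added once per peptide chain.
.water_mass <- function(monoisotopic = FALSE) {
  if (monoisotopic) 18.0105646863 else 18.01528
}

#' Load the nine amino-acid group scheme
#'
#' Nine possibly overlapping residue sets (acidic, aromatic, basic,
#' charged, hydrophobic, polar-and-charged, polar-non-charged, small,
#' tiny). Shipped as a data file so alternative schemes are drop-in.
#'
#' @return Named list of character vectors of residues.
#' @export
load_aa_groups <- function() {
  df <- .read_scale_file("aa_groups.tsv")
  setNames(lapply(df$residues, function(s) .residues(s)), df$group)
}

.check_sequence <- function(sequence) {
  if (length(sequence) != 1 || is.na(sequence) || !nzchar(sequence)) {
    .ud_stop("sequence must be a single non-empty string",
             "urodegradome_validation_error")
  }
  if (.has_noncanonical_code(sequence)) {
    .ud_stop("sequence contains non-canonical residue code (B/Z/U/O/X)",
             c("urodegradome_noncanonical_error", "urodegradome_validation_error"))
  }
  if (!.is_canonical_seq(sequence)) {
    .ud_stop("sequence contains characters outside the 20-letter alphabet",
             "urodegradome_validation_error")
  }
  invisible(TRUE)
}

#' Per-residue composition of a peptide
#'
#' @param sequence Canonical peptide sequence.
#' @return Named numeric vector of 20 fractions summing to 1.
#' @export
residue_composition <- function(sequence) {
  .check_sequence(sequence)
  res <- .residues(sequence)
  counts <- table(factor(res, levels = canonical_residues()))
  as.vector(counts) / length(res) -> frac
  setNames(frac, canonical_residues())
}

#' Composition in the nine physicochemical amino-acid groups
#'
#' Each fraction is the number of residues belonging to the group divided
#' by the peptide length; groups overlap, so fractions do not sum to 1.
#'
#' @param sequence Canonical peptide sequence.
#' @param scheme Group scheme, default [load_aa_groups()].
#' @return Named numeric vector of nine fractions in `[0, 1]`.
#' @export
group_composition <- function(sequence, scheme = load_aa_groups()) {
  .check_sequence(sequence)
  res <- .residues(sequence)
  vapply(scheme, function(set) mean(res %in% set), numeric(1))
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over ionisable groups: each basic group
#' (N-terminus, K, R, H) contributes `+1/(1 + 10^(pH - pKa))`, each acidic
#' group (C-terminus, D, E, C, Y) contributes `-1/(1 + 10^(pKa - pH))`.
#' The result is strictly decreasing in pH.
#'
#' @param sequence Canonical peptide sequence.
#' @param pH pH value(s) in `[0, 14]`; vectorised.
#' @param pka A [load_pka_scale()] object.
#' @return Net charge in elementary-charge units, one value per `pH`.
#' @export
net_charge <- function(sequence, pH, pka = load_pka_scale()) {
  .check_sequence(sequence)
  if (any(pH < 0 | pH > 14)) {
    .ud_stop("pH out of range [0, 14]", "urodegradome_argument_error")
  }
  res <- .residues(sequence)
  n_basic <- c(Nterm = 1, K = sum(res == "K"), R = sum(res == "R"),
               H = sum(res == "H"))
  n_acidic <- c(Cterm = 1, D = sum(res == "D"), E = sum(res == "E"),
                C = sum(res == "C"), Y = sum(res == "Y"))
  vapply(pH, function(p) {
    pos <- sum(n_basic / (1 + 10^(p - pka$basic[names(n_basic)])))
    neg <- sum(n_acidic / (1 + 10^(pka$acidic[names(n_acidic)] - p)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Finds the pH in `[0, 14]` where [net_charge()] crosses zero. Because
#' net charge is strictly decreasing in pH, the root is unique; bisection
#' runs to `|charge| < tol` or `max_iter` halvings.
#'
#' @param sequence Canonical peptide sequence.
#' @param pka A [load_pka_scale()] object.
#' @param tol Charge tolerance (default `1e-6`).
#' @param max_iter Maximum bisection iterations (default 100).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, pka = load_pka_scale(),
                              tol = 1e-6, max_iter = 100L) {
  .check_sequence(sequence)
  lo <- 0; hi <- 14
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    q <- net_charge(sequence, mid, pka)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Peptide molecular weight
#'
#' Sum of residue masses plus one water mass. Average masses by default,
#' matching conventional peptidome reporting; monoisotopic by flag.
#'
#' @param sequence Canonical peptide sequence.
#' @param monoisotopic Use monoisotopic masses.
#' @param masses Residue mass table, default [load_mass_table()].
#' @return Mass in Daltons.
#' @export
peptide_mw <- function(sequence, monoisotopic = FALSE,
                       masses = load_mass_table(monoisotopic)) {
  .check_sequence(sequence)
  sum(masses[.residues(sequence)]) + .water_mass(monoisotopic)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean per-residue hydropathy index (Kyte-Doolittle by default); positive
#' values indicate hydrophobic peptides.
#'
#' @param sequence Canonical peptide sequence.
#' @param scale Hydropathy scale, default [load_hydropathy_scale()].
#' @return Dimensionless GRAVY score.
#' @export
gravy <- function(sequence, scale = load_hydropathy_scale()) {
  .check_sequence(sequence)
  mean(scale[.residues(sequence)])
}

#' Physicochemical descriptor panel for a set of peptides
#'
#' Computes, per sequence: residue count, molecular weight (Da),
#' isoelectric point (pH units), GRAVY, proline fraction, and (optionally)
#' an antimicrobial-activity probability via a pluggable predictor. The
#' antimicrobial predictor is a hook because the upstream tool is an
#' external web service; the default reports `NA`.
#'
#' @param sequences Character vector of canonical peptide sequences.
#' @param pka_scale Name of the pKa scale (see [load_pka_scale()]).
#' @param monoisotopic Use monoisotopic masses.
#' @param amp_predictor `NULL`, or a function mapping a character vector of
#'   sequences to probabilities in `[0, 1]`.
#' @return Data frame with one row per peptide and attribute `metadata`
#'   naming the scales used.
#' @export
descriptor_panel <- function(sequences, pka_scale = "emboss",
                             monoisotopic = FALSE, amp_predictor = NULL) {
  pka <- load_pka_scale(pka_scale)
  masses <- load_mass_table(monoisotopic)
  hydro <- load_hydropathy_scale()
  amp <- if (is.null(amp_predictor)) rep(NA_real_, length(sequences)) else {
    p <- amp_predictor(sequences)
    stopifnot(length(p) == length(sequences))
    p
  }
  out <- data.frame(
    sequence = sequences,
    length = nchar(sequences),
    mol_weight = vapply(sequences, peptide_mw, numeric(1),
                        monoisotopic = monoisotopic, masses = masses),
    isoelectric_point = vapply(sequences, isoelectric_point, numeric(1),
                               pka = pka),
    gravy = vapply(sequences, gravy, numeric(1), scale = hydro),
    proline_fraction = vapply(sequences, function(s) {
      .check_sequence(s); mean(.residues(s) == "P")
    }, numeric(1)),
    amp_probability = amp,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "metadata") <- list(
    pka_scale = pka$name,
    mass_convention = if (monoisotopic) "monoisotopic" else "average",
    hydropathy_scale = "kyte_doolittle",
    amp_predictor = !is.null(amp_predictor)
  )
  out
}

#' Descriptor distribution summaries per disease class
#'
#' Summarises the distribution of each descriptor per class (n, mean,
#' median, quartiles, and a binned density), for classes with at least
#' `min_peptides` unique peptides; smaller classes are excluded with a
#' notice. Typical input is the signature peptides of each class plus the
#' health reference set (see [signature_class_peptides()]).
#'
#' @param peptides Data frame with columns `class` and `sequence`; one row
#'   per unique peptide.
#' @param min_peptides Minimum unique peptides per class (default 20).
#' @param descriptors Descriptor columns to summarise.
#' @param n_bins Number of density bins per descriptor (default 20).
#' @param ... Passed to [descriptor_panel()].
#' @return A `class_distribution` list: `summary` (class x descriptor
#'   rows), `density` (binned densities in long format), `excluded`
#'   (classes below threshold), and the panel `metadata`.
#' @export
class_distributions <- function(peptides, min_peptides = 20,
                                descriptors = c("length", "mol_weight",
                                                "isoelectric_point", "gravy",
                                                "proline_fraction"),
                                n_bins = 20, ...) {
  stopifnot(all(c("class", "sequence") %in% names(peptides)))
  peptides <- unique(peptides[, c("class", "sequence")])
  counts <- table(peptides$class)
  excluded <- names(counts)[counts < min_peptides]
  if (length(excluded) > 0) {
    message("excluding class(es) below the ", min_peptides,
            "-peptide threshold: ", paste(excluded, collapse = ", "))
  }
  keep <- setdiff(names(counts), excluded)
  peptides <- peptides[peptides$class %in% keep, , drop = FALSE]
  if (nrow(peptides) == 0) {
    .ud_stop("no class meets the minimum peptide threshold",
             "urodegradome_empty_error")
  }
  panel <- descriptor_panel(peptides$sequence, ...)
  panel$class <- peptides$class
  summ <- list(); dens <- list()
  for (d in descriptors) {
    rng <- range(panel[[d]], finite = TRUE)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    mids <- (head(breaks, -1) + breaks[-1]) / 2
    for (cl in sort(keep)) {
      x <- panel[[d]][panel$class == cl]
      q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      summ[[length(summ) + 1]] <- data.frame(
        class = cl, descriptor = d, n = length(x), mean = mean(x),
        q1 = q[1], median = q[2], q3 = q[3], stringsAsFactors = FALSE)
      h <- hist(x, breaks = breaks, plot = FALSE, include.lowest = TRUE)
      dens[[length(dens) + 1]] <- data.frame(
        class = cl, descriptor = d, bin_mid = mids, density = h$density,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(summary = do.call(rbind, summ),
                 density = do.call(rbind, dens),
                 excluded = excluded,
                 metadata = attr(panel, "metadata")),
            class = "class_distribution")
}

#' Collect signature peptides per class, plus the health reference
#'
#' Helper assembling the input of [class_distributions()]: the degree-1
#' peptides of each disease class (from a [extract_signatures()] result and
#' its source table) together with all unique peptides of a health table.
#'
#' @param signatures A `signature_set`.
#' @param table The disease [association_table()] the signatures came from.
#' @param health Optional health [association_table()].
#' @return Data frame with columns `class`, `sequence`, `key`.
#' @export
signature_class_peptides <- function(signatures, table, health = NULL) {
  stopifnot(inherits(signatures, "signature_set"),
            inherits(table, "association_table"))
  sig <- signatures$peptides
  cls <- unname(table$condition_class[sig$condition])
  out <- unique(data.frame(class = cls, sequence = sig$sequence,
                           key = sig$peptide, stringsAsFactors = FALSE))
  if (!is.null(health)) {
    h <- health$records[!duplicated(health$records$key), , drop = FALSE]
    out <- rbind(out, data.frame(class = "health", sequence = h$sequence,
                                 key = h$key, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
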