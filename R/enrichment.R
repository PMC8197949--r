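# Fold-enrichment of predicted protease activity over the health reference
# library, with hypergeometric testing and Bonferroni correction.

#' Build the health reference library
#'
#' Tallies the total number of prediction events `N` and the per-protease
#' event counts `K` from a health-set [predict_degradome()] result.
#'
#' @param health_predictions A `prediction_set` from the health table
#'   (typically with `grouping = "all"`).
#' @return A `reference_library`: list with `N` and named numeric `K`.
#' @export
build_reference <- function(health_predictions) {
  stopifnot(inherits(health_predictions, "prediction_set"))
  ev <- health_predictions$events
  # One event per (peptide, terminus, protease), regardless of grouping.
  ev <- ev[!duplicated(paste(ev$key, ev$terminus, ev$protease_id, sep = "\r")), ,
           drop = FALSE]
  if (nrow(ev) == 0) {
    .ud_stop("health prediction set is empty", "urodegradome_empty_error")
  }
  K <- table(ev$protease_id)
  K <- setNames(as.numeric(K), names(K))
  K <- K[order(names(K))]
  structure(list(N = sum(K), K = K), class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat("Health reference library:", x$N, "prediction events,",
      length(x$K), "proteases\n")
  invisible(x)
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X` hypergeometric with population size `N`, `K`
#' successes in the population, and `n` draws. Vectorised; exact via
#' [stats::phyper()].
#'
#' @param k Observed successes in the draw.
#' @param K Successes in the population.
#' @param n Number of draws.
#' @param N Population size.
#' @return Probabilities in `[0, 1]`; `1` exactly when `k <= 0`, `0` when
#'   `k > min(n, K)`.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  args <- cbind(k = k, K = K, n = n, N = N)
  k <- args[, "k"]; K <- args[, "K"]; n <- args[, "n"]; N <- args[, "N"]
  if (any(k < 0 | K < 0 | n < 0 | k > n | n > N | K > N)) {
    .ud_stop("need 0 <= k <= n <= N and 0 <= K <= N",
             "urodegradome_argument_error")
  }
  unname(ifelse(k <= 0, 1, phyper(k - 1, K, N - K, n, lower.tail = FALSE)))
}

#' Enrichment of predicted protease activity over the health reference
#'
#' For each (group, protease) with disease events `k` out of `n` group
#' events, against reference counts `K` out of `N`: fold-enrichment
#' `(k/n)/(K/N)`, upper-tail hypergeometric p-value (population = the
#' reference library, draws = the group's events), and Bonferroni
#' adjustment over the `m` tests performed in this call (the pairs with
#' `K > 0`). Proteases predicted only in disease (`K = 0, k > 0`) are
#' flagged `disease_only`: their fold-enrichment is undefined and no test
#' is performed, but they are reported.
#'
#' @param disease_predictions A `prediction_set` for the disease table.
#' @param reference A [build_reference()] library.
#' @param alpha Significance level for the adjusted p-value (default 0.05).
#' @param correction Multiple-testing correction; only `"bonferroni"`.
#' @param rules Optional [specificity_rules()]; if given, any disease
#'   protease absent from it raises an error.
#' @return An `enrichment_results` data frame with columns `group,
#'   protease_id, k, n, K, N, fold_enrichment, p_raw, p_adj, significant,
#'   disease_only`, ordered by `(p_adj, -fold_enrichment, protease_id)`;
#'   attributes `alpha`, `m`, `correction`, `grouping`.
#' @export
enrich <- function(disease_predictions, reference, alpha = 0.05,
                   correction = c("bonferroni"), rules = NULL) {
  stopifnot(inherits(disease_predictions, "prediction_set"),
            inherits(reference, "reference_library"))
  correction <- match.arg(correction)
  if (alpha <= 0 || alpha >= 1) {
    .ud_stop("alpha must be in (0, 1)", "urodegradome_argument_error")
  }
  if (!is.null(rules)) {
    unknown <- setdiff(unique(disease_predictions$events$protease_id),
                       rules$protease_id)
    if (length(unknown) > 0) {
      .ud_stop(paste0("protease(s) in disease predictions absent from rule registry: ",
                      paste(unknown, collapse = ", ")),
               "urodegradome_rule_error")
    }
  }
  counts <- disease_predictions$counts
  totals <- disease_predictions$totals
  N <- reference$N
  groups <- names(totals)
  rows <- list()
  for (g in groups) {
    n <- totals[[g]]
    if (n > N) {
      .ud_stop(paste0("group '", g, "' has more events (", n,
                      ") than the reference library (", N,
                      "); the reference-population urn is undefined"),
               "urodegradome_argument_error")
    }
    sub <- counts[counts$group == g, , drop = FALSE]
    k_map <- setNames(sub$n_events, sub$protease_id)
    prot <- sort(union(names(k_map), names(reference$K)))
    k <- ifelse(prot %in% names(k_map), k_map[prot], 0)
    K <- ifelse(prot %in% names(reference$K), reference$K[prot], 0)
    keep <- k > 0 | K > 0
    rows[[g]] <- data.frame(
      group = g, protease_id = prot[keep], k = unname(k[keep]), n = n,
      K = unname(K[keep]), N = N, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$disease_only <- res$K == 0 & res$k > 0
  res$fold_enrichment <- ifelse(res$K > 0, (res$k / res$n) / (res$K / res$N), NA_real_)
  res$p_raw <- NA_real_
  testable <- res$K > 0
  res$p_raw[testable] <- hypergeom_upper_tail(res$k[testable], res$K[testable],
                                              res$n[testable], res$N[testable])
  m <- sum(testable)
  res$p_adj <- pmin(1, res$p_raw * m)
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  ord <- order(res$p_adj, -res$fold_enrichment, res$protease_id, na.last = TRUE)
  res <- res[ord, c("group", "protease_id", "k", "n", "K", "N",
                    "fold_enrichment", "p_raw", "p_adj", "significant",
                    "disease_only")]
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  attr(res, "m") <- m
  attr(res, "correction") <- correction
  attr(res, "grouping") <- disease_predictions$grouping
  class(res) <- c("enrichment_results", "data.frame")
  res
}

#' Fold-enrichment heatmap bins
#'
#' Labels fold-enrichment values with the standard display bins:
#' 0-1 (under-representation), 1-10, 10-20, 20-30, >30.
#'
#' @param fold Numeric fold-enrichment values (`NA` allowed).
#' @return Factor with the five bin labels.
#' @export
fold_bins <- function(fold) {
  cut(fold, breaks = c(-Inf, 1, 10, 20, 30, Inf),
      labels = c("0-1", "1-10", "10-20", "20-30", ">30"), right = TRUE)
}

#' Write enrichment results (long format with fold bins)
#'
#' Output mirrors the result columns plus a `fold_bin` column, preceded by
#' `#`-prefixed metadata lines recording alpha, m, the correction and the
#' grouping.
#'
#' @param x An `enrichment_results` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path) {
  stopifnot(inherits(x, "enrichment_results"))
  out <- as.data.frame(x)
  out$fold_bin <- as.character(fold_bins(out$fold_enrichment))
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# alpha=", attr(x, "alpha")),
    paste0("# m=", attr(x, "m")),
    paste0("# correction=", attr(x, "correction")),
    paste0("# grouping=", attr(x, "grouping"))
  ), con)
  suppressWarnings(
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  )
  invisible(path)
}

#' Binary significance matrix (condition x protease)
#'
#' Collapses enrichment results to the binary matrix consumed by the
#' minimal-signature search: entry `TRUE` iff the protease is significantly
#' enriched in the group.
#'
#' @param x An `enrichment_results` data frame.
#' @return An [enrichment_matrix()].
#' @export
significance_matrix <- function(x) {
  stopifnot(inherits(x, "enrichment_results"))
  groups <- sort(unique(x$group))
  prot <- sort(unique(x$protease_id))
  mat <- matrix(FALSE, nrow = length(groups), ncol = length(prot),
                dimnames = list(groups, prot))
  sig <- x[x$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    mat[cbind(match(sig$group, groups), match(sig$protease_id, prot))] <- TRUE
  }
  enrichment_matrix(mat)
}
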