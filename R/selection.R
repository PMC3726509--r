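#' Consensus selection from four stability rankings
#'
#' Combines the per-method rankings into an aggregate score (default: mean
#' rank across methods, ascending) and applies an intergroup veto: genes
#' whose absolute intergroup variation exceeds a configurable quantile of
#' the panel's intergroup variations are demoted below all unflagged genes,
#' whatever their stability ranks. This mirrors the practice of excluding an
#' otherwise-stable gene that separates sample subgroups (such a gene tracks
#' group composition, not loading). Ties in the aggregate score are broken
#' by the NormFinder value (the only method with an explicit intergroup
#' model), then by gene ID.
#'
#' @param reports list of [stability_report()]s covering the same gene set
#'   (typically the four methods).
#' @param intergroup optional named numeric vector of per-gene intergroup
#'   variation (e.g. the max |d_ig| from
#'   [normfinder_stability()]`$extras$intergroup`); `NULL` disables the
#'   veto.
#' @param n_select size of the selected set (default 5).
#' @param rule aggregation rule: `"mean_rank"` (default), `"median_rank"`,
#'   or `"borda"` (mean rank counted from the bottom, equivalent ordering,
#'   reported as a score where higher is better).
#' @param intergroup_quantile quantile of `|intergroup|` above which a gene
#'   is flagged (default 0.9).
#' @return List of class `ConsensusResult`: `table` (per-gene ranks, score,
#'   flag, final order), `selected`, `flagged`, `rule`.
#' @export
aggregate_rankings <- function(reports, intergroup = NULL, n_select = 5,
                               rule = c("mean_rank", "median_rank", "borda"),
                               intergroup_quantile = 0.9) {
  rule <- match.arg(rule)
  if (length(reports) < 1L) rs_validation_error("no reports given")
  genes <- sort(reports[[1L]]$ranking)
  for (r in reports) {
    if (!inherits(r, "StabilityReport"))
      rs_validation_error("reports must be StabilityReport objects")
    if (!setequal(r$ranking, genes))
      rs_validation_error("reports cover different gene sets")
  }
  if (n_select > length(genes))
    rs_validation_error("n_select exceeds the number of genes")

  rank_mat <- vapply(reports, function(r)
    stats::setNames(seq_along(r$ranking), r$ranking)[genes],
    numeric(length(genes)))
  colnames(rank_mat) <- vapply(reports, `[[`, character(1), "method")
  score <- switch(rule,
                  mean_rank = rowMeans(rank_mat),
                  median_rank = apply(rank_mat, 1L, stats::median),
                  borda = rowMeans(length(genes) - rank_mat))
  ascending <- rule != "borda"

  flagged <- rep(FALSE, length(genes))
  names(flagged) <- genes
  if (!is.null(intergroup)) {
    missing_ig <- setdiff(genes, names(intergroup))
    if (length(missing_ig) > 0L)
      rs_validation_error("intergroup variation missing for: %s",
                          paste(missing_ig, collapse = ", "))
    ig <- abs(intergroup[genes])
    cut <- stats::quantile(ig, intergroup_quantile, type = 7, names = FALSE)
    flagged <- ig > cut
  }

  nf <- Filter(function(r) r$method == "normfinder", reports)
  tiebreak <- if (length(nf) > 0L) nf[[1L]]$values[genes] else
    stats::setNames(rep(0, length(genes)), genes)
  key <- if (ascending) score else -score
  ord <- order(flagged, key, tiebreak, genes)

  tab <- data.frame(gene = genes, rank_mat, score = score,
                    intergroup_flag = flagged, check.names = FALSE)
  tab <- tab[ord, ]
  tab$final_rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, selected = tab$gene[seq_len(n_select)],
                 flagged = genes[flagged], rule = rule,
                 intergroup_quantile = intergroup_quantile),
            class = "ConsensusResult")
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf("ConsensusResult (%s): selected {%s}%s\n", x$rule,
              paste(x$selected, collapse = ", "),
              if (length(x$flagged) > 0L)
                sprintf("; intergroup-flagged: %s",
                        paste(x$flagged, collapse = ", ")) else ""))
  invisible(x)
}

#' Compare reference-gene sets against individual genes
#'
#' Appends one ephemeral quasi-gene per named set to the Ct table, evaluates
#' all four stability measures over the augmented panel, and reports each
#' set's values next to the best individual gene per method — the layout
#' used to show that a well-chosen set outperforms every single gene on the
#' relative measures (delta-Ct, geNorm, NormFinder), while the
#' interval-based Haller measure may still prefer an individual gene.
#' The input table is never modified.
#'
#' @param ct_tbl a [ct_table()].
#' @param sets named list of character vectors (gene sets, members present
#'   in the table).
#' @param alpha Haller confidence parameter.
#' @param use_groups pass group labels to NormFinder when present.
#' @return List of class `SetComparison`: `table` (rows: best individual
#'   gene, then one row per set; columns: the four measures), `best_genes`
#'   (which gene was best per method), `reports` (full augmented-panel
#'   reports).
#' @export
compare_sets <- function(ct_tbl, sets, alpha = 0.05, use_groups = TRUE) {
  if (length(sets) == 0L) rs_validation_error("no sets given")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    rs_validation_error("sets must be named")
  genes <- ct_genes(ct_tbl)
  aug <- ct_tbl
  for (nm in names(sets))
    aug <- append_quasi_gene(aug, sets[[nm]], name = nm)

  methods <- c("delta_ct", "genorm", "normfinder", "haller")
  reports <- lapply(methods, function(m)
    ct_stability(aug, method = m, alpha = alpha, use_groups = use_groups))
  names(reports) <- methods

  best_genes <- vapply(reports, function(r) {
    v <- r$values[genes]
    names(v)[order(v, names(v))][1L]
  }, character(1))
  best_vals <- vapply(methods, function(m)
    unname(reports[[m]]$values[best_genes[[m]]]), numeric(1))
  set_vals <- vapply(methods, function(m)
    unname(reports[[m]]$values[names(sets)]),
    numeric(length(sets)))
  set_vals <- matrix(set_vals, nrow = length(sets),
                     dimnames = list(names(sets), methods))

  tab <- rbind(best_gene = best_vals, set_vals)
  tab <- as.data.frame(tab)
  tab <- cbind(system = c(sprintf("best gene (%s)",
                                  paste(unique(best_genes), collapse = "/")),
                          names(sets)),
               tab)
  rownames(tab) <- NULL
  structure(list(table = tab, best_genes = best_genes, reports = reports),
            class = "SetComparison")
}

#' @export
print.SetComparison <- function(x, ...) {
  cat("SetComparison:\n")
  print(x$table, digits = 4)
  invisible(x)
}
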