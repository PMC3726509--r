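#' Percentile-ratio variability of one probeset
#'
#' The screening statistic is the ratio of the 95th to the 5th percentile of
#' log-scale expression across samples. It is methodologically close to an
#' interquartile range covering 90% of samples instead of 50%, and being a
#' quantile ratio it is insensitive to outliers. For a stable probeset whose
#' percentiles sit at `m(1-w)` and `m(1+w)` with small relative half-width
#' `w`, the ratio is `(1+w)/(1-w) = 1 + 2w + 2w^2/(1-w)`, i.e. about
#' `1 + 2w`, so ascending ratio order is ascending relative-spread order.
#' The ordering rationale presumes a positive log-expression scale, so a
#' non-positive 5th percentile is an error, not a fallback.
#'
#' Percentile convention: linear interpolation between order statistics
#' ([stats::quantile()] type 7), used consistently here and in the Haller
#' measure's 95th percentile.
#'
#' @param values log-scale expression values for one probeset (>= 2 finite
#'   values).
#' @return List with `p5`, `p95` and `ratio = p95/p5`.
#' @export
variability_ratio <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values) || any(!is.finite(values)))
    rs_validation_error("need >= 2 finite values")
  p <- stats::quantile(values, c(0.05, 0.95), type = 7, names = FALSE)
  if (p[1L] <= 0)
    rs_computation_error(
      "non-positive 5th percentile (%g); log expression must be positive",
      p[1L])
  list(p5 = p[1L], p95 = p[2L], ratio = p[2L] / p[1L])
}

#' Rank probesets by percentile-ratio variability
#'
#' Ascending order in the 95th/5th percentile ratio; ties broken
#' lexicographically by probeset ID so the ordering is deterministic.
#'
#' @param em an [expression_matrix()].
#' @return data.frame with columns `probeset`, `p5`, `p95`, `ratio`, `rank`,
#'   ordered most stable first.
#' @export
rank_probesets <- function(em) {
  if (!inherits(em, "ExpressionMatrix"))
    rs_validation_error("em must be an ExpressionMatrix")
  ids <- rownames(em$values)
  stats_list <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    stats_list[[i]] <- tryCatch(
      variability_ratio(em$values[i, ]),
      refstab_error = function(e)
        rs_computation_error("probeset %s: %s", ids[i], conditionMessage(e)))
  }
  df <- data.frame(probeset = ids,
                   p5 = vapply(stats_list, `[[`, numeric(1), "p5"),
                   p95 = vapply(stats_list, `[[`, numeric(1), "p95"),
                   ratio = vapply(stats_list, `[[`, numeric(1), "ratio"))
  df <- df[order(df$ratio, df$probeset), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Intersect top-K stable lists across datasets
#'
#' Takes the `k` most stable probesets from each per-dataset ranking, maps
#' them to gene symbols, and intersects the symbol sets across all datasets.
#' A symbol counts as "in the top-k" of a dataset if any of its probesets
#' is (symbol-level union). Probesets without a symbol are dropped with a
#' reported count. Pairwise and leave-one-out intersections are reported as
#' well, since sub-intersections show which datasets drive the final list.
#'
#' @param rankings list of rankings: data.frames from [rank_probesets()] or
#'   character vectors of probesets ordered most stable first. Names are
#'   used as dataset labels.
#' @param k top-list size (positive, at most the shortest ranking).
#' @param annotation named character vector probeset -> symbol (see
#'   [load_annotation()]), or `NULL` to intersect at probeset level.
#' @return List of class `ScreenResult`: `symbols` (sorted intersection
#'   across all datasets), `top_k` (per-dataset symbol sets), `pairwise` and
#'   `leave_one_out` intersections, `n_unmapped` dropped probeset count,
#'   `k`, `level`.
#' @export
top_k_intersection <- function(rankings, k, annotation = NULL) {
  if (!is.list(rankings) || length(rankings) < 1L)
    rs_validation_error("rankings must be a non-empty list")
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k != round(k))
    rs_validation_error("k must be a positive integer")
  ids <- lapply(rankings, function(r) {
    if (is.data.frame(r)) as.character(r$probeset) else as.character(r)
  })
  if (any(vapply(ids, length, integer(1)) < k))
    rs_validation_error("k = %d exceeds the length of a ranking", k)
  if (is.null(names(ids)) || any(!nzchar(names(ids))))
    names(ids) <- paste0("dataset", seq_along(ids))

  n_unmapped <- 0L
  to_symbols <- function(top) {
    if (is.null(annotation)) return(sort(unique(top)))
    sym <- annotation[top]
    n_unmapped <<- n_unmapped + sum(is.na(sym))
    sort(unique(sym[!is.na(sym)]))
  }
  top_k <- lapply(ids, function(v) to_symbols(v[seq_len(k)]))
  if (n_unmapped > 0L)
    message(n_unmapped, " top-k probeset(s) without a gene symbol dropped")

  nm <- names(top_k)
  pairwise <- list()
  if (length(top_k) >= 2L) {
    for (i in seq_len(length(top_k) - 1L)) for (j in (i + 1L):length(top_k))
      pairwise[[paste(nm[i], nm[j], sep = "&")]] <-
        intersect(top_k[[i]], top_k[[j]])
  }
  leave_one_out <- list()
  if (length(top_k) >= 3L) {
    for (i in seq_along(top_k))
      leave_one_out[[paste0("without_", nm[i])]] <-
        sort(Reduce(intersect, top_k[-i]))
  }
  structure(list(symbols = sort(Reduce(intersect, top_k)),
                 top_k = top_k, pairwise = pairwise,
                 leave_one_out = leave_one_out,
                 n_unmapped = n_unmapped, k = k,
                 level = if (is.null(annotation)) "probeset" else "symbol"),
            class = "ScreenResult")
}

#' @export
print.ScreenResult <- function(x, ...) {
  cat(sprintf("ScreenResult: %d datasets, k = %d, %d %s(s) in common\n",
              length(x$top_k), x$k, length(x$symbols), x$level))
  invisible(x)
}
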