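# The four stability measures. Conventions fixed across the module:
#  - sample SD (n-1 denominator) everywhere;
#  - log base 2 for expression ratios (any base gives the same ranking);
#  - lower value = more stable; reports rank ascending, ties by gene ID.

pair_sd_means <- function(x) {
  # x: genes x samples matrix. For each gene j, mean over partners k != j of
  # the sample SD across samples of x[j, ] - x[k, ].
  g <- nrow(x)
  if (g < 2L) rs_validation_error("need >= 2 genes")
  if (ncol(x) < 2L) rs_validation_error("need >= 2 samples")
  sds <- matrix(0, g, g)
  for (j in seq_len(g - 1L)) for (k in (j + 1L):g) {
    sds[j, k] <- sds[k, j] <- stats::sd(x[j, ] - x[k, ])
  }
  stats::setNames(rowSums(sds) / (g - 1L), rownames(x))
}

#' Comparative delta-Ct stability
#'
#' For every ordered gene pair (j, k) the per-sample Ct difference
#' `dCt_jk(s) = Ct_j(s) - Ct_k(s)` is formed (replicates collapsed to the
#' per-pair mean Ct first); the stability value of gene j is the mean, over
#' partners k != j, of the sample standard deviation of `dCt_jk` across
#' samples. A gene that moves in lockstep with the panel gets a low value.
#' The measure is invariant to a per-sample additive Ct shift (a global
#' loading difference), which cancels in every pairwise difference.
#'
#' @param ct_tbl a [ct_table()] with >= 2 genes and >= 2 samples.
#' @return A [stability_report()] with `method = "delta_ct"` (Ct-scale SD).
#' @export
delta_ct_stability <- function(ct_tbl) {
  m <- ct_mean_matrix(ct_tbl)
  stability_report("delta_ct", pair_sd_means(m))
}

#' geNorm M-values
#'
#' The M-value of gene j is the mean, over all other genes k, of the
#' standard deviation across samples of the log2 expression ratio
#' `log2(A_j / A_k)`. When every gene has efficiency 2 and a common
#' threshold, `log2(A_j/A_k) = Ct_k - Ct_j`, so M coincides exactly with the
#' comparative delta-Ct value.
#'
#' @param expr positive expression matrix, genes x samples (e.g. from
#'   [ct_expression_matrix()]).
#' @return A [stability_report()] with `method = "genorm"` (SD of log2
#'   ratios).
#' @export
genorm_m <- function(expr) {
  expr <- as.matrix(expr)
  if (anyNA(expr) || any(!is.finite(expr)) || any(expr <= 0))
    rs_computation_error("geNorm needs strictly positive expression values")
  if (is.null(rownames(expr)))
    rs_validation_error("expression matrix needs gene rownames")
  stability_report("genorm", pair_sd_means(log2(expr)))
}

#' geNorm ranking by stepwise exclusion
#'
#' Iteratively removes the gene with the highest M-value and recomputes M on
#' the remaining panel until two genes remain; those two cannot be told
#' apart by the measure (each is the other's only partner) and share rank 1.
#' The returned ranking lists the final pair first (tied, ordered by gene
#' ID), then the excluded genes in reverse exclusion order.
#'
#' @param expr positive expression matrix, genes x samples (>= 2 genes;
#'   with exactly 2 there is nothing to exclude).
#' @return List of class `GenormRanking`: `ranking` (best first),
#'   `exclusion_order` (worst first), `final_pair`, `rank` (named numeric,
#'   final pair tied at 1), `m_trace` (M-values at each exclusion step).
#' @export
genorm_ranking <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2L) rs_validation_error("need >= 2 genes")
  current <- expr
  exclusion <- character(0)
  m_trace <- list()
  while (nrow(current) > 2L) {
    m <- genorm_m(current)$values
    worst <- names(m)[order(-m, names(m))][1L]
    m_trace[[length(m_trace) + 1L]] <- m
    exclusion <- c(exclusion, worst)
    current <- current[setdiff(rownames(current), worst), , drop = FALSE]
  }
  final_pair <- sort(rownames(current))
  ranking <- c(final_pair, rev(exclusion))
  rank <- stats::setNames(seq_along(ranking), ranking)
  rank[final_pair] <- 1
  structure(list(ranking = ranking, exclusion_order = exclusion,
                 final_pair = final_pair, rank = rank, m_trace = m_trace),
            class = "GenormRanking")
}

#' @export
print.GenormRanking <- function(x, ...) {
  cat(sprintf("GenormRanking: best pair {%s}; exclusion order: %s\n",
              paste(x$final_pair, collapse = ", "),
              paste(rev(x$exclusion_order), collapse = " < ")))
  invisible(x)
}

# One centering pass of the variance-decomposition fit on a genes x samples
# block: subtract the w-weighted over-genes mean from every sample (the
# sample-effect estimate), then per-gene means and raw residual variances.
.nf_center_fit <- function(x, w) {
  n <- ncol(x)
  z <- sweep(x, 2L, as.vector(w %*% x))
  m <- rowMeans(z)
  u <- rowSums((z - m)^2) / (n - 1L)
  list(m = m, u = u, n = n)
}

# Inverse-variance weights from residual variances. The model is
# heteroscedastic across genes, so efficient estimation of the per-sample
# effect must downweight the noisiest genes or their scatter contaminates
# every residual. Exactly one reweighting pass is used: first-pass
# (unweighted) variances all contain the common reference term, which keeps
# the weights bounded — open-ended iteration would let one quiet gene
# absorb the sample effect into itself and zero out its own residuals.
.nf_weights <- function(u) {
  if (max(u) <= 0) return(rep(1 / length(u), length(u)))  # noise-free block
  w <- 1 / pmax(u, max(u) * 1e-8)
  w / sum(w)
}

# Under w-weighted centering the raw residual variance u_i has expectation
# sigma_i^2 (1 - 2 w_i) + sum_k w_k^2 sigma_k^2; invert that for reporting
# (u itself orders the genes).
.nf_correct <- function(u, w) {
  pmax((u - sum(w^2 * u)) / pmax(1 - 2 * w, 0.25), 0)
}

#' NormFinder-style variance-decomposition stability
#'
#' Fits the model `x_igj = alpha_i + b_gj + d_ig + eps_igj` to log-scale
#' expression (gene effect, per-sample effect, gene-by-group deviation
#' summing to zero over genes, noise with gene/group-specific variance).
#' Per-sample effects are removed by subtracting an inverse-variance
#' weighted mean over genes from every sample, in two passes (>= 3 genes
#' required): the model is heteroscedastic across genes, and efficient
#' estimation of the sample effect must downweight the noisiest genes or
#' their scatter contaminates every residual.
#'
#' Without groups the stability value is the residual SD of a gene after
#' removing per-sample effects. (The weighted centering mixes a small
#' common share of panel variance into every residual; this additive term
#' does not affect the ordering, and a bias-corrected per-gene variance is
#' reported in `extras$sigma2`.)
#'
#' With groups, the raw deviation of gene i in group g is `d_ig`, the
#' gene-by-group mean after removing sample and gene effects. Its true
#' between-group spread `gamma^2` is estimated by marginal maximum
#' likelihood under `d_ig ~ N(0, gamma^2 + Var(d_ig))` — a proper
#' empirical-Bayes fit that precision-weights genes, so the noisy
#' deviations of high-variance genes cannot swamp the estimate — and each
#' deviation is shrunk by `gamma^2 / (gamma^2 + Var(d_ig))`. The stability
#' value is the mean over groups of `|d_ig (shrunk)| + SE(group mean)`,
#' combining systematic intergroup deviation with within-group variation;
#' a candidate reference gene must score low on both (a gene with low
#' intragroup scatter but a real group offset tracks group composition,
#' not sample loading, and must not be used for normalization).
#'
#' @param expr log-scale expression matrix, genes x samples (>= 3 genes).
#'   Use `log2([ct_expression_matrix()])` for Ct data.
#' @param groups optional character vector of group labels, one per column
#'   (or named by sample); each group needs >= 2 samples.
#' @return A [stability_report()] with `method = "normfinder"`; with groups,
#'   `extras$intergroup` holds the shrunken deviations `d_ig` (genes x
#'   groups), `extras$sigma2` the bias-corrected within-group variances and
#'   `extras$gamma2` the fitted between-group spread.
#' @export
normfinder_stability <- function(expr, groups = NULL) {
  x <- as.matrix(expr)
  if (nrow(x) < 3L)
    rs_validation_error("need >= 3 genes for the variance decomposition")
  if (anyNA(x) || any(!is.finite(x)))
    rs_computation_error("non-finite log expression values")
  if (is.null(rownames(x)))
    rs_validation_error("expression matrix needs gene rownames")

  if (is.null(groups)) {
    pass1 <- .nf_center_fit(x, rep(1 / nrow(x), nrow(x)))
    w <- .nf_weights(pass1$u)
    f <- .nf_center_fit(x, w)
    return(stability_report("normfinder", sqrt(f$u),
                            extras = list(sigma2 = .nf_correct(f$u, w))))
  }

  if (!is.null(names(groups)) && !is.null(colnames(x))) {
    missing_s <- setdiff(colnames(x), names(groups))
    if (length(missing_s) > 0L)
      rs_validation_error("no group label for sample(s): %s",
                          paste(missing_s, collapse = ", "))
    groups <- groups[colnames(x)]
  }
  if (length(groups) != ncol(x))
    rs_validation_error("one group label per sample required")
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  n_g <- table(factor(groups, lv))
  if (any(n_g < 2L))
    rs_validation_error("every group needs >= 2 samples")

  blocks <- lapply(lv, function(g) x[, groups == g, drop = FALSE])
  names(blocks) <- lv
  ng <- nrow(x)
  pass1 <- lapply(blocks, .nf_center_fit, w = rep(1 / ng, ng))
  df_g <- vapply(pass1, function(f) f$n - 1, numeric(1))
  u_pool <- Reduce(`+`, Map(function(f, d) f$u * d, pass1, df_g)) / sum(df_g)
  # one common weight vector for every group: the weighted combination of
  # gene baselines subtracted with the sample effect must be identical
  # across groups, or it masquerades as a shared group deviation
  w <- .nf_weights(u_pool)
  fits <- lapply(blocks, .nf_center_fit, w = w)
  m_mat <- vapply(fits, `[[`, numeric(nrow(x)), "m")          # genes x groups
  u_mat <- vapply(fits, `[[`, numeric(nrow(x)), "u")
  n_vec <- vapply(fits, `[[`, numeric(1), "n")
  sigma2 <- apply(u_mat, 2L, .nf_correct, w = w)

  # alpha_i estimated as the sample-size weighted mean of the group means;
  # d_ig is the remaining gene-by-group deviation
  w_g <- n_vec / sum(n_vec)
  alpha <- as.vector(m_mat %*% w_g)
  d_hat <- m_mat - alpha
  var_d <- sweep(u_mat, 2L, n_vec, `/`)
  # marginal ML for the true between-group spread under
  # d_hat ~ N(0, gamma^2 + var_d); precision-weights genes so noisy
  # deviations of high-variance genes cannot swamp the estimate
  nll <- function(g2) sum(log(g2 + var_d) + d_hat^2 / (g2 + var_d))
  upper <- max(d_hat^2)
  gamma2 <- if (upper <= 0) 0 else {
    opt <- stats::optimize(nll, c(0, upper), tol = 1e-12)
    if (nll(0) <= opt$objective) 0 else opt$minimum
  }
  shrink <- gamma2 / (gamma2 + var_d)
  shrink[!is.finite(shrink)] <- 0
  d_tilde <- d_hat * shrink
  rho <- abs(d_tilde) + sqrt(var_d)
  values <- stats::setNames(rowMeans(rho), rownames(x))
  dimnames(d_tilde) <- list(rownames(x), lv)
  dimnames(sigma2) <- list(rownames(x), lv)
  stability_report("normfinder", values,
                   extras = list(intergroup = d_tilde, sigma2 = sigma2,
                                 gamma2 = gamma2,
                                 group_sizes = stats::setNames(as.integer(n_g),
                                                               lv)))
}

#' Haller equivalence-test fold-change stability
#'
#' For each gene and each unordered sample pair (k, l) a two-sided
#' `1 - alpha` Welch confidence interval is built for the mean Ct difference
#' from the replicate values, then mapped to the expression-fold scale
#' through the gene's own efficiency: a Ct-difference bound `c` becomes the
#' fold `E^-c` (since `A = I/E^Ct`). The pair's contribution is the larger
#' fold magnitude `max(delta, 1/delta)` over both interval endpoints — the
#' maximum fold change that cannot be excluded at level alpha — and the
#' gene's stability value is the 95th percentile (linear-interpolation
#' convention, as in the microarray screen) of all pair contributions.
#' Values are always >= 1, and because interval endpoints rather than point
#' estimates enter, the measure is deliberately pessimistic: it reports the
#' poor case, not the average one.
#'
#' When both samples of a pair have zero replicate variance the interval is
#' degenerate and the point fold change `E^|D|` is used.
#'
#' @param ct_tbl a [ct_table()] with >= 2 replicate Ct values per
#'   gene/sample pair (replicates are used as independent observations; with
#'   `nested = TRUE` the run means are used instead, respecting the
#'   run-by-replicate nesting at the cost of degrees of freedom).
#' @param alpha confidence parameter in (0, 1), default 0.05.
#' @param nested collapse PCR replicates to run means before the interval.
#' @param pooled_endpoints if `TRUE`, pool both endpoint magnitudes of every
#'   pair into one percentile computation instead of taking per-pair maxima.
#' @return A [stability_report()] with `method = "haller"` (fold change
#'   >= 1); `extras$pairs` holds, per gene, the sample pairs with their
#'   Ct-difference estimates, fold-change interval endpoints and
#'   contributions.
#' @export
haller_stability <- function(ct_tbl, alpha = 0.05, nested = FALSE,
                             pooled_endpoints = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    rs_validation_error("alpha must be in (0, 1)")
  genes <- ct_genes(ct_tbl)
  samples <- ct_samples(ct_tbl)
  if (length(samples) < 2L) rs_validation_error("need >= 2 samples")
  d <- ct_tbl$data
  if (nested) {
    d <- stats::aggregate(ct ~ gene + sample + run, data = d, FUN = mean)
    d$rep <- 1L
  }

  values <- numeric(length(genes))
  names(values) <- genes
  pairs <- list()
  for (g in genes) {
    dg <- d[d$gene == g, ]
    sp <- split(dg$ct, factor(dg$sample, samples))
    n <- vapply(sp, length, integer(1))
    if (any(n < 2L))
      rs_validation_error(
        "gene %s: >= 2 replicate Ct values per sample required", g)
    mu <- vapply(sp, mean, numeric(1))
    v <- vapply(sp, stats::var, numeric(1))
    E <- ct_tbl$efficiencies[[g]]
    S <- length(samples)
    idx <- which(upper.tri(matrix(0, S, S)), arr.ind = TRUE)
    k <- idx[, 1L]; l <- idx[, 2L]
    D <- mu[k] - mu[l]
    se2 <- v[k] / n[k] + v[l] / n[l]
    half <- numeric(length(D))
    pos <- se2 > 0
    if (any(pos)) {
      df <- se2[pos]^2 / ((v[k][pos] / n[k][pos])^2 / (n[k][pos] - 1L) +
                          (v[l][pos] / n[l][pos])^2 / (n[l][pos] - 1L))
      half[pos] <- stats::qt(1 - alpha / 2, df) * sqrt(se2[pos])
    }
    # endpoints of the Ct-difference CI are D -/+ half; on the fold scale
    # (fold = E^-c) the worst magnitude over both endpoints is E^(|D| + half)
    if (pooled_endpoints) {
      contrib <- c(E^abs(D - half), E^abs(D + half))
    } else {
      contrib <- E^(abs(D) + half)
    }
    values[g] <- stats::quantile(contrib, 0.95, type = 7, names = FALSE)
    pairs[[g]] <- data.frame(sample_k = samples[k], sample_l = samples[l],
                             d_ct = unname(D), half_width = half,
                             fold_low = E^(-(unname(D) + half)),
                             fold_high = E^(-(unname(D) - half)),
                             contribution = if (pooled_endpoints)
                               E^(abs(unname(D)) + half) else contrib)
  }
  stability_report("haller", pmax(values, 1),
                   extras = list(alpha = alpha, nested = nested,
                                 pooled_endpoints = pooled_endpoints,
                                 pairs = pairs))
}

#' Run a stability measure on a CtTable
#'
#' Dispatcher used by the command-line driver: builds the expression input a
#' measure needs from the Ct table and runs it.
#'
#' @param ct_tbl a [ct_table()].
#' @param method one of `"delta_ct"`, `"genorm"`, `"normfinder"`,
#'   `"haller"`.
#' @param alpha Haller confidence parameter.
#' @param use_groups pass the table's group labels to NormFinder when
#'   present.
#' @return A [stability_report()].
#' @export
ct_stability <- function(ct_tbl,
                         method = c("delta_ct", "genorm", "normfinder",
                                    "haller"),
                         alpha = 0.05, use_groups = TRUE) {
  method <- match.arg(method)
  switch(method,
         delta_ct = delta_ct_stability(ct_tbl),
         genorm = genorm_m(ct_expression_matrix(ct_tbl)),
         normfinder = normfinder_stability(
           log2(ct_expression_matrix(ct_tbl)),
           groups = if (use_groups) ct_tbl$groups else NULL),
         haller = haller_stability(ct_tbl, alpha = alpha))
}
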