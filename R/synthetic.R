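# Seeded generators for every input format the pipeline consumes. All
# randomness flows through derive_seed() so biological and technical noise
# live on independent streams: zeroing one never changes the draws of the
# other, and regeneration with the same seed is bit-for-bit identical.

derive_seed <- function(seed, stream) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    rs_validation_error("seed must be a single finite number")
  as.integer((abs(seed) %% 97651) * 21727 + stream * 7919) %% 2147483647L
}

#' Generate a replicated Ct table with known ground truth
#'
#' Simulates the data structure of a typical reference-gene validation
#' study: a panel of candidate genes measured by RT-qPCR on tumor biopsies
#' in two unbalanced receptor-status subgroups, with a run-by-replicate
#' grid per gene/sample pair. The model, on the log2 expression scale, is
#'
#'     x_is = L_s + d_{i, g(s)} + beta_is,   beta_is ~ N(0, sigma_i^2)
#'
#' with `L_s` a shared per-sample loading shift, `d` optional per-gene group
#' offsets and `sigma_i` gene-specific biological variability tiers. The Ct
#' value converts through each gene's own efficiency,
#' `Ct_is = b_i - x_is * ln(2)/ln(E_i)`, so genes with different
#' efficiencies carry different Ct-scale variance for equal expression
#' variance — the coupling the stability measures must disentangle. Each
#' replicate adds run-level noise (shared within a run) plus PCR-level
#' noise.
#'
#' Defaults mirror a realistic study design: 18 genes x 39 samples with a
#' 25/14 group split, 3 runs x 3 PCR replicates, efficiencies evenly spaced
#' over 1.76-2.10, biological tiers {0.1, 0.5, 1.5} log2 units assigned
#' cyclically, loading SD 0.5 log2, run/PCR noise 0.15/0.10 Ct.
#'
#' @param n_genes,n_samples panel dimensions.
#' @param group_split integer vector of group sizes summing to `n_samples`,
#'   or `NULL` for ungrouped data.
#' @param sigma_tiers biological SD tiers (log2 units), recycled over genes
#'   in order; `truth$sigma` records the per-gene assignment.
#' @param efficiency_range range over which per-gene efficiencies are evenly
#'   spaced.
#' @param loading_sd SD of the shared per-sample loading shift (log2 units).
#' @param run_sd,pcr_sd technical noise SDs (Ct units): run-level noise is
#'   drawn once per gene/sample/run, PCR-level noise once per well.
#' @param n_runs,n_reps replicate grid dimensions.
#' @param group_offsets optional named numeric vector of per-gene group
#'   offsets (log2 units): the named genes are shifted by +offset/2 in the
#'   first group and -offset/2 in the second.
#' @param baseline_ct_range range for per-gene baseline Ct values.
#' @param ct_range realistic Ct range; generated values outside it trigger a
#'   warning (never silent clipping).
#' @param seed required integer seed.
#' @return List with `table` (a [ct_table()]) and `truth` (per-gene sigma,
#'   efficiencies, baselines, loading shifts, group offsets, noise SDs,
#'   seed).
#' @export
generate_ct_dataset <- function(n_genes = 18, n_samples = 39,
                                group_split = c(25, 14),
                                sigma_tiers = c(0.1, 0.5, 1.5),
                                efficiency_range = c(1.76, 2.10),
                                loading_sd = 0.5,
                                run_sd = 0.15, pcr_sd = 0.10,
                                n_runs = 3, n_reps = 3,
                                group_offsets = NULL,
                                baseline_ct_range = c(20, 28),
                                ct_range = c(15, 35),
                                seed) {
  if (missing(seed)) rs_validation_error("seed is required")
  if (any(sigma_tiers < 0) || loading_sd < 0 || run_sd < 0 || pcr_sd < 0)
    rs_validation_error("SD parameters must be non-negative")
  if (n_genes < 2L || n_samples < 2L || n_runs < 1L || n_reps < 1L)
    rs_validation_error("invalid dimensions")
  if (!is.null(group_split) && sum(group_split) != n_samples)
    rs_validation_error("group_split must sum to n_samples")

  genes <- sprintf("G%02d", seq_len(n_genes))
  samples <- sprintf("S%02d", seq_len(n_samples))
  sigma <- stats::setNames(rep_len(sigma_tiers, n_genes), genes)
  eff <- stats::setNames(
    if (n_genes == 1L) mean(efficiency_range) else
      seq(efficiency_range[1L], efficiency_range[2L], length.out = n_genes),
    genes)

  groups <- NULL
  if (!is.null(group_split)) {
    labels <- paste0("grp", seq_along(group_split))
    groups <- stats::setNames(rep(labels, group_split), samples)
  }
  d_mat <- matrix(0, n_genes, if (is.null(group_split)) 1L
                  else length(group_split),
                  dimnames = list(genes, unique(groups)))
  if (!is.null(group_offsets)) {
    if (is.null(group_split) || length(group_split) < 2L)
      rs_validation_error("group_offsets need >= 2 groups")
    bad <- setdiff(names(group_offsets), genes)
    if (length(bad) > 0L)
      rs_validation_error("group_offsets name unknown gene(s): %s",
                          paste(bad, collapse = ", "))
    d_mat[names(group_offsets), 1L] <- group_offsets / 2
    d_mat[names(group_offsets), 2L] <- -group_offsets / 2
  }

  # biological stream: structure (baselines, loading) + biological noise
  set.seed(derive_seed(seed, 1L))
  baseline <- stats::setNames(
    stats::runif(n_genes, baseline_ct_range[1L], baseline_ct_range[2L]),
    genes)
  loading <- stats::setNames(stats::rnorm(n_samples, 0, loading_sd), samples)
  beta <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
                 dimnames = list(genes, samples)) * sigma
  g_of_s <- if (is.null(groups)) rep(1L, n_samples) else
    match(groups, colnames(d_mat))
  x <- sweep(beta, 2L, loading, `+`) + d_mat[, g_of_s, drop = FALSE]
  ct_true <- baseline - x * (log(2) / log(eff))

  # technical stream: run- and well-level noise
  set.seed(derive_seed(seed, 2L))
  run_noise <- array(stats::rnorm(n_genes * n_samples * n_runs, 0, run_sd),
                     dim = c(n_genes, n_samples, n_runs))
  pcr_noise <- array(stats::rnorm(n_genes * n_samples * n_runs * n_reps,
                                  0, pcr_sd),
                     dim = c(n_genes, n_samples, n_runs, n_reps))

  grid <- expand.grid(gene = seq_len(n_genes), sample = seq_len(n_samples),
                      run = seq_len(n_runs), rep = seq_len(n_reps))
  ct <- ct_true[cbind(grid$gene, grid$sample)] +
    run_noise[cbind(grid$gene, grid$sample, grid$run)] +
    pcr_noise[cbind(grid$gene, grid$sample, grid$run, grid$rep)]
  if (any(ct < ct_range[1L] | ct > ct_range[2L]))
    warning(sprintf("%d Ct value(s) outside the realistic range [%g, %g]",
                    sum(ct < ct_range[1L] | ct > ct_range[2L]),
                    ct_range[1L], ct_range[2L]))

  tbl <- ct_table(data.frame(gene = genes[grid$gene],
                             sample = samples[grid$sample],
                             run = grid$run, rep = grid$rep, ct = ct),
                  efficiencies = eff, groups = groups, threshold = 1)
  truth <- list(baseline_ct = baseline, sigma = sigma, efficiencies = eff,
                loading = loading, group_offsets = d_mat, groups = groups,
                run_sd = run_sd, pcr_sd = pcr_sd, loading_sd = loading_sd,
                seed = seed)
  list(table = tbl, truth = truth)
}

#' Generate a dilution series with known efficiency
#'
#' `Ct(d) = ct_at_first + log_{E_true}(d / d_first) + noise`: each extra
#' `E_true`-fold dilution costs one cycle, so a noise-free series inverts
#' exactly to `E_true` under [efficiency_from_dilution()].
#'
#' @param E_true true amplification factor (> 1).
#' @param dilutions dilution factors (default: seven steps, 1:25 to
#'   1:5000).
#' @param ct_at_first mean Ct at the least dilute point.
#' @param noise_sd Gaussian Ct noise SD.
#' @param replicates replicate reactions per dilution.
#' @param seed integer seed (only the noise is random).
#' @return A [dilution_series()].
#' @export
generate_dilution_series <- function(E_true = 2,
                                     dilutions = c(25, 100, 250, 500,
                                                   1000, 2500, 5000),
                                     ct_at_first = 18, noise_sd = 0,
                                     replicates = 3, seed = 1) {
  if (E_true <= 1) rs_validation_error("E_true must be > 1")
  if (noise_sd < 0) rs_validation_error("noise_sd must be non-negative")
  dilutions <- sort(unique(dilutions))
  set.seed(derive_seed(seed, 3L))
  grid <- expand.grid(dilution = dilutions, replicate = seq_len(replicates))
  mu <- ct_at_first + log(grid$dilution / dilutions[1L]) / log(E_true)
  grid$ct <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
  dilution_series(dilutions, grid)
}

#' Generate a collection of microarray matrices with a planted stable core
#'
#' Emulates the input of the cross-dataset screening stage: several
#' log2-scale expression matrices sharing a probeset universe, in which a
#' planted subset of probesets has low spread in every dataset while the
#' rest get dataset-specific spreads. With `k` at least the planted-set
#' size (and sufficient separation), [top_k_intersection()] recovers the
#' planted set exactly.
#'
#' @param n_datasets number of matrices.
#' @param n_probesets probeset universe size.
#' @param n_samples_list per-dataset sample counts (recycled).
#' @param n_stable_shared size of the planted shared-stable core.
#' @param stable_sd per-sample SD of planted probesets (log2 units).
#' @param unstable_sd_range per-dataset SD range of the remaining probesets.
#' @param seed integer seed.
#' @return List with `matrices` (list of [expression_matrix()]),
#'   `annotation` (one-to-one probeset -> symbol map) and `truth` (planted
#'   probesets and symbols).
#' @export
generate_microarray_collection <- function(n_datasets = 4,
                                           n_probesets = 500,
                                           n_samples_list = c(80, 60, 50, 40),
                                           n_stable_shared = 25,
                                           stable_sd = 0.02,
                                           unstable_sd_range = c(0.2, 1.0),
                                           seed) {
  if (missing(seed)) rs_validation_error("seed is required")
  if (n_stable_shared > n_probesets)
    rs_validation_error("n_stable_shared exceeds n_probesets")
  probesets <- sprintf("PS%05d", seq_len(n_probesets))
  symbols <- sprintf("GENE%05d", seq_len(n_probesets))
  annotation <- stats::setNames(symbols, probesets)
  n_samples_list <- rep_len(n_samples_list, n_datasets)

  set.seed(derive_seed(seed, 4L))
  planted <- sort(sample(probesets, n_stable_shared))
  baseline <- stats::setNames(stats::runif(n_probesets, 6, 10), probesets)

  matrices <- vector("list", n_datasets)
  for (ds in seq_len(n_datasets)) {
    set.seed(derive_seed(seed, 100L + ds))
    sds <- stats::runif(n_probesets, unstable_sd_range[1L],
                        unstable_sd_range[2L])
    sds[probesets %in% planted] <- stable_sd
    n_s <- n_samples_list[ds]
    vals <- baseline + matrix(stats::rnorm(n_probesets * n_s),
                              n_probesets, n_s) * sds
    colnames(vals) <- sprintf("D%d_S%03d", ds, seq_len(n_s))
    rownames(vals) <- probesets
    matrices[[ds]] <- expression_matrix(vals, log_base = 2)
  }
  names(matrices) <- sprintf("dataset%d", seq_len(n_datasets))
  list(matrices = matrices, annotation = annotation,
       truth = list(planted_probesets = planted,
                    planted_symbols = sort(unname(annotation[planted])),
                    seed = seed))
}
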