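# In-code fixtures: everything is built programmatically, no files shipped.

# CtTable from a genes x samples matrix of Ct values, one replicate per pair
# unless `reps` asks for more (replicate values then repeat the matrix value).
make_ct_table <- function(ct_mat, efficiencies = NULL, groups = NULL,
                          threshold = 1, runs = 1, reps = 1) {
  genes <- rownames(ct_mat)
  samples <- colnames(ct_mat)
  if (is.null(efficiencies))
    efficiencies <- stats::setNames(rep(2, length(genes)), genes)
  grid <- expand.grid(gene = genes, sample = samples,
                      run = seq_len(runs), rep = seq_len(reps),
                      stringsAsFactors = FALSE)
  grid$ct <- ct_mat[cbind(grid$gene, grid$sample)]
  ct_table(grid, efficiencies = efficiencies, groups = groups,
           threshold = threshold)
}

# The worked three-gene example: two genes tracking each other perfectly
# plus one flat gene, so the pairwise-SD arithmetic is checkable by hand.
hand_example_table <- function() {
  m <- rbind(G1 = c(20, 21, 22), G2 = c(25, 26, 27), G3 = c(30, 30, 30))
  colnames(m) <- c("s1", "s2", "s3")
  make_ct_table(m)
}

# Random replicated CtTable with all efficiencies 2 (for the exact
# delta-Ct / geNorm equivalence) or random efficiencies otherwise.
random_ct_table <- function(seed, n_genes = 5, n_samples = 7,
                            runs = 2, reps = 2, equal_e = TRUE) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  samples <- sprintf("s%02d", seq_len(n_samples))
  grid <- expand.grid(gene = genes, sample = samples,
                      run = seq_len(runs), rep = seq_len(reps),
                      stringsAsFactors = FALSE)
  grid$ct <- stats::runif(nrow(grid), 18, 30)
  eff <- if (equal_e) stats::setNames(rep(2, n_genes), genes) else
    stats::setNames(stats::runif(n_genes, 1.76, 2.10), genes)
  ct_table(grid, efficiencies = eff)
}
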