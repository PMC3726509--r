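test_that("delta-Ct hand-worked three-gene example is exact", {
  rep <- delta_ct_stability(hand_example_table())
  expect_equal(rep$values, c(G1 = 0.5, G2 = 0.5, G3 = 1.0),
               tolerance = 1e-12)
  expect_identical(rep$ranking, c("G1", "G2", "G3"))
})

test_that("co-moving genes score zero and loading shifts cancel", {
  m <- rbind(A = c(20, 23, 21, 26), B = c(25, 28, 26, 31),
             C = c(18, 21, 19, 24))
  colnames(m) <- paste0("s", 1:4)
  tbl <- make_ct_table(m)
  expect_equal(unname(delta_ct_stability(tbl)$values), rep(0, 3))

  base <- random_ct_table(21)
  shift <- stats::setNames(stats::runif(7, -3, 3),
                           sprintf("s%02d", 1:7))
  shifted <- base
  shifted$data$ct <- base$data$ct + shift[base$data$sample]
  expect_equal(delta_ct_stability(shifted)$values,
               delta_ct_stability(base)$values, tolerance = 1e-10)
  expect_equal(genorm_m(ct_expression_matrix(shifted))$values,
               genorm_m(ct_expression_matrix(base))$values,
               tolerance = 1e-10)
})

test_that("geNorm equals delta-Ct exactly when all E = 2 and I common", {
  for (seed in 1:10) {
    tbl <- random_ct_table(seed, equal_e = TRUE)
    d <- delta_ct_stability(tbl)$values
    g <- genorm_m(ct_expression_matrix(tbl))$values
    expect_equal(g, d, tolerance = 1e-10)
  }
})

test_that("geNorm matches a naive double-loop reference implementation", {
  tbl <- random_ct_table(31, n_genes = 6, equal_e = FALSE)
  a <- ct_expression_matrix(tbl)
  # brute-force oracle straight from the definition
  oracle <- sapply(rownames(a), function(j) {
    others <- setdiff(rownames(a), j)
    mean(sapply(others, function(k) stats::sd(log2(a[j, ] / a[k, ]))))
  })
  expect_equal(genorm_m(a)$values, oracle, tolerance = 1e-10)

  prop <- rbind(A = c(1, 2, 3, 4) * 1e-6, B = c(2, 4, 6, 8) * 1e-6)
  colnames(prop) <- paste0("s", 1:4)
  expect_equal(unname(genorm_m(prop)$values), c(0, 0), tolerance = 1e-12)
})

test_that("geNorm stepwise exclusion removes the noisiest gene first", {
  a <- ct_expression_matrix(hand_example_table())
  gr <- genorm_ranking(a)
  expect_identical(gr$exclusion_order, "G3")
  expect_identical(gr$final_pair, c("G1", "G2"))
  expect_equal(unname(gr$rank[c("G1", "G2")]), c(1, 1))

  # strictly nested noise levels: exclusion order matches noise order
  set.seed(13)
  sds <- c(0.05, 0.15, 0.4, 1.0, 2.5)
  x <- 2^(12 + matrix(stats::rnorm(5 * 80), 5, 80) * sds)
  rownames(x) <- sprintf("n%d", 1:5)
  colnames(x) <- sprintf("s%02d", 1:80)
  gr2 <- genorm_ranking(x)
  expect_identical(gr2$exclusion_order, c("n5", "n4", "n3"))

  two <- genorm_ranking(x[1:2, ])
  expect_length(two$exclusion_order, 0L)
  expect_equal(unname(two$rank), c(1, 1))
})

test_that("NormFinder recovers variability tiers and is shift invariant", {
  sim <- suppressWarnings(generate_ct_dataset(seed = 11, group_split = NULL))
  x <- log2(ct_expression_matrix(sim$table))
  nf <- normfinder_stability(x)
  expect_gte(cor(nf$values, sim$truth$sigma[names(nf$values)],
                 method = "spearman"), 0.9)
  # a per-sample shift is a sample effect: removed by the fit
  nf2 <- normfinder_stability(sweep(x, 2L, stats::rnorm(ncol(x), 0, 2), `+`))
  expect_equal(nf2$values, nf$values, tolerance = 1e-9)
})

test_that("NormFinder intergroup deviations vanish for exchangeable genes", {
  sim <- suppressWarnings(generate_ct_dataset(seed = 77, sigma_tiers = 0.4))
  nf <- normfinder_stability(log2(ct_expression_matrix(sim$table)),
                             groups = sim$table$groups)
  expect_lt(max(abs(nf$extras$intergroup)), 0.06)
  expect_lt(max(nf$values) / min(nf$values), 2)
})

test_that("NormFinder flags a planted group offset as intergroup variation", {
  sim <- suppressWarnings(
    generate_ct_dataset(seed = 204, group_offsets = c(G04 = 1.0)))
  nf <- normfinder_stability(log2(ct_expression_matrix(sim$table)),
                             groups = sim$table$groups)
  ig <- apply(abs(nf$extras$intergroup), 1L, max)
  expect_identical(names(which.max(ig)), "G04")
  expect_gt(ig[["G04"]], 2 * max(ig[names(ig) != "G04"]))
})

test_that("NormFinder validates its inputs", {
  x <- matrix(stats::rnorm(4), 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_error(normfinder_stability(x), ">= 3",
               class = "refstab_validation_error")
  x6 <- matrix(stats::rnorm(18), 3, 6,
               dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:6)))
  expect_error(normfinder_stability(x6, groups = c(rep("g1", 5), "g2")),
               ">= 2 samples", class = "refstab_validation_error")
})

test_that("Haller intervals collapse to fold 1 without replicate variation", {
  m <- rbind(A = c(20, 20, 20), B = c(24, 24, 24))
  colnames(m) <- paste0("s", 1:3)
  tbl <- make_ct_table(m, runs = 3, reps = 3)  # identical replicate sets
  h <- haller_stability(tbl)
  expect_equal(unname(h$values), c(1, 1))
})

test_that("Haller pair intervals match the Welch interval from t.test", {
  set.seed(19)
  cts1 <- 20 + stats::rnorm(9, 0, 0.3)
  cts2 <- 21 + stats::rnorm(9, 0, 0.5)
  grid <- expand.grid(gene = "A", sample = c("s1", "s2"), run = 1:3,
                      rep = 1:3, stringsAsFactors = FALSE)
  grid$ct <- NA_real_
  grid$ct[grid$sample == "s1"] <- cts1
  grid$ct[grid$sample == "s2"] <- cts2
  e <- 1.94
  tbl <- ct_table(rbind(grid,
                        data.frame(gene = "B", sample = rep(c("s1", "s2"),
                                                            each = 9),
                                   run = rep(1:3, each = 3), rep = 1:3,
                                   ct = 25 + stats::rnorm(18, 0, 0.2))),
                  efficiencies = c(A = e, B = 1.9))
  h <- haller_stability(tbl, alpha = 0.05)
  p <- h$extras$pairs[["A"]]
  welch <- stats::t.test(cts1, cts2, conf.level = 0.95)
  expect_equal(p$d_ct, unname(welch$estimate[1] - welch$estimate[2]),
               tolerance = 1e-10)
  expect_equal(p$fold_low, e^(-welch$conf.int[2]), tolerance = 1e-10)
  expect_equal(p$fold_high, e^(-welch$conf.int[1]), tolerance = 1e-10)
  expect_equal(p$contribution,
               max(e^abs(welch$conf.int)), tolerance = 1e-10)
  # M is the type-7 95th percentile of pair contributions
  expect_equal(unname(h$values["A"]), p$contribution)
})

test_that("Haller is pessimistic relative to point-estimate fold changes", {
  sim <- suppressWarnings(generate_ct_dataset(seed = 42))
  h <- haller_stability(sim$table)
  m <- ct_mean_matrix(sim$table)
  s <- ncol(m)
  for (g in rownames(m)[c(1, 7, 18)]) {
    d_abs <- abs(outer(m[g, ], m[g, ], `-`))[upper.tri(diag(s))]
    point <- stats::quantile(sim$table$efficiencies[[g]]^d_abs, 0.95,
                             type = 7, names = FALSE)
    expect_gte(h$values[[g]], point)
  }
})

test_that("Haller nested mode uses run means and needs replicates", {
  sim <- suppressWarnings(generate_ct_dataset(seed = 6, n_genes = 3,
                                              n_samples = 4,
                                              group_split = NULL))
  h_flat <- haller_stability(sim$table)
  h_nest <- haller_stability(sim$table, nested = TRUE)
  expect_true(all(h_nest$values >= 1))
  expect_false(identical(h_flat$values, h_nest$values))

  m1 <- rbind(A = c(20, 21), B = c(22, 23))
  colnames(m1) <- c("s1", "s2")
  single <- make_ct_table(m1)
  expect_error(haller_stability(single), ">= 2 replicate",
               class = "refstab_validation_error")
  expect_error(haller_stability(sim$table, alpha = 0),
               class = "refstab_validation_error")
})

test_that("stability measures are invariant to gene and sample relabeling", {
  tbl <- random_ct_table(55, equal_e = FALSE)
  perm <- tbl
  map_g <- stats::setNames(c("q", "w", "e", "r", "t"), ct_genes(tbl))
  map_s <- stats::setNames(sprintf("z%02d", 7:1), ct_samples(tbl))
  perm$data$gene <- unname(map_g[perm$data$gene])
  perm$data$sample <- unname(map_s[perm$data$sample])
  names(perm$efficiencies) <- unname(map_g[names(perm$efficiencies)])
  perm <- ct_table(perm$data, perm$efficiencies, threshold = perm$threshold)
  for (method in c("delta_ct", "genorm", "haller")) {
    v1 <- ct_stability(tbl, method)$values
    v2 <- ct_stability(perm, method)$values
    expect_equal(unname(v2[map_g[names(v1)]]), unname(v1),
                 tolerance = 1e-10)
  }
})
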