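test_that("a minimal well-formed Ct CSV loads with all entries", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,sample,run,rep,ct",
               "A,s1,1,1,20.5", "A,s2,1,1,21.0",
               "B,s1,1,1,25.0", "B,s2,1,1,26.5"), path)
  tbl <- load_ct_table(path, efficiencies = c(A = 2, B = 1.9))
  expect_s3_class(tbl, "CtTable")
  expect_equal(nrow(tbl$data), 4L)
  expect_equal(ct_genes(tbl), c("A", "B"))
  expect_false(tbl$ragged)
})

test_that("malformed Ct inputs are rejected, never repaired", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,sample,run,rep,ct",
               "A,s1,1,1,20.5", "A,s2,1,1,NA", "B,s1,1,1,25.0",
               "B,s2,1,1,26.0"), path)
  expect_error(load_ct_table(path, efficiencies = c(A = 2, B = 2)),
               "row 2", class = "refstab_parse_error")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,sample,ct", "A,s1,20"), path2)
  expect_error(load_ct_table(path2, efficiencies = c(A = 2)),
               "missing required column", class = "refstab_parse_error")

  df <- data.frame(gene = c("A", "B"), sample = "s1", run = 1L, rep = 1L,
                   ct = c(20, 25))
  expect_error(ct_table(df, efficiencies = c(A = 2, B = 1.0)),
               "> 1", class = "refstab_validation_error")
  expect_error(ct_table(transform(df, ct = c(-1, 25)),
                        efficiencies = c(A = 2, B = 2)),
               "positive", class = "refstab_validation_error")
  expect_error(ct_table(df, efficiencies = c(A = 2, B = 2),
                        groups = c(s2 = "x")),
               "no group label", class = "refstab_validation_error")
  expect_error(ct_table(rbind(df, df), efficiencies = c(A = 2, B = 2)),
               "duplicate", class = "refstab_validation_error")
})

test_that("ragged replicate grids are flagged, not imputed", {
  grid <- expand.grid(gene = c("A", "B"), sample = c("s1", "s2"),
                      run = 1:2, rep = 1L, stringsAsFactors = FALSE)
  grid$ct <- 20 + seq_len(nrow(grid))
  full <- ct_table(grid, efficiencies = c(A = 2, B = 2))
  expect_false(full$ragged)
  ragged <- ct_table(grid[-1L, ], efficiencies = c(A = 2, B = 2))
  expect_true(ragged$ragged)
})

test_that("Ct tables round-trip through write and load", {
  sim <- suppressWarnings(generate_ct_dataset(seed = 9, n_genes = 4,
                                              n_samples = 6,
                                              group_split = c(4, 2)))
  path <- withr::local_tempfile(fileext = ".csv")
  eff_path <- withr::local_tempfile(fileext = ".csv")
  grp_path <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(sim$table, path, efficiencies_path = eff_path,
                 groups_path = grp_path)
  back <- load_ct_table(path, efficiencies = eff_path, groups = grp_path,
                        threshold = sim$table$threshold)
  expect_equal(back$data$ct, sim$table$data$ct, tolerance = 1e-12)
  expect_identical(back$data$gene, sim$table$data$gene)
  expect_identical(back$data$sample, sim$table$data$sample)
  expect_equal(back$efficiencies, sim$table$efficiencies, tolerance = 1e-12)
  expect_identical(back$groups, sim$table$groups)
  expect_identical(back$ragged, sim$table$ragged)
})

test_that("expression matrices load from plain TSV and series-matrix dialect", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ID\tS1\tS2", "p1\t7.1\t7.2", "p2\t8.0\t8.1",
               "p3\t6.5\t6.4"), path)
  em <- load_expression_matrix(path)
  expect_s3_class(em, "ExpressionMatrix")
  expect_equal(dim(em$values), c(3L, 2L))
  expect_equal(em$log_base, 2)
  expect_equal(em$values["p2", "S2"], 8.1)

  gm <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("!Series_title\t\"fake\"", "!Series_platform_id\tGPL96",
               "!series_matrix_table_begin",
               "\"ID_REF\"\t\"GSM1\"\t\"GSM2\"",
               "\"p1\"\t7.1\t7.2", "\"p2\"\t8.0\t8.1",
               "!series_matrix_table_end"), gm)
  em2 <- load_expression_matrix(gm)
  expect_equal(rownames(em2$values), c("p1", "p2"))
  expect_equal(em2$values["p1", 1L], 7.1)
})

test_that("duplicate probesets and empty matrices are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ID\tS1\tS2", "p1\t7.1\t7.2", "p1\t8.0\t8.1"), path)
  expect_error(load_expression_matrix(path), "duplicate",
               class = "refstab_validation_error")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("ID\tS1", empty)
  expect_error(load_expression_matrix(empty),
               class = "refstab_validation_error")
})

test_that("stability reports write sorted, tie-stable, and round-trip", {
  rep3 <- stability_report("genorm",
                           c(zeta = 0.25, alpha = 0.75, mid = 0.25))
  # ties broken by gene ID: zeta and mid share M, mid ranks first
  expect_identical(rep3$ranking, c("mid", "zeta", "alpha"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stability_report(rep3, path)
  lines <- readLines(path)
  expect_match(lines[1L], "^gene\tmethod\tM\trank$")
  expect_identical(length(lines), 4L)

  vals <- c(a = 1 / 3, b = sqrt(2) / 10, c = 0.1234567890123)
  repx <- stability_report("delta_ct", vals)
  write_stability_report(repx, path)
  back <- read_stability_report(path)
  expect_equal(back$values[names(vals)], vals, tolerance = 1e-12)
  expect_identical(back$method, "delta_ct")
  expect_identical(back$ranking, repx$ranking)
})

test_that("stability report validation enforces measure ranges", {
  expect_error(stability_report("haller", c(a = 0.5, b = 2)),
               ">= 1", class = "refstab_validation_error")
  expect_error(stability_report("delta_ct", c(a = -0.5, b = 1)),
               class = "refstab_validation_error")
  expect_error(stability_report("delta_ct", c(a = 1, b = 2),
                                ranking = c("a", "x")),
               "permutation", class = "refstab_validation_error")
})

test_that("dilution series validate shape and direction", {
  ct <- expand.grid(dilution = c(25, 100, 250), replicate = 1:2)
  ct$ct <- 18 + log2(ct$dilution / 25)
  ds <- dilution_series(c(25, 100, 250), ct)
  expect_s3_class(ds, "DilutionSeries")
  expect_error(dilution_series(c(25, 100), ct[ct$dilution != 250, ]),
               ">= 3", class = "refstab_validation_error")
  ct_rev <- transform(ct, ct = rev(ct))
  expect_warning(dilution_series(c(25, 100, 250), ct_rev), "decreases")
})

test_that("annotation tables load with unmapped probesets flagged", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probeset\tsymbol", "p1\tGENE1", "p2\t", "p3\tGENE2"), path)
  ann <- load_annotation(path)
  expect_identical(ann[["p1"]], "GENE1")
  expect_true(is.na(ann[["p2"]]))
})
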