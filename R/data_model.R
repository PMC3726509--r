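#' Replicated Ct table
#'
#' Container for replicated RT-qPCR threshold-cycle (Ct) measurements.
#' Measurements are stored in long format with two replicate indices: `run`
#' (the repeat of a whole qPCR run) and `rep` (the PCR replicate within a
#' run), because typical designs measure each gene/sample combination on a
#' dense run-by-replicate grid (e.g. 3 runs x 3 PCR replicates = 9 Ct
#' values). Each gene carries its own amplification efficiency `E` (the
#' per-cycle amplification factor, 2 = perfect doubling), and the table
#' carries a single fluorescence threshold `I`: under the exponential qPCR
#' model the expression level behind a measurement is `A = I / E^Ct`. `I`
#' cancels in every ratio-based stability measure, so its default of 1 is
#' harmless; it is kept explicit so the model stays exact.
#'
#' @param data data.frame with columns `gene`, `sample`, `run`, `rep`, `ct`
#'   (Ct in cycles, positive).
#' @param efficiencies named numeric vector, one per-cycle amplification
#'   factor per gene; all must exceed 1 (values above 2.2 draw a warning --
#'   a perfect PCR doubles, so E > 2.2 indicates a calibration problem).
#' @param groups optional named character vector mapping every sample to a
#'   group label (e.g. ER status); if given it must cover each sample exactly
#'   once.
#' @param threshold fluorescence threshold `I` (single positive scalar,
#'   arbitrary units).
#'
#' @return An object of class `CtTable`: a list with elements `data`
#'   (validated long-format data.frame), `efficiencies`, `groups`,
#'   `threshold` and `ragged` (TRUE when the (run, rep) grid is not identical
#'   across gene/sample combinations; raggedness is surfaced, never imputed).
#' @export
ct_table <- function(data, efficiencies, groups = NULL, threshold = 1) {
  required <- c("gene", "sample", "run", "rep", "ct")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L)
    rs_parse_error("Ct data is missing required column(s): %s",
                   paste(missing_cols, collapse = ", "))
  data <- as.data.frame(data)[required]
  data$gene <- as.character(data$gene)
  data$sample <- as.character(data$sample)
  if (!is.numeric(data$ct) || anyNA(data$ct) || any(!is.finite(data$ct)))
    rs_parse_error("all Ct values must be finite numbers")
  if (any(data$ct <= 0))
    rs_validation_error("all Ct values must be positive (cycles)")

  genes <- sort(unique(data$gene))
  samples <- sort(unique(data$sample))

  if (is.null(names(efficiencies)) || anyNA(names(efficiencies)))
    rs_validation_error("efficiencies must be a named numeric vector")
  missing_eff <- setdiff(genes, names(efficiencies))
  if (length(missing_eff) > 0L)
    rs_validation_error("no efficiency given for gene(s): %s",
                        paste(missing_eff, collapse = ", "))
  efficiencies <- efficiencies[genes]
  if (any(!is.finite(efficiencies)) || any(efficiencies <= 1))
    rs_validation_error("all efficiencies must be finite and > 1")
  if (any(efficiencies > 2.2))
    warning("efficiency above 2.2 for: ",
            paste(genes[efficiencies > 2.2], collapse = ", "),
            " (a perfect PCR doubles per cycle)")

  if (!is.null(groups)) {
    groups <- vapply(groups, as.character, character(1))
    missing_grp <- setdiff(samples, names(groups))
    if (length(missing_grp) > 0L)
      rs_validation_error("no group label for sample(s): %s",
                          paste(missing_grp, collapse = ", "))
    groups <- groups[samples]
  }

  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    rs_validation_error("threshold I must be a single positive scalar")

  # every (gene, sample) pair must have >= 1 Ct; a dense identical replicate
  # grid across pairs is the normal case, anything else is flagged ragged
  key <- paste(data$gene, data$sample, sep = "\r")
  all_pairs <- as.vector(outer(genes, samples, paste, sep = "\r"))
  absent <- setdiff(all_pairs, unique(key))
  if (length(absent) > 0L)
    rs_validation_error("%d gene/sample pair(s) have no Ct value",
                        length(absent))
  slot <- paste(data$run, data$rep, sep = "\r")
  if (anyDuplicated(paste(key, slot, sep = "\r")))
    rs_validation_error("duplicate (gene, sample, run, rep) entries")
  grids <- split(slot, key)
  ref <- sort(grids[[1L]])
  ragged <- !all(vapply(grids, function(g) identical(sort(g), ref),
                        logical(1)))

  structure(list(data = data, efficiencies = efficiencies, groups = groups,
                 threshold = threshold, ragged = ragged),
            class = "CtTable")
}

#' @export
print.CtTable <- function(x, ...) {
  cat(sprintf("CtTable: %d genes x %d samples, %d Ct values%s%s\n",
              length(ct_genes(x)), length(ct_samples(x)), nrow(x$data),
              if (x$ragged) " (ragged replicates)" else "",
              if (!is.null(x$groups))
                sprintf(", %d groups", length(unique(x$groups))) else ""))
  invisible(x)
}

#' Genes and samples of a CtTable
#' @param x a `CtTable`.
#' @return Character vector of gene (resp. sample) identifiers, sorted.
#' @export
ct_genes <- function(x) sort(unique(x$data$gene))

#' @rdname ct_genes
#' @export
ct_samples <- function(x) sort(unique(x$data$sample))

#' Read a replicated Ct table from CSV
#'
#' Expects a long-format CSV with header columns `gene,sample,run,rep,ct`.
#' Efficiencies come from a sidecar CSV (`gene,efficiency`) or a named
#' vector; group labels optionally from a sidecar CSV (`sample,group`).
#' Lines starting with `#` are treated as comments.
#'
#' @param path path to the Ct CSV.
#' @param efficiencies named numeric vector, or path to a `gene,efficiency`
#'   CSV.
#' @param groups optional named character vector, or path to a
#'   `sample,group` CSV.
#' @param threshold fluorescence threshold `I`.
#' @return A validated [ct_table()].
#' @export
load_ct_table <- function(path, efficiencies, groups = NULL, threshold = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = "character")
  required <- c("gene", "sample", "run", "rep", "ct")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    rs_parse_error("%s: missing required column(s): %s", path,
                   paste(missing_cols, collapse = ", "))
  ct_num <- suppressWarnings(as.numeric(df$ct))
  bad <- which(is.na(ct_num))
  if (length(bad) > 0L)
    rs_parse_error("%s: non-numeric Ct value '%s' in data row %d",
                   path, df$ct[bad[1L]], bad[1L])
  df$ct <- ct_num
  df$run <- suppressWarnings(as.integer(df$run))
  df$rep <- suppressWarnings(as.integer(df$rep))
  if (anyNA(df$run) || anyNA(df$rep))
    rs_parse_error("%s: non-integer run/rep replicate index", path)

  if (is.character(efficiencies) && length(efficiencies) == 1L) {
    ef <- utils::read.csv(efficiencies, stringsAsFactors = FALSE,
                          comment.char = "#")
    if (!all(c("gene", "efficiency") %in% names(ef)))
      rs_parse_error("%s: expected columns gene,efficiency", efficiencies)
    efficiencies <- stats::setNames(as.numeric(ef$efficiency),
                                    as.character(ef$gene))
  }
  if (is.character(groups) && length(groups) == 1L) {
    gf <- utils::read.csv(groups, stringsAsFactors = FALSE,
                          comment.char = "#")
    if (!all(c("sample", "group") %in% names(gf)))
      rs_parse_error("%s: expected columns sample,group", groups)
    groups <- stats::setNames(as.character(gf$group),
                              as.character(gf$sample))
  }
  ct_table(df, efficiencies = efficiencies, groups = groups,
           threshold = threshold)
}

#' Write a CtTable (plus sidecars) to CSV
#'
#' @param x a `CtTable`.
#' @param path output path for the long-format Ct CSV.
#' @param efficiencies_path,groups_path sidecar paths; defaults derive from
#'   `path` by inserting `_efficiencies` / `_groups` before the extension.
#' @param header optional character vector written as leading `#` comment
#'   lines (e.g. provenance from the command-line driver).
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path,
                           efficiencies_path = sidecar_path(path, "efficiencies"),
                           groups_path = sidecar_path(path, "groups"),
                           header = NULL) {
  write_with_header(x$data, path, header, sep = ",")
  eff <- data.frame(gene = names(x$efficiencies),
                    efficiency = fmt_num(unname(x$efficiencies)))
  write_with_header(eff, efficiencies_path, header, sep = ",")
  if (!is.null(x$groups)) {
    grp <- data.frame(sample = names(x$groups), group = unname(x$groups))
    write_with_header(grp, groups_path, header, sep = ",")
  }
  invisible(path)
}

sidecar_path <- function(path, tag) {
  sub("(\\.[A-Za-z0-9]+)$", sprintf("_%s\\1", tag), path)
}

# floats are serialized with 15 significant digits so write/read round trips
# are faithful well past the 12 digits the report format promises
fmt_num <- function(x) formatC(x, digits = 15, format = "g")

write_with_header <- function(df, path, header = NULL, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header) && length(header) > 0L)
    writeLines(paste0("# ", header), con)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Log-scale expression matrix
#'
#' @param values numeric matrix, probesets in rows (rownames required),
#'   samples in columns; log-scale expression with no missing values.
#' @param log_base base of the log transform the values are on (default 2,
#'   the RMA convention). Stored explicitly: the percentile-ratio
#'   variability statistic is not invariant to base changes.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, log_base = 2) {
  values <- as.matrix(values)
  if (nrow(values) == 0L || ncol(values) == 0L)
    rs_validation_error("expression matrix is empty")
  if (is.null(rownames(values)))
    rs_validation_error("expression matrix needs probeset rownames")
  if (anyDuplicated(rownames(values)))
    rs_validation_error("duplicate probeset IDs: %s",
                        paste(unique(rownames(values)[duplicated(rownames(values))]),
                              collapse = ", "))
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values)))
    rs_validation_error("expression matrix contains missing/non-finite values")
  if (!is.numeric(log_base) || length(log_base) != 1L || log_base <= 1)
    rs_validation_error("log_base must be a single number > 1")
  structure(list(values = values, log_base = log_base),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probesets x %d samples (log%g scale)\n",
              nrow(x$values), ncol(x$values), x$log_base))
  invisible(x)
}

#' Read a log-scale expression matrix
#'
#' Accepts a plain TSV (first column probeset ID, remaining columns samples)
#' or the GEO series-matrix dialect: leading `!` metadata lines are skipped
#' and values are read from the block delimited by
#' `!series_matrix_table_begin` / `!series_matrix_table_end`; quoted IDs are
#' unquoted.
#'
#' @param path input file.
#' @param log_base declared base of the log transform (default 2).
#' @return An [expression_matrix()].
#' @export
load_expression_matrix <- function(path, log_base = 2) {
  lines <- readLines(path)
  if (any(startsWith(lines, "!"))) {
    beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
    end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
    if (length(beg) == 1L && length(end) == 1L && end > beg + 1L) {
      lines <- lines[(beg + 1L):(end - 1L)]
    } else {
      lines <- lines[!startsWith(lines, "!")]
    }
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    rs_validation_error("%s: no data rows", path)
  df <- utils::read.delim(text = lines, stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "\"")
  if (ncol(df) < 2L)
    rs_validation_error("%s: expected probeset ID column plus sample columns",
                        path)
  ids <- gsub('^"|"$', "", as.character(df[[1L]]))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals))
    rs_parse_error("%s: non-numeric expression values", path)
  rownames(vals) <- ids
  expression_matrix(vals, log_base = log_base)
}

#' Read a probeset-to-gene-symbol annotation table
#'
#' TSV with columns `probeset` and `symbol`. Mapping may be many-to-one
#' (several probesets per symbol). Probesets with an empty/`NA` symbol are
#' kept but flagged unmapped; downstream symbol-level operations drop them
#' with a reported count.
#'
#' @param path TSV path.
#' @return Named character vector probeset -> symbol; unmapped probesets
#'   carry `NA`.
#' @export
load_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("probeset", "symbol") %in% names(df)))
    rs_parse_error("%s: expected columns probeset,symbol", path)
  sym <- as.character(df$symbol)
  sym[!nzchar(trimws(sym)) | is.na(sym)] <- NA_character_
  stats::setNames(sym, as.character(df$probeset))
}

#' Stability report
#'
#' One stability measure evaluated on a gene panel. `values` are on the
#' measure's own scale: Ct-scale SD for `delta_ct`, SD of log2 expression
#' ratios for `genorm`, log2-expression variation for `normfinder`, and a
#' fold change (>= 1) for `haller`. Lower is always more stable. The ranking
#' is ascending in the value with ties broken by gene ID, except when a
#' method supplies its own ranking (geNorm stepwise exclusion).
#'
#' @param method one of `"delta_ct"`, `"genorm"`, `"normfinder"`, `"haller"`.
#' @param values named numeric vector of per-gene stability values.
#' @param ranking optional explicit gene ranking (permutation of
#'   `names(values)`); default orders by value then gene ID.
#' @param extras method-specific list (e.g. NormFinder intergroup
#'   variations).
#' @return An object of class `StabilityReport`.
#' @export
stability_report <- function(method, values,
                             ranking = NULL, extras = list()) {
  method <- match.arg(method,
                      c("delta_ct", "genorm", "normfinder", "haller"))
  if (is.null(names(values)) || anyNA(names(values)))
    rs_validation_error("stability values must be named by gene")
  if (anyNA(values) || any(!is.finite(values)))
    rs_validation_error("non-finite stability values")
  lo <- if (method == "haller") 1 else 0
  if (any(values < lo - 1e-12))
    rs_validation_error("%s stability values must be >= %g", method, lo)
  values <- pmax(values, lo)
  if (is.null(ranking)) {
    ranking <- names(values)[order(values, names(values))]
  } else if (!setequal(ranking, names(values)) ||
             length(ranking) != length(values)) {
    rs_validation_error("ranking must be a permutation of the gene set")
  }
  structure(list(method = method, values = values, ranking = ranking,
                 extras = extras),
            class = "StabilityReport")
}

#' @export
print.StabilityReport <- function(x, ...) {
  cat(sprintf("StabilityReport [%s]: %d genes; most stable: %s (%.4g)\n",
              x$method, length(x$values), x$ranking[1L],
              x$values[x$ranking[1L]]))
  invisible(x)
}

#' Write / read a stability report
#'
#' TSV with columns `gene, method, M, rank`, sorted by rank then gene ID so
#' output is bit-stable; values carry 15 significant digits.
#'
#' @param report a `StabilityReport`.
#' @param path output TSV path.
#' @param header optional `#` comment lines.
#' @return `path` invisibly (writer); a `StabilityReport` (reader).
#' @export
write_stability_report <- function(report, path, header = NULL) {
  genes <- report$ranking
  df <- data.frame(gene = genes, method = report$method,
                   M = unname(report$values[genes]),
                   rank = seq_along(genes))
  df <- df[order(df$rank, df$gene), ]
  write_with_header(df, path, header, sep = "\t")
  invisible(path)
}

#' @rdname write_stability_report
#' @export
read_stability_report <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("gene", "method", "M", "rank") %in% names(df)))
    rs_parse_error("%s: expected columns gene,method,M,rank", path)
  stability_report(unique(df$method),
                   stats::setNames(df$M, df$gene),
                   ranking = df$gene[order(df$rank)])
}

#' Dilution series for efficiency calibration
#'
#' @param dilution_factors positive dilution factors (e.g. 25, 100, ...,
#'   5000 for 1:25 ... 1:5000); at least 3 distinct values.
#' @param ct data.frame with columns `dilution`, `replicate`, `ct`.
#' @return An object of class `DilutionSeries`.
#' @export
dilution_series <- function(dilution_factors, ct) {
  dilution_factors <- sort(unique(as.numeric(dilution_factors)))
  if (length(dilution_factors) < 3L || any(dilution_factors <= 0))
    rs_validation_error("need >= 3 distinct positive dilution factors")
  if (!all(c("dilution", "replicate", "ct") %in% names(ct)))
    rs_validation_error("ct must have columns dilution,replicate,ct")
  if (!all(ct$dilution %in% dilution_factors))
    rs_validation_error("ct rows reference unknown dilution factors")
  if (anyNA(ct$ct) || any(!is.finite(ct$ct)))
    rs_validation_error("non-finite Ct in dilution series")
  # more dilute template crosses threshold later; a decreasing trend means
  # the series is mislabeled
  m <- tapply(ct$ct, ct$dilution, mean)
  m <- m[order(as.numeric(names(m)))]
  if (stats::cor(as.numeric(names(m)), as.numeric(m)) < 0)
    warning("mean Ct decreases with dilution factor; check series labels")
  structure(list(dilution_factors = dilution_factors,
                 ct = as.data.frame(ct)[c("dilution", "replicate", "ct")]),
            class = "DilutionSeries")
}

#' Read a dilution series from CSV (`dilution,replicate,ct`)
#' @param path CSV path.
#' @return A [dilution_series()].
#' @export
load_dilution_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("dilution", "replicate", "ct") %in% names(df)))
    rs_parse_error("%s: expected columns dilution,replicate,ct", path)
  dilution_series(unique(df$dilution), df)
}
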