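#' Aggregate efficiency of a gene set
#'
#' A reference-gene set scored as a single "quasi-gene" gets the geometric
#' mean of its members' amplification efficiencies. Computed in the log
#' domain.
#'
#' @param efficiencies numeric vector of member efficiencies (all > 1).
#' @return The aggregate efficiency, which always lies between the smallest
#'   and largest member efficiency.
#' @export
quasi_efficiency <- function(efficiencies) {
  if (length(efficiencies) == 0L)
    rs_validation_error("empty efficiency set")
  if (any(!is.finite(efficiencies)) || any(efficiencies <= 1))
    rs_validation_error("all efficiencies must be finite and > 1")
  exp(mean(log(efficiencies)))
}

#' Derived Ct of a quasi-gene for one replicate slot
#'
#' The quasi-gene's expression level is defined as the geometric mean of the
#' member expression levels (the set's normalization factor). Under the
#' exponential model `A = I / E^Ct` with a common threshold, the Ct value
#' that reproduces that expression at the aggregate efficiency `E~` is
#'
#'     C~ = (1/n) * sum_i Ct_i * log_{E~}(E_i)
#'
#' i.e. a weighted mean of member Cts with weights `ln(E_i)/ln(E~)` that
#' average to 1. When all member efficiencies are equal this reduces to the
#' arithmetic mean of the Cts; for a singleton it is the member's Ct
#' exactly.
#'
#' @param cts member Ct values for one replicate slot (aligned with
#'   `efficiencies`).
#' @param efficiencies member efficiencies (all > 1).
#' @return The derived Ct value, satisfying
#'   `I / E~^C~ = geometric mean of I / E_i^Ct_i` to machine precision.
#' @export
quasi_ct <- function(cts, efficiencies) {
  if (length(cts) != length(efficiencies))
    rs_validation_error("cts and efficiencies must have equal length")
  if (length(cts) == 0L) rs_validation_error("empty member set")
  if (length(cts) == 1L) return(as.numeric(cts))  # guard the 0/0 weight
  e_tilde <- quasi_efficiency(efficiencies)
  w <- log(efficiencies) / log(e_tilde)
  mean(cts * w)
}

#' Append a quasi-gene to a Ct table
#'
#' Adds one pseudo-gene whose Ct at every (sample, run, rep) slot is the
#' derived quasi-Ct over the members' Cts at that same slot (positional
#' pairing of the replicate grid), and whose efficiency is the members'
#' geometric mean. Members must share an identical replicate grid; ragged
#' grids are an error, never imputed. The input table is not modified.
#'
#' @param ct_tbl a [ct_table()].
#' @param members character vector of member gene IDs (>= 1, all present).
#' @param name identifier for the new pseudo-gene (must not collide).
#' @return A new `CtTable` containing all original genes plus the
#'   quasi-gene.
#' @export
append_quasi_gene <- function(ct_tbl, members, name = "quasi") {
  members <- unique(as.character(members))
  if (length(members) == 0L) rs_validation_error("empty member set")
  absent <- setdiff(members, ct_genes(ct_tbl))
  if (length(absent) > 0L)
    rs_validation_error("member gene(s) not in table: %s",
                        paste(absent, collapse = ", "))
  if (name %in% ct_genes(ct_tbl))
    rs_validation_error("gene '%s' already exists in the table", name)

  d <- ct_tbl$data[ct_tbl$data$gene %in% members, ]
  slot <- paste(d$sample, d$run, d$rep, sep = "\r")
  counts <- table(slot)
  if (any(counts != length(members)))
    rs_validation_error(
      "members do not share an identical replicate grid (ragged)")

  e <- ct_tbl$efficiencies[members]
  e_tilde <- quasi_efficiency(e)
  w <- if (length(members) == 1L) 1 else log(e) / log(e_tilde)
  wt <- stats::setNames(w, members)[d$gene]
  qct <- tapply(d$ct * wt, slot, sum) / length(members)
  parts <- do.call(rbind, strsplit(names(qct), "\r", fixed = TRUE))
  new_rows <- data.frame(gene = name, sample = parts[, 1L],
                         run = as.integer(parts[, 2L]),
                         rep = as.integer(parts[, 3L]),
                         ct = as.numeric(qct))
  ct_table(rbind(ct_tbl$data, new_rows),
           efficiencies = c(ct_tbl$efficiencies,
                            stats::setNames(e_tilde, name)),
           groups = ct_tbl$groups, threshold = ct_tbl$threshold)
}
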