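#' Bundled reference tables: 2013 Brazilian federative-unit results
#'
#' Three small CSV tables shipped with the package record the published 2013
#' state-level results for the Popular Pharmacy Program (BPPP) and the Basic
#' Component of Pharmaceutical Assistance (BCPA) across the 26 Brazilian
#' states and the Federal District:
#'
#' * `brazil_equity_2013()` — per-state MDEA equity index, standard error
#'   and 95% confidence interval, plus the five regional averages.
#' * `brazil_transfers_2013()` — effective and frontier-projected transfer
#'   values (millions of reais) per state and program, with regional
#'   subtotals and grand totals.
#' * `brazil_reallocation_2013()` — equity coefficients and allocated values
#'   under the complementary and substitution budget-constraint hypotheses.
#' * `brazil_variable_stats_2013()` — the descriptive table (mean/SD) of the
#'   five need and two service variables, stored verbatim as printed. Note
#'   two printed oddities kept as-is: the hypertension mean reads 1.2
#'   "thousands" although the accompanying text speaks of over a million
#'   diagnoses (the unit is likely millions for that row), and the elderly
#'   mean/SD split (978.0 / 71.4) is ambiguous in the printed layout.
#'
#' The underlying per-state needs data (survey and registry sources) were
#' never published, so the equity indices themselves cannot be recomputed
#' from raw inputs; these tables are the authoritative printed values from
#' which every derived quantity (capture percentages, required increases,
#' reallocations, regional means) can be reproduced arithmetically. Two
#' cells of the reallocation table were illegible in the available printed
#' layout and are reconstructed from the proportional reallocation rule
#' (Minas Gerais substitution BPPP coefficient 0.070; the Amazonas
#' substitution BPPP/BCPA value pair parsed as 11.31/147.86); both
#' reconstructions agree with the rule to under 0.05.
#'
#' @param include_aggregates if `TRUE`, regional (and, for transfers, total)
#'   rows are included, flagged by `row_type`; default `FALSE` returns the
#'   27 state rows only.
#' @return a data.frame; see each function's columns below.
#' @name reference-tables
NULL

.read_fixture <- function(file) {
  utils::read.csv(system.file("extdata", file, package = "pharmequity",
                              mustWork = TRUE),
                  stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' @rdname reference-tables
#' @export
brazil_equity_2013 <- function(include_aggregates = FALSE) {
  df <- .read_fixture("brazil_equity_2013.csv")
  if (!include_aggregates) df <- df[df$row_type == "state", ]
  rownames(df) <- NULL
  df
}

#' @rdname reference-tables
#' @export
brazil_transfers_2013 <- function(include_aggregates = FALSE) {
  df <- .read_fixture("brazil_transfers_2013.csv")
  if (!include_aggregates) df <- df[df$row_type == "state", ]
  rownames(df) <- NULL
  df
}

#' @rdname reference-tables
#' @export
brazil_reallocation_2013 <- function() {
  .read_fixture("brazil_reallocation_2013.csv")
}

#' @rdname reference-tables
#' @export
brazil_variable_stats_2013 <- function() {
  .read_fixture("brazil_variable_stats_2013.csv")
}

#' Projection table from the bundled 2013 transfer values
#'
#' Reshapes [brazil_transfers_2013()] into the long `projection_table`
#' layout used by [reallocate()] and [capture_percentage()].
#'
#' @return a `projection_table` with 54 rows (27 units x 2 programs).
#' @export
brazil_projection_2013 <- function() {
  df <- brazil_transfers_2013()
  long <- rbind(
    data.frame(dmu_id = df$dmu_id, program = "BPPP",
               effective = df$effective_bppp, projected = df$projected_bppp),
    data.frame(dmu_id = df$dmu_id, program = "BCPA",
               effective = df$effective_bcpa, projected = df$projected_bcpa)
  )
  long <- long[order(match(long$dmu_id, df$dmu_id), long$program), ]
  rownames(long) <- NULL
  as_projection_table(long)
}
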