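#' Write a result object to CSV or JSON
#'
#' Every result type in the package (MDEA summaries, projection tables,
#' reallocations, descriptive statistics, plain data.frames) serialises to
#' a flat table; column names are stable and match the documented fields of
#' each type.
#'
#' @param x an `mdea` fit (its summary table is written), a
#'   `projection_table`, a `reallocation`, or any data.frame.
#' @param path output file path.
#' @param format `"csv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- if (inherits(x, "mdea")) x$summary else as.data.frame(x)
  if (inherits(x, "reallocation")) df$hypothesis <- attr(x, "hypothesis")
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Run the full equity analysis on a dataset
#'
#' Convenience wrapper chaining [mdea()], [regional_average()] and the
#' writers: fits the subset-ensemble model, appends regional-average rows,
#' and optionally writes the per-unit table to disk.
#'
#' @param dataset a [dmu_dataset()] or a path to a CSV readable by
#'   [read_dmu_dataset()].
#' @param out optional output CSV path.
#' @param ... passed to [mdea()] (e.g. `se_mode`).
#' @return the summary data.frame (per-unit rows, then regional rows when
#'   regions are mapped), invisibly when `out` is given.
#' @export
run_equity_analysis <- function(dataset, out = NULL, ...) {
  if (is.character(dataset)) dataset <- read_dmu_dataset(dataset)
  fit <- mdea(dataset, ...)
  res <- fit$summary
  if (!anyNA(res$region)) {
    reg <- regional_average(fit)
    res <- rbind(res, data.frame(
      dmu_id = names(reg), name = names(reg), region = names(reg),
      ei_mean = as.numeric(reg), se = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, n_models = res$n_models[1],
      degenerate_count = NA_integer_, full_ei = NA_real_))
  }
  if (!is.null(out)) {
    utils::write.csv(res, out, row.names = FALSE, fileEncoding = "UTF-8")
    return(invisible(res))
  }
  res
}

#' Recompute every published derived quantity from the bundled tables
#'
#' Re-derives, from the bundled 2013 reference tables alone, each quantity
#' that follows arithmetically from the printed values: the aggregate
#' required-increase percentages per program, per-state capture
#' percentages, reallocated values under both budget hypotheses, the
#' confidence-interval relation, regional average indices, and the grand
#' total of effective BPPP transfers. Each row compares the recomputed
#' value against the printed one at the printed precision, with a tolerance
#' that absorbs print-rounding of intermediates.
#'
#' @return data.frame with columns `check`, `computed`, `printed`,
#'   `tolerance`, `pass`.
#' @examples
#' rep <- reproduce_reference_results()
#' all(rep$pass)
#' @export
reproduce_reference_results <- function() {
  tr <- brazil_transfers_2013()
  eq <- brazil_equity_2013()
  re <- brazil_reallocation_2013()
  pt <- brazil_projection_2013()
  comp <- reallocate(pt, "complementary")
  subs <- reallocate(pt, "substitution", pooled_effective = 2850.00)
  cell <- function(r, id, prog) r$allocated[r$dmu_id == id & r$program == prog]
  rows <- list(
    list("required increase, BPPP (%)",
         required_increase(sum(tr$effective_bppp), sum(tr$projected_bppp)),
         22.71, 0.005),
    list("required increase, BCPA (%)",
         required_increase(sum(tr$effective_bcpa), sum(tr$projected_bcpa)),
         46.71, 0.005),
    list("capture, Amapa BPPP (%)",
         capture_percentage(tr$effective_bppp[tr$dmu_id == "AP"],
                            tr$projected_bppp[tr$dmu_id == "AP"]), 1.1, 0.05),
    list("capture, Amazonas BPPP (%)",
         capture_percentage(tr$effective_bppp[tr$dmu_id == "AM"],
                            tr$projected_bppp[tr$dmu_id == "AM"]), 5.8, 0.05),
    list("complementary allocation, Sao Paulo BPPP",
         cell(comp, "SP", "BPPP"), 307.03, 0.05),
    list("complementary allocation, Tocantins BPPP",
         cell(comp, "TO", "BPPP"), 14.31, 0.05),
    list("substitution allocation, Tocantins BPPP",
         cell(subs, "TO", "BPPP"), 12.31, 0.05),
    list("substitution allocation, Rio Grande do Sul BPPP",
         cell(subs, "RS", "BPPP"), 165.81, 0.05),
    list("CI lower bound, Tocantins",
         eq$ei_mean[eq$dmu_id == "TO"] - 1.96 * eq$se[eq$dmu_id == "TO"],
         0.6237, 0.0005),
    list("regional mean equity index, North",
         mean(eq$ei_mean[eq$region == "North"]), 0.7837, 0.0005),
    list("grand total effective BPPP (millions)",
         sum(tr$effective_bppp), 1824.34, 0.005)
  )
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(check = r[[1]], computed = r[[2]], printed = r[[3]],
               tolerance = r[[4]], row.names = NULL)))
  # tolerances absorb half an ulp at the printed precision plus the
  # documented print-rounding of intermediates
  out$pass <- abs(out$computed - out$printed) <= out$tolerance
  out
}
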