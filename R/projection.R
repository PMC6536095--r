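#' Effective vs projected service values (frontier projection table)
#'
#' For every unit and every service (program), pairs the observed
#' ("effective") transfer value with the frontier ("projected") value from
#' the full DEA model — radial expansion plus output slack, i.e. the peer
#' target. This is the unconstrained scenario: it says what each unit would
#' have to receive to sit on the equity frontier if budgets could grow.
#'
#' @param x an [mdea()] fit, a [dmu_dataset()] (full-model DEA is run), or a
#'   data.frame already holding columns `dmu_id`, `program`, `effective`,
#'   `projected` (used as-is after validation).
#' @param ... unused.
#' @return An object of class `projection_table`: a data.frame with columns
#'   `dmu_id`, `program`, `effective`, `projected`, ordered by unit then
#'   program. Projected values never fall below effective values (up to
#'   solver tolerance); frontier units with zero slack have
#'   `projected == effective`.
#' @seealso [reallocate()], [capture_percentage()], [required_increase()]
#' @export
project_to_frontier <- function(x, ...) UseMethod("project_to_frontier")

#' @rdname project_to_frontier
#' @export
project_to_frontier.dmu_dataset <- function(x, ...) {
  fits <- lapply(seq_along(x$dmu_id), function(i) dea(x, i))
  project_to_frontier.mdea(list(full = fits, dataset = x))
}

#' @rdname project_to_frontier
#' @export
project_to_frontier.mdea <- function(x, ...) {
  ds <- x$dataset
  rows <- do.call(rbind, lapply(seq_along(x$full), function(i) {
    f <- x$full[[i]]
    data.frame(dmu_id = ds$dmu_id[i], program = ds$services_names,
               effective = unname(ds$services[i, ]),
               projected = if (f$degenerate) unname(ds$services[i, ])
                           else unname(f$projected),
               row.names = NULL)
  }))
  as_projection_table(rows)
}

#' @rdname project_to_frontier
#' @export
project_to_frontier.data.frame <- function(x, ...) as_projection_table(x)

#' Coerce a data.frame to a projection table
#'
#' @param df data.frame with columns `dmu_id`, `program`, `effective`,
#'   `projected`.
#' @param tol allowed shortfall of projected below effective, to absorb
#'   rounding in externally printed tables; default 0.02.
#' @return a `projection_table`.
#' @export
as_projection_table <- function(df, tol = 0.02) {
  need <- c("dmu_id", "program", "effective", "projected")
  if (length(missing <- setdiff(need, names(df))))
    stop("projection table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- which(df$projected < df$effective - tol)
  if (length(bad))
    stop(sprintf("projected < effective for dmu '%s', program '%s'",
                 df$dmu_id[bad[1]], df$program[bad[1]]), call. = FALSE)
  structure(df[need], class = c("projection_table", "data.frame"))
}

#' Capture percentage: share of the optimal value actually received
#'
#' `100 * effective / projected`, the percentage of the frontier-optimal
#' transfer a unit actually captures. Reported in percent to one decimal in
#' printed tables; full precision is returned here.
#'
#' @param effective,projected numeric vectors (recycled).
#' @return percentages; `NA` where `projected == 0` (undefined).
#' @examples
#' capture_percentage(0.11, 9.75)  # ~1.1
#' @export
capture_percentage <- function(effective, projected) {
  out <- 100 * effective / projected
  out[projected == 0] <- NA_real_
  out
}

#' Aggregate increase required to bring every unit to the frontier
#'
#' `100 * (projected_total - effective_total) / projected_total`: the
#' percentage by which the projected aggregate exceeds the effective one,
#' expressed relative to the projected total — equivalently, the aggregate
#' coverage deficit of the program.
#'
#' @param effective_total,projected_total positive totals with
#'   `projected_total >= effective_total`.
#' @return percentage (full precision).
#' @examples
#' required_increase(1824.34, 2360.30)  # ~22.71
#' @export
required_increase <- function(effective_total, projected_total) {
  stopifnot(effective_total > 0)
  if (any(projected_total < effective_total - 1e-9))
    stop("projected total below effective total", call. = FALSE)
  100 * (projected_total - effective_total) / projected_total
}

#' Budget-constrained reallocation of program transfers
#'
#' Redistributes the budget already available in proportion to each unit's
#' frontier-projected value, under two hypotheses about how the programs
#' relate:
#'
#' * **complementary** — the programs require separate budgets; each
#'   program's own effective total is redistributed across units:
#'   `coefficient = projected / sum(projected within program)` and
#'   `allocated = coefficient * sum(effective within program)`.
#' * **substitution** — the programs are mutually exclusive and share one
#'   pooled budget: `coefficient = projected / sum(all projected)` and
#'   `allocated = coefficient * pooled effective total` across all
#'   unit-program cells.
#'
#' Both schemes conserve the relevant budget exactly. Coefficients are
#' scale-free in the projected values.
#'
#' @param projection a `projection_table` (see [project_to_frontier()]).
#' @param hypothesis `"complementary"` or `"substitution"`.
#' @param pooled_effective optional override of the pooled budget used under
#'   the substitution hypothesis (e.g. a published rounded total); default
#'   is the exact sum of effective values.
#' @return An object of class `reallocation`: a data.frame with columns
#'   `dmu_id`, `program`, `coefficient`, `allocated`, plus attributes
#'   `hypothesis` and `budget`.
#' @examples
#' pt <- as_projection_table(data.frame(
#'   dmu_id = c("A", "B"), program = "P",
#'   effective = c(1, 3), projected = c(2, 6)))
#' reallocate(pt, "complementary")
#' @export
reallocate <- function(projection,
                       hypothesis = c("complementary", "substitution"),
                       pooled_effective = NULL) {
  stopifnot(inherits(projection, "projection_table"))
  hypothesis <- match.arg(hypothesis)
  df <- as.data.frame(projection)
  if (sum(df$projected) <= 0)
    stop("zero projected grand total; reallocation undefined", call. = FALSE)
  if (hypothesis == "complementary") {
    coefficient <- stats::ave(df$projected, df$program,
                              FUN = function(p) p / sum(p))
    budget_p <- stats::ave(df$effective, df$program, FUN = sum)
    allocated <- coefficient * budget_p
    budget <- tapply(df$effective, df$program, sum)
  } else {
    budget <- if (is.null(pooled_effective)) sum(df$effective)
              else pooled_effective
    coefficient <- df$projected / sum(df$projected)
    allocated <- coefficient * budget
  }
  structure(
    data.frame(dmu_id = df$dmu_id, program = df$program,
               coefficient = coefficient, allocated = allocated,
               row.names = NULL),
    class = c("reallocation", "data.frame"),
    hypothesis = hypothesis, budget = budget)
}

#' @export
print.reallocation <- function(x, digits = 3, ...) {
  cat(sprintf("Budget-constrained reallocation (%s hypothesis)\n",
              attr(x, "hypothesis")))
  df <- as.data.frame(x)
  df$coefficient <- round(df$coefficient, digits)
  df$allocated <- round(df$allocated, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Regress the coverage deficit on pharmacy accreditation
#'
#' Ordinary least squares of the relative coverage deficit, `1 - ei`, on the
#' share of private pharmacies accredited to the program, summarising how
#' much of the equity shortfall tracks private-sector adhesion.
#'
#' @param ei per-unit mean equity indices (or an [mdea()] fit).
#' @param pharmacy_ratio per-unit accredited-pharmacy share in `[0, 1]`.
#' @return An object of class `deficit_regression`: list with `slope`,
#'   `intercept`, `r_squared`, and the underlying `lm` fit (`model`).
#' @export
deficit_regression <- function(ei, pharmacy_ratio) {
  if (inherits(ei, "mdea")) ei <- ei$summary$ei_mean
  if (length(ei) != length(pharmacy_ratio))
    stop("ei and pharmacy_ratio lengths differ", call. = FALSE)
  if (length(ei) < 3) stop("need at least 3 units", call. = FALSE)
  if (stats::var(pharmacy_ratio) == 0)
    stop("pharmacy_ratio has zero variance; slope undefined", call. = FALSE)
  deficit <- 1 - ei
  fit <- stats::lm(deficit ~ pharmacy_ratio)
  # exact-fit inputs are legitimate here; lm's perfect-fit warning is noise
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 model = fit),
            class = "deficit_regression")
}

#' @export
print.deficit_regression <- function(x, ...) {
  cat(sprintf("coverage deficit ~ pharmacy ratio: slope %.4f, intercept %.4f, R^2 %.3f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}
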