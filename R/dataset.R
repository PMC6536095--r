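#' Default variable names for state-level pharmaceutical-assistance data
#'
#' Five need indicators (disease prevalence counts, elderly population, and a
#' negative-income index) and two service variables (federal transfer values
#' for the Popular Pharmacy Program, BPPP, and for the Basic Component of
#' Pharmaceutical Assistance, BCPA).
#'
#' @name variable-names
#' @keywords internal
NULL

.default_needs <- c("hypertension_thousands", "diabetics_thousands",
                    "asthmatics_thousands", "elderly_thousands",
                    "negative_income_index")
.default_services <- c("bppp_value_millions", "bcpa_value_millions")
.regions <- c("North", "Northeast", "Southeast", "South", "Midwest")

#' Construct a DMU dataset
#'
#' Bundles one row per decision-making unit (DMU) — here, a federative unit —
#' holding a needs vector (DEA inputs) and a services vector (DEA outputs).
#' Needs must be strictly positive: DEA compares units against convex
#' combinations of peers with no greater needs, and a zero need makes that
#' comparison degenerate. Services must be nonnegative; a unit whose services
#' are all zero is kept but flagged degenerate (no radial expansion of a zero
#' vector is defined, and downstream solvers assign it an equity index of 0).
#'
#' @param dmu_id character vector of unique unit identifiers.
#' @param needs numeric matrix (units x need variables) with column names.
#' @param services numeric matrix (units x service variables) with column names.
#' @param name display names; defaults to `dmu_id`.
#' @param region optional region label per unit.
#' @return An object of class `dmu_dataset`: a list with elements `dmu_id`,
#'   `name`, `region`, `needs`, `services`, `degenerate` (logical flag per
#'   unit), `needs_names`, `services_names`.
#' @examples
#' d <- dmu_dataset(c("A", "B"),
#'                  needs = cbind(pop = c(10, 20)),
#'                  services = cbind(transfer = c(5, 9)))
#' d
#' @export
dmu_dataset <- function(dmu_id, needs, services, name = dmu_id, region = NULL) {
  dmu_id <- as.character(dmu_id)
  needs <- as.matrix(needs)
  services <- as.matrix(services)
  storage.mode(needs) <- "double"
  storage.mode(services) <- "double"
  n <- length(dmu_id)
  if (nrow(needs) != n || nrow(services) != n)
    stop("needs and services must have one row per dmu_id", call. = FALSE)
  if (is.null(colnames(needs)) || is.null(colnames(services)))
    stop("needs and services matrices require column names", call. = FALSE)
  if (anyDuplicated(dmu_id))
    stop("dmu_id values must be unique", call. = FALSE)
  if (anyDuplicated(colnames(needs)) || anyDuplicated(colnames(services)))
    stop("variable names must be unique", call. = FALSE)
  for (j in colnames(needs)) {
    bad <- which(!is.finite(needs[, j]) | needs[, j] <= 0)
    if (length(bad))
      stop(sprintf("need '%s' must be strictly positive; violated by dmu '%s'",
                   j, dmu_id[bad[1]]), call. = FALSE)
  }
  for (j in colnames(services)) {
    bad <- which(!is.finite(services[, j]) | services[, j] < 0)
    if (length(bad))
      stop(sprintf("service '%s' must be nonnegative; violated by dmu '%s'",
                   j, dmu_id[bad[1]]), call. = FALSE)
  }
  rownames(needs) <- rownames(services) <- dmu_id
  structure(list(
    dmu_id = dmu_id,
    name = as.character(name),
    region = if (is.null(region)) rep(NA_character_, n) else as.character(region),
    needs = needs,
    services = services,
    degenerate = rowSums(services) == 0,
    needs_names = colnames(needs),
    services_names = colnames(services)
  ), class = "dmu_dataset")
}

#' @export
print.dmu_dataset <- function(x, ...) {
  cat(sprintf("DMU dataset: %d units, %d needs, %d services\n",
              length(x$dmu_id), length(x$needs_names), length(x$services_names)))
  cat("  needs:   ", paste(x$needs_names, collapse = ", "), "\n")
  cat("  services:", paste(x$services_names, collapse = ", "), "\n")
  if (any(x$degenerate))
    cat("  degenerate (all-zero services):",
        paste(x$dmu_id[x$degenerate], collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.dmu_dataset <- function(x, ...) {
  data.frame(dmu_id = x$dmu_id, name = x$name, region = x$region,
             as.data.frame(x$needs), as.data.frame(x$services),
             row.names = NULL, check.names = FALSE)
}

#' @export
length.dmu_dataset <- function(x) length(x$dmu_id)

#' Subset a DMU dataset by unit
#'
#' @param x a `dmu_dataset`.
#' @param i index or dmu_id vector.
#' @param ... unused.
#' @return a `dmu_dataset` with the selected units, order preserved as given.
#' @export
`[.dmu_dataset` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$dmu_id)
  dmu_dataset(x$dmu_id[i], x$needs[i, , drop = FALSE],
              x$services[i, , drop = FALSE],
              name = x$name[i], region = x$region[i])
}

#' Read a state-level dataset from CSV
#'
#' Expects a UTF-8, comma-separated file with a header row, dot decimals, and
#' one row per decision-making unit. Column names are resolved through
#' `mapping`, so files with different headers can be loaded without editing.
#' Values are used as printed: services in millions of currency, needs in
#' thousands of persons (plus a dimensionless negative-income index); no
#' rescaling is applied.
#'
#' @param path path to the CSV file.
#' @param mapping named list with entries `dmu_id`, `name` (optional),
#'   `region` (optional), `needs` (character vector of need columns),
#'   `services` (character vector of service columns). Defaults to the
#'   standard seven-variable layout.
#' @return a validated [dmu_dataset()] with row order preserved.
#' @seealso [write_dmu_dataset()], [transform_negative_income()]
#' @export
read_dmu_dataset <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(mapping))
    mapping <- list(dmu_id = "dmu_id", name = "name", region = "region",
                    needs = .default_needs, services = .default_services)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  required <- c(mapping$dmu_id, mapping$needs, mapping$services)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  nm <- if (!is.null(mapping$name) && mapping$name %in% names(df))
    df[[mapping$name]] else df[[mapping$dmu_id]]
  rg <- if (!is.null(mapping$region) && mapping$region %in% names(df))
    df[[mapping$region]] else NULL
  needs <- as.matrix(df[mapping$needs])
  services <- as.matrix(df[mapping$services])
  dmu_dataset(df[[mapping$dmu_id]], needs, services, name = nm, region = rg)
}

#' Write a DMU dataset to CSV
#'
#' Numeric fields are written at full double precision (15 significant
#' digits), so a write/read round trip reproduces the dataset exactly.
#'
#' @param dataset a [dmu_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dmu_dataset <- function(dataset, path) {
  df <- as.data.frame(dataset)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Turn an income level into a positive "negative income" need indicator
#'
#' DEA need variables must be strictly positive and larger values must encode
#' greater need, but income works the other way around: poorer units need
#' more support. The default transform reflects and standardises income,
#' `(max(income) - income) / sd(income) + epsilon`, so the richest unit gets
#' the small floor `epsilon` and poorer units get proportionally larger
#' values. Any strictly positive, income-decreasing transform serves the same
#' purpose; this one is the package default because it is unit-free.
#'
#' @param income numeric vector of income levels (length >= 2).
#' @param epsilon positive floor added so the maximum-income unit keeps a
#'   strictly positive need; default 0.01.
#' @return numeric vector of strictly positive need values, decreasing in
#'   income.
#' @examples
#' transform_negative_income(c(10, 20, 40))
#' @export
transform_negative_income <- function(income, epsilon = 0.01) {
  stopifnot(is.numeric(income), length(income) >= 2, epsilon > 0)
  s <- stats::sd(income)
  if (s == 0) stop("income has zero variance; transform undefined", call. = FALSE)
  (max(income) - income) / s + epsilon
}

#' Per-variable descriptive statistics
#'
#' Unweighted mean and sample standard deviation of every need and service
#' column, mirroring the descriptive table that usually accompanies a DEA
#' variable set.
#'
#' @param dataset a [dmu_dataset()] with at least two units.
#' @return data.frame with columns `variable`, `vector` ("needs"/"services"),
#'   `mean`, `sd`.
#' @export
descriptive_stats <- function(dataset) {
  stopifnot(inherits(dataset, "dmu_dataset"))
  if (length(dataset$dmu_id) < 2)
    stop("descriptive statistics need at least two units (sample SD undefined)",
         call. = FALSE)
  m <- cbind(dataset$needs, dataset$services)
  data.frame(
    variable = colnames(m),
    vector = rep(c("needs", "services"),
                 c(length(dataset$needs_names), length(dataset$services_names))),
    mean = apply(m, 2, mean),
    sd = apply(m, 2, stats::sd),
    row.names = NULL
  )
}
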