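#' Enumerate all input/output submodels
#'
#' Every pairing of a non-empty subset of need variables with a non-empty
#' subset of service variables defines one DEA submodel; with `m` needs and
#' `s` services there are `(2^m - 1) * (2^s - 1)` of them. Order is
#' deterministic: lexicographic by needs bitmask, then services bitmask,
#' where bit `j` selects the `j`-th variable. The final element is always
#' the full model (all needs, all services).
#'
#' @param needs_names,services_names character vectors of variable labels.
#' @return list of submodels, each a list with elements `needs` and
#'   `services`.
#' @examples
#' length(enumerate_submodels(letters[1:5], c("y1", "y2")))  # 93
#' @export
enumerate_submodels <- function(needs_names, services_names) {
  m <- length(needs_names); s <- length(services_names)
  if (!m || !s) stop("variable label sets must be non-empty", call. = FALSE)
  out <- vector("list", (2^m - 1) * (2^s - 1))
  k <- 0L
  for (ni in seq_len(2^m - 1)) {
    nsel <- needs_names[bitwAnd(ni, 2^(seq_len(m) - 1)) > 0]
    for (si in seq_len(2^s - 1)) {
      k <- k + 1L
      out[[k]] <- list(needs = nsel,
                       services = services_names[bitwAnd(si, 2^(seq_len(s) - 1)) > 0])
    }
  }
  out
}

#' Fit the multiple-DEA (MDEA) equity model
#'
#' With few units and many variables, plain DEA ranks too many units as
#' efficient. MDEA restores discrimination by solving the output-oriented
#' VRS model for *every* non-empty subset pair of needs and services and
#' treating each unit's equity indices across submodels as a distribution:
#' the reported index is the ensemble mean, with a standard error and a
#' normal 95% confidence interval describing the spread across submodels.
#'
#' Submodels are enumerated exhaustively (never sampled), so the fit is
#' fully reproducible: no randomness is involved. A submodel in which the
#' target's selected services are all zero contributes an equity index of 0
#' and is counted in `degenerate_count`.
#'
#' @param dataset a [dmu_dataset()] with at least two units.
#' @param z critical value for the confidence interval; default 1.96 (95%).
#' @param se_mode `"sd_over_sqrt_n"` (default): SE of the ensemble mean,
#'   sample SD of the submodel indices divided by `sqrt(n_models)`; or
#'   `"sd"`: the ensemble SD itself.
#' @return An object of class `mdea` with components `ei` (units x submodels
#'   matrix of equity indices), `submodels`, `summary` (per-unit mean, se,
#'   ci_low, ci_high, n_models, degenerate_count, full-model index),
#'   `full` (list of full-model [dea()] fits, slacks maximised), `dataset`,
#'   `z`, `se_mode`. Confidence bounds are not truncated at 1.
#' @examples
#' d <- dmu_dataset(c("A", "B", "C"),
#'                  needs = cbind(x = c(1, 2, 2)),
#'                  services = cbind(y = c(1, 4, 2)))
#' fit <- mdea(d)
#' coef(fit)
#' summary(fit)
#' @seealso [dea()], [regional_average()], [project_to_frontier()]
#' @export
mdea <- function(dataset, z = 1.96, se_mode = c("sd_over_sqrt_n", "sd")) {
  stopifnot(inherits(dataset, "dmu_dataset"))
  se_mode <- match.arg(se_mode)
  if (length(dataset$dmu_id) < 2)
    stop("MDEA needs at least two units", call. = FALSE)
  subs <- enumerate_submodels(dataset$needs_names, dataset$services_names)
  n <- length(dataset$dmu_id)
  ei <- matrix(NA_real_, n, length(subs),
               dimnames = list(dataset$dmu_id, NULL))
  for (j in seq_along(subs)) {
    for (i in seq_len(n)) {
      f <- dea(dataset, i, needs = subs[[j]]$needs,
               services = subs[[j]]$services, two_phase = FALSE)
      ei[i, j] <- f$ei
    }
  }
  full <- lapply(seq_len(n), function(i) dea(dataset, i))
  names(full) <- dataset$dmu_id
  degen <- vapply(seq_len(n), function(i) {
    sum(vapply(subs, function(sm)
      all(dataset$services[i, sm$services] == 0), logical(1)))
  }, integer(1))
  stats_ <- t(vapply(seq_len(n), function(i)
    unlist(summarize_ei(ei[i, ], z = z, se_mode = se_mode)), numeric(4)))
  summary_df <- data.frame(
    dmu_id = dataset$dmu_id, name = dataset$name, region = dataset$region,
    ei_mean = stats_[, "mean"], se = stats_[, "se"],
    ci_low = stats_[, "ci_low"], ci_high = stats_[, "ci_high"],
    n_models = length(subs), degenerate_count = degen,
    full_ei = vapply(full, `[[`, numeric(1), "ei"),
    row.names = NULL
  )
  structure(list(ei = ei, submodels = subs, summary = summary_df,
                 full = full, dataset = dataset, z = z, se_mode = se_mode),
            class = "mdea")
}

#' Summarise an ensemble of equity indices
#'
#' @param ei_values numeric vector of equity indices, one per submodel.
#' @param z critical value; default 1.96.
#' @param se_mode see [mdea()].
#' @return list with `mean`, `se`, `ci_low`, `ci_high`. With a single value
#'   the SE is 0 and the interval collapses to the mean.
#' @examples
#' summarize_ei(c(0.5, 1))  # mean 0.75, se 0.25
#' @export
summarize_ei <- function(ei_values, z = 1.96,
                         se_mode = c("sd_over_sqrt_n", "sd")) {
  se_mode <- match.arg(se_mode)
  if (!length(ei_values)) stop("empty ensemble", call. = FALSE)
  m <- mean(ei_values)
  s <- if (length(ei_values) > 1) stats::sd(ei_values) else 0
  se <- if (se_mode == "sd_over_sqrt_n") s / sqrt(length(ei_values)) else s
  list(mean = m, se = se, ci_low = m - z * se, ci_high = m + z * se)
}

#' Regional average equity index
#'
#' Unweighted arithmetic mean of member-unit indices per region.
#'
#' @param ei named numeric vector of per-unit mean equity indices, or an
#'   [mdea()] fit.
#' @param region character vector of region labels aligned with `ei`
#'   (ignored when `ei` is an `mdea` fit, which carries its own regions).
#' @return named numeric vector of per-region means.
#' @export
regional_average <- function(ei, region = NULL) {
  if (inherits(ei, "mdea")) {
    region <- ei$summary$region
    ei <- ei$summary$ei_mean
  }
  if (is.null(region) || length(region) != length(ei))
    stop("every unit must be mapped to a region", call. = FALSE)
  if (anyNA(region)) stop("unmapped unit (region is NA)", call. = FALSE)
  out <- tapply(ei, region, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' @export
print.mdea <- function(x, ...) {
  cat(sprintf("MDEA fit: %d units x %d submodels (%d needs, %d services)\n",
              nrow(x$ei), ncol(x$ei), length(x$dataset$needs_names),
              length(x$dataset$services_names)))
  cat(sprintf("  equity index (ensemble mean): %.4f to %.4f; %d unit(s) on the full-model frontier\n",
              min(x$summary$ei_mean), max(x$summary$ei_mean),
              sum(x$summary$full_ei >= 1 - 1e-9)))
  invisible(x)
}

#' @export
summary.mdea <- function(object, ...) {
  out <- object$summary
  class(out) <- c("summary.mdea", "data.frame")
  out
}

#' @export
print.summary.mdea <- function(x, digits = 4, ...) {
  df <- x
  class(df) <- "data.frame"
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mdea <- function(object, ...) {
  stats::setNames(object$summary$ei_mean, object$summary$dmu_id)
}

#' @export
fitted.mdea <- function(object, ...) {
  stats::setNames(object$summary$full_ei, object$summary$dmu_id)
}

#' Dispersion plot of the submodel equity-index ensembles
#'
#' One box per unit, ordered by ensemble mean, showing how the equity index
#' varies across input/output submodels.
#'
#' @param x an [mdea()] fit.
#' @param ... passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.mdea <- function(x, ...) {
  ord <- order(x$summary$ei_mean)
  graphics::boxplot(t(x$ei[ord, , drop = FALSE]), las = 2,
                    ylab = "equity index (submodel ensemble)", ...)
  invisible(x)
}
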