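#' Min-max normalize sweep columns
#'
#' Scales each regression variable to \[0, 1\] by min-max normalization —
#' response included, as in the reference analysis.  The extra-pair dummy is
#' already 0/1 and passes through unchanged.  A constant column cannot be
#' scaled and raises an error naming the column.
#'
#' @param table A `sweep_table` (or compatible data.frame).
#' @param columns Columns to scale.
#' @return The table with the named columns scaled; attribute `normalized`
#'   set to `TRUE`.
#' @export
normalize_columns <- function(table,
                              columns = c("female_radius", "season_duration",
                                          "number_of_males", "extra_pair",
                                          "percentage_monogamy")) {
  for (cl in intersect(columns, names(table))) {
    x <- as.numeric(table[[cl]])
    rng <- range(x)
    if (diff(rng) == 0) {
      stop(sprintf("column '%s' is constant and cannot be min-max normalized",
                   cl), call. = FALSE)
    }
    table[[cl]] <- (x - rng[1]) / diff(rng)
  }
  attr(table, "normalized") <- TRUE
  table
}

#' Fit the normalized regression of percentage monogamy
#'
#' Ordinary least squares of (normalized) percentage monogamy on any subset
#' of the four predictors: number of males, female radius (dispersion),
#' season duration and the extra-pair-copulation dummy.  All variables are
#' min-max normalized first (set `normalize = FALSE` for pre-scaled tables).
#' The model includes an intercept by default; set `intercept = FALSE` only
#' for comparison, as dropping it inflates R-squared artifactually.
#'
#' @param table A `sweep_table`.
#' @param predictors Character vector, subset of
#'   `c("number_of_males", "female_radius", "season_duration", "extra_pair")`.
#' @param intercept Include an intercept term.
#' @param normalize Min-max normalize the variables first.
#' @return An object of class `monog_regression`: list with `coefficients`
#'   (term, estimate, std_error, t_value, p_value), `r_squared`,
#'   `adj_r_squared`, `n`, `predictors` and the underlying `fit`.
#' @examples
#' tab <- make_fixture("linear_sweep_table")
#' fit_regression(tab, normalize = FALSE)
#' @export
fit_regression <- function(table,
                           predictors = c("number_of_males", "female_radius",
                                          "season_duration", "extra_pair"),
                           intercept = TRUE,
                           normalize = TRUE) {
  allowed <- c("number_of_males", "female_radius", "season_duration",
               "extra_pair")
  if (!length(predictors) || !all(predictors %in% allowed)) {
    stop("'predictors' must be a non-empty subset of: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(c("percentage_monogamy", predictors), names(table))
  if (length(missing_cols)) {
    stop("table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (normalize) {
    table <- normalize_columns(table,
                               columns = c(predictors, "percentage_monogamy"))
  }
  df <- as.data.frame(table)[c("percentage_monogamy", predictors)]
  fml <- reformulate(predictors, response = "percentage_monogamy",
                     intercept = intercept)
  fit <- lm(fml, data = df)
  if (anyNA(coef(fit))) {
    stop("rank-deficient design: aliased predictors ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  s <- summary(fit)
  cf <- s$coefficients
  out <- list(
    coefficients = data.frame(
      term = rownames(cf),
      estimate = cf[, "Estimate"],
      std_error = cf[, "Std. Error"],
      t_value = cf[, "t value"],
      p_value = cf[, "Pr(>|t|)"],
      row.names = NULL
    ),
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    n = nrow(df),
    predictors = predictors,
    intercept = intercept,
    fit = fit
  )
  class(out) <- "monog_regression"
  out
}

#' @export
print.monog_regression <- function(x, digits = 3, ...) {
  cat(sprintf("Normalized OLS of percentage monogamy (n = %d)\n", x$n))
  cf <- x$coefficients
  cf$estimate <- round(cf$estimate, digits)
  cf$std_error <- round(cf$std_error, digits)
  cf$t_value <- round(cf$t_value, 2)
  cf$p_value <- format.pval(cf$p_value, digits = 3, eps = 2e-16)
  print(cf, row.names = FALSE)
  cat(sprintf("Multiple R-squared %.3f, adjusted R-squared %.3f\n",
              x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' Coefficient lookup helper
#'
#' @param x A `monog_regression`.
#' @param term Term name.
#' @return The point estimate.
#' @export
coef_estimate <- function(x, term) {
  stopifnot(inherits(x, "monog_regression"))
  i <- match(term, x$coefficients$term)
  if (is.na(i)) stop(sprintf("no term '%s' in model", term), call. = FALSE)
  x$coefficients$estimate[i]
}

#' Subset regressions at a fixed refractory period
#'
#' Restricts the sweep to one refractory-period value (default 10) and fits
#' the full 4-predictor normalized model plus each single-predictor model in
#' isolation, reporting R-squared and adjusted R-squared for each.
#'
#' @param table A `sweep_table` containing a `refractory_period_duration`
#'   column.
#' @param refractory Refractory-period value selecting the subset.
#' @return A list of class `subset_regressions` with elements `refractory`,
#'   `n`, `full` (a `monog_regression`) and `isolated` (named list of
#'   single-predictor `monog_regression` objects).
#' @export
subset_regressions <- function(table, refractory = 10L) {
  if (!"refractory_period_duration" %in% names(table)) {
    stop("table lacks a 'refractory_period_duration' column", call. = FALSE)
  }
  sub <- table[table$refractory_period_duration == refractory, , drop = FALSE]
  if (!nrow(sub)) {
    stop(sprintf("no sweep rows with refractory period %s", refractory),
         call. = FALSE)
  }
  preds <- c("number_of_males", "female_radius", "season_duration",
             "extra_pair")
  out <- list(
    refractory = refractory,
    n = nrow(sub),
    full = fit_regression(sub, preds),
    isolated = setNames(
      lapply(preds, function(p) fit_regression(sub, p)),
      preds
    )
  )
  class(out) <- "subset_regressions"
  out
}

#' @export
print.subset_regressions <- function(x, ...) {
  cat(sprintf("Regressions on the refractory = %s subset (n = %d)\n",
              x$refractory, x$n))
  cat(sprintf("  full 4-predictor model: R2 = %.3f, adjusted R2 = %.3f\n",
              x$full$r_squared, x$full$adj_r_squared))
  for (p in names(x$isolated)) {
    cat(sprintf("  %s alone: R2 = %.3f\n", p, x$isolated[[p]]$r_squared))
  }
  invisible(x)
}

#' Monogamy-on-dispersion fit within one cell slice
#'
#' Simple regression of percentage monogamy on female radius, restricted to
#' one (males, season duration, guarding, refractory) slice of the sweep —
#' the regime in which female dispersion is the dominant predictor is few
#' males and a short season with guarding on.
#'
#' @param table A `sweep_table`.
#' @param number_of_males,season_duration,mate_guarding,refractory_period_duration
#'   Values selecting the slice.
#' @return The R-squared of the fit, with attributes `n` (rows used) and
#'   `slope`.
#' @export
dispersion_fit <- function(table,
                           number_of_males = 15L,
                           season_duration = 200L,
                           mate_guarding = TRUE,
                           refractory_period_duration = 10L) {
  sel <- table$number_of_males == number_of_males &
    table$season_duration == season_duration &
    table$mate_guarding == mate_guarding
  if ("refractory_period_duration" %in% names(table)) {
    sel <- sel &
      table$refractory_period_duration == refractory_period_duration
  }
  sub <- table[sel, , drop = FALSE]
  if (!nrow(sub)) stop("no sweep rows match the requested slice", call. = FALSE)
  y <- sub$percentage_monogamy
  x <- sub$female_radius
  if (var(y) == 0) {
    r2 <- 0
    slope <- 0
  } else {
    fit <- lm(y ~ x)
    r2 <- summary(fit)$r.squared
    slope <- unname(coef(fit)[2])
  }
  structure(r2, n = nrow(sub), slope = slope)
}
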