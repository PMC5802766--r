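#' Parameter-sweep grid
#'
#' Full cross-product of the swept parameter values.  The defaults are the
#' reference grid: 3 male counts x 7 female radii x 4 season durations x 2
#' refractory durations x 2 guarding settings = 336 cells.
#'
#' @param number_of_males,female_radius,season_duration,refractory_period_duration,mate_guarding
#'   Vectors of values to cross.
#' @return A data.frame with one row per cell and a leading `cell` id column.
#' @examples
#' nrow(sweep_grid())  # 336
#' @export
sweep_grid <- function(number_of_males = c(15L, 20L, 25L),
                       female_radius = seq(5L, 35L, by = 5L),
                       season_duration = c(200L, 400L, 600L, 800L),
                       refractory_period_duration = c(10L, 30L),
                       mate_guarding = c(TRUE, FALSE)) {
  g <- expand.grid(
    number_of_males = as.integer(number_of_males),
    female_radius = as.integer(female_radius),
    season_duration = as.integer(season_duration),
    refractory_period_duration = as.integer(refractory_period_duration),
    mate_guarding = as.logical(mate_guarding),
    KEEP.OUT.ATTRS = FALSE
  )
  cbind(cell = seq_len(nrow(g)), g)
}

#' Derive a per-run seed
#'
#' Counter-based seed derivation: `base_seed + 1024 * cell + replicate`,
#' reduced modulo 2^31 - 1.  Injective over all (cell, replicate) pairs as
#' long as `replicate < 1024`, so independent runs of a sweep can never
#' collide or be reordered.
#'
#' @param base_seed Non-negative base seed of the sweep.
#' @param cell 1-based cell index in the grid.
#' @param replicate 1-based replicate index (must be below 1024).
#' @return A single integer seed.
#' @export
derive_seed <- function(base_seed, cell, replicate) {
  stopifnot(base_seed >= 0, cell >= 0, replicate >= 0, replicate < 1024)
  as.integer((base_seed + 1024 * cell + replicate) %% 2147483647)
}

#' Run a parameter sweep
#'
#' Executes every grid cell x replicate as an independent seeded run and
#' returns the long-format results table.  Rows are deterministic functions
#' of (`base_seed`, cell, replicate) only, so the table is reproducible and
#' order-insensitive.
#'
#' @param grid A [sweep_grid()] data.frame (any subset of columns present is
#'   applied over `params_base`).
#' @param replicates Replicate runs per cell.
#' @param base_seed Base seed from which every run seed is derived.
#' @param generations Generations per run (override of `params_base`; the
#'   reference scale is 150, reduce for desk-scale runs).
#' @param params_base A [sim_params()] object supplying all non-swept fields.
#' @param verbose Print one progress line per cell.
#' @return A `sweep_table` data.frame: one row per (cell, replicate) with the
#'   swept parameters, `extra_pair` (= `!mate_guarding`), `seed` and
#'   `percentage_monogamy`.
#' @export
run_sweep <- function(grid = sweep_grid(),
                      replicates = 5L,
                      base_seed = 1L,
                      generations = NULL,
                      params_base = sim_params(),
                      verbose = FALSE) {
  stopifnot(nrow(grid) >= 1, replicates >= 1)
  par_cols <- intersect(
    c("number_of_males", "number_of_females", "female_radius",
      "season_duration", "refractory_period_duration", "mate_guarding"),
    names(grid)
  )
  if (!length(par_cols)) stop("grid contains no parameter columns", call. = FALSE)
  cells <- if ("cell" %in% names(grid)) grid$cell else seq_len(nrow(grid))

  rows <- vector("list", nrow(grid) * replicates)
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    over <- as.list(grid[i, par_cols, drop = FALSE])
    if (!is.null(generations)) over$generations <- as.integer(generations)
    p <- do.call(sim_params, modifyList(unclass(params_base)[
      setdiff(names(unclass(params_base)), "seed")], over))
    for (r in seq_len(replicates)) {
      seed <- derive_seed(base_seed, cells[i], r)
      res <- tryCatch(
        run_simulation(p, seed = seed),
        error = function(e) {
          stop(sprintf("sweep run failed in cell %d (replicate %d): %s",
                       cells[i], r, conditionMessage(e)), call. = FALSE)
        }
      )
      k <- k + 1L
      rows[[k]] <- data.frame(
        cell = cells[i],
        replicate = r,
        seed = seed,
        number_of_males = p$number_of_males,
        female_radius = p$female_radius,
        season_duration = p$season_duration,
        refractory_period_duration = p$refractory_period_duration,
        mate_guarding = p$mate_guarding,
        extra_pair = as.integer(!p$mate_guarding),
        percentage_monogamy = res$percentage_monogamy
      )
    }
    if (verbose) {
      message(sprintf("cell %d/%d done (%s)", i, nrow(grid),
                      paste(names(over), unlist(over), sep = "=",
                            collapse = ", ")))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Per-cell summaries of a sweep
#'
#' Mean percentage monogamy per parameter cell with a Student-t 95 percent
#' confidence interval over replicates (`mean +/- qt(0.975, n - 1) * se`).
#' Cells with a single replicate get `NA` interval bounds.
#'
#' @param table A `sweep_table`.
#' @param conf_level Confidence level for the interval.
#' @return A data.frame with one row per cell: parameter columns, `n`,
#'   `mean`, `sd`, `ci_lower`, `ci_upper`.
#' @export
summarize_cells <- function(table, conf_level = 0.95) {
  keys <- intersect(
    c("number_of_males", "female_radius", "season_duration",
      "refractory_period_duration", "mate_guarding", "extra_pair"),
    names(table)
  )
  if (!"percentage_monogamy" %in% names(table)) {
    stop("table lacks a 'percentage_monogamy' column", call. = FALSE)
  }
  agg <- aggregate(
    table["percentage_monogamy"],
    by = table[keys],
    FUN = function(v) c(n = length(v), mean = mean(v), sd = sd(v))
  )
  stats <- agg$percentage_monogamy
  out <- agg[keys]
  out$n <- as.integer(stats[, "n"])
  out$mean <- stats[, "mean"]
  out$sd <- stats[, "sd"]
  half <- rep(NA_real_, nrow(out))
  ok <- out$n >= 2
  half[ok] <- qt(1 - (1 - conf_level) / 2, out$n[ok] - 1) *
    out$sd[ok] / sqrt(out$n[ok])
  out$ci_lower <- out$mean - half
  out$ci_upper <- out$mean + half
  out[do.call(order, out[keys]), , drop = FALSE]
}
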