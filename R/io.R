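#' Load a single-run configuration
#'
#' Reads a YAML file with one key per [sim_params()] field.  Missing keys
#' take the reference defaults; unknown keys are rejected.  An empty file
#' yields the full default parameter set.
#'
#' @param path Path to a YAML file.
#' @return A validated [sim_params()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  allowed <- names(formals(sim_params))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bad <- names(cfg)[vapply(cfg, length, 1L) != 1L]
  if (length(bad)) {
    stop("single-run config fields must be scalars (lists found in: ",
         paste(bad, collapse = ", "), "); use load_sweep_config() for grids",
         call. = FALSE)
  }
  do.call(sim_params, cfg)
}

#' Load a sweep configuration
#'
#' Reads a YAML file in which any swept [sim_params()] field may hold a list
#' of values (cross-product semantics), plus the sweep keys `replicates` and
#' `base_seed` and an optional `generations` override.  Scalar parameter
#' keys override the defaults of the base parameter set.
#'
#' @param path Path to a YAML file.
#' @return A list with `grid` (a [sweep_grid()]-style data.frame),
#'   `replicates`, `base_seed`, `generations` and `params_base`.
#' @export
load_sweep_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  sweepable <- c("number_of_males", "female_radius", "season_duration",
                 "refractory_period_duration", "mate_guarding")
  allowed <- c(names(formals(sim_params)), "replicates", "base_seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  replicates <- if (is.null(cfg$replicates)) 5L else as.integer(cfg$replicates)
  base_seed <- if (is.null(cfg$base_seed)) 1L else as.integer(cfg$base_seed)
  generations <- if (is.null(cfg$generations)) NULL
                 else as.integer(cfg$generations)
  cfg$replicates <- NULL
  cfg$base_seed <- NULL
  cfg$generations <- NULL

  multi <- names(cfg)[vapply(cfg, length, 1L) > 1L]
  bad <- setdiff(multi, sweepable)
  if (length(bad)) {
    stop("only ", paste(sweepable, collapse = ", "),
         " may hold value lists; got lists in: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  grid_args <- cfg[intersect(names(cfg), sweepable)]
  scalars <- cfg[setdiff(names(cfg), sweepable)]
  params_base <- do.call(sim_params, scalars)
  grid <- do.call(sweep_grid, grid_args)
  list(grid = grid, replicates = replicates, base_seed = base_seed,
       generations = generations, params_base = params_base)
}

#' Write / read a sweep table as CSV
#'
#' `write_sweep()` serializes numeric columns at full (17 significant digit)
#' precision so that `read_sweep()` restores a bit-identical table.
#'
#' @param table A `sweep_table`.
#' @param path Output CSV path.
#' @return `write_sweep()` returns `path` invisibly; `read_sweep()` returns
#'   the `sweep_table`.
#' @export
write_sweep <- function(table, path) {
  out <- as.data.frame(table)
  for (cl in names(out)) {
    if (is.double(out[[cl]])) out[[cl]] <- sprintf("%.17g", out[[cl]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if ("mate_guarding" %in% names(tab)) {
    tab$mate_guarding <- as.logical(tab$mate_guarding)
  }
  for (cl in intersect(c("cell", "replicate", "seed", "number_of_males",
                         "female_radius", "season_duration",
                         "refractory_period_duration", "extra_pair"),
                       names(tab))) {
    tab[[cl]] <- as.integer(tab[[cl]])
  }
  class(tab) <- c("sweep_table", "data.frame")
  tab
}

#' Write a regression result as JSON
#'
#' Mirrors the summary-table fields: per-predictor estimate, standard error,
#' t and p values, plus multiple and adjusted R-squared.
#'
#' @param x A `monog_regression`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_regression_json <- function(x, path) {
  stopifnot(inherits(x, "monog_regression"))
  obj <- list(
    coefficients = x$coefficients,
    r_squared = x$r_squared,
    adj_r_squared = x$adj_r_squared,
    n = x$n,
    predictors = x$predictors,
    intercept = x$intercept
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run manifest
#'
#' Captures everything needed to reproduce a sweep bit-identically: the
#' package version, the configuration (echoed and hashed), the base seed and
#' every derived per-run seed.
#'
#' @param params_base A [sim_params()] object (non-swept fields).
#' @param grid The sweep grid used.
#' @param replicates,base_seed Sweep settings.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(params_base, grid, replicates, base_seed) {
  cells <- if ("cell" %in% names(grid)) grid$cell else seq_len(nrow(grid))
  seeds <- outer(cells, seq_len(replicates),
                 function(cl, r) mapply(derive_seed, base_seed, cl, r))
  cfg <- list(params = unclass(params_base),
              grid = as.data.frame(grid),
              replicates = replicates,
              base_seed = base_seed)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg, tmp, version = 2)
  hash <- unname(tools::md5sum(tmp))
  structure(list(
    version = as.character(packageVersion("matesim")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = cfg,
    config_hash = hash,
    base_seed = base_seed,
    seeds = seeds
  ), class = "run_manifest")
}

#' Deterministic miniature fixtures
#'
#' Small worlds and tables used by the validation tests:
#' * `"toy_world_1m1f"`: a 7x1 strip with one polygamous male at (0, 0) and
#'   one female at (6, 0) — under one-patch-per-tick movement they meet at
#'   tick 6.
#' * `"toy_world_2m1f"`: a 5x5 world, one female at (2, 2), male 1 standing
#'   on her patch (distance 0) and male 2 at (2, 4) (distance 2), both
#'   polygamous — the occupant blocks the rival.
#' * `"linear_sweep_table"`: the full sweep grid with a noiseless response
#'   planted in normalized units,
#'   `y = 0.3 + 0.6 males + 0.3 radius - 0.2 duration - 0.15 extra_pair`;
#'   `fit_regression(..., normalize = FALSE)` recovers the coefficients
#'   exactly.
#' * `"neutral_mode_config"`: a small [sim_params()] set with
#'   `neutral = TRUE` for drift validation.
#'
#' @param name Fixture name.
#' @return The fixture object.
#' @export
make_fixture <- function(name) {
  switch(
    name,
    toy_world_1m1f = {
      w <- list(
        width = 7L, height = 1L, wrap = FALSE,
        fx = 6L, fy = 0L,
        f_pregnant = 0L, f_refractory = 0L, f_father = NA_integer_,
        mx = 0L, my = 0L,
        genotype = 0L, partner = NA_integer_, seasons_lived = 0L,
        pool = integer(0), tick = 0L, season = 0L, generation = 1L
      )
      class(w) <- "sim_world"
      w
    },
    toy_world_2m1f = {
      w <- list(
        width = 5L, height = 5L, wrap = FALSE,
        fx = 2L, fy = 2L,
        f_pregnant = 0L, f_refractory = 0L, f_father = NA_integer_,
        mx = c(2L, 2L), my = c(2L, 4L),
        genotype = c(0L, 0L), partner = rep(NA_integer_, 2),
        seasons_lived = c(0L, 0L),
        pool = integer(0), tick = 0L, season = 0L, generation = 1L
      )
      class(w) <- "sim_world"
      w
    },
    linear_sweep_table = {
      g <- sweep_grid()
      norm <- function(x) (x - min(x)) / (max(x) - min(x))
      tab <- data.frame(
        cell = g$cell,
        replicate = 1L,
        seed = 0L,
        number_of_males = norm(g$number_of_males),
        female_radius = norm(g$female_radius),
        season_duration = norm(g$season_duration),
        refractory_period_duration = g$refractory_period_duration,
        mate_guarding = g$mate_guarding,
        extra_pair = as.numeric(!g$mate_guarding)
      )
      tab$percentage_monogamy <- 0.3 + 0.6 * tab$number_of_males +
        0.3 * tab$female_radius - 0.2 * tab$season_duration -
        0.15 * tab$extra_pair
      class(tab) <- c("sweep_table", "data.frame")
      tab
    },
    neutral_mode_config = sim_params(
      number_of_males = 10L, number_of_females = 10L, female_radius = 5L,
      season_duration = 100L, refractory_period_duration = 10L,
      mate_guarding = TRUE, generations = 20L, longevity = 2L,
      neutral = TRUE
    ),
    stop(sprintf("unknown fixture '%s'", name), call. = FALSE)
  )
}
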