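#' Percentage monogamy
#'
#' The primary outcome of a run: the percentage of breeding seasons in which
#' *strictly* more than half the male population carried the monogamous
#' genotype.  A season with exactly half does not count.
#'
#' @param season_counts Integer vector of per-season monogamous-male counts.
#' @param number_of_males Total male population size.
#' @return A percentage in \[0, 100\].
#' @examples
#' percentage_monogamy(c(12, 9, 15, 11), 20)  # 75
#' @export
percentage_monogamy <- function(season_counts, number_of_males) {
  if (length(season_counts) == 0L) {
    stop("'season_counts' must be non-empty", call. = FALSE)
  }
  100 * mean(season_counts > number_of_males / 2)
}

#' Run a full simulation
#'
#' Executes `generations x longevity` breeding seasons: males are dispersed
#' at random patches at each season start, the season runs for
#' `season_duration` ticks ([run_season()]), and after every `longevity`
#' seasons the male cohort is replaced from the trait pool
#' ([generation_turnover()]).
#'
#' @param params A [sim_params()] object.
#' @param seed RNG seed; defaults to `params$seed`.  If `NA`, the current RNG
#'   state is used.
#' @return An object of class `sim_result`: a list with `params`, `seed`,
#'   `seasons` (one row per season: `season`, `generation`,
#'   `monogamous_count`, `pregnancies`, `copulations`), `pool_log` (one row
#'   per generation: `generation`, `pool_size`, `pool_monogamy_fraction`,
#'   logged just before turnover) and `percentage_monogamy`.
#' @examples
#' res <- run_simulation(sim_params(generations = 3, seed = 1))
#' res$percentage_monogamy
#' @export
run_simulation <- function(params = sim_params(), seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed) && !is.na(seed)) set.seed(as.integer(seed))

  world <- new_world(params)
  gens <- params$generations
  lon <- params$longevity
  nsea <- gens * lon

  mono <- integer(nsea)
  pregs <- integer(nsea)
  cops <- numeric(nsea)
  pool_size <- integer(gens)
  pool_frac <- numeric(gens)

  k <- 0L
  for (g in seq_len(gens)) {
    for (s in seq_len(lon)) {
      world <- place_males(world)
      out <- run_season(world, params)
      world <- out$world
      k <- k + 1L
      mono[k] <- out$summary$monogamous_count
      pregs[k] <- out$summary$pregnancies
      cops[k] <- out$summary$copulations
    }
    pool_size[g] <- length(world$pool)
    pool_frac[g] <- if (length(world$pool)) mean(world$pool) else NA_real_
    world <- generation_turnover(world, params)
  }

  res <- list(
    params = params,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    seasons = data.frame(
      season = seq_len(nsea),
      generation = rep(seq_len(gens), each = lon),
      monogamous_count = mono,
      pregnancies = pregs,
      copulations = cops
    ),
    pool_log = data.frame(
      generation = seq_len(gens),
      pool_size = pool_size,
      pool_monogamy_fraction = pool_frac
    ),
    percentage_monogamy = percentage_monogamy(mono, params$number_of_males)
  )
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Simulation result: %d males / %d females (ASR %.0f%%), radius %d, season %d ticks\n",
    p$number_of_males, p$number_of_females,
    adult_sex_ratio(p$number_of_males, p$number_of_females),
    p$female_radius, p$season_duration))
  cat(sprintf("  refractory %d, mate_guarding %s, %d generations x %d seasons\n",
              p$refractory_period_duration, p$mate_guarding,
              p$generations, p$longevity))
  cat(sprintf("  percentage monogamy: %.1f%%\n", x$percentage_monogamy))
  invisible(x)
}
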