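#' Simulation parameters
#'
#' Construct and validate the full parameter set of one simulation run.
#' Defaults are the reference study conditions: 20 females, pregnancy chance
#' 0.05 per copulation, male longevity of 4 breeding seasons, mutation
#' standard deviation 0.35, 150 generations, and a 300-tick season.
#'
#' @param number_of_males Number of male agents (constant over the run).
#' @param number_of_females Number of female agents (fixed territories).
#' @param female_radius Patches between adjacent females on the lattice.
#' @param season_duration Ticks per breeding season; a male moves one patch
#'   per tick.
#' @param refractory_period_duration Ticks a female rejects all males after a
#'   non-conceptive copulation.
#' @param mate_guarding If `TRUE`, a paired monogamous male stays on his
#'   partner's patch, excluding all other males; if `FALSE` he wanders while
#'   she is refractory, which opens a window for extra-pair copulation.
#' @param pregnancy_chance Probability that any one copulation results in
#'   pregnancy.
#' @param longevity Breeding seasons per male generation; all males are
#'   replaced together after this many seasons.
#' @param generations Number of male generations to simulate.
#' @param mutation_sigma Standard deviation of the Gaussian perturbation
#'   applied to the father's genotype at inheritance.
#' @param wrap If `TRUE` the grid is toroidal; the default is a bounded
#'   rectangle.
#' @param proximity_blocking Availability variant: if `TRUE`, a female is
#'   unavailable to a male whenever any other male is strictly closer to her;
#'   the default (`FALSE`) blocks her only while another male occupies her
#'   patch.  See [is_available()].
#' @param neutral Debug flag: both genotypes behave polygamously (no pairing,
#'   no guarding), so the trait is selectively neutral and should drift.
#' @param seed Optional RNG seed stored with the parameters and used by
#'   [run_simulation()].
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params(number_of_males = 15, season_duration = 200)
#' p$number_of_males
#' @export
sim_params <- function(number_of_males = 20L,
                       number_of_females = 20L,
                       female_radius = 20L,
                       season_duration = 300L,
                       refractory_period_duration = 10L,
                       mate_guarding = TRUE,
                       pregnancy_chance = 0.05,
                       longevity = 4L,
                       generations = 150L,
                       mutation_sigma = 0.35,
                       wrap = FALSE,
                       proximity_blocking = FALSE,
                       neutral = FALSE,
                       seed = NULL) {
  p <- list(
    number_of_males = number_of_males,
    number_of_females = number_of_females,
    female_radius = female_radius,
    season_duration = season_duration,
    refractory_period_duration = refractory_period_duration,
    mate_guarding = mate_guarding,
    pregnancy_chance = pregnancy_chance,
    longevity = longevity,
    generations = generations,
    mutation_sigma = mutation_sigma,
    wrap = wrap,
    proximity_blocking = proximity_blocking,
    neutral = neutral,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )

  chk_count <- function(x, name, min = 1L) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) ||
        x != as.integer(x) || x < min) {
      stop(sprintf("'%s' must be a single integer >= %d", name, min),
           call. = FALSE)
    }
    as.integer(x)
  }
  chk_flag <- function(x, name) {
    if (length(x) != 1L || !is.logical(x) || is.na(x)) {
      stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
    }
    x
  }

  p$number_of_males <- chk_count(p$number_of_males, "number_of_males")
  p$number_of_females <- chk_count(p$number_of_females, "number_of_females")
  p$female_radius <- chk_count(p$female_radius, "female_radius")
  p$season_duration <- chk_count(p$season_duration, "season_duration", 0L)
  p$refractory_period_duration <-
    chk_count(p$refractory_period_duration, "refractory_period_duration", 0L)
  p$longevity <- chk_count(p$longevity, "longevity")
  p$generations <- chk_count(p$generations, "generations")
  p$mate_guarding <- chk_flag(p$mate_guarding, "mate_guarding")
  p$wrap <- chk_flag(p$wrap, "wrap")
  p$proximity_blocking <- chk_flag(p$proximity_blocking, "proximity_blocking")
  p$neutral <- chk_flag(p$neutral, "neutral")

  if (length(p$pregnancy_chance) != 1L || !is.numeric(p$pregnancy_chance) ||
      is.na(p$pregnancy_chance) ||
      p$pregnancy_chance < 0 || p$pregnancy_chance > 1) {
    stop("'pregnancy_chance' must be a probability in [0, 1]", call. = FALSE)
  }
  if (length(p$mutation_sigma) != 1L || !is.numeric(p$mutation_sigma) ||
      is.na(p$mutation_sigma) || p$mutation_sigma < 0) {
    stop("'mutation_sigma' must be a non-negative number", call. = FALSE)
  }

  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (sim_params)\n")
  cat(sprintf("  males: %d  females: %d  ASR: %.0f%%\n",
              x$number_of_males, x$number_of_females,
              adult_sex_ratio(x$number_of_males, x$number_of_females)))
  cat(sprintf("  female_radius: %d  season_duration: %d  refractory: %d\n",
              x$female_radius, x$season_duration,
              x$refractory_period_duration))
  cat(sprintf("  mate_guarding: %s  pregnancy_chance: %g\n",
              x$mate_guarding, x$pregnancy_chance))
  cat(sprintf("  longevity: %d  generations: %d  mutation_sigma: %g\n",
              x$longevity, x$generations, x$mutation_sigma))
  if (x$wrap) cat("  toroidal grid\n")
  if (x$proximity_blocking) cat("  proximity-blocking availability rule\n")
  if (x$neutral) cat("  NEUTRAL MODE: genotypes behave identically\n")
  if (!is.na(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Adult sex ratio
#'
#' Percentage of males among the adult population, `100 * m / (m + f)`.
#' With 20 females, 15/20/25 males give ASRs of 43, 50 and 56 percent
#' (rounded).
#'
#' @param number_of_males,number_of_females Adult counts.
#' @return ASR in percent.
#' @examples
#' round(adult_sex_ratio(15, 20))
#' @export
adult_sex_ratio <- function(number_of_males, number_of_females) {
  stopifnot(number_of_males >= 0, number_of_females >= 0,
            number_of_males + number_of_females > 0)
  100 * number_of_males / (number_of_males + number_of_females)
}
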