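#' Is a female available to a candidate male?
#'
#' A female is available iff she is neither pregnant nor refractory and no
#' other male has her locked up.  Two locks exist:
#' * with `mate_guarding` on, a pair-bonded female is unavailable to every
#'   male except her partner — guarding is fully efficient;
#' * under the default rule a female is blocked while another male occupies
#'   her patch; with `proximity_blocking = TRUE` she is blocked whenever any
#'   other male is strictly closer (Chebyshev) than the candidate, distance
#'   ties never blocking.
#'
#' @param world A `sim_world`.
#' @param female,male 1-based agent indices.
#' @param params A [sim_params()] object (supplies `mate_guarding` and
#'   `proximity_blocking`).
#' @return `TRUE` or `FALSE`.
#' @export
is_available <- function(world, female, male, params = sim_params()) {
  cpp_is_available(world, params, as.integer(female), as.integer(male))
}

#' Select a male's target female
#'
#' The nearest available female (see [is_available()]); exact distance ties
#' are broken by the lowest female id.
#'
#' @param world A `sim_world`.
#' @param male 1-based male index.
#' @param params A [sim_params()] object.
#' @return The female id, or `NA_integer_` if no female is available.
#' @export
select_target <- function(world, male, params = sim_params()) {
  t <- cpp_select_target(world, params, as.integer(male))
  if (t == 0L) NA_integer_ else t
}

#' Step one male for one tick
#'
#' Applies the per-tick behaviour rule for a single male:
#' * a paired monogamous male with mate guarding on stays on his partner's
#'   patch and copulates whenever her refractory period ends;
#' * a paired monogamous male with guarding off wanders randomly while she is
#'   refractory (or pregnant) and otherwise moves one patch back toward her,
#'   copulating on arrival — he never courts other females;
#' * any other male moves one patch toward his selected target and copulates
#'   on reaching her patch, or moves to a uniform random neighbour patch when
#'   no female is available.
#'
#' Consumes random draws (movement tie-breaks, copulation outcome).
#'
#' @param world A `sim_world`.
#' @param male 1-based male index.
#' @param params A [sim_params()] object.
#' @return The updated world.
#' @export
step_male <- function(world, male, params) {
  cpp_step_male(world, params, as.integer(male))
}

#' Attempt a copulation
#'
#' With probability `pregnancy_chance` the female becomes pregnant for the
#' rest of the season, recording the father's genotype; otherwise she enters
#' the refractory period.  A monogamous male without a partner pair-bonds
#' with her regardless of the outcome.  Calling this on a pregnant or
#' refractory female is an error.
#'
#' @param world A `sim_world`.
#' @param male,female 1-based agent indices (must be co-located).
#' @param params A [sim_params()] object.
#' @return A list with elements `world` (updated) and `outcome`
#'   (`"pregnant"` or `"refractory"`).
#' @export
attempt_copulation <- function(world, male, female, params) {
  female <- as.integer(female)
  male <- as.integer(male)
  if (world$f_pregnant[female] != 0L || world$f_refractory[female] > 0L) {
    stop("attempt_copulation: female is pregnant or refractory", call. = FALSE)
  }
  cpp_attempt_copulation(world, params, male, female)
}

#' Advance the world by one tick
#'
#' Decrements all positive refractory counters by one, then steps every male
#' once in a freshly shuffled order.
#'
#' @param world A `sim_world`.
#' @param params A [sim_params()] object.
#' @return The updated world.
#' @export
run_tick <- function(world, params) {
  cpp_tick(world, params)
}

#' Run one breeding season
#'
#' Executes exactly `season_duration` ticks, then closes the season: every
#' pregnant female contributes one mutated copy of the father's genotype to
#' the trait pool, pregnancies and refractory states are cleared, and every
#' male's seasons-lived counter increments.  Males are *not* re-dispersed
#' here; call [place_males()] at the start of the next season.
#'
#' @param world A `sim_world` with males already placed.
#' @param params A [sim_params()] object.
#' @return A list with `world` (updated) and `summary`, a one-row data.frame
#'   with `monogamous_count`, `pregnancies` and `copulations`.
#' @export
run_season <- function(world, params) {
  res <- cpp_run_season(world, params)
  w <- res$world
  summary <- data.frame(
    monogamous_count = sum(w$genotype),
    pregnancies = sum(w$f_pregnant),
    copulations = as.numeric(res$copulations)
  )
  w <- contribute_progeny(w, params)
  nf <- length(w$fx)
  w$f_pregnant <- integer(nf)
  w$f_father <- rep(NA_integer_, nf)
  w$f_refractory <- integer(nf)
  w$seasons_lived <- w$seasons_lived + 1L
  w$season <- w$season + 1L
  list(world = w, summary = summary)
}
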