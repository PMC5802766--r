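#' Threshold rounding of a perturbed genotype
#'
#' The model's custom rounding rule: any value greater than or equal to 0.5
#' maps to 1 (monogamous), anything smaller to 0 (polygamous).
#'
#' @param x Numeric vector.
#' @return Integer vector of 0/1.
#' @examples
#' round_genotype(c(0.49, 0.5, 1.2, -0.3))
#' @export
round_genotype <- function(x) {
  as.integer(x >= 0.5)
}

#' Mutate a genotype at inheritance
#'
#' A progeny's genotype is the father's genotype plus Gaussian noise with
#' mean 0 and standard deviation `sigma`, passed through the threshold
#' rounding rule: `G1 = round_genotype(G0 + N(0, sigma))`.  With
#' `sigma = 0.35` the flip probability is `1 - pnorm(0.5 / 0.35)`, about
#' 0.0766, and is symmetric for both genotypes.
#'
#' @param g0 Integer vector of parental genotypes (0 or 1).
#' @param sigma Mutation standard deviation.
#' @return Integer vector of progeny genotypes.
#' @export
mutate_genotype <- function(g0, sigma = 0.35) {
  if (length(g0) == 0L) return(integer(0))
  if (!all(g0 %in% c(0L, 1L))) {
    stop("genotypes must be 0 (polygamous) or 1 (monogamous)", call. = FALSE)
  }
  if (sigma < 0) stop("'sigma' must be non-negative", call. = FALSE)
  round_genotype(g0 + rnorm(length(g0), mean = 0, sd = sigma))
}

#' Contribute progeny to the trait pool
#'
#' At season end, each pregnant female appends exactly one entry to the trait
#' pool: the father's genotype passed through [mutate_genotype()].  The pool
#' accumulates across the seasons of one generation and is consumed at
#' generation turnover.
#'
#' @param world A `sim_world` (pregnancies not yet cleared).
#' @param params A [sim_params()] object (supplies `mutation_sigma`).
#' @return The updated world.
#' @export
contribute_progeny <- function(world, params) {
  preg <- which(world$f_pregnant == 1L)
  if (length(preg)) {
    fathers <- world$f_father[preg]
    if (anyNA(fathers)) {
      stop("pregnant female without recorded father genotype", call. = FALSE)
    }
    world$pool <- c(world$pool,
                    mutate_genotype(fathers, params$mutation_sigma))
  }
  world
}

#' Generation turnover
#'
#' All males die together after `longevity` seasons and are replaced by a new
#' cohort whose genotypes are drawn uniformly with replacement from the trait
#' pool; the pool is then cleared, seasons-lived counters reset and the new
#' males placed at random patches.  The male count never changes, keeping the
#' adult sex ratio constant.  If no female got pregnant during the whole
#' generation the pool is empty; the new cohort then inherits the dying
#' cohort's genotype multiset unchanged (no selection occurred).
#'
#' @param world A `sim_world` at the end of a generation.
#' @param params A [sim_params()] object.
#' @return The updated world, with `generation` incremented.
#' @export
generation_turnover <- function(world, params) {
  nm <- length(world$genotype)
  if (length(world$pool) == 0L) {
    newg <- world$genotype
  } else {
    newg <- world$pool[sample.int(length(world$pool), nm, replace = TRUE)]
  }
  world$genotype <- as.integer(newg)
  world$pool <- integer(0)
  world$seasons_lived <- integer(nm)
  world$generation <- world$generation + 1L
  place_males(world)
}

#' First-generation male genotypes
#'
#' Each founding male has an equal chance of being monogamous (1) or
#' polygamous (0): independent Bernoulli(0.5) draws.
#'
#' @param params A [sim_params()] object.
#' @return Integer vector of length `number_of_males`.
#' @export
init_first_generation <- function(params) {
  as.integer(runif(params$number_of_males) < 0.5)
}
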