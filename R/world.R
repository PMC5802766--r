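#' Place females on a regular lattice
#'
#' Females hold fixed, regularly spaced territories: a rows x cols lattice
#' with nearest-neighbour spacing of exactly `female_radius` patches, centred
#' in a bounded world of `cols * female_radius` by `rows * female_radius`
#' patches.  The lattice is the most-square factorization,
#' `cols = ceiling(sqrt(n))`, filled row-major.
#'
#' @param params A [sim_params()] object.
#' @return A data.frame with columns `id`, `x`, `y` (0-based patch
#'   coordinates) and attributes `width` and `height`.
#' @examples
#' place_females(sim_params(number_of_females = 20, female_radius = 5))
#' @export
place_females <- function(params) {
  n <- params$number_of_females
  r <- params$female_radius
  if (n < 1 || r < 1) {
    stop("number_of_females and female_radius must be positive", call. = FALSE)
  }
  cols <- ceiling(sqrt(n))
  rows <- ceiling(n / cols)
  width <- cols * r
  height <- rows * r
  off <- (r - 1L) %/% 2L
  idx <- seq_len(n) - 1L
  out <- data.frame(
    id = seq_len(n),
    x = off + (idx %% cols) * r,
    y = off + (idx %/% cols) * r
  )
  attr(out, "width") <- as.integer(width)
  attr(out, "height") <- as.integer(height)
  out
}

#' Create a fresh simulation world
#'
#' Builds the world for one run: females placed on their lattice, first-
#' generation male genotypes drawn (each monogamous with probability 0.5),
#' males dispersed at random patches, all counters zeroed and the trait pool
#' empty.  Consumes random draws; seed beforehand for reproducibility.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `sim_world`: a named list of state vectors
#'   (`fx`, `fy`, `f_pregnant`, `f_refractory`, `f_father`, `mx`, `my`,
#'   `genotype`, `partner`, `seasons_lived`, `pool`, counters).
#' @export
new_world <- function(params) {
  pf <- place_females(params)
  nf <- params$number_of_females
  nm <- params$number_of_males
  world <- list(
    width = attr(pf, "width"),
    height = attr(pf, "height"),
    wrap = params$wrap,
    fx = as.integer(pf$x),
    fy = as.integer(pf$y),
    f_pregnant = integer(nf),
    f_refractory = integer(nf),
    f_father = rep(NA_integer_, nf),
    mx = integer(nm),
    my = integer(nm),
    genotype = init_first_generation(params),
    partner = rep(NA_integer_, nm),
    seasons_lived = integer(nm),
    pool = integer(0),
    tick = 0L,
    season = 0L,
    generation = 1L
  )
  class(world) <- "sim_world"
  place_males(world)
}

#' Disperse males at random patches
#'
#' Assigns every male an independent uniform-random patch and dissolves all
#' pair bonds; called at the start of each breeding season.
#'
#' @param world A `sim_world` object.
#' @return The updated world.
#' @export
place_males <- function(world) {
  nm <- length(world$mx)
  world$mx <- as.integer(sample.int(world$width, nm, replace = TRUE) - 1L)
  world$my <- as.integer(sample.int(world$height, nm, replace = TRUE) - 1L)
  world$partner <- rep(NA_integer_, nm)
  world
}

#' @export
print.sim_world <- function(x, ...) {
  cat(sprintf("Simulation world %dx%d patches%s\n", x$width, x$height,
              if (isTRUE(x$wrap)) " (toroidal)" else ""))
  cat(sprintf("  %d females (%d pregnant, %d refractory), %d males (%d monogamous)\n",
              length(x$fx), sum(x$f_pregnant), sum(x$f_refractory > 0),
              length(x$mx), sum(x$genotype)))
  cat(sprintf("  generation %d, season %d, tick %d, trait pool size %d\n",
              x$generation, x$season, x$tick, length(x$pool)))
  invisible(x)
}

#' Chebyshev patch distance
#'
#' Distance metric of the model: number of 8-neighbour king moves between two
#' patches, respecting the world's wrap flag.
#'
#' @param world A `sim_world` (supplies dimensions and topology).
#' @param x1,y1,x2,y2 Patch coordinates.
#' @return Integer distance (vectorised).
#' @export
patch_distance <- function(world, x1, y1, x2, y2) {
  dx <- abs(x1 - x2)
  dy <- abs(y1 - y2)
  if (isTRUE(world$wrap)) {
    dx <- pmin(dx, world$width - dx)
    dy <- pmin(dy, world$height - dy)
  }
  as.integer(pmax(dx, dy))
}
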