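# Independent brute-force oracles, written directly from the behavioural
# rules and kept free of the package's engine code paths.

chebyshev <- function(x1, y1, x2, y2) pmax(abs(x1 - x2), abs(y1 - y2))

# Availability rule re-derived from scratch: neither pregnant nor refractory,
# not pair-bonded to another male when guarding is on, and not locked by the
# distance rule (default: another male on her patch; proximity variant: any
# other male strictly closer -- ties never block).
oracle_available <- function(world, f, m, mate_guarding = TRUE,
                             proximity_blocking = FALSE) {
  if (world$f_pregnant[f] == 1L || world$f_refractory[f] > 0L) return(FALSE)
  others <- setdiff(seq_along(world$mx), m)
  if (mate_guarding && any(world$partner[others] == f, na.rm = TRUE)) {
    return(FALSE)
  }
  d <- chebyshev(world$mx[m], world$my[m], world$fx[f], world$fy[f])
  dists <- chebyshev(world$mx[others], world$my[others],
                     world$fx[f], world$fy[f])
  if (proximity_blocking) !any(dists < d) else d == 0L || !any(dists == 0L)
}

# A random small bounded world with arbitrary agent states.
random_toy_world <- function(nm = 3L, nf = 2L, size = 5L) {
  w <- list(
    width = size, height = size, wrap = FALSE,
    fx = sample.int(size, nf, replace = TRUE) - 1L,
    fy = sample.int(size, nf, replace = TRUE) - 1L,
    f_pregnant = sample(0:1, nf, replace = TRUE, prob = c(0.7, 0.3)),
    f_refractory = sample(0:3, nf, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
    f_father = rep(NA_integer_, nf),
    mx = sample.int(size, nm, replace = TRUE) - 1L,
    my = sample.int(size, nm, replace = TRUE) - 1L,
    genotype = sample(0:1, nm, replace = TRUE),
    partner = rep(NA_integer_, nm),
    seasons_lived = integer(nm),
    pool = integer(0), tick = 0L, season = 0L, generation = 1L
  )
  w$f_father[w$f_pregnant == 1L] <- 0L
  w$f_refractory[w$f_pregnant == 1L] <- 0L
  class(w) <- "sim_world"
  w
}

# A hand-buildable world: explicit agent coordinates and states.
toy_world <- function(fx, fy, mx, my, width = 10L, height = 10L,
                      genotype = rep(0L, length(mx)),
                      partner = rep(NA_integer_, length(mx)),
                      f_pregnant = rep(0L, length(fx)),
                      f_refractory = rep(0L, length(fx))) {
  w <- list(
    width = as.integer(width), height = as.integer(height), wrap = FALSE,
    fx = as.integer(fx), fy = as.integer(fy),
    f_pregnant = as.integer(f_pregnant),
    f_refractory = as.integer(f_refractory),
    f_father = rep(NA_integer_, length(fx)),
    mx = as.integer(mx), my = as.integer(my),
    genotype = as.integer(genotype),
    partner = as.integer(partner),
    seasons_lived = integer(length(mx)),
    pool = integer(0), tick = 0L, season = 0L, generation = 1L
  )
  class(w) <- "sim_world"
  w
}
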