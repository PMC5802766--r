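params0 <- sim_params(pregnancy_chance = 0, refractory_period_duration = 10,
                      season_duration = 200)

test_that("availability: pregnant or refractory females refuse every male", {
  w <- toy_world(fx = 2, fy = 2, mx = c(0, 4), my = c(2, 2), width = 5, height = 5)
  expect_true(is_available(w, 1, 1))
  w$f_pregnant <- 1L
  expect_false(is_available(w, 1, 1))
  expect_false(is_available(w, 1, 2))
  w$f_pregnant <- 0L
  w$f_refractory <- 3L
  expect_false(is_available(w, 1, 1))
})

test_that("availability: an occupant male blocks her, distant rivals do not", {
  # male 1 at distance 2, male 2 at distance 5: neither occupies her patch
  w <- toy_world(fx = 5, fy = 0, mx = c(3, 0), my = c(0, 0), width = 11, height = 1)
  expect_true(is_available(w, 1, 1))
  expect_true(is_available(w, 1, 2))
  # a male on her patch (distance 0) blocks everyone else but not himself
  w3 <- toy_world(fx = 2, fy = 2, mx = c(2, 3), my = c(2, 2), width = 5, height = 5)
  expect_true(is_available(w3, 1, 1))
  expect_false(is_available(w3, 1, 2))
})

test_that("with guarding on, a pair-bonded female refuses everyone but her partner", {
  w <- toy_world(fx = 2, fy = 2, mx = c(2, 3), my = c(2, 2), width = 5, height = 5,
                 genotype = c(1L, 0L), partner = c(1L, NA))
  pg <- sim_params(mate_guarding = TRUE)
  png <- sim_params(mate_guarding = FALSE)
  expect_true(is_available(w, 1, 1, pg))
  expect_false(is_available(w, 1, 2, pg))
  # even a rival standing on her patch is refused while she is guarded
  w$mx[2] <- 2L; w$my[2] <- 2L
  expect_false(is_available(w, 1, 2, pg))
  # without guarding the bond does not lock her: once her partner has
  # wandered off her patch she is open to extra-pair copulation
  w$mx[1] <- 3L; w$mx[2] <- 4L
  expect_true(is_available(w, 1, 2, png))
})

test_that("proximity variant: a strictly closer male blocks, a tie does not", {
  pp <- sim_params(proximity_blocking = TRUE)
  # male 1 at distance 2, male 2 at distance 5
  w <- toy_world(fx = 5, fy = 0, mx = c(3, 0), my = c(0, 0), width = 11, height = 1)
  expect_true(is_available(w, 1, 1, pp))
  expect_false(is_available(w, 1, 2, pp))
  # equal distances: neither blocks the other
  w2 <- toy_world(fx = 2, fy = 2, mx = c(0, 4), my = c(2, 2), width = 5, height = 5)
  expect_true(is_available(w2, 1, 1, pp))
  expect_true(is_available(w2, 1, 2, pp))
})

test_that("availability agrees with a brute-force oracle on random toy worlds", {
  set.seed(99)
  for (case in 1:60) {
    w <- random_toy_world(nm = 3, nf = 2, size = 5)
    # occasionally pair a monogamous male to a female
    if (case %% 3 == 0) {
      w$genotype[1] <- 1L
      w$partner[1] <- 1L
    }
    for (prox in c(FALSE, TRUE)) for (mg in c(TRUE, FALSE)) {
      p <- sim_params(proximity_blocking = prox, mate_guarding = mg)
      for (f in 1:2) for (m in 1:3) {
        expect_equal(is_available(w, f, m, p),
                     oracle_available(w, f, m, mate_guarding = mg,
                                      proximity_blocking = prox),
                     info = sprintf("case %d prox %s guard %s female %d male %d",
                                    case, prox, mg, f, m))
      }
    }
  }
})

test_that("target selection: nearest available female, ties to lowest id", {
  # two available females at distances 4 and 9
  w <- toy_world(fx = c(4, 9), fy = c(0, 0), mx = 0, my = 0,
                 width = 10, height = 1)
  expect_equal(select_target(w, 1), 1L)
  # nearer one pregnant -> farther one chosen
  w$f_pregnant <- c(1L, 0L)
  expect_equal(select_target(w, 1), 2L)
  # all pregnant -> none
  w$f_pregnant <- c(1L, 1L)
  expect_true(is.na(select_target(w, 1)))
  # equal distances -> lowest id, stable under female relabelling
  w2 <- toy_world(fx = c(3, 3), fy = c(0, 4), mx = 3, my = 2,
                  width = 7, height = 7)
  expect_equal(select_target(w2, 1), 1L)
  w3 <- toy_world(fx = c(3, 3), fy = c(4, 0), mx = 3, my = 2,
                  width = 7, height = 7)
  expect_equal(select_target(w3, 1), 1L)
})

test_that("a searching male closes exactly one patch of distance per tick", {
  w <- make_fixture("toy_world_1m1f")
  for (k in 1:6) {
    w <- step_male(w, 1, params0)
    expect_equal(patch_distance(w, w$mx, w$my, w$fx, w$fy), 6L - k)
  }
  # on arrival at tick 6 he copulated: pregnancy_chance 0 -> she is refractory
  expect_equal(w$f_refractory, 10L)
})

test_that("a male with no available female makes a one-patch random move", {
  set.seed(5)
  w <- toy_world(fx = 4, fy = 4, mx = 2, my = 2, width = 9, height = 9,
                 f_pregnant = 1L)
  for (k in 1:20) {
    before <- c(w$mx, w$my)
    w <- step_male(w, 1, params0)
    expect_equal(chebyshev(before[1], before[2], w$mx, w$my), 1L)
  }
})

test_that("copulation outcome follows pregnancy_chance and records the father", {
  w <- toy_world(fx = 0, fy = 0, mx = 0, my = 0, genotype = 1L)
  p1 <- sim_params(pregnancy_chance = 1)
  out <- attempt_copulation(w, 1, 1, p1)
  expect_equal(out$outcome, "pregnant")
  expect_equal(out$world$f_pregnant, 1L)
  expect_equal(out$world$f_father, 1L)
  expect_equal(out$world$f_refractory, 0L)
  # monogamous male pair-bonds regardless of outcome
  expect_equal(out$world$partner, 1L)

  out0 <- attempt_copulation(w, 1, 1, params0)
  expect_equal(out0$outcome, "refractory")
  expect_equal(out0$world$f_refractory, 10L)
  expect_equal(out0$world$f_pregnant, 0L)
  expect_equal(out0$world$partner, 1L)

  # violating the precondition is an error, not a silent no-op
  expect_error(attempt_copulation(out$world, 1, 1, p1), "pregnant")
  expect_error(attempt_copulation(out0$world, 1, 1, p1), "refractory")
})

test_that("pregnancy frequency matches pregnancy_chance", {
  set.seed(31)
  w <- toy_world(fx = 0, fy = 0, mx = 0, my = 0)
  p <- sim_params(pregnancy_chance = 0.05)
  hits <- 0L
  n <- 20000L
  for (i in seq_len(n)) {
    out <- attempt_copulation(w, 1, 1, p)
    if (out$outcome == "pregnant") hits <- hits + 1L
  }
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(hits / n - 0.05), 4 * se)
})

test_that("a guarding male stays put and copulates the tick her refractory ends", {
  # paired monogamous male on his partner's patch, she is refractory for 10
  w <- toy_world(fx = 3, fy = 3, mx = 3, my = 3, width = 7, height = 7,
                 genotype = 1L, partner = 1L, f_refractory = 10L)
  for (k in 1:9) {
    w <- run_tick(w, params0)
    expect_equal(c(w$mx, w$my), c(3L, 3L))
    expect_equal(w$f_refractory, 10L - k)
  }
  w <- run_tick(w, params0)  # counter hits 0, he copulates immediately
  expect_equal(c(w$mx, w$my), c(3L, 3L))
  expect_equal(w$f_refractory, 10L)
})

test_that("guarding keeps the pair co-located and excludes rivals all season", {
  set.seed(17)
  p <- sim_params(number_of_males = 6, number_of_females = 4,
                  female_radius = 5, season_duration = 150,
                  mate_guarding = TRUE)
  w <- new_world(p)
  w$genotype <- rep(1L, 6)  # all monogamous to maximise pairing
  for (t in 1:150) {
    w <- run_tick(w, p)
    paired <- which(!is.na(w$partner))
    for (m in paired) {
      f <- w$partner[m]
      expect_equal(patch_distance(w, w$mx[m], w$my[m], w$fx[f], w$fy[f]), 0L)
      rivals <- setdiff(seq_along(w$mx), m)
      expect_false(any(vapply(rivals, function(r) is_available(w, f, r),
                              logical(1))))
    }
  }
})

test_that("non-guarding monogamous male wanders while partner is refractory, then returns", {
  png <- sim_params(pregnancy_chance = 0, refractory_period_duration = 30,
                    mate_guarding = FALSE)
  w <- toy_world(fx = 5, fy = 5, mx = 5, my = 5, width = 11, height = 11,
                 genotype = 1L, partner = 1L, f_refractory = 30L)
  moved <- FALSE
  for (k in 1:29) {
    before <- c(w$mx, w$my)
    w <- run_tick(w, png)
    step <- chebyshev(before[1], before[2], w$mx, w$my)
    expect_equal(step, 1L)  # unbiased random walk, one patch per tick
    if (!identical(c(w$mx, w$my), c(5L, 5L))) moved <- TRUE
  }
  expect_true(moved)
  # once she is receptive again he closes in and copulates on arrival
  d <- patch_distance(w, w$mx, w$my, w$fx, w$fy)
  for (k in seq_len(d + 1)) w <- run_tick(w, png)
  expect_equal(w$f_refractory, 30L - patch_distance(w, w$mx, w$my, w$fx, w$fy))
})

test_that("a zero-length season changes nothing", {
  set.seed(4)
  p <- sim_params(season_duration = 0)
  w <- new_world(p)
  out <- run_season(w, p)
  expect_equal(out$summary$copulations, 0)
  expect_equal(out$summary$pregnancies, 0L)
  expect_identical(out$world$pool, integer(0))
  expect_identical(out$world$mx, w$mx)
})

test_that("guarded-pair copulation schedule is exactly every refractory-period ticks", {
  # one monogamous male alone with one female on a 1x1 world:
  # copulations at ticks 1, 1+r, 1+2r, ... with pregnancy_chance 0
  p <- sim_params(number_of_males = 1, number_of_females = 1,
                  female_radius = 1, season_duration = 200,
                  refractory_period_duration = 10, pregnancy_chance = 0)
  set.seed(8)
  w <- new_world(p)
  w$genotype <- 1L
  out <- run_season(w, p)
  expect_equal(out$summary$copulations, floor((200 - 1) / 10) + 1)  # 20
})

test_that("season pregnancy probability of an isolated pair matches the closed form", {
  # with copulations every r ticks from tick 1, the number of independent
  # pregnancy trials in a season is N = floor((T - 1)/r) + 1
  p <- sim_params(number_of_males = 1, number_of_females = 1,
                  female_radius = 1, season_duration = 200,
                  refractory_period_duration = 10, pregnancy_chance = 0.05,
                  longevity = 1, generations = 3000)
  res <- run_simulation(p, seed = 123)
  n_trials <- floor((200 - 1) / 10) + 1
  p_closed <- 1 - (1 - 0.05)^n_trials
  phat <- mean(res$seasons$pregnancies)
  se <- sqrt(p_closed * (1 - p_closed) / nrow(res$seasons))
  expect_lt(abs(phat - p_closed), 4 * se)
})

test_that("a pregnant female is never copulated with again within the season", {
  set.seed(12)
  p <- sim_params(number_of_males = 8, number_of_females = 4,
                  female_radius = 5, season_duration = 120,
                  pregnancy_chance = 0.2)
  w <- new_world(p)
  pregnant_at <- rep(NA_integer_, 4)
  for (t in 1:120) {
    w <- run_tick(w, p)
    newly <- which(w$f_pregnant == 1L & is.na(pregnant_at))
    pregnant_at[newly] <- t
    # a pregnant female must stay pregnant and non-refractory
    known <- which(!is.na(pregnant_at))
    expect_true(all(w$f_pregnant[known] == 1L))
    expect_true(all(w$f_refractory[known] == 0L))
  }
  expect_true(any(!is.na(pregnant_at)))
})

test_that("population sizes and female positions are invariant over a run", {
  p <- sim_params(number_of_males = 10, number_of_females = 6,
                  female_radius = 5, season_duration = 50,
                  generations = 2, longevity = 2)
  set.seed(3)
  w <- new_world(p)
  fx0 <- w$fx; fy0 <- w$fy
  for (g in 1:2) {
    for (s in 1:2) {
      w <- place_males(w)
      out <- run_season(w, p)
      w <- out$world
      expect_length(w$mx, 10L)
      expect_length(w$fx, 6L)
      expect_identical(w$fx, fx0)
      expect_identical(w$fy, fy0)
    }
    w <- generation_turnover(w, p)
    expect_length(w$genotype, 10L)
  }
})
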