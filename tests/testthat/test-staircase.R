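test_that("staircase steps follow the transformed up-down rule", {
  sc <- staircase_spec(n_up = 1, n_down = 2,
                       step_schedule = c(0.115, 0.075, 0.05, 0.04),
                       n_trials = 50, start_radius = 2)
  st <- staircase_init(sc)
  # two consecutive "circle" responses decrement log10 radius by 0.115
  st <- staircase_step(st, "circle")
  expect_equal(staircase_radius(st), 2)        # no move yet
  st <- staircase_step(st, "circle")
  expect_equal(log10(staircase_radius(st)), log10(2) - 0.115,
               tolerance = 1e-12)
  # one "rectangle" response bumps it up (1-up) and counts a reversal
  st <- staircase_step(st, "rectangle")
  expect_equal(st$reversals, 1L)
  expect_equal(log10(staircase_radius(st)), log10(2) - 0.115 + 0.115,
               tolerance = 1e-12)
})

test_that("the step schedule advances on reversals, from the next update", {
  sc <- staircase_spec(1, 1, c(0.115, 0.075, 0.05, 0.04), 50, 1)
  st <- staircase_init(sc)
  st <- staircase_step(st, "circle")     # down 0.115, no reversal yet
  st <- staircase_step(st, "rectangle")  # up, reversal 1, still 0.115
  lr1 <- log10(staircase_radius(st))
  st <- staircase_step(st, "circle")     # down, reversal 2, uses 0.075
  expect_equal(log10(staircase_radius(st)), lr1 - 0.075, tolerance = 1e-12)
  st <- staircase_step(st, "rectangle")  # reversal 3 epoch: 0.05
  expect_equal(st$reversals, 3L)
  lr3 <- log10(staircase_radius(st))
  st <- staircase_step(st, "rectangle")  # run continues: step 0.04 now
  expect_equal(log10(staircase_radius(st)), lr3 + 0.04, tolerance = 1e-12)
  # all later steps stay at the terminal 0.04
  for (resp in c("circle", "rectangle", "circle", "rectangle")) {
    lr <- log10(staircase_radius(st))
    st <- staircase_step(st, resp)
    expect_equal(abs(log10(staircase_radius(st)) - lr), 0.04,
                 tolerance = 1e-12)
  }
})

test_that("a constant responder drives a monotone track with zero reversals", {
  sc <- staircase_spec(1, 2, c(0.115, 0.075, 0.05, 0.04), 30, 2)
  st <- staircase_init(sc)
  radii <- numeric(0)
  while (!st$terminated) {
    radii <- c(radii, staircase_radius(st))
    st <- staircase_step(st, "rectangle")
  }
  expect_true(all(diff(radii) >= 0))
  expect_true(all(radii > 0))
  expect_equal(st$reversals, 0L)
  expect_error(staircase_step(st, "circle"), "terminated")
})

test_that("interleaved runs conserve per-staircase trial counts", {
  sp <- gaussian_type_spec(seed = 8)
  rects <- design_rectangles(exp1_design(), 4.88)
  sc <- motorlottery:::design_staircases(exp1_design(), rects)
  trials <- run_staircases(sc$specs, sc$rects, choice_responder(sp),
                           seed = 8)
  expect_equal(nrow(trials), 20 * 50)                # full first design
  expect_true(all(table(trials$staircase_id) == 50))
  expect_true(all(trials$circle_r_mm > 0))
  # second design: 8 x 60
  rects2 <- design_rectangles(exp2_design(), 4.88)
  sc2 <- motorlottery:::design_staircases(exp2_design(), rects2)
  trials2 <- run_staircases(sc2$specs, sc2$rects, choice_responder(sp),
                            seed = 8)
  expect_equal(nrow(trials2), 8 * 60)
  # determinism
  trials3 <- run_staircases(sc2$specs, sc2$rects, choice_responder(sp),
                            seed = 8)
  expect_identical(trials2, trials3)
})

test_that("staircases converge to their nominal tracking percentiles", {
  # Weibull responder with known parameters; the tracked probability of a
  # 1-up/2-down rule is sqrt(1/2) ~ 70.7%, of 2-up/1-down 29.3%, of
  # 1-up/1-down 50%
  a <- 2; g <- 6
  p_of_r <- function(r) 1 - exp(-(r / a)^g)
  r_at <- function(p) a * (-log(1 - p))^(1 / g)
  rules <- list(c(1, 2), c(2, 1), c(1, 1))
  targets <- c(sqrt(0.5), 1 - sqrt(0.5), 0.5)
  set.seed(99)
  for (k in seq_along(rules)) {
    finals <- replicate(500, {
      sc <- staircase_spec(rules[[k]][1], rules[[k]][2],
                           c(0.115, 0.075, 0.05, 0.04), 50, 2)
      st <- staircase_init(sc)
      tail_r <- numeric(0)
      while (!st$terminated) {
        r <- staircase_radius(st)
        if (st$trials_done >= 30) tail_r <- c(tail_r, r)
        st <- staircase_step(st,
          if (runif(1) < p_of_r(r)) "circle" else "rectangle")
      }
      mean(log(tail_r))
    })
    conv <- exp(mean(finals))
    expect_equal(conv, r_at(targets[k]),
                 tolerance = 3 * sd(finals) / sqrt(500) / r_at(targets[k]) +
                   0.03)
  }
})

test_that("a deterministic responder oscillates within one terminal step", {
  thr <- 2.3
  sc <- staircase_spec(1, 1, c(0.15, 0.10, 0.08, 0.06), 60, 1.5)
  st <- staircase_init(sc)
  radii <- numeric(0)
  while (!st$terminated) {
    r <- staircase_radius(st)
    radii <- c(radii, r)
    st <- staircase_step(st, if (r > thr) "circle" else "rectangle")
  }
  late <- log10(radii[40:60])
  expect_lt(max(late) - min(late), 2 * 0.06 + 1e-9)
  expect_lt(abs(mean(late) - log10(thr)), 0.06 + 1e-9)
})
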