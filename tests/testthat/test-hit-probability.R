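test_that("rectangle hit probability matches closed forms and limits", {
  # w = 2 sigma_h, h = 2 sigma_v: erf(1/sqrt(2))^2
  p <- rect_hit_prob(rect_target(8, 11.52), 4, 5.76)
  expect_equal(p, (2 * pnorm(1) - 1)^2, tolerance = 1e-12)
  # total mass and vanishing-width limits
  expect_equal(rect_hit_prob(rect_target(1e4, 1e4), 4, 5.76), 1,
               tolerance = 1e-12)
  expect_lt(rect_hit_prob(rect_target(1e-9, 10), 4, 5.76), 1e-9)
  expect_error(rect_hit_prob(circle_target(1), 4, 5.76), "rectangle")
})

test_that("circle hit probability matches the Rayleigh closed form and quadrature", {
  # isotropic: P(r) = 1 - exp(-r^2 / 2 sigma^2); r = sigma sqrt(2 ln 2) -> 1/2
  expect_equal(circle_hit_prob(circle_target(4 * sqrt(2 * log(2))), 4, 4),
               0.5, tolerance = 1e-10)
  for (r in c(0.5, 2, 5, 12)) {
    expect_equal(circle_hit_prob(circle_target(r), 4, 4),
                 1 - exp(-r^2 / 32), tolerance = 1e-9)
  }
  # anisotropic case against adaptive quadrature
  ref <- integrate(function(x) dnorm(x, 0, 4) *
                     (pnorm(sqrt(25 - x^2) / 5.76) -
                        pnorm(-sqrt(25 - x^2) / 5.76)),
                   -5, 5, rel.tol = 1e-13, abs.tol = 1e-13)$value
  expect_equal(circle_hit_prob(circle_target(5), 4, 5.76), ref,
               tolerance = 1e-10)
  expect_lt(circle_hit_prob(circle_target(1e-8), 4, 5.76), 1e-12)
})

test_that("quadratures agree with Monte-Carlo oracles within 3 MC SE", {
  cases <- list(
    list(shape = rect_target(8, 4), rho = 0),
    list(shape = rect_target(3, 12), rho = 0.4),
    list(shape = circle_target(5), rho = 0),
    list(shape = circle_target(9, center = c(3, -2)), rho = 0))
  for (cs in cases) {
    mc <- mc_hit_prob(cs$shape, 4, 5.76, rho = cs$rho, n = 1e6,
                      seed = 17 + cs$rho * 10)
    p <- if (cs$shape$kind == "rectangle")
      rect_hit_prob(cs$shape, 4, 5.76, rho = cs$rho)
    else circle_hit_prob(cs$shape, 4, 5.76, rho = cs$rho)
    expect_lt(abs(p - mc$p), 3 * mc$se)
  }
})

test_that("hit probability is monotone in target size", {
  sizes <- seq(1, 12, length.out = 8)
  p_rect <- vapply(sizes, function(s)
    rect_hit_prob(rect_target(s, 5), 4, 5.76), numeric(1))
  p_circ <- vapply(sizes, function(s)
    circle_hit_prob(circle_target(s), 4, 5.76), numeric(1))
  expect_true(all(diff(p_rect) > 0))
  expect_true(all(diff(p_circ) > 0))
})

test_that("swapping rectangle orientation and inverting anisotropy is a symmetry", {
  m1 <- gaussian_internal_model(20, 1.44)
  m2 <- gaussian_internal_model(20, 1 / 1.44)
  expect_equal(model_hit_prob(rect_target(8, 2), m1),
               model_hit_prob(rect_target(2, 8), m2), tolerance = 1e-12)
  expect_equal(equivalent_radius(rect_target(8, 2), m1),
               equivalent_radius(rect_target(2, 8), m2), tolerance = 1e-9)
})

test_that("equivalent radius solves the indifference equation", {
  # area-matching identity
  expect_equal(equivalent_radius(rect_target(4, 1), area_matching_model()),
               sqrt(4 / pi), tolerance = 1e-12)
  # Gaussian isotropic, 2x2 square vs brute-force grid oracle
  m <- gaussian_internal_model(1, 1)
  r_eq <- equivalent_radius(rect_target(2, 2), m)
  grid <- seq(0.5, 2, by = 1e-5)
  target <- (2 * pnorm(1) - 1)^2
  oracle <- grid[which.min(abs((1 - exp(-grid^2 / 2)) - target))]
  expect_equal(r_eq, oracle, tolerance = 1e-4)
  # the defining equation holds to tight tolerance
  expect_equal(circle_hit_prob(circle_target(r_eq), 1, 1),
               rect_hit_prob(rect_target(2, 2), 1, 1), tolerance = 1e-8)
  # anisotropic case too
  m2 <- gaussian_internal_model(9, 1.5)
  r2 <- equivalent_radius(rect_target(6, 1.5), m2)
  sds <- motorlottery:::gaussian_model_sds(m2)
  expect_equal(circle_hit_prob(circle_target(r2), sds[[1]], sds[[2]]),
               rect_hit_prob(rect_target(6, 1.5), sds[[1]], sds[[2]]),
               tolerance = 1e-8)
})

test_that("equivalent radius approaches the area radius as internal variance grows", {
  rect <- rect_target(4, 1)
  r_area <- sqrt(4 / pi)
  r_small <- equivalent_radius(rect, gaussian_internal_model(0.5, 1))
  r_big <- equivalent_radius(rect, gaussian_internal_model(1e6, 1))
  expect_equal(r_big, r_area, tolerance = 1e-5)
  # for an isotropic model a circle beats an equal-area rectangle, so the
  # equivalent radius falls below the area radius at finite variance
  expect_lt(r_small, r_area)
  # and the approach is monotone
  s2s <- c(0.5, 2, 8, 32, 128)
  rs <- vapply(s2s, function(s2)
    equivalent_radius(rect, gaussian_internal_model(s2, 1)), numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_true(all(rs < r_area))
})

test_that("choice order is invariant under monotone probability distortion", {
  m <- gaussian_internal_model(23, 1.2)
  shapes <- list(rect_target(8, 2), rect_target(2, 8), circle_target(2.5),
                 circle_target(1.6), rect_target(5, 5))
  p <- vapply(shapes, model_hit_prob, numeric(1), model = m)
  for (f in list(function(x) x^0.6, function(x) log(x + 1e-9),
                 function(x) 1 - exp(-3 * x), stats::qnorm)) {
    w <- f(p)
    expect_equal(order(w), order(p))
  }
})
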