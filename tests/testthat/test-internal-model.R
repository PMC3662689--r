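exp1_rects <- function(sigma_bar = 4.88)
  design_rectangles(exp1_design(), sigma_bar)

test_that("noiseless radii identify the generating Gaussian model", {
  rects <- exp1_rects()
  gen <- gaussian_internal_model(23.04, 1.44)
  r <- vapply(rects, equivalent_radius, numeric(1), model = gen)
  fit <- fit_gaussian_model(r, rects)
  expect_equal(fit$sigma2_tilde, 23.04, tolerance = 1e-3)
  expect_equal(fit$eta_tilde, 1.44, tolerance = 1e-3)
  expect_lte(fit$sigma_e, 1e-5)
})

test_that("area model has closed-form residuals and dominates exact area data", {
  rects <- exp1_rects()
  r_area <- vapply(rects, function(rc) sqrt(rc$w * rc$h / pi), numeric(1))
  # constant multiplicative offset c: sigma_e = |log c|
  for (c0 in c(0.8, 1.25)) {
    fa <- fit_area_model(r_area * c0, rects)
    expect_equal(fa$sigma_e, abs(log(c0)), tolerance = 1e-10)
  }
  # exact area-matching radii: the nested test must favor area matching
  fit <- fit_internal_model(r_area, rects)
  expect_identical(fit$type, "area_matching")
  expect_lte(fit$lambda, qchisq(0.95, 2))
})

test_that("area-model residual SD is estimated without bias", {
  rects <- exp1_rects()
  r_area <- vapply(rects, function(rc) sqrt(rc$w * rc$h / pi), numeric(1))
  set.seed(77)
  n_rep <- 500
  est <- replicate(n_rep, {
    fit_area_model(r_area * exp(rnorm(10, 0, 0.05)), rects)$sigma_e
  })
  # the MLE sqrt(mean residual^2) at n = 10 carries a small-sample bias, so
  # compare against its simulated sampling distribution rather than 0.05
  ref <- mean(replicate(2000, sqrt(mean(rnorm(10, 0, 0.05)^2))))
  expect_lt(abs(mean(est) - ref), 3 * sd(est) / sqrt(n_rep))
})

test_that("classification applies the chi-square criterion with 2 df", {
  # lambda = 2 below the 5.99 criterion: area matching
  out <- classify_internal_model(-10, -11)
  expect_equal(out$lambda, 2)
  expect_identical(out$type, "area_matching")
  expect_equal(out$critical, qchisq(0.95, 2), tolerance = 1e-12)
  # lambda = 20: gaussian
  expect_identical(classify_internal_model(-1, -11)$type, "gaussian")
  # equal likelihoods: area matching
  expect_identical(classify_internal_model(-5, -5)$type, "area_matching")
  expect_warning(classify_internal_model(-6, -5), "negative")
})

test_that("gaussian likelihood nests the area likelihood on arbitrary data", {
  rects <- exp1_rects()
  set.seed(31)
  for (i in 1:5) {
    r <- exp(log(vapply(rects, function(rc) sqrt(rc$w * rc$h / pi),
                        numeric(1))) + rnorm(10, 0, 0.2))
    g <- fit_gaussian_model(r, rects)
    a <- fit_area_model(r, rects)
    expect_gte(g$logL, a$logL - 1e-6)
  }
})

test_that("anisotropy becomes unidentifiable as internal variance grows", {
  # spread between the radii predicted under eta = 1 and eta = 1.44 shrinks
  # monotonically with the variance parameter
  rects <- exp1_rects()
  spread <- vapply(c(5, 20, 80, 320, 1280), function(s2) {
    r1 <- vapply(rects, equivalent_radius, numeric(1),
                 model = gaussian_internal_model(s2, 1))
    r2 <- vapply(rects, equivalent_radius, numeric(1),
                 model = gaussian_internal_model(s2, 1.44))
    max(abs(log(r1) - log(r2)))
  }, numeric(1))
  expect_true(all(diff(spread) < 0))
})

test_that("classification is invariant to global unit rescaling", {
  rects <- exp1_rects()
  gen <- gaussian_internal_model(23.04, 1.44)
  set.seed(41)
  r <- vapply(rects, equivalent_radius, numeric(1), model = gen) *
    exp(rnorm(10, 0, 0.05))
  fit_mm <- fit_internal_model(r, rects)
  rects_cm <- lapply(rects, function(rc) rect_target(rc$w / 10, rc$h / 10))
  fit_cm <- fit_internal_model(r / 10, rects_cm)
  expect_identical(fit_mm$type, fit_cm$type)
  expect_equal(fit_cm$sigma2_tilde * 100, fit_mm$sigma2_tilde,
               tolerance = 1e-3)
  expect_equal(fit_cm$eta_tilde, fit_mm$eta_tilde, tolerance = 1e-3)
  expect_equal(fit_cm$lambda, fit_mm$lambda, tolerance = 1e-3)
})

test_that("an inflated-variance generator drives the fit into the area regime", {
  rects <- exp1_rects()
  gen <- gaussian_internal_model(23.04 * 500, 1)   # enormous assumed variance
  set.seed(51)
  r <- vapply(rects, equivalent_radius, numeric(1), model = gen) *
    exp(rnorm(10, 0, 0.03))
  g <- fit_gaussian_model(r, rects)
  a <- fit_area_model(r, rects)
  # fitted variance blows up and the likelihood gap collapses
  expect_gt(g$sigma2_tilde / 23.04, 10)
  expect_lt(2 * (g$logL - a$logL), qchisq(0.95, 2))
})

test_that("bootstrap CIs are deterministic and collapse for a noiseless subject", {
  sp <- gaussian_type_spec(seed = 6, gamma_choice = 4)
  rep <- run_subject(sp, reduced_design(), seed = 6)
  b1 <- bootstrap_cis(rep$endpoints, rep$staircases$specs,
                      rep$staircases$rects, rep$psychometric, fit = rep$fit,
                      n_boot = 12, seed = 5)
  b2 <- bootstrap_cis(rep$endpoints, rep$staircases$specs,
                      rep$staircases$rects, rep$psychometric, fit = rep$fit,
                      n_boot = 12, seed = 5)
  expect_identical(b1$ci_sigma2_ratio, b2$ci_sigma2_ratio)
  expect_identical(b1$ci_eta_ratio, b2$ci_eta_ratio)
  expect_error(bootstrap_cis(rep$endpoints, rep$staircases$specs,
                             rep$staircases$rects, rep$psychometric,
                             n_boot = 1), "at least 2")
})
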