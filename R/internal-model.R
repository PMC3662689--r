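# Inverting measured equivalent radii to the chooser's internal model.
#
# Gaussian model: log r_hat_j = log r_eq(rect_j; sigma2~, eta~) + eps,
# eps ~ N(0, sigma_e^2), with r_eq the equivalent-radius map of the Gaussian
# internal model. Area-matching model: the nested special case in which the
# predicted radii are the area-equivalent radii sqrt(w h / pi) (the
# infinite-variance limit), leaving sigma_e as the only parameter. The two
# fits are compared by a likelihood-ratio test against chi-square with 2
# degrees of freedom (3 parameters vs 1).

SIGMA_E_FLOOR <- 1e-6    # log-units; guards the degenerate zero-residual fit

# profile log-likelihood of log-normal residuals with a floored sigma_e
lognormal_profile_ll <- function(rss, n) {
  s2 <- max(rss / n, SIGMA_E_FLOOR^2)
  -n / 2 * log(2 * pi * s2) - rss / (2 * s2)
}

rects_to_wh <- function(rects) {
  if (is.data.frame(rects)) {
    stopifnot(all(c("w", "h") %in% names(rects)))
    return(rects[, c("w", "h")])
  }
  stopifnot(all(vapply(rects, is_rect, logical(1))))
  data.frame(w = vapply(rects, function(r) r$w, numeric(1)),
             h = vapply(rects, function(r) r$h, numeric(1)))
}

#' Fit the Gaussian internal model to measured equivalent radii
#'
#' Maximum-likelihood estimates of the internal variance `sigma2_tilde`,
#' anisotropy `eta_tilde` and residual SD `sigma_e` under log-normal
#' deviations of the measured equivalent radii from the radii the Gaussian
#' internal model predicts. The residual SD is profiled out; the search runs
#' a coarse grid over variance (0.1-1000 times the squared mean measured
#' radius) and anisotropy (0.25-4), then Nelder-Mead refinement on log
#' parameters. The variance is clamped to a wide numerical box whose upper
#' end behaves as the area-matching limit.
#'
#' @param r_eq_measured Measured equivalent radii (mm), one per rectangle.
#' @param rects The matching rectangles: a list of centered [rect_target()]s
#'   or a data frame with columns `w`, `h` (mm).
#' @param init Optional warm start `c(sigma2_tilde, eta_tilde)`.
#' @param n_grid_sigma2,n_grid_eta Coarse-grid resolution.
#' @param grid Run the coarse-grid multi-start (default `TRUE`). With a
#'   trusted `init` (e.g. bootstrap replicates around an existing fit) the
#'   grid may be skipped.
#' @return List with `sigma2_tilde`, `eta_tilde`, `sigma_e`, `logL`,
#'   `predicted` radii.
#' @export
fit_gaussian_model <- function(r_eq_measured, rects, init = NULL,
                               n_grid_sigma2 = 5L, n_grid_eta = 5L,
                               grid = TRUE, reltol = 1e-10, maxit = 500L) {
  wh <- rects_to_wh(rects)
  n <- nrow(wh)
  if (length(r_eq_measured) != n)
    stop("one measured radius per rectangle required")
  if (n < 3L) stop("need at least 3 rectangles")
  if (any(r_eq_measured <= 0)) stop("equivalent radii must be positive")
  if (stats::sd(log(r_eq_measured)) == 0 && n > 1L)
    stop("all measured radii identical; model is unidentifiable")
  lr <- log(r_eq_measured)
  scale2 <- exp(mean(lr))^2
  lo_s2 <- log(1e-4 * scale2); hi_s2 <- log(1e8 * scale2)
  lo_et <- log(1 / 64); hi_et <- log(64)

  warm <- new.env(parent = emptyenv())   # Newton warm start across evals
  obj <- function(par) {       # par = (log sigma2, log eta), clamped
    s2 <- exp(min(max(par[1], lo_s2), hi_s2))
    et <- exp(min(max(par[2], lo_et), hi_et))
    pred <- r_eq_gaussian(wh$w, wh$h, s2, et, r0 = warm$r0)
    warm$r0 <- pred
    rss <- sum((lr - log(pred))^2)
    -lognormal_profile_ll(rss, n)
  }

  starts <- NULL
  if (grid) {
    grid_s2 <- log(scale2) + log(10) * seq(-1, 3, length.out = n_grid_sigma2)
    grid_et <- seq(log(0.25), log(4), length.out = n_grid_eta)
    starts <- as.matrix(expand.grid(grid_s2, grid_et))
  }
  if (!is.null(init)) starts <- rbind(starts, log(init))
  if (is.null(starts)) stop("either run the grid or supply `init`")
  vals <- apply(starts, 1L, function(p) { warm$r0 <- NULL; obj(p) })
  p0 <- starts[which.min(vals), ]
  warm$r0 <- NULL
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  s2 <- exp(min(max(fit$par[1], lo_s2), hi_s2))
  et <- exp(min(max(fit$par[2], lo_et), hi_et))
  pred <- r_eq_gaussian(wh$w, wh$h, s2, et)
  rss <- sum((lr - log(pred))^2)
  # the area-matching limit is the upper boundary of the variance box;
  # evaluate it with its exact limiting predictions (the area radii) so a
  # plateau-stalled refinement can never report less than the nested null
  pred_b <- sqrt(wh$w * wh$h / pi)
  rss_b <- sum((lr - log(pred_b))^2)
  if (lognormal_profile_ll(rss_b, n) > lognormal_profile_ll(rss, n)) {
    s2 <- exp(hi_s2); et <- 1; pred <- pred_b; rss <- rss_b
  }
  list(sigma2_tilde = s2, eta_tilde = et,
       sigma_e = max(sqrt(rss / n), SIGMA_E_FLOOR),
       logL = lognormal_profile_ll(rss, n),
       predicted = pred)
}

#' Fit the area-matching model
#'
#' Closed-form MLE of the residual SD under
#' `log r_hat_j = log sqrt(w_j h_j / pi) + eps`.
#'
#' @inheritParams fit_gaussian_model
#' @return List with `sigma_e`, `logL`, `predicted` radii.
#' @export
fit_area_model <- function(r_eq_measured, rects) {
  wh <- rects_to_wh(rects)
  n <- nrow(wh)
  if (length(r_eq_measured) != n)
    stop("one measured radius per rectangle required")
  if (n < 3L) stop("need at least 3 rectangles")
  if (any(r_eq_measured <= 0)) stop("equivalent radii must be positive")
  pred <- sqrt(wh$w * wh$h / pi)
  rss <- sum((log(r_eq_measured) - log(pred))^2)
  list(sigma_e = max(sqrt(rss / n), SIGMA_E_FLOOR),
       logL = lognormal_profile_ll(rss, n),
       predicted = pred)
}

#' Classify a chooser as Gaussian-type or area-matching-type
#'
#' Nested likelihood-ratio test: `lambda = 2 (logL_gaussian - logL_area)`
#' compared to the 95th percentile of the chi-square distribution with 2
#' degrees of freedom (Gaussian: variance, anisotropy, residual SD; area
#' matching: residual SD only).
#'
#' @param logL_gaussian,logL_area Maximized log-likelihoods on the same data.
#' @param alpha Test level (default 0.05).
#' @return List with `lambda`, `critical`, `df`, `type`.
#' @export
classify_internal_model <- function(logL_gaussian, logL_area, alpha = 0.05) {
  lambda <- 2 * (logL_gaussian - logL_area)
  if (lambda < -1e-6)
    warning("negative likelihood-ratio statistic beyond tolerance; ",
            "the Gaussian fit likely missed its optimum - refit advised")
  lambda <- max(lambda, 0)
  crit <- stats::qchisq(1 - alpha, df = 2)
  list(lambda = lambda, critical = crit, df = 2L,
       type = if (lambda > crit) "gaussian" else "area_matching")
}

#' Fit and classify the internal model in one call
#'
#' Runs [fit_gaussian_model()], [fit_area_model()] and
#' [classify_internal_model()] on the same measured radii.
#'
#' @inheritParams fit_gaussian_model
#' @param alpha Level of the nested test.
#' @return An object of class `model_fit_result`.
#' @export
fit_internal_model <- function(r_eq_measured, rects, init = NULL,
                               alpha = 0.05) {
  g <- fit_gaussian_model(r_eq_measured, rects, init = init)
  a <- fit_area_model(r_eq_measured, rects)
  cl <- classify_internal_model(g$logL, a$logL, alpha = alpha)
  structure(list(sigma2_tilde = g$sigma2_tilde, eta_tilde = g$eta_tilde,
                 sigma_e = g$sigma_e, logL_gaussian = g$logL,
                 logL_area = a$logL, sigma_e_area = a$sigma_e,
                 lambda = cl$lambda, type = cl$type,
                 critical = cl$critical,
                 r_eq_measured = r_eq_measured, rects = rects_to_wh(rects)),
            class = "model_fit_result")
}

#' @export
print.model_fit_result <- function(x, ...) {
  cat(sprintf("<internal model fit> type = %s (lambda = %.2f vs %.2f)\n",
              x$type, x$lambda, x$critical))
  cat(sprintf("  sigma2~ = %.4g mm^2, eta~ = %.3f, sigma_e = %.4g\n",
              x$sigma2_tilde, x$eta_tilde, x$sigma_e))
  invisible(x)
}

#' Bootstrap confidence intervals for the internal-model parameters
#'
#' Re-runs the whole virtual experiment `n_boot` times: training endpoints
#' are resampled nonparametrically from the non-timeout trials; staircase
#' responses are regenerated parametrically from the psychometric functions
#' fitted to the real data, with the original adaptive staircase logic; the
#' psychometric and Gaussian-model fits are then repeated on each replicate.
#' Percentile 95% intervals are reported for the variance ratio
#' `sigma2~ / sigma2` and the anisotropy ratio `eta~ / eta`.
#'
#' @param endpoints Endpoint data frame of the subject.
#' @param specs,rects Staircase specifications and their paired rectangles,
#'   exactly as used in the original run (see [run_staircases()]).
#' @param psy_fit The [fit_psychometric()] fit to the subject's real trials.
#' @param fit Optional original [fit_internal_model()] result, used as a
#'   warm start.
#' @param n_boot Number of virtual experiments (>= 2; 1000 for final CIs).
#' @param seed Master seed; each replicate draws from a named substream.
#' @return List with `ci_sigma2_ratio`, `ci_eta_ratio` (2.5/97.5
#'   percentiles) and the matrix of bootstrap `draws`.
#' @export
bootstrap_cis <- function(endpoints, specs, rects, psy_fit, fit = NULL,
                          n_boot = 1000L, seed = 1L) {
  if (n_boot < 2L) stop("n_boot must be at least 2")
  stopifnot(inherits(psy_fit, "psychometric_fit"))
  e <- usable_endpoints(endpoints)
  n_e <- nrow(e)
  if (n_e < 2L) stop("need at least 2 usable endpoints")
  # lookup a_j by rectangle id
  a_by_id <- stats::setNames(psy_fit$per_rect$a, psy_fit$per_rect$rect_id)
  rect_ids <- names(rects)
  if (is.null(rect_ids)) rect_ids <- as.character(seq_along(rects))
  if (!all(rect_ids %in% names(a_by_id)))
    stop("rects must carry the rect_id names present in the psychometric fit")
  gamma <- psy_fit$gamma
  # responder looks rectangles up by their dimensions, not by id plumbing
  dim_key <- vapply(rects, function(r) paste0(r$w, "x", r$h), character(1))
  a_by_dim <- stats::setNames(unname(a_by_id[rect_ids]), dim_key)
  # unique rectangles for the model inversion, in fit order
  uniq <- !duplicated(rect_ids)
  fit_rects <- rects[uniq]
  names(fit_rects) <- rect_ids[uniq]
  init <- if (!is.null(fit)) c(fit$sigma2_tilde, fit$eta_tilde) else NULL

  draws <- matrix(NA_real_, n_boot, 2,
                  dimnames = list(NULL, c("sigma2_ratio", "eta_ratio")))
  for (b in seq_len(n_boot)) {
    bseed <- substream_seed(seed, paste0("boot", b))
    old <- .Random.seed_save()
    set.seed(bseed)
    eb <- e[sample.int(n_e, n_e, replace = TRUE), , drop = FALSE]
    .Random.seed_restore(old)
    motor_b <- fit_true_distribution(eb)
    responder_b <- function(rect, radius) {
      a <- a_by_dim[[paste0(rect$w, "x", rect$h)]]
      p <- psy_prob(radius, a, gamma)
      if (stats::runif(1) < p) "circle" else "rectangle"
    }
    trials_b <- run_staircases(specs, rects, responder_b, seed = bseed)
    psy_b <- try(suppressWarnings(
      fit_psychometric(trials_b, starts = c(4), init = psy_fit)),
      silent = TRUE)
    if (inherits(psy_b, "try-error")) next
    r_b <- psy_b$per_rect$r_eq[match(rect_ids[uniq], psy_b$per_rect$rect_id)]
    g_b <- try(fit_gaussian_model(r_b, fit_rects, init = init,
                                  grid = is.null(init),
                                  reltol = 1e-8, maxit = 300L),
               silent = TRUE)
    if (inherits(g_b, "try-error")) next
    draws[b, ] <- c(g_b$sigma2_tilde / motor_b$sigma2,
                    g_b$eta_tilde / motor_b$eta)
  }
  ok <- stats::complete.cases(draws)
  if (sum(ok) < 2L) stop("bootstrap produced fewer than 2 usable replicates")
  qs <- apply(draws[ok, , drop = FALSE], 2L, stats::quantile,
              probs = c(0.025, 0.975))
  list(ci_sigma2_ratio = unname(qs[, "sigma2_ratio"]),
       ci_eta_ratio = unname(qs[, "eta_ratio"]),
       n_used = sum(ok), draws = draws)
}
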