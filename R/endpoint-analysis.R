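# Estimation of the true motor error distribution from training endpoints,
# plus the distributional checks run per subject: one-tailed F test for
# vertical elongation, Q-Q linearity per axis, and the sensitivity of
# rectangle hit probabilities to the observed endpoint correlation.

usable_endpoints <- function(endpoints) {
  stopifnot(is.data.frame(endpoints),
            all(c("x_mm", "y_mm", "timed_out") %in% names(endpoints)))
  endpoints[!endpoints$timed_out & is.finite(endpoints$x_mm) &
              is.finite(endpoints$y_mm), , drop = FALSE]
}

#' Fit the true motor error distribution
#'
#' Per-axis sample standard deviations (n-1 denominator) and Pearson
#' correlation of the non-timeout endpoints. Timed-out trials are excluded;
#' they carry no endpoint.
#'
#' @param endpoints Data frame with columns `x_mm`, `y_mm`, `timed_out`
#'   (as from [simulate_endpoints()] or read from CSV).
#' @return A [motor_error()] object with `n_used` set.
#' @export
fit_true_distribution <- function(endpoints) {
  e <- usable_endpoints(endpoints)
  n <- nrow(e)
  if (n < 2L) stop("need at least 2 usable (non-timeout) endpoints")
  sh <- stats::sd(e$x_mm)
  sv <- stats::sd(e$y_mm)
  if (sh == 0 || sv == 0) stop("zero variance in endpoints; cannot fit")
  motor_error(sigma_h = sh, sigma_v = sv,
              rho = stats::cor(e$x_mm, e$y_mm), n_used = n)
}

#' One-tailed F test for vertical elongation
#'
#' Tests equality of the horizontal and vertical endpoint variances against
#' the one-sided alternative that the vertical variance is larger:
#' `F = s_v^2 / s_h^2` on (n-1, n-1) degrees of freedom.
#'
#' @inheritParams fit_true_distribution
#' @param alpha Significance level for the `vertical_elongated` flag.
#' @return List with `F`, `df`, `p`, `vertical_elongated`.
#' @export
isotropy_test <- function(endpoints, alpha = 0.05) {
  e <- usable_endpoints(endpoints)
  n <- nrow(e)
  if (n < 2L) stop("need at least 2 usable endpoints")
  s2h <- stats::var(e$x_mm)
  s2v <- stats::var(e$y_mm)
  if (s2h == 0) stop("zero horizontal variance")
  F <- s2v / s2h
  p <- stats::pf(F, n - 1L, n - 1L, lower.tail = FALSE)
  list(F = F, df = c(n - 1L, n - 1L), p = p,
       vertical_elongated = p < alpha)
}

#' Quantile-quantile linearity per axis
#'
#' Correlation between the sorted endpoint coordinates and standard normal
#' quantiles (`ppoints`), the numeric counterpart of judging a Q-Q plot to be
#' linear. Values near 1 support a (bivariate) Gaussian description.
#'
#' @inheritParams fit_true_distribution
#' @return List with `r_x`, `r_y`.
#' @export
qq_linearity <- function(endpoints) {
  e <- usable_endpoints(endpoints)
  n <- nrow(e)
  if (n < 10L) stop("need at least 10 usable endpoints for a Q-Q check")
  q <- stats::qnorm(stats::ppoints(n))
  if (stats::sd(e$x_mm) == 0 || stats::sd(e$y_mm) == 0)
    stop("degenerate endpoints: zero variance")
  list(r_x = stats::cor(sort(e$x_mm), q),
       r_y = stats::cor(sort(e$y_mm), q))
}

#' Sensitivity of rectangle hit probabilities to endpoint correlation
#'
#' For each centered axis-aligned rectangle, compares the hit probability
#' with the fitted correlation against the uncorrelated fit and reports the
#' maximum absolute change in percentage points. Circles are rotation
#' invariant, so only rectangles are affected by the correlation "tilt".
#'
#' @param motor A [motor_error()].
#' @param rects List of centered [rect_target()]s.
#' @return Maximum `|P(rho) - P(0)| * 100` over the rectangles.
#' @export
correlation_sensitivity <- function(motor, rects) {
  stopifnot(inherits(motor, "motor_error"), length(rects) >= 1L)
  if (!all(vapply(rects, is_rect, logical(1))))
    stop("all shapes must be rectangles")
  d <- vapply(rects, function(rc) {
    abs(rect_hit_prob(rc, motor$sigma_h, motor$sigma_v, motor$rho) -
          rect_hit_prob(rc, motor$sigma_h, motor$sigma_v, 0))
  }, numeric(1))
  max(d) * 100
}
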