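# Hit probabilities of rectangles and circles under centered bivariate
# Gaussian (and uniform-disk) error models, and the equivalent-radius solver.
#
# All probabilities are the mass of the error density inside the target
# region; the aim point is the origin. Rectangles with rho = 0 are closed-form
# products of normal CDF differences. Circles and correlated rectangles are
# 1-D chord integrals evaluated by fixed-order Gauss-Legendre quadrature after
# substitutions that leave analytic integrands.

# mass of N(0, diag(sh, sv)) over a disk of radius r centered at (cx, cy);
# vectorized over r. theta-substitution x = cx + r sin(theta) removes the
# sqrt singularity at the disk's horizontal extremes.
circle_mass_theta <- function(r, sh, sv, cx = 0, cy = 0, n = 80L) {
  g <- gauss_legendre(n)
  th <- g$x * (pi / 2)
  wt <- g$w * (pi / 2)
  x <- cx + outer(sin(th), r)            # n x length(r)
  ch <- outer(cos(th), r)
  f <- stats::dnorm(x, 0, sh) *
    (stats::pnorm((cy + ch) / sv) - stats::pnorm((cy - ch) / sv)) * ch
  as.numeric(crossprod(wt, f))
}

# same mass integrating over x on a range truncated to +-8.5 sh around 0;
# used when r >> sh would concentrate the theta integrand in a narrow spike.
circle_mass_x <- function(r, sh, sv, cx = 0, cy = 0, n = 80L) {
  g <- gauss_legendre(n)
  vapply(seq_along(r), function(i) {
    ri <- r[i]
    lo <- max(cx - ri, -8.5 * sh)
    hi <- min(cx + ri, 8.5 * sh)
    if (lo >= hi) return(0)
    x <- (lo + hi) / 2 + (hi - lo) / 2 * g$x
    wt <- (hi - lo) / 2 * g$w
    ch <- sqrt(pmax(ri^2 - (x - cx)^2, 0))
    f <- stats::dnorm(x, 0, sh) *
      (stats::pnorm((cy + ch) / sv) - stats::pnorm((cy - ch) / sv))
    sum(wt * f)
  }, numeric(1))
}

circle_mass <- function(r, sh, sv, cx = 0, cy = 0, n = 80L) {
  use_theta <- r <= 8 * sh
  out <- numeric(length(r))
  if (any(use_theta))
    out[use_theta] <- circle_mass_theta(r[use_theta], sh, sv, cx, cy, n)
  if (any(!use_theta))
    out[!use_theta] <- circle_mass_x(r[!use_theta], sh, sv, cx, cy, n)
  pmin(pmax(out, 0), 1)
}

# density of N(0, diag(sh, sv)) integrated along the boundary circle:
# d/dr of circle_mass for a centered circle; vectorized over r.
circle_mass_deriv <- function(r, sh, sv, n = 80L) {
  g <- gauss_legendre(n)
  al <- (g$x + 1) * (pi / 4)      # [0, pi/2]
  wt <- g$w * (pi / 4)
  f <- stats::dnorm(outer(cos(al), r), 0, sh) *
       stats::dnorm(outer(sin(al), r), 0, sv)
  4 * r * as.numeric(crossprod(wt, f))
}

#' Probability of hitting a rectangle
#'
#' Mass of a centered bivariate Gaussian error distribution inside an
#' axis-aligned rectangle. With uncorrelated axes this is the closed-form
#' product of per-axis normal CDF differences; with `rho != 0` the joint mass
#' is a 1-D integral of the conditional vertical CDF, evaluated by high-order
#' Gauss-Legendre quadrature (absolute error well below 1e-9).
#'
#' @param rect A rectangle from [rect_target()].
#' @param sigma_h,sigma_v Per-axis SDs of the error distribution (mm).
#' @param rho Correlation between horizontal and vertical error.
#' @return Hit probability in `[0, 1]`.
#' @examples
#' rect_hit_prob(rect_target(8, 11.52), sigma_h = 4, sigma_v = 5.76)
#' @export
rect_hit_prob <- function(rect, sigma_h, sigma_v, rho = 0) {
  if (!is_rect(rect)) stop("`rect` must be a rectangle target")
  stopifnot(sigma_h > 0, sigma_v > 0, abs(rho) < 1)
  x1 <- rect$center[1] - rect$w / 2; x2 <- rect$center[1] + rect$w / 2
  y1 <- rect$center[2] - rect$h / 2; y2 <- rect$center[2] + rect$h / 2
  if (rho == 0) {
    return((stats::pnorm(x2 / sigma_h) - stats::pnorm(x1 / sigma_h)) *
             (stats::pnorm(y2 / sigma_v) - stats::pnorm(y1 / sigma_v)))
  }
  lo <- max(x1, -8.5 * sigma_h); hi <- min(x2, 8.5 * sigma_h)
  if (lo >= hi) return(0)
  g <- gauss_legendre(80L)
  x <- (lo + hi) / 2 + (hi - lo) / 2 * g$x
  wt <- (hi - lo) / 2 * g$w
  mu <- rho * sigma_v / sigma_h * x
  s <- sigma_v * sqrt(1 - rho^2)
  p <- sum(wt * stats::dnorm(x, 0, sigma_h) *
             (stats::pnorm((y2 - mu) / s) - stats::pnorm((y1 - mu) / s)))
  min(max(p, 0), 1)
}

#' Probability of hitting a circle
#'
#' Mass of a centered bivariate Gaussian (uncorrelated axes) inside a circle,
#' evaluated as a 1-D chord integral. In the isotropic centered case this
#' agrees with the Rayleigh closed form `1 - exp(-r^2 / (2 sigma^2))`.
#' Correlated errors are handled by rotating to the principal axes of the
#' covariance (a circle is rotation invariant).
#'
#' @param circle A circle from [circle_target()].
#' @param sigma_h,sigma_v Per-axis SDs of the error distribution (mm).
#' @param rho Correlation between horizontal and vertical error.
#' @return Hit probability in `[0, 1]`.
#' @examples
#' circle_hit_prob(circle_target(4 * sqrt(2 * log(2))), 4, 4)  # 0.5
#' @export
circle_hit_prob <- function(circle, sigma_h, sigma_v, rho = 0) {
  if (!is_circle(circle)) stop("`circle` must be a circle target")
  stopifnot(sigma_h > 0, sigma_v > 0, abs(rho) < 1)
  cx <- circle$center[1]; cy <- circle$center[2]
  if (rho != 0) {
    S <- matrix(c(sigma_h^2, rho * sigma_h * sigma_v,
                  rho * sigma_h * sigma_v, sigma_v^2), 2, 2)
    e <- eigen(S, symmetric = TRUE)
    ctr <- drop(t(e$vectors) %*% c(cx, cy))
    sigma_h <- sqrt(e$values[1]); sigma_v <- sqrt(e$values[2])
    cx <- ctr[1]; cy <- ctr[2]
  }
  circle_mass(circle$r, sigma_h, sigma_v, cx, cy)
}

# -- uniform-disk model geometry ---------------------------------------------

# intersection area of two circles with radii r1, r2, centers d apart
lens_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a1 + a2 - 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) *
                         (d - r1 + r2) * (d + r1 + r2))
}

# intersection area of an axis-aligned rectangle and a disk (numeric chord
# integral; integrand is piecewise analytic, split at the chord breakpoints)
rect_disk_area <- function(rect, R, disk_center = c(0, 0)) {
  x1 <- rect$center[1] - rect$w / 2 - disk_center[1]
  x2 <- rect$center[1] + rect$w / 2 - disk_center[1]
  y1 <- rect$center[2] - rect$h / 2 - disk_center[2]
  y2 <- rect$center[2] + rect$h / 2 - disk_center[2]
  lo <- max(x1, -R); hi <- min(x2, R)
  if (lo >= hi) return(0)
  g <- gauss_legendre(200L)
  x <- (lo + hi) / 2 + (hi - lo) / 2 * g$x
  wt <- (hi - lo) / 2 * g$w
  ch <- sqrt(pmax(R^2 - x^2, 0))
  sum(wt * pmax(pmin(y2, ch) - pmax(y1, -ch), 0))
}

#' Hit probability of a target under an internal model
#'
#' Evaluates the hit probability a chooser with the given internal model
#' would assign to a target, aiming at the origin. Gaussian models use the
#' quadratures of [rect_hit_prob()] / [circle_hit_prob()]; the uniform-disk
#' model uses intersection areas divided by the disk area; the area-matching
#' model has no probability scale and is rejected here (its choices are
#' defined by area order, see [equivalent_radius()]).
#'
#' @param shape A [rect_target()] or [circle_target()].
#' @param model An [internal_model][gaussian_internal_model()].
#' @return Hit probability in `[0, 1]`.
#' @export
model_hit_prob <- function(shape, model) {
  stopifnot(inherits(shape, "target_shape"), inherits(model, "internal_model"))
  switch(model$form,
    gaussian = {
      sds <- gaussian_model_sds(model)
      if (shape$kind == "rectangle")
        rect_hit_prob(shape, sds[["sigma_h"]], sds[["sigma_v"]])
      else circle_hit_prob(shape, sds[["sigma_h"]], sds[["sigma_v"]])
    },
    uniform_disk = {
      R <- model$disk_radius
      a <- if (shape$kind == "rectangle") rect_disk_area(shape, R)
           else lens_area(R, shape$r, sqrt(sum(shape$center^2)))
      a / (pi * R^2)
    },
    area_matching = stop(
      "area-matching assigns no probabilities; use equivalent_radius()"))
}

# -- equivalent radius -------------------------------------------------------

# vectorized equivalent radii of centered w x h rectangles under a Gaussian
# internal model (sigma2, eta): solves circle mass = rectangle mass by
# safeguarded Newton on log r. Used heavily inside model fitting.
r_eq_gaussian <- function(w, h, sigma2, eta, r0 = NULL) {
  sh <- sqrt(sigma2 / eta); sv <- sqrt(sigma2 * eta)
  p_rect <- (2 * stats::pnorm(w / (2 * sh)) - 1) *
            (2 * stats::pnorm(h / (2 * sv)) - 1)
  r <- if (is.null(r0)) sqrt(w * h / pi) else r0  # area radius: upper start
  act <- seq_along(r)                       # not-yet-converged entries
  lo <- rep(0, length(r)); hi <- rep(Inf, length(r))
  for (iter in 1:60) {
    p <- circle_mass(r[act], sh, sv, n = 48L)
    err <- p - p_rect[act]
    keep <- abs(err) >= 1e-13 + 1e-11 * p_rect[act]
    if (!any(keep)) break
    act <- act[keep]; err <- err[keep]
    below <- err < 0
    lo[act[below]] <- pmax(lo[act[below]], r[act[below]])
    hi[act[!below]] <- pmin(hi[act[!below]], r[act[!below]])
    dp <- circle_mass_deriv(r[act], sh, sv, n = 48L)
    step <- err / pmax(dp * r[act], .Machine$double.xmin) # Newton in log r
    step <- pmin(pmax(step, -1), 1)
    r_new <- r[act] * exp(-step)
    # fall back to bisection when Newton leaves the bracket
    bad <- !(r_new > lo[act] & r_new < hi[act]) | !is.finite(r_new)
    if (any(bad)) {
      ab <- act[bad]
      hb <- ifelse(is.finite(hi[ab]), hi[ab], 2 * r[ab])
      r_new[bad] <- sqrt(pmax(lo[ab], 1e-12) * hb)
    }
    r[act] <- r_new
  }
  r
}

#' Equivalent radius of a rectangle under an internal model
#'
#' The radius of the circle the internal model deems exactly as hittable as
#' the given rectangle (identical assumed hit probability, both centered on
#' the aim point). For the area-matching model this is the area-equivalent
#' radius `sqrt(w h / pi)`; for Gaussian and uniform-disk models the unique
#' root of the probability-equality equation, solved to relative tolerance
#' below 1e-8. As the Gaussian model's variance grows the equivalent radius
#' converges to the area-equivalent radius: area matching is the
#' infinite-variance limit.
#'
#' @param rect A centered rectangle from [rect_target()].
#' @param model An [internal_model][gaussian_internal_model()].
#' @return Equivalent radius in mm.
#' @examples
#' equivalent_radius(rect_target(4, 1), area_matching_model())  # sqrt(4/pi)
#' @export
equivalent_radius <- function(rect, model) {
  if (!is_rect(rect)) stop("`rect` must be a rectangle target")
  stopifnot(inherits(model, "internal_model"))
  if (any(rect$center != 0))
    stop("equivalent radius is defined for centered rectangles")
  switch(model$form,
    area_matching = sqrt(rect$w * rect$h / pi),
    gaussian = r_eq_gaussian(rect$w, rect$h, model$sigma2_tilde,
                             model$eta_tilde),
    uniform_disk = {
      R <- model$disk_radius
      p_rect <- rect_disk_area(rect, R) / (pi * R^2)
      # centered circle vs disk: mass is min(r, R)^2 / R^2
      r <- R * sqrt(p_rect)
      if (p_rect >= 1)
        stop("rectangle covers the whole disk; equivalent radius is not unique")
      r
    })
}
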