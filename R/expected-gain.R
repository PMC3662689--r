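# Motor-lottery expected gain: a reward circle and a penalty circle on a
# common horizontal axis, endpoints scattered around the chosen aim point by
# the error model. Landing in the overlap accrues both reward and penalty.

#' Reward/penalty condition of a motor lottery
#'
#' A green reward circle centered at the origin and a red penalty circle of
#' equal radius displaced along the positive x axis. Hitting the overlap
#' accrues both payoffs.
#'
#' @param reward Points for landing in the reward circle (default +100).
#' @param penalty Points (usually negative) for landing in the penalty circle.
#' @param circle_radius Radius of both circles in mm (default 8.97).
#' @param center_distance Distance between the two centers in mm.
#' @return An object of class `reward_condition`.
#' @export
reward_condition <- function(reward = 100, penalty, circle_radius = 8.97,
                             center_distance) {
  stopifnot(is.numeric(reward), is.numeric(penalty),
            is.numeric(circle_radius), is.numeric(center_distance))
  if (circle_radius <= 0) stop("circle_radius must be positive")
  if (center_distance < 0) stop("center_distance must be nonnegative")
  structure(list(reward = reward, penalty = penalty,
                 circle_radius = circle_radius,
                 center_distance = center_distance),
            class = "reward_condition")
}

#' @export
print.reward_condition <- function(x, ...) {
  cat(sprintf(
    "<reward condition> +%g / %g, R = %g mm, center distance = %g mm\n",
    x$reward, x$penalty, x$circle_radius, x$center_distance))
  invisible(x)
}

#' The six standard lottery conditions
#'
#' Reward +100; penalty -100 or -500; circle radius 8.97 mm; center distance
#' 1, 1.5 or 2 times the radius. These are the classic speeded-pointing
#' lottery conditions used for the hypothetical-chooser simulations.
#'
#' @return A list of six [reward_condition()] objects.
#' @export
default_reward_conditions <- function() {
  out <- list()
  for (k in c(1, 1.5, 2)) for (pen in c(-100, -500)) {
    out[[length(out) + 1L]] <- reward_condition(
      reward = 100, penalty = pen, circle_radius = 8.97,
      center_distance = k * 8.97)
  }
  out
}

# hit probability of one payoff circle (center ctr, radius R) for an aim
# point `aim`, under motor_error / internal_model `em`
payoff_circle_prob <- function(ctr, R, aim, em) {
  rel <- ctr - aim
  if (inherits(em, "motor_error")) {
    circle_hit_prob(circle_target(R, center = rel),
                    em$sigma_h, em$sigma_v, em$rho)
  } else if (em$form == "gaussian") {
    sds <- gaussian_model_sds(em)
    circle_hit_prob(circle_target(R, center = rel),
                    sds[["sigma_h"]], sds[["sigma_v"]])
  } else if (em$form == "uniform_disk") {
    lens_area(em$disk_radius, R, sqrt(sum(rel^2))) / (pi * em$disk_radius^2)
  } else stop("area-matching model assigns no probabilities")
}

#' Expected gain of an aim point
#'
#' `reward * P(reward circle) + penalty * P(penalty circle)` with both
#' probabilities computed under the supplied error model (a true
#' [motor_error()] or an [internal_model][gaussian_internal_model()]).
#'
#' @param aim Numeric length-2 aim point (mm), relative to the reward-circle
#'   center.
#' @param cond A [reward_condition()].
#' @param error_model A `motor_error` or `internal_model` object.
#' @return Expected gain in points.
#' @export
expected_gain <- function(aim, cond, error_model) {
  stopifnot(inherits(cond, "reward_condition"), is.numeric(aim),
            length(aim) == 2L)
  cond$reward *
    payoff_circle_prob(c(0, 0), cond$circle_radius, aim, error_model) +
  cond$penalty *
    payoff_circle_prob(c(cond$center_distance, 0), cond$circle_radius, aim,
                       error_model)
}

#' Aim point maximizing expected gain
#'
#' The expected-gain surface is symmetric about the axis through the two
#' circle centers, so the optimum lies on it. The search scans that axis on a
#' 0.05 mm grid over a generous window and refines the best grid point by
#' golden-section search to 0.001 mm. Ties on a flat plateau (possible for
#' the uniform-disk model) are broken toward the smallest displacement from
#' the reward-circle center.
#'
#' @inheritParams expected_gain
#' @param grid_step Coarse scan step in mm.
#' @return List with `aim` (length-2, mm) and `gain` (points).
#' @export
optimal_aim <- function(cond, error_model, grid_step = 0.05) {
  f <- function(x) expected_gain(c(x, 0), cond, error_model)
  R <- cond$circle_radius
  xs <- seq(-8 * R, cond$center_distance + 2 * R, by = grid_step)
  v <- vapply(xs, f, numeric(1))
  near <- which(v > max(v) - 1e-9)
  x0 <- xs[near[which.min(abs(xs[near]))]]
  o <- stats::optimize(f, c(x0 - grid_step, x0 + grid_step),
                       maximum = TRUE, tol = 1e-4)
  # keep the plateau tie-break: prefer x0 if refinement gained nothing
  if (o$objective <= f(x0) + 1e-12 && abs(x0) < abs(o$maximum)) {
    return(list(aim = c(x0, 0), gain = f(x0)))
  }
  list(aim = c(o$maximum, 0), gain = o$objective)
}

#' Efficiency of a chooser with a (possibly wrong) internal model
#'
#' For each condition, finds the aim point that maximizes expected gain under
#' the internal model, evaluates the *true* expected gain at that aim, and
#' divides by the maximum true expected gain. The default aggregate is the
#' mean of the per-condition ratios; the ratio of summed gains is also
#' available.
#'
#' @param model The chooser's [internal_model][gaussian_internal_model()]
#'   (or a `motor_error`, giving efficiency 100).
#' @param true_error The true [motor_error()] distribution.
#' @param conds List of [reward_condition()]s
#'   (default [default_reward_conditions()]).
#' @param aggregate `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @return List with `percent` (efficiency x100),
#'   `mean_aim_displacement_mm`, and a `per_condition` data frame
#'   (model aim, true-optimal aim, gains, per-condition ratio).
#' @export
efficiency <- function(model, true_error, conds = default_reward_conditions(),
                       aggregate = c("mean_of_ratios", "ratio_of_means")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(true_error, "motor_error"), length(conds) >= 1L)
  rows <- lapply(conds, function(cond) {
    true_opt <- optimal_aim(cond, true_error)
    model_opt <- optimal_aim(cond, model)
    g_at_model <- expected_gain(model_opt$aim, cond, true_error)
    data.frame(penalty = cond$penalty,
               center_distance = cond$center_distance,
               aim_true = true_opt$aim[1], aim_model = model_opt$aim[1],
               gain_max = true_opt$gain, gain_model = g_at_model,
               ratio = g_at_model / true_opt$gain,
               displacement = sqrt(sum((model_opt$aim - true_opt$aim)^2)))
  })
  per <- do.call(rbind, rows)
  pct <- if (aggregate == "mean_of_ratios") mean(per$ratio) * 100
         else sum(per$gain_model) / sum(per$gain_max) * 100
  list(percent = pct,
       mean_aim_displacement_mm = mean(per$displacement),
       per_condition = per,
       aggregate = aggregate)
}
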