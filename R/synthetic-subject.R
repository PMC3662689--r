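# Synthetic subjects: endpoint scatter with the bivariate-Gaussian structure
# the analysis assumes, and choice responses generated from a configurable
# internal model passed through a Weibull-shaped decision-noise link. One
# master seed spawns independent named substreams so endpoint and choice
# generation can be tested in isolation.

# deterministic 31-bit substream seed from a master seed and a stream name
substream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Specification of a synthetic subject
#'
#' Bundles the generative parameters of a simulated participant: the true
#' endpoint distribution (per-axis SDs in mm, correlation), the internal
#' model driving her target choices, the steepness of the decision-noise
#' link, a timeout rate, and a master seed. The defaults describe a typical
#' participant: vertically elongated endpoints with SD ratio 1.44
#' (`sigma_h` 4 mm, `sigma_v` 5.76 mm), uncorrelated axes, 5% timeouts, and
#' an internal model with the correct variance but isotropic shape -- the
#' modal empirical pattern.
#'
#' @param sigma_h,sigma_v True per-axis endpoint SDs in mm (> 0).
#' @param rho True correlation, strictly inside (-1, 1).
#' @param internal_model The [internal_model][gaussian_internal_model()]
#'   driving choices. Default: Gaussian with `sigma2_tilde = sigma_h *
#'   sigma_v` (accurate variance) and `eta_tilde = 1` (assumed isotropic).
#' @param gamma_choice Steepness of the Weibull decision link (> 0); larger
#'   values mean more consistent choices. `Inf` gives a deterministic
#'   chooser.
#' @param timeout_rate Probability a reach misses the time limit, in `[0, 1)`.
#' @param seed Master seed (integer).
#' @return An object of class `subject_spec`.
#' @export
subject_spec <- function(sigma_h = 4, sigma_v = 5.76, rho = 0,
                         internal_model = NULL, gamma_choice = 4,
                         timeout_rate = 0.05, seed = 1L) {
  if (!is.finite(sigma_h) || sigma_h <= 0) stop("sigma_h must be positive")
  if (!is.finite(sigma_v) || sigma_v <= 0) stop("sigma_v must be positive")
  if (!is.finite(rho) || abs(rho) >= 1) stop("|rho| must be < 1")
  if (timeout_rate < 0 || timeout_rate >= 1)
    stop("timeout_rate must lie in [0, 1)")
  if (!(is.infinite(gamma_choice) || gamma_choice > 0))
    stop("gamma_choice must be positive")
  if (is.null(internal_model))
    internal_model <- gaussian_internal_model(sigma_h * sigma_v, 1)
  stopifnot(inherits(internal_model, "internal_model"))
  structure(list(sigma_h = sigma_h, sigma_v = sigma_v, rho = rho,
                 internal_model = internal_model,
                 gamma_choice = gamma_choice,
                 timeout_rate = timeout_rate, seed = as.integer(seed)),
            class = "subject_spec")
}

#' @export
print.subject_spec <- function(x, ...) {
  cat(sprintf(
    "<subject spec> sigma_h = %g, sigma_v = %g mm, rho = %g, timeouts %g%%\n",
    x$sigma_h, x$sigma_v, x$rho, 100 * x$timeout_rate))
  cat(sprintf("  gamma_choice = %g, seed = %d\n  choice model: ",
              x$gamma_choice, x$seed))
  print(x$internal_model)
  invisible(x)
}

#' Simulate training-task endpoints
#'
#' Draws `n` speeded-reach endpoints around the aim point from the subject's
#' true bivariate Gaussian. Each trial independently times out with
#' probability `timeout_rate`; timed-out trials carry no endpoint (`NA`
#' coordinates) and are excluded from all downstream estimation.
#'
#' @param spec A [subject_spec()].
#' @param n Number of training trials (>= 1).
#' @return A data frame with columns `x_mm`, `y_mm`, `timed_out`.
#' @export
simulate_endpoints <- function(spec, n) {
  stopifnot(inherits(spec, "subject_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive count")
  n <- as.integer(n)
  withr_seed <- substream_seed(spec$seed, "endpoints")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(withr_seed)
  timed_out <- stats::runif(n) < spec$timeout_rate
  m <- sum(!timed_out)
  z <- matrix(stats::rnorm(2 * m), ncol = 2)
  L <- chol(matrix(c(spec$sigma_h^2,
                     spec$rho * spec$sigma_h * spec$sigma_v,
                     spec$rho * spec$sigma_h * spec$sigma_v,
                     spec$sigma_v^2), 2, 2))
  xy <- z %*% L
  out <- data.frame(x_mm = NA_real_, y_mm = NA_real_, timed_out = timed_out)
  out$x_mm[!timed_out] <- xy[, 1]
  out$y_mm[!timed_out] <- xy[, 2]
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# probability the subject reports "circle easier" for circle radius r paired
# with rectangle `rect`. The link is the same Quick-Weibull family used for
# fitting, positioned so its point of subjective equality equals the internal
# model's equivalent radius r_eq*: P = 1 - exp(-(r/a)^gamma) with
# a = r_eq* / ln(2)^(1/gamma).
choice_probability <- function(r, r_eq_star, gamma) {
  if (is.infinite(gamma)) return(ifelse(r > r_eq_star, 1,
                                        ifelse(r < r_eq_star, 0, 0.5)))
  a <- r_eq_star / log(2)^(1 / gamma)
  1 - exp(-(r / a)^gamma)
}

#' Simulate one two-interval choice
#'
#' The subject evaluates the rectangle and the circle under her internal
#' model; indifference occurs at the model's equivalent radius `r_eq*`. The
#' probability of reporting the circle as easier follows a Quick-Weibull
#' decision link with steepness `gamma_choice` whose point of subjective
#' equality is `r_eq*`; the response is a Bernoulli draw on the current RNG
#' stream. `gamma_choice = Inf` gives the deterministic step-function
#' chooser.
#'
#' @param rect A centered rectangle from [rect_target()].
#' @param circle A circle from [circle_target()] (or a radius in mm).
#' @param spec A [subject_spec()].
#' @param r_eq_star Optional precomputed equivalent radius (mm) of `rect`
#'   under `spec$internal_model`, to avoid recomputation in staircase loops.
#' @return `"circle"` or `"rectangle"`.
#' @seealso [choice_responder()] for a cached closure usable with
#'   [run_staircases()].
#' @export
simulate_choice <- function(rect, circle, spec, r_eq_star = NULL) {
  stopifnot(inherits(spec, "subject_spec"))
  r <- if (inherits(circle, "target_shape")) {
    if (!is_circle(circle)) stop("`circle` must be a circle target")
    circle$r
  } else {
    if (!is.numeric(circle) || circle <= 0) stop("degenerate circle radius")
    circle
  }
  if (is.null(r_eq_star))
    r_eq_star <- equivalent_radius(rect, spec$internal_model)
  p <- choice_probability(r, r_eq_star, spec$gamma_choice)
  if (stats::runif(1) < p) "circle" else "rectangle"
}

#' Choice responder closure for staircase runs
#'
#' Wraps [simulate_choice()] with a per-rectangle cache of equivalent radii
#' under the subject's internal model. The returned function has signature
#' `(rect, radius)` and draws from the current RNG stream.
#'
#' @param spec A [subject_spec()].
#' @return A function `(rect, radius) -> "circle" | "rectangle"`.
#' @export
choice_responder <- function(spec) {
  stopifnot(inherits(spec, "subject_spec"))
  cache <- new.env(parent = emptyenv())
  function(rect, radius) {
    key <- paste0(rect$w, "x", rect$h)
    r_eq <- cache[[key]]
    if (is.null(r_eq)) {
      r_eq <- equivalent_radius(rect, spec$internal_model)
      cache[[key]] <- r_eq
    }
    simulate_choice(rect, radius, spec, r_eq_star = r_eq)
  }
}

#' Write endpoint and choice tables as CSV
#'
#' Delimited-text external interface: endpoints as `x_mm, y_mm, timed_out`,
#' choice trials as produced by [run_staircases()]. Plain `utils::write.csv`
#' wrappers kept for a stable on-disk contract.
#'
#' @param x A data frame (endpoints or choice trials).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
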