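# Quick-Weibull psychometric fitting. The probability of judging the circle
# easier than rectangle j at circle radius r is
#   P_j(r) = 1 - exp(-(r / a_j)^gamma),
# with a per-rectangle position a_j and one steepness gamma shared across
# rectangles. Maximum-likelihood fitting is done on log parameters (so
# positivity is structural) with multiple seeded starts. The equivalent
# radius -- the point of subjective equality, P = 1/2 -- is
#   r_eq = a * ln(2)^(1/gamma),
# which depends on both estimates.

psy_prob <- function(r, a, gamma) 1 - exp(-(r / a)^gamma)

psy_nll <- function(par, r, y, j, n_rect) {
  gamma <- exp(par[1L])
  a <- exp(par[1L + j])          # par[2..] are log a_j, indexed per trial
  p <- psy_prob(r, a, gamma)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (1 - y) * log1p(-p))
}

# analytic gradient of psy_nll in (log gamma, log a_1..log a_J)
psy_nll_grad <- function(par, r, y, j, n_rect) {
  gamma <- exp(par[1L])
  a <- exp(par[1L + j])
  u <- log(r / a)
  t <- exp(gamma * u)
  p <- 1 - exp(-t)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  dll_dt <- (y / p - (1 - y) / (1 - p)) * exp(-t)   # d logL / dt per trial
  # exp(-t) underflow kills these terms; zero them before forming t products
  dead <- !is.finite(t) | t > 500
  dll_dt[dead] <- 0
  t[dead] <- 0
  g_loggamma <- -sum(dll_dt * t * u * gamma)
  g_loga <- -vapply(seq_len(n_rect), function(k)
    sum(dll_dt[j == k] * (-gamma * t[j == k])), numeric(1))
  c(g_loggamma, g_loga)
}

#' Fit the Quick-Weibull psychometric model to choice trials
#'
#' Maximizes the Bernoulli log-likelihood of `P(choose circle | r)` jointly
#' over per-rectangle positions `a_j` and a shared steepness `gamma`, from
#' several starting steepness values, keeping the best optimum. Data that
#' are perfectly separable in radius push `gamma` to infinity; fits reaching
#' the declared cap are refit with `gamma` fixed at the cap and flagged.
#'
#' @param trials Choice-trial data frame as from [run_staircases()]
#'   (columns `rect_id`, `circle_r_mm`, `response`).
#' @param gamma_cap Upper bound on the fitted steepness (default 50).
#' @param starts Steepness starting values for the multi-start search.
#' @param init Optional warm start: a previous `psychometric_fit` whose
#'   parameters seed a single additional start.
#' @return An object of class `psychometric_fit`: data frame `per_rect`
#'   (`rect_id`, `a`, `r_eq`), shared `gamma`, `logL`, `separable` flag.
#' @export
fit_psychometric <- function(trials, gamma_cap = 50,
                             starts = c(0.7, 1.5, 3, 8, 20), init = NULL) {
  stopifnot(is.data.frame(trials),
            all(c("rect_id", "circle_r_mm", "response") %in% names(trials)))
  if (any(trials$circle_r_mm <= 0)) stop("circle radii must be positive")
  rect_ids <- sort(unique(trials$rect_id))
  j <- match(trials$rect_id, rect_ids)
  n_rect <- length(rect_ids)
  r <- trials$circle_r_mm
  y <- as.numeric(trials$response == "circle")
  n_distinct <- tapply(r, j, function(v) length(unique(v)))
  if (any(n_distinct < 2L))
    stop("need at least 2 distinct radii per rectangle")

  a0 <- as.numeric(tapply(seq_along(r), j, function(ii) {
    # radius at the empirical 50% crossing; geometric mean as fallback
    exp(mean(log(r[ii])))
  }))
  if (all(y == 1) || all(y == 0)) {
    # one-sided responding: the PSE lies beyond the tested range; pin the
    # steepness at the cap and flag
    warning("perfectly separable responses: gamma capped at ", gamma_cap)
    a_deg <- if (all(y == 1)) as.numeric(tapply(r, j, min)) / 2
             else as.numeric(tapply(r, j, max)) * 2
    return(structure(list(
      per_rect = data.frame(rect_id = rect_ids, a = a_deg,
                            r_eq = equivalent_radius_from_fit(a_deg,
                                                              gamma_cap)),
      gamma = gamma_cap,
      logL = -psy_nll(c(log(gamma_cap), log(a_deg[seq_len(n_rect)])),
                      r, y, j, n_rect),
      separable = TRUE), class = "psychometric_fit"))
  }
  start_list <- lapply(starts, function(g0) c(log(g0), log(a0)))
  if (!is.null(init))
    start_list <- c(start_list,
                    list(c(log(init$gamma), log(init$per_rect$a))))
  best <- NULL
  for (p0 in start_list) {
    fit <- try(stats::optim(p0, psy_nll, psy_nll_grad, r = r, y = y, j = j,
                            n_rect = n_rect, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value - 1e-10) best <- fit
  }
  if (is.null(best)) stop("psychometric optimization failed from all starts")
  gamma <- exp(best$par[1L])
  a <- exp(best$par[-1L])
  separable <- FALSE
  if (gamma > gamma_cap) {
    separable <- TRUE
    gamma <- gamma_cap
    # refit positions with the steepness pinned at the cap
    nll_a <- function(la) psy_nll(c(log(gamma_cap), la), r, y, j, n_rect)
    ref <- stats::optim(log(a), nll_a, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    a <- exp(ref$par)
    best$value <- ref$value
    warning("perfectly separable responses: gamma capped at ", gamma_cap)
  }
  structure(list(
    per_rect = data.frame(rect_id = rect_ids, a = a,
                          r_eq = equivalent_radius_from_fit(a, gamma)),
    gamma = gamma, logL = -best$value, separable = separable),
    class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric fit> gamma = %.3f, logL = %.2f%s\n", x$gamma,
              x$logL, if (x$separable) " (separable, gamma capped)" else ""))
  print(x$per_rect, row.names = FALSE)
  invisible(x)
}

#' Equivalent radius from fitted psychometric parameters
#'
#' The radius at which the fitted choice probability is one half:
#' `r_eq = a * ln(2)^(1/gamma)`.
#'
#' @param a Position parameter(s), mm (> 0).
#' @param gamma Shared steepness (> 0); may be `Inf` (then `r_eq = a`).
#' @return Equivalent radius (vectorized over `a`).
#' @export
equivalent_radius_from_fit <- function(a, gamma) {
  stopifnot(all(a > 0), gamma > 0)
  if (is.infinite(gamma)) return(a)
  a * log(2)^(1 / gamma)
}

#' Choice-consistency index
#'
#' The shared steepness of a [fit_psychometric()] fit; steeper functions
#' mean the subject repeats the same choice for the same pair more reliably.
#'
#' @param fit A `psychometric_fit`.
#' @return List with `gamma` and the `separable` flag.
#' @export
consistency_index <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  list(gamma = fit$gamma, separable = fit$separable)
}
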