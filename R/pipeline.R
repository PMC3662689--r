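# End-to-end orchestration: simulate a subject, estimate her true error
# distribution, run the choice experiment, fit and classify her internal
# model, optionally bootstrap confidence intervals, and report. Two shipped
# designs mirror the two experiments; the across-task statistics
# (paired t on log radii, Fisher's exact on type counts) live here too.

#' Experiment design
#'
#' Rectangles come in 4:1 (horizontal) and 1:4 (vertical) orientations, with
#' short sides forming a geometric sequence of multiples of the subject's
#' mean endpoint SD `sigma_bar`. Each rectangle is paired with one or more
#' transformed up-down staircases on the radius of the comparison circle.
#'
#' @param size_multipliers Short-side lengths as multiples of `sigma_bar`.
#' @param staircase_rules List of `c(n_up, n_down)` pairs run per rectangle.
#' @param n_trials Trials per staircase.
#' @param step_schedule log10 steps by reversal epoch.
#' @param n_training Training reaches used to estimate the true distribution.
#' @param task `"probability"`, `"area"`, or `"probability_with_feedback"`.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(size_multipliers, staircase_rules, n_trials,
                              step_schedule, n_training,
                              task = c("probability", "area",
                                       "probability_with_feedback")) {
  task <- match.arg(task)
  stopifnot(all(size_multipliers > 0), n_trials >= 1, n_training >= 2)
  structure(list(size_multipliers = size_multipliers,
                 staircase_rules = staircase_rules,
                 n_trials = as.integer(n_trials),
                 step_schedule = step_schedule,
                 n_training = as.integer(n_training), task = task),
            class = "experiment_design")
}

#' First experiment design: 10 rectangles, paired 1-up/2-down and
#' 2-up/1-down 50-trial staircases (20 staircases, 1000 trials), 300
#' training reaches.
#' @return An `experiment_design`.
#' @export
exp1_design <- function() {
  experiment_design(
    size_multipliers = c(0.60, 0.90, 1.35, 2.025, 3.0375),
    staircase_rules = list(c(1L, 2L), c(2L, 1L)),
    n_trials = 50L,
    step_schedule = c(0.115, 0.075, 0.05, 0.04),
    n_training = 300L)
}

#' Second experiment design: 8 rectangles, one 1-up/1-down 60-trial
#' staircase each (480 trials), 600 training reaches.
#' @return An `experiment_design`.
#' @export
exp2_design <- function() {
  experiment_design(
    size_multipliers = c(0.60, 0.90, 1.35, 2.025),
    staircase_rules = list(c(1L, 1L)),
    n_trials = 60L,
    step_schedule = c(0.15, 0.10, 0.08, 0.06),
    n_training = 600L)
}

#' Rectangle set of a design, scaled to a subject
#'
#' @param design An [experiment_design()].
#' @param sigma_bar The subject's mean endpoint SD in mm.
#' @return Named list of centered [rect_target()]s (`h*` horizontal 4:1,
#'   `v*` vertical 1:4).
#' @export
design_rectangles <- function(design, sigma_bar) {
  stopifnot(inherits(design, "experiment_design"), sigma_bar > 0)
  out <- list()
  for (i in seq_along(design$size_multipliers)) {
    s <- design$size_multipliers[i] * sigma_bar
    out[[paste0("h", i)]] <- rect_target(4 * s, s)
    out[[paste0("v", i)]] <- rect_target(s, 4 * s)
  }
  out
}

# staircase specs + rect list expanded per rule, ready for run_staircases
design_staircases <- function(design, rects) {
  specs <- list(); sc_rects <- list()
  for (id in names(rects)) {
    for (rule in design$staircase_rules) {
      specs[[length(specs) + 1L]] <- staircase_spec(
        n_up = rule[1], n_down = rule[2],
        step_schedule = design$step_schedule,
        n_trials = design$n_trials,
        start_radius = sqrt(rects[[id]]$w * rects[[id]]$h / pi))
      sc_rects[[length(sc_rects) + 1L]] <- rects[[id]]
      names(sc_rects)[length(sc_rects)] <- id
    }
  }
  list(specs = specs, rects = sc_rects)
}

#' Run one synthetic subject through the full pipeline
#'
#' Simulates training endpoints, estimates the true motor error
#' distribution, scales the design's rectangles to the fitted mean SD, runs
#' the interleaved staircases against the subject's internal model, fits the
#' shared-steepness psychometric model, inverts the equivalent radii to a
#' Gaussian internal model, classifies the subject by the nested test, and
#' (optionally) bootstraps confidence intervals. Fully deterministic for a
#' fixed seed.
#'
#' @param spec A [subject_spec()].
#' @param design An [experiment_design()] (default [exp1_design()]).
#' @param seed Master seed (default: the spec's seed).
#' @param n_boot Bootstrap replicates for CIs (0 skips the bootstrap).
#' @return An object of class `subject_report`.
#' @export
run_subject <- function(spec, design = exp1_design(), seed = spec$seed,
                        n_boot = 0L) {
  stopifnot(inherits(spec, "subject_spec"),
            inherits(design, "experiment_design"))
  spec$seed <- as.integer(seed)
  endpoints <- simulate_endpoints(spec, design$n_training)
  motor <- fit_true_distribution(endpoints)
  rects <- design_rectangles(design, motor$sigma_bar)
  sc <- design_staircases(design, rects)
  trials <- run_staircases(sc$specs, sc$rects, choice_responder(spec),
                           seed = spec$seed)
  psy <- suppressWarnings(fit_psychometric(trials))
  ord <- match(names(rects), psy$per_rect$rect_id)
  r_eq <- psy$per_rect$r_eq[ord]
  fit <- fit_internal_model(r_eq, rects)
  boot <- NULL
  if (n_boot > 0L)
    boot <- bootstrap_cis(endpoints, sc$specs, sc$rects, psy, fit = fit,
                          n_boot = n_boot, seed = spec$seed)
  structure(list(spec = spec, design = design, seed = spec$seed,
                 endpoints = endpoints, motor = motor, rects = rects,
                 staircases = sc, trials = trials, psychometric = psy,
                 r_eq = stats::setNames(r_eq, names(rects)), fit = fit,
                 bootstrap = boot,
                 sigma2_ratio = fit$sigma2_tilde / motor$sigma2,
                 eta_ratio = fit$eta_tilde / motor$eta),
            class = "subject_report")
}

#' @export
print.subject_report <- function(x, ...) {
  cat(sprintf("<subject report> seed %d, %d choice trials\n", x$seed,
              nrow(x$trials)))
  print(x$motor)
  print(x$fit)
  cat(sprintf("  sigma2~/sigma2 = %.3f, eta~/eta = %.3f\n",
              x$sigma2_ratio, x$eta_ratio))
  if (!is.null(x$bootstrap)) {
    cat(sprintf("  95%% CI sigma2 ratio [%.3f, %.3f], eta ratio [%.3f, %.3f]\n",
                x$bootstrap$ci_sigma2_ratio[1], x$bootstrap$ci_sigma2_ratio[2],
                x$bootstrap$ci_eta_ratio[1], x$bootstrap$ci_eta_ratio[2]))
  }
  invisible(x)
}

#' Write a subject report as JSON
#'
#' Serializes the scalar summary of a [run_subject()] report (type, fitted
#' parameters, ratios, likelihoods, CIs) to JSON; trial-level tables are
#' written separately as CSV via [write_trials_csv()].
#'
#' @param report A `subject_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subject_report <- function(report, path) {
  stopifnot(inherits(report, "subject_report"))
  out <- list(
    seed = report$seed,
    n_endpoints_used = report$motor$n_used,
    sigma_h = report$motor$sigma_h, sigma_v = report$motor$sigma_v,
    rho = report$motor$rho, sigma2 = report$motor$sigma2,
    eta = report$motor$eta, sigma_bar = report$motor$sigma_bar,
    gamma = report$psychometric$gamma,
    r_eq = as.list(report$r_eq),
    sigma2_tilde = report$fit$sigma2_tilde,
    eta_tilde = report$fit$eta_tilde,
    sigma2_ratio = report$sigma2_ratio, eta_ratio = report$eta_ratio,
    lambda = report$fit$lambda, type = report$fit$type)
  if (!is.null(report$bootstrap)) {
    out$ci_sigma2_ratio <- report$bootstrap$ci_sigma2_ratio
    out$ci_eta_ratio <- report$bootstrap$ci_eta_ratio
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Paired comparison of probability-task and area-task radii
#'
#' One-sample two-tailed t test on the log differences
#' `log(r_prob / r_area)` across rectangles. A negative direction means the
#' probability-task radii are smaller, the signature of a chooser who
#' discounts rectangle area by its spread under a Gaussian model.
#'
#' @param prob_radii,area_radii Equivalent radii (mm) for identical
#'   rectangles in the two tasks.
#' @return List with `t`, `df`, `p`, `direction`, `mean_log_ratio`.
#' @export
compare_tasks <- function(prob_radii, area_radii) {
  if (length(prob_radii) != length(area_radii))
    stop("paired radii required")
  if (length(prob_radii) < 2L) stop("need at least 2 pairs")
  if (any(prob_radii <= 0) || any(area_radii <= 0))
    stop("radii must be positive")
  d <- log(prob_radii) - log(area_radii)
  if (stats::sd(d) == 0)
    stop("zero variance in log ratios; t test undefined (identical radii)")
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       direction = sign(mean(d)), mean_log_ratio = mean(d))
}

#' Association between chooser types across tasks
#'
#' Fisher's exact test (hypergeometric enumeration) on a 2x2 table of type
#' counts, e.g. Gaussian-type vs area-matching-type in one task crossed with
#' the same classification in another.
#'
#' @param counts A 2x2 matrix of nonnegative integer counts.
#' @return List with `p_two_sided`, `p_one_sided` (alternative: first row's
#'   first-column proportion greater), and the `odds_ratio` estimate.
#' @export
type_association <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("counts must be 2x2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("empty margin")
  two <- stats::fisher.test(counts)
  one <- stats::fisher.test(counts, alternative = "greater")
  list(p_two_sided = two$p.value, p_one_sided = one$p.value,
       odds_ratio = unname(two$estimate))
}
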