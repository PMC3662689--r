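# Transformed up-down staircases on circle radius. "Down" (radius shrinks,
# the circle gets harder) follows n_down consecutive "circle easier"
# responses; "up" follows n_up consecutive "rectangle easier" responses.
# Updates are multiplicative: the log10 radius moves by the current step,
# with the step schedule advancing one epoch at each reversal (the step that
# produces a reversal still uses the pre-reversal size; the new size applies
# from the next update). A 1-up/2-down track converges near the 70.7%
# choose-circle point, 2-up/1-down near 29.3%, 1-up/1-down near 50%.

#' Staircase specification
#'
#' @param n_up Consecutive "rectangle" responses required to increase the
#'   radius.
#' @param n_down Consecutive "circle" responses required to decrease it.
#' @param step_schedule Positive, non-increasing log10 steps; entry k applies
#'   until the k-th reversal, the last entry for all later reversals.
#' @param n_trials Trials after which the staircase terminates.
#' @param start_radius Starting circle radius in mm.
#' @return An object of class `staircase_spec`.
#' @export
staircase_spec <- function(n_up, n_down, step_schedule, n_trials,
                           start_radius) {
  stopifnot(n_up >= 1, n_down >= 1, n_trials >= 1, start_radius > 0)
  if (any(step_schedule <= 0)) stop("steps must be positive")
  if (any(diff(step_schedule) > 0)) stop("steps must be non-increasing")
  structure(list(n_up = as.integer(n_up), n_down = as.integer(n_down),
                 step_schedule = step_schedule,
                 n_trials = as.integer(n_trials),
                 start_radius = start_radius),
            class = "staircase_spec")
}

#' Initialize a staircase
#'
#' @param spec A [staircase_spec()].
#' @return A live staircase state (class `staircase_state`).
#' @export
staircase_init <- function(spec) {
  stopifnot(inherits(spec, "staircase_spec"))
  structure(list(spec = spec, log_r = log10(spec$start_radius),
                 run_circle = 0L, run_rect = 0L,
                 reversals = 0L, last_dir = 0L,
                 trials_done = 0L, terminated = FALSE),
            class = "staircase_state")
}

#' Current circle radius presented by a staircase
#'
#' @param state A `staircase_state`.
#' @return Radius in mm.
#' @export
staircase_radius <- function(state) 10^state$log_r

#' Advance a staircase by one response
#'
#' Records the response at the current radius and applies the transformed
#' up-down rule. Stepping a terminated staircase is an error.
#'
#' @param state A live `staircase_state`.
#' @param response `"circle"` or `"rectangle"`.
#' @return The updated `staircase_state`.
#' @export
staircase_step <- function(state, response) {
  stopifnot(inherits(state, "staircase_state"))
  if (state$terminated) stop("staircase already terminated")
  response <- match.arg(response, c("circle", "rectangle"))
  sc <- state$spec
  if (response == "circle") {
    state$run_circle <- state$run_circle + 1L
    state$run_rect <- 0L
  } else {
    state$run_rect <- state$run_rect + 1L
    state$run_circle <- 0L
  }
  dir <- 0L
  if (state$run_circle >= sc$n_down) dir <- -1L     # circle easy: shrink it
  if (state$run_rect >= sc$n_up) dir <- +1L         # circle hard: grow it
  if (dir != 0L) {
    k <- min(state$reversals + 1L, length(sc$step_schedule))
    state$log_r <- state$log_r + dir * sc$step_schedule[k]
    if (state$last_dir != 0L && dir != state$last_dir)
      state$reversals <- state$reversals + 1L
    state$last_dir <- dir
    state$run_circle <- 0L
    state$run_rect <- 0L
  }
  state$trials_done <- state$trials_done + 1L
  if (state$trials_done >= sc$n_trials) state$terminated <- TRUE
  state
}

#' Run interleaved staircases against a responder
#'
#' Each staircase is paired with a rectangle and produces exactly `n_trials`
#' choice trials. Interleaving is round-robin: every round presents one trial
#' from each live staircase, in an order shuffled within the round from the
#' seeded stream (the same stream feeds the responder's Bernoulli draws, so
#' a fixed seed reproduces the full trial table).
#'
#' @param specs List of [staircase_spec()]s.
#' @param rects List of centered [rect_target()]s, one per staircase.
#' @param responder Function `(rect, radius) -> "circle" | "rectangle"`, e.g.
#'   from [choice_responder()].
#' @param interleave Shuffle staircase order within rounds (default `TRUE`);
#'   `FALSE` runs staircases to completion one after another.
#' @param seed Integer seed for the shuffling/response stream.
#' @return Data frame of choice trials: `trial_index`, `staircase_id`,
#'   `rect_id`, `rect_w_mm`, `rect_h_mm`, `circle_r_mm`, `response`.
#' @export
run_staircases <- function(specs, rects, responder, interleave = TRUE,
                           seed = 1L) {
  stopifnot(length(specs) == length(rects), length(specs) >= 1L,
            is.function(responder))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, "choices"))
  states <- lapply(specs, staircase_init)
  n_sc <- length(specs)
  total <- sum(vapply(specs, function(s) s$n_trials, integer(1)))
  rows <- vector("list", total)
  idx <- 0L
  rect_ids <- names(rects)
  if (is.null(rect_ids)) rect_ids <- as.character(seq_along(rects))
  if (interleave) {
    repeat {
      live <- which(!vapply(states, function(s) s$terminated, logical(1)))
      if (!length(live)) break
      for (j in sample(live)) {
        r <- staircase_radius(states[[j]])
        resp <- responder(rects[[j]], r)
        states[[j]] <- staircase_step(states[[j]], resp)
        idx <- idx + 1L
        rows[[idx]] <- list(j, rect_ids[j], rects[[j]]$w, rects[[j]]$h,
                            r, resp)
      }
    }
  } else {
    for (j in seq_len(n_sc)) {
      while (!states[[j]]$terminated) {
        r <- staircase_radius(states[[j]])
        resp <- responder(rects[[j]], r)
        states[[j]] <- staircase_step(states[[j]], resp)
        idx <- idx + 1L
        rows[[idx]] <- list(j, rect_ids[j], rects[[j]]$w, rects[[j]]$h,
                            r, resp)
      }
    }
  }
  out <- data.frame(
    trial_index = seq_len(idx),
    staircase_id = vapply(rows, `[[`, integer(0L + 1L), 1L),
    rect_id = vapply(rows, `[[`, character(1), 2L),
    rect_w_mm = vapply(rows, `[[`, numeric(1), 3L),
    rect_h_mm = vapply(rows, `[[`, numeric(1), 4L),
    circle_r_mm = vapply(rows, `[[`, numeric(1), 5L),
    response = vapply(rows, `[[`, character(1), 6L))
  out
}
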