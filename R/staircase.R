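#' Staircase configuration
#'
#' Transformed two-up/two-down staircase for the static ambiguity-threshold
#' task: the morph level changes only after two successive identical
#' categorizations, by three pictures before the first reversal and one
#' picture afterwards; a stair ends after at least four reversals and at
#' least five presentations. Levels are clamped to the 1..21 continuum.
#'
#' @param step_before_first_reversal,step_after Step sizes in pictures.
#' @param min_reversals,min_presentations Completion rule.
#' @param literal If `TRUE`, use the divergent literal direction reading
#'   (two "angry" responses step toward the angry pole); the default steps
#'   toward the pole opposite the repeated response, which seeks the
#'   category boundary.
#' @return An object of class `stair_config`.
#' @export
stair_config <- function(step_before_first_reversal = 3, step_after = 1,
                         min_reversals = 4, min_presentations = 5,
                         literal = FALSE) {
  stopifnot(step_before_first_reversal > 0, step_after > 0, min_reversals >= 1)
  structure(
    list(step_before_first_reversal = step_before_first_reversal,
         step_after = step_after, min_reversals = min_reversals,
         min_presentations = min_presentations, literal = literal),
    class = "stair_config"
  )
}

new_stair <- function(stair_id, avatar_id, start_level, config) {
  list(stair_id = stair_id, avatar_id = avatar_id,
       start_level = as.integer(start_level),
       current_level = as.integer(start_level),
       presentations = 0L,
       run_response = NA_character_,
       movement_direction = NA_integer_,
       step_size = config$step_before_first_reversal,
       reversal_levels = numeric(0),
       reversal_steps = numeric(0),
       complete = FALSE)
}

#' Initialise a staircase session
#'
#' Two randomly interleaved stairs per avatar: one starting at the fully
#' angry expression (level 1) and one at the fully happy expression
#' (level 21).
#'
#' @param avatar_ids Character vector of avatar identifiers.
#' @param config A [stair_config()].
#' @return List of stair states.
#' @export
init_session <- function(avatar_ids, config = stair_config()) {
  stopifnot(length(avatar_ids) >= 1)
  stairs <- list()
  for (av in avatar_ids) {
    stairs[[paste0(av, "_up")]] <- new_stair(paste0(av, "_up"), av, 1L, config)
    stairs[[paste0(av, "_down")]] <- new_stair(paste0(av, "_down"), av, 21L, config)
  }
  stairs
}

#' Pick the next stair to present
#'
#' Uniformly random among the incomplete stairs.
#'
#' @param session List of stair states.
#' @return The index (into `session`) of the chosen stair.
#' @export
next_stair <- function(session) {
  open <- unname(which(!vapply(session, `[[`, logical(1), "complete")))
  if (length(open) == 0) stop("all stairs are complete")
  if (length(open) == 1) open else open[sample.int(length(open), 1)]
}

#' Update one stair with a categorization response
#'
#' Applies the two-up/two-down rule: after two successive identical
#' responses the level steps toward the opposite emotion's pole (two
#' "angry" responses step toward happy, i.e. upward on the 1=angry..21=happy
#' continuum), and the response run resets; otherwise the level is
#' unchanged. A reversal is recorded when the realised movement direction
#' flips, tagged with the step size used by the flipping movement; the step
#' size drops from 3 to 1 after the first reversal. Completion is
#' re-evaluated after every presentation.
#'
#' @param stair A stair state.
#' @param response `"angry"` or `"happy"`.
#' @param config A [stair_config()].
#' @return The updated stair state.
#' @export
update_stair <- function(stair, response, config = stair_config()) {
  if (stair$complete) stop("response delivered to a completed stair")
  stopifnot(response %in% c("angry", "happy"))
  stair$presentations <- stair$presentations + 1L

  if (!is.na(stair$run_response) && stair$run_response == response) {
    # second identical response in a row: move
    dir <- if (response == "angry") 1L else -1L   # toward the opposite pole
    if (config$literal) dir <- -dir
    step <- stair$step_size
    stair$current_level <- max(1L, min(21L, stair$current_level + dir * step))
    if (!is.na(stair$movement_direction) && dir != stair$movement_direction) {
      stair$reversal_levels <- c(stair$reversal_levels, stair$current_level)
      stair$reversal_steps <- c(stair$reversal_steps, step)
      if (length(stair$reversal_levels) == 1)
        stair$step_size <- config$step_after
    }
    stair$movement_direction <- dir
    stair$run_response <- NA_character_
  } else {
    stair$run_response <- response
  }
  stair$complete <- is_complete(stair, config)
  stair
}

#' Stair completion rule
#'
#' TRUE once the stair has recorded at least `min_reversals` reversals and
#' at least `min_presentations` presentations.
#'
#' @param stair A stair state.
#' @param config A [stair_config()].
#' @return Logical.
#' @export
is_complete <- function(stair, config = stair_config()) {
  length(stair$reversal_levels) >= config$min_reversals &&
    stair$presentations >= config$min_presentations
}

#' Ambiguity threshold from completed stairs
#'
#' Mean of the picture levels at which reversals with step size 1 occurred,
#' pooled over the supplied stairs (typically the two stairs of one avatar).
#' Reversals recorded while the step size was still 3 are excluded.
#'
#' @param stairs List of stair states.
#' @return The threshold level.
#' @export
ambiguity_threshold <- function(stairs) {
  if (!is.null(stairs$stair_id)) stairs <- list(stairs)
  lv <- unlist(lapply(stairs, function(s) s$reversal_levels[s$reversal_steps == 1]))
  if (length(lv) == 0) stop("no step-1 reversals recorded")
  mean(lv)
}

#' Staircase JND
#'
#' Dispersion of the step-1 reversal levels: the sample SD by default.
#'
#' @param stairs List of stair states.
#' @return Sample SD of the pooled step-1 reversal levels.
#' @export
staircase_jnd <- function(stairs) {
  if (!is.null(stairs$stair_id)) stairs <- list(stairs)
  lv <- unlist(lapply(stairs, function(s) s$reversal_levels[s$reversal_steps == 1]))
  if (length(lv) < 2) stop("need at least two step-1 reversals")
  stats::sd(lv)
}

#' Simulate a full staircase session for one observer
#'
#' Interleaves the stairs at random, draws categorizations from the
#' observer's link function, and updates until every stair completes (or a
#' safety cap on presentations is hit).
#'
#' @param params An [observer_params()] (uses `cat_threshold`, `cat_sigma`).
#' @param avatar_ids Avatars to test.
#' @param config A [stair_config()].
#' @param seed Optional integer seed.
#' @param max_presentations Safety cap per session.
#' @param record_log Keep the per-presentation log (disable for large
#'   simulation sweeps).
#' @return List with `stairs` (final states) and `log` (one row per
#'   presentation: `stair_id`, `avatar_id`, `presentation_index`, `level`,
#'   `response`, `step_size`, `is_reversal`; `NULL` when
#'   `record_log = FALSE`).
#' @export
run_staircase_session <- function(params, avatar_ids = c("M1", "M2", "F1", "F2"),
                                  config = stair_config(), seed = NULL,
                                  max_presentations = 2000,
                                  record_log = TRUE) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  session <- init_session(avatar_ids, config)
  log <- if (record_log) vector("list", max_presentations) else NULL
  total <- 0L
  while (any(!vapply(session, `[[`, logical(1), "complete")) &&
         total < max_presentations) {
    i <- next_stair(session)
    st <- session[[i]]
    level <- st$current_level
    response <- simulate_categorization(params, level)
    n_rev_before <- length(st$reversal_levels)
    st <- update_stair(st, response, config)
    total <- total + 1L
    if (record_log) {
      log[[total]] <- list(
        stair_id = st$stair_id, avatar_id = st$avatar_id,
        presentation_index = st$presentations, level = level,
        response = response, step_size = st$step_size,
        is_reversal = length(st$reversal_levels) > n_rev_before
      )
    }
    session[[i]] <- st
  }
  if (record_log) {
    log <- do.call(rbind, lapply(log[seq_len(total)], as.data.frame,
                                 stringsAsFactors = FALSE))
  }
  list(stairs = session, log = log)
}
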