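#' Stimulus continuum for one avatar
#'
#' Builds the 21-level anger-to-happiness morph continuum for a single avatar
#' face. Physical level 1 is the fully angry expression, level 21 the fully
#' happy one, and level 11 the ambiguous midpoint (50% anger, 50% happiness).
#' Anger share at level k is (21 - k)/20 and happiness share (k - 1)/20, so
#' the two shares always sum to one.
#'
#' @param avatar_id Identifier for the avatar (e.g. `"M1"`).
#' @param avatar_sex `"male"` or `"female"`.
#' @return An object of class `continuum_spec`: a list with `avatar_id`,
#'   `avatar_sex`, `n_levels` (always 21), and a data frame `levels` with
#'   columns `level`, `anger_share`, `happiness_share`, `stimulus_id`.
#' @examples
#' cs <- build_continuum("M1", "male")
#' cs$levels$anger_share[11]  # 0.5 at the ambiguous midpoint
#' @export
build_continuum <- function(avatar_id, avatar_sex = c("male", "female")) {
  avatar_sex <- match.arg(avatar_sex)
  level <- 1:21
  levels <- data.frame(
    level = level,
    anger_share = (21 - level) / 20,
    happiness_share = (level - 1) / 20,
    stimulus_id = sprintf("%s_L%02d", avatar_id, level),
    stringsAsFactors = FALSE
  )
  structure(
    list(avatar_id = avatar_id, avatar_sex = avatar_sex,
         n_levels = 21L, levels = levels),
    class = "continuum_spec"
  )
}

#' Animation specification for one emotion condition
#'
#' An animation runs through 11 frames of the continuum and always ends at the
#' ambiguous level 11: angry-to-ambiguous ascends physical levels 1..11,
#' happy-to-ambiguous descends 21..11. The first and last frames are shown for
#' 200 ms, the nine intermediate frames for 80 ms each, and the animation is
#' followed by a 250 ms pixelated mask.
#'
#' @param emotion `"angry_to_ambiguous"` or `"happy_to_ambiguous"`.
#' @param continuum A `continuum_spec` from [build_continuum()].
#' @return An object of class `animation_spec` with `emotion`, `frames`
#'   (physical levels), `durations_ms`, `mask_duration_ms`, and the avatar
#'   identifiers.
#' @export
build_animation <- function(emotion = c("angry_to_ambiguous", "happy_to_ambiguous"),
                            continuum) {
  emotion <- match.arg(emotion)
  stopifnot(inherits(continuum, "continuum_spec"))
  frames <- if (emotion == "angry_to_ambiguous") 1:11 else 21:11
  structure(
    list(
      emotion = emotion,
      avatar_id = continuum$avatar_id,
      avatar_sex = continuum$avatar_sex,
      frames = as.integer(frames),
      durations_ms = c(200, rep(80, 9), 200),
      mask_duration_ms = 250
    ),
    class = "animation_spec"
  )
}

#' Convert a motion-aligned probe level to a physical continuum level
#'
#' The analysis coordinate is motion-aligned: level 11 is the animation
#' endpoint and larger values lie further along the direction of change, for
#' both emotions. For angry-to-ambiguous animations motion direction and
#' physical level coincide (identity map); for happy-to-ambiguous animations
#' the motion descends the continuum, so physical = 22 - motion.
#'
#' @param emotion Emotion condition (vectorised).
#' @param motion_level Integer motion-aligned level(s).
#' @return Integer physical level(s).
#' @examples
#' motion_to_physical("happy_to_ambiguous", 14)  # 8
#' @export
motion_to_physical <- function(emotion, motion_level) {
  stopifnot(all(emotion %in% c("angry_to_ambiguous", "happy_to_ambiguous")))
  motion_level <- as.integer(motion_level)
  ifelse(emotion == "angry_to_ambiguous", motion_level, 22L - motion_level)
}

#' Randomised trial schedule for the probe-judgement task
#'
#' Generates the full factorial crossing 2 Emotion x 2 Avatar Sex x 2 Avatar
#' Identity x 7 Probe x 3 repetitions (168 analysis trials), uniformly
#' shuffled, preceded by 5 training trials drawn from a held-out avatar so
#' none of the training stimuli recur in the main task. A fixation-cross
#' jitter (800-1200 ms) is stored per trial for timeline completeness.
#'
#' @param seed Integer seed; the schedule is fully deterministic given it.
#' @return A data frame with one row per trial and columns `trial_index`,
#'   `is_training`, `emotion`, `avatar_sex`, `avatar_id`,
#'   `probe_motion_level`, `probe_physical_level`, `repetition`,
#'   `fixation_ms`, `seed`.
#' @export
generate_schedule <- function(seed = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed))
  avatars <- data.frame(
    avatar_sex = c("male", "male", "female", "female"),
    avatar_id = c("M1", "M2", "F1", "F2"),
    stringsAsFactors = FALSE
  )
  main <- expand.grid(
    emotion = c("angry_to_ambiguous", "happy_to_ambiguous"),
    avatar_idx = 1:4,
    probe_motion_level = 8:14,
    repetition = 1:3,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  main$avatar_sex <- avatars$avatar_sex[main$avatar_idx]
  main$avatar_id <- avatars$avatar_id[main$avatar_idx]
  main$avatar_idx <- NULL
  main <- main[sample.int(nrow(main)), , drop = FALSE]
  main$is_training <- FALSE

  # held-out avatar "T1": its stimuli never appear in the main task
  training <- data.frame(
    emotion = sample(c("angry_to_ambiguous", "happy_to_ambiguous"), 5, replace = TRUE),
    probe_motion_level = sample(8:14, 5, replace = TRUE),
    repetition = 1L,
    avatar_sex = sample(c("male", "female"), 5, replace = TRUE),
    avatar_id = "T1",
    is_training = TRUE,
    stringsAsFactors = FALSE
  )
  sched <- rbind(training[, names(main)], main)
  sched$probe_physical_level <- motion_to_physical(sched$emotion, sched$probe_motion_level)
  sched$fixation_ms <- round(stats::runif(nrow(sched), 800, 1200))
  sched$trial_index <- seq_len(nrow(sched))
  sched$seed <- as.integer(seed)
  rownames(sched) <- NULL
  sched[, c("trial_index", "is_training", "emotion", "avatar_sex", "avatar_id",
            "probe_motion_level", "probe_physical_level", "repetition",
            "fixation_ms", "seed")]
}

#' Write / read a trial schedule as CSV
#'
#' @param schedule Data frame from [generate_schedule()].
#' @param path File path.
#' @return `read_schedule` returns the schedule data frame.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(schedule, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
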