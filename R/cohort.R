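#' Cohort simulation configuration
#'
#' Describes a synthetic participant cohort with optional group structure.
#' Group-level means for the forward displacements default to the planning
#' values for a high/low schizotypy contrast (high: 0.45 frames for
#' happy-to-ambiguous, -0.1 for angry-to-ambiguous; low: 0.2 and 0.1), with
#' a between-participant SD of 1 frame. Questionnaire totals are truncated
#' discretised normals within each instrument's bounds; SPQ totals can also
#' be produced from simulated item responses (74 yes/no items) so the scorer
#' is exercised end to end.
#'
#' @param n_per_group Participants per group (>= 1).
#' @param groups Group labels; one or two groups.
#' @param delta_happy_mean,delta_angry_mean Named numeric vectors (one value
#'   per group) of mean forward displacement in frames.
#' @param delta_sd Between-participant SD of the displacements (frames).
#' @param sigma_mean,sigma_sd Memory-noise distribution (truncated below at
#'   0.3 frames).
#' @param criterion_mean,criterion_sd Equality criterion distribution
#'   (truncated below at 0.5 frames).
#' @param lapse_max Per-participant lapse rates are uniform on \[0, lapse_max\].
#' @param spq_mean,spq_sd Named per-group mean/SD of the SPQ item-endorsement
#'   propensity scale (total-score scale, 0..74).
#' @param generate_items If `TRUE`, simulate the 74 dichotomous SPQ items and
#'   derive totals/factors from them via [score_spq()] and the synthetic key.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 10,
                          groups = c("high", "low"),
                          delta_happy_mean = c(high = 0.45, low = 0.2),
                          delta_angry_mean = c(high = -0.1, low = 0.1),
                          delta_sd = 1,
                          sigma_mean = 1, sigma_sd = 0.15,
                          criterion_mean = 1.5, criterion_sd = 0.2,
                          lapse_max = 0.08,
                          spq_mean = c(high = 25, low = 11),
                          spq_sd = c(high = 6, low = 5),
                          generate_items = TRUE,
                          seed = 1L) {
  stopifnot(n_per_group >= 1, length(groups) >= 1,
            all(groups %in% names(delta_happy_mean)),
            all(groups %in% names(delta_angry_mean)),
            all(groups %in% names(spq_mean)), all(groups %in% names(spq_sd)),
            delta_sd >= 0, sigma_mean > 0, criterion_mean > 0,
            lapse_max >= 0, lapse_max <= 1)
  structure(
    list(n_per_group = as.integer(n_per_group), groups = groups,
         delta_happy_mean = delta_happy_mean,
         delta_angry_mean = delta_angry_mean, delta_sd = delta_sd,
         sigma_mean = sigma_mean, sigma_sd = sigma_sd,
         criterion_mean = criterion_mean, criterion_sd = criterion_sd,
         lapse_max = lapse_max,
         spq_mean = spq_mean, spq_sd = spq_sd,
         generate_items = generate_items,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

rnorm_trunc <- function(n, mean, sd, lower) {
  pmax(stats::rnorm(n, mean, sd), lower)
}

# discretised normal clamped to an instrument's score range
score_draw <- function(n, mean, sd, lo, hi) {
  pmin(pmax(round(stats::rnorm(n, mean, sd)), lo), hi)
}

#' Synthetic SPQ scoring key
#'
#' The published item-to-dimension key is not reproduced here; this synthetic
#' key assigns the 74 items to the nine dimensions in blocks and maps the
#' dimensions onto the three-factor structure (cognitive-perceptual,
#' interpersonal, disorganised), with suspiciousness loading on both the
#' cognitive-perceptual and interpersonal factors. It exists to exercise the
#' scorer, not to score real SPQ data.
#'
#' @return Data frame with columns `item`, `dimension`, `factors` (a
#'   comma-separated list of factor names).
#' @export
spq_synthetic_key <- function() {
  dims <- c("ideas_of_reference", "odd_beliefs", "unusual_perceptions",
            "suspiciousness", "social_anxiety", "no_close_friends",
            "constricted_affect", "odd_behaviour", "odd_speech")
  dim_factor <- c(
    ideas_of_reference = "cognitive_perceptual",
    odd_beliefs = "cognitive_perceptual",
    unusual_perceptions = "cognitive_perceptual",
    suspiciousness = "cognitive_perceptual,interpersonal",
    social_anxiety = "interpersonal",
    no_close_friends = "interpersonal",
    constricted_affect = "interpersonal",
    odd_behaviour = "disorganised",
    odd_speech = "disorganised"
  )
  dimension <- rep(dims, length.out = 74)[order(rep(seq_along(dims), length.out = 74))]
  data.frame(
    item = 1:74,
    dimension = dimension,
    factors = unname(dim_factor[dimension]),
    stringsAsFactors = FALSE
  )
}

#' Simulate a participant cohort
#'
#' Draws participant-level observer parameters from the group distributions in
#' `config`, runs every participant through a freshly randomised trial
#' schedule of the probe-judgement task, and simulates questionnaire scores.
#' Fully deterministic given `config$seed`.
#'
#' @param config A `cohort_config`.
#' @return List with class `cohort`: `trials` (long-format trial table, one
#'   row per non-training trial per participant, schema of
#'   [simulate_trials()] plus `participant_id` and `group`), `participants`
#'   (one row per participant with questionnaire scores and the true
#'   generative parameters), and, when `config$generate_items`, `spq_items`
#'   (participants x 74 matrix of 0/1 responses).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  groups <- rep(config$groups, each = config$n_per_group)
  n <- length(groups)
  ids <- sprintf("P%03d", seq_len(n))

  delta_happy <- stats::rnorm(n, config$delta_happy_mean[groups], config$delta_sd)
  delta_angry <- stats::rnorm(n, config$delta_angry_mean[groups], config$delta_sd)
  sigma <- rnorm_trunc(n, config$sigma_mean, config$sigma_sd, 0.3)
  criterion <- rnorm_trunc(n, config$criterion_mean, config$criterion_sd, 0.5)
  lapse <- stats::runif(n, 0, config$lapse_max)

  # SPQ: item propensity set so expected total matches the group mean
  spq_mu <- pmin(pmax(stats::rnorm(n, config$spq_mean[groups], config$spq_sd[groups]), 0), 74)
  key <- spq_synthetic_key()
  spq_items <- NULL
  if (config$generate_items) {
    spq_items <- matrix(
      stats::rbinom(n * 74, 1, rep(spq_mu / 74, each = 74)),
      nrow = n, ncol = 74, byrow = TRUE,
      dimnames = list(ids, paste0("item", 1:74))
    )
    spq_scores <- score_spq(spq_items, key)
    spq_total <- spq_scores$total
    spq_cp <- spq_scores$factors[, "cognitive_perceptual"]
    spq_int <- spq_scores$factors[, "interpersonal"]
    spq_dis <- spq_scores$factors[, "disorganised"]
  } else {
    spq_total <- round(spq_mu)
    spq_cp <- round(spq_total * 0.45)
    spq_int <- round(spq_total * 0.45)
    spq_dis <- spq_total - pmin(spq_total, round(spq_total * 0.6))
  }

  participants <- data.frame(
    participant_id = ids, group = groups,
    spq_total = spq_total,
    spq_cognitive_perceptual = spq_cp,
    spq_interpersonal = spq_int,
    spq_disorganised = spq_dis,
    pdi_total = score_draw(n, 6, 3, 0, 21),
    lshs_total = score_draw(n, 15, 8, 0, 64),
    sticsa_state = score_draw(n, 33, 8, 21, 84),
    sticsa_trait = score_draw(n, 36, 9, 21, 84),
    tmt_a = round(rnorm_trunc(n, 25, 8, 8), 1),
    letter_number = score_draw(n, 14, 3, 0, 24),
    delta_happy = delta_happy, delta_angry = delta_angry,
    sigma = sigma, criterion = criterion, lapse = lapse,
    stringsAsFactors = FALSE
  )

  trial_list <- vector("list", n)
  for (i in seq_len(n)) {
    params <- observer_params(
      delta_happy = delta_happy[i], delta_angry = delta_angry[i],
      sigma = sigma[i], criterion = criterion[i], lapse = lapse[i]
    )
    sched <- generate_schedule(seed = sample.int(.Machine$integer.max, 1))
    sched <- sched[!sched$is_training, , drop = FALSE]
    simd <- simulate_trials(params, sched)
    simd$participant_id <- ids[i]
    simd$group <- groups[i]
    trial_list[[i]] <- simd
  }
  trials <- do.call(rbind, trial_list)
  rownames(trials) <- NULL

  structure(list(trials = trials, participants = participants,
                 spq_items = spq_items, config = config),
            class = "cohort")
}
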