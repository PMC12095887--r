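#' Generative observer parameters
#'
#' The synthetic observer remembers the animation endpoint with Gaussian noise
#' and a forward displacement along the motion direction, and answers "equal"
#' when the probe falls within a symmetric interval criterion around the
#' remembered endpoint. Attentional lapses occur with probability `lapse` and
#' guess "equal" with probability `guess_equal`. Confidence ratings 1-4 are a
#' cutpoint mapping of the distance between the decision evidence and the
#' criterion boundary; response times follow a shifted lognormal.
#'
#' All displacement/noise quantities are in motion-aligned frames (the probe
#' coordinate where 11 is the animation endpoint).
#'
#' @param delta_happy,delta_angry Forward displacement (frames) of the
#'   remembered endpoint for happy-to-ambiguous and angry-to-ambiguous
#'   animations; positive values are a forward bias.
#' @param sigma Memory noise SD (frames), > 0.
#' @param criterion Equality half-width c (frames), > 0.
#' @param lapse Lapse probability in \[0, 1\].
#' @param guess_equal Probability a lapse yields "equal" (default 0.5).
#' @param conf_cutpoints Three strictly increasing thresholds on evidence
#'   magnitude mapping to ratings 1-4.
#' @param cat_threshold Physical level of subjective ambiguity used by the
#'   staircase categorizer (default 11).
#' @param cat_sigma Categorization noise SD (physical levels), > 0.
#' @param rt_meanlog,rt_sdlog,rt_shift_ms Shifted-lognormal RT parameters;
#'   `rt_shift_ms` >= 0 bounds the support from below.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(delta_happy = 0.35, delta_angry = 0.1,
                            sigma = 1, criterion = 1.5,
                            lapse = 0.05, guess_equal = 0.5,
                            conf_cutpoints = c(0.5, 1.25, 2.25),
                            cat_threshold = 11, cat_sigma = 1,
                            rt_meanlog = log(400), rt_sdlog = 0.4,
                            rt_shift_ms = 300) {
  stopifnot(sigma > 0, criterion > 0, lapse >= 0, lapse <= 1,
            guess_equal >= 0, guess_equal <= 1,
            length(conf_cutpoints) == 3, all(diff(conf_cutpoints) > 0),
            cat_sigma > 0, rt_shift_ms >= 0)
  structure(
    list(delta_happy = delta_happy, delta_angry = delta_angry,
         sigma = sigma, criterion = criterion,
         lapse = lapse, guess_equal = guess_equal,
         conf_cutpoints = conf_cutpoints,
         cat_threshold = cat_threshold, cat_sigma = cat_sigma,
         rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
         rt_shift_ms = rt_shift_ms),
    class = "observer_params"
  )
}

delta_for <- function(params, emotion) {
  ifelse(emotion == "happy_to_ambiguous", params$delta_happy, params$delta_angry)
}

#' Analytic probability of an "equal" response
#'
#' Closed form for the generative observer: with remembered endpoint
#' mu = 11 + delta(emotion) and Gaussian memory noise sigma, the probe at
#' motion-aligned level L is judged "equal" when it falls within the interval
#' criterion of half-width c, so
#' p = (1 - lapse) \* \[Phi((L - mu + c)/sigma) - Phi((L - mu - c)/sigma)\]
#'   + lapse \* guess_equal.
#' The profile over L is bell-shaped and peaks at mu.
#'
#' @param params An `observer_params`.
#' @param emotion Emotion condition (vectorised, recycled against
#'   `motion_level`).
#' @param motion_level Probe level(s) in the motion-aligned coordinate.
#' @return Probability(ies) in \[0, 1\].
#' @export
equal_probability <- function(params, emotion, motion_level) {
  stopifnot(inherits(params, "observer_params"))
  mu <- 11 + delta_for(params, emotion)
  core <- stats::pnorm((motion_level - mu + params$criterion) / params$sigma) -
    stats::pnorm((motion_level - mu - params$criterion) / params$sigma)
  (1 - params$lapse) * core + params$lapse * params$guess_equal
}

#' Simulate probe-judgement trials
#'
#' Draws the generative mechanism behind [equal_probability()] trial by
#' trial: a noisy remembered endpoint R = 11 + delta + e with
#' e ~ N(0, sigma^2); the response is "equal" iff |L - R| < c. Lapse trials
#' guess "equal" with probability `guess_equal` and draw a uniform confidence
#' rating. Non-lapse confidence maps the evidence margin ||L - R| - c|
#' through the cutpoints (larger margins from the decision boundary give
#' higher ratings). RTs are shifted lognormal.
#'
#' @param params An `observer_params`.
#' @param trials Data frame with columns `emotion` and `probe_motion_level`
#'   (e.g. a schedule from [generate_schedule()]).
#' @return `trials` with added columns `response` ("equal"/"different"),
#'   `confidence` (1-4), `rt_ms`, `is_lapse`.
#' @export
simulate_trials <- function(params, trials) {
  stopifnot(inherits(params, "observer_params"),
            all(c("emotion", "probe_motion_level") %in% names(trials)))
  n <- nrow(trials)
  L <- trials$probe_motion_level
  remembered <- 11 + delta_for(params, trials$emotion) +
    stats::rnorm(n, 0, params$sigma)
  margin <- abs(L - remembered) - params$criterion
  resp <- ifelse(margin < 0, "equal", "different")
  conf <- 1L + findInterval(abs(margin), params$conf_cutpoints)

  is_lapse <- stats::runif(n) < params$lapse
  if (any(is_lapse)) {
    nl <- sum(is_lapse)
    resp[is_lapse] <- ifelse(stats::runif(nl) < params$guess_equal,
                             "equal", "different")
    conf[is_lapse] <- sample.int(4L, nl, replace = TRUE)
  }
  trials$response <- resp
  trials$confidence <- as.integer(conf)
  trials$rt_ms <- params$rt_shift_ms +
    stats::rlnorm(n, params$rt_meanlog, params$rt_sdlog)
  trials$is_lapse <- is_lapse
  trials
}

#' Simulate binary angry/happy categorizations
#'
#' Categorizer for the static ambiguity-threshold task:
#' P("happy") = Phi((level - cat_threshold)/cat_sigma), a monotone link in
#' the physical morph level.
#'
#' @param params An `observer_params`.
#' @param physical_level Physical continuum level(s) in 1..21.
#' @return Character vector of `"angry"`/`"happy"` responses.
#' @export
simulate_categorization <- function(params, physical_level) {
  stopifnot(inherits(params, "observer_params"),
            all(physical_level >= 1 & physical_level <= 21))
  p_happy <- stats::pnorm((physical_level - params$cat_threshold) / params$cat_sigma)
  ifelse(stats::runif(length(physical_level)) < p_happy, "happy", "angry")
}
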