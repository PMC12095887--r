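#' Remove anticipatory responses
#'
#' Trials answered faster than the threshold are treated as outliers and
#' dropped before any aggregation (strict inequality: exactly 250 ms is
#' retained under the default).
#'
#' @param trials Data frame with an `rt_ms` column.
#' @param threshold_ms Cutoff in ms (default 250).
#' @return The retained trials, with attribute `n_removed`.
#' @export
exclude_fast_trials <- function(trials, threshold_ms = 250) {
  if (!"rt_ms" %in% names(trials)) stop("trials must have an 'rt_ms' column")
  keep <- trials$rt_ms >= threshold_ms
  out <- trials[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Proportion-"equal" profiles per participant and emotion
#'
#' Aggregates cleaned trials into one profile per participant x emotion over
#' motion-aligned probe levels 8..14: trial counts, "equal" counts, and their
#' ratio. Training trials (if flagged) are dropped. Levels with no trials are
#' kept with `n_trials = 0` and `NA` proportion, and the profile is flagged.
#'
#' @param trials Data frame with `participant_id`, `emotion`,
#'   `probe_motion_level`, `response`, optionally `is_training`.
#' @return Data frame with columns `participant_id`, `emotion`,
#'   `motion_level`, `n_trials`, `n_equal`, `proportion`.
#' @export
build_profiles <- function(trials) {
  stopifnot(all(c("participant_id", "emotion", "probe_motion_level", "response")
                %in% names(trials)))
  if ("is_training" %in% names(trials))
    trials <- trials[!trials$is_training, , drop = FALSE]
  grid <- expand.grid(
    motion_level = 8:14,
    emotion = unique(trials$emotion),
    participant_id = unique(trials$participant_id),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  key <- interaction(trials$participant_id, trials$emotion,
                     trials$probe_motion_level, drop = FALSE)
  n_trials <- tapply(trials$response, key, length)
  n_equal <- tapply(trials$response == "equal", key, sum)
  gk <- paste(grid$participant_id, grid$emotion, grid$motion_level, sep = ".")
  grid$n_trials <- as.integer(ifelse(is.na(n_trials[gk]), 0L, n_trials[gk]))
  grid$n_equal <- as.integer(ifelse(is.na(n_equal[gk]), 0L, n_equal[gk]))
  grid$proportion <- ifelse(grid$n_trials > 0, grid$n_equal / grid$n_trials, NA_real_)
  grid[, c("participant_id", "emotion", "motion_level",
           "n_trials", "n_equal", "proportion")]
}

#' Scaled logistic probability density
#'
#' The three-parameter curve fitted to proportion-"equal" profiles:
#' f(L) = 4 A exp(-z) / (1 + exp(-z))^2 with z = (L - mu)/s. The factor 4
#' normalises the logistic density kernel so the peak value at L = mu equals
#' the scaling factor A; mu is the PSE and s the deviation from which the
#' JND derives.
#'
#' @param L Probe level(s).
#' @param mu Distribution mean (PSE).
#' @param s Distribution deviation, > 0.
#' @param A Scaling factor (peak proportion), in (0, 1].
#' @return Curve value(s).
#' @export
scaled_logistic_density <- function(L, mu, s, A) {
  stopifnot(s > 0)
  z <- (L - mu) / s
  ez <- exp(-abs(z))          # symmetric kernel, computed stably
  4 * A * ez / (1 + ez)^2
}

#' Fit the scaled logistic density to one proportion profile
#'
#' Least-squares fit of (mu, s, A) to the level-wise proportions, with
#' multi-start initialisation (mu0 at the empirical peak; s0 in
#' \{0.5, 1, 2\}; A0 at the max proportion) and box constraints
#' mu in \[4, 18\], s in \[0.05, 10\], A in (0, 1\]. Profiles that are flat,
#' empty, or fail the optimiser are returned with `converged = FALSE`.
#'
#' @param profile Data frame for one participant x emotion with columns
#'   `motion_level`, `proportion` (and optionally `n_trials`).
#' @param jnd_method Passed to [jnd_from_fit()].
#' @return A one-row data frame of class `psych_fit`: `pse`, `s`, `A`,
#'   `jnd`, `sse`, `converged`.
#' @export
fit_psychometric <- function(profile, jnd_method = "hwhm") {
  ok <- !is.na(profile$proportion)
  L <- profile$motion_level[ok]
  p <- profile$proportion[ok]
  fail <- data.frame(pse = NA_real_, s = NA_real_, A = NA_real_,
                     jnd = NA_real_, sse = NA_real_, converged = FALSE)
  class(fail) <- c("psych_fit", "data.frame")
  if (length(L) < 5) return(fail)
  if (max(p) - min(p) < 1e-8 || max(p) <= 0) return(fail)  # no identifiable peak

  obj <- function(par) {
    sum((scaled_logistic_density(L, par[1], par[2], par[3]) - p)^2)
  }
  lower <- c(4, 0.05, 1e-6)
  upper <- c(18, 10, 1)
  mu0 <- L[which.max(p)]
  A0 <- min(max(p), 1)
  best <- NULL
  for (s0 in c(0.5, 1, 2)) {
    fit <- try(stats::optim(c(mu0, s0, A0), obj, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(factr = 1e4)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(fail)
  out <- data.frame(pse = best$par[1], s = best$par[2], A = best$par[3],
                    sse = best$value, converged = best$convergence == 0)
  out$jnd <- if (out$converged) {
    jnd_from_fit(list(s = out$s), method = jnd_method)
  } else NA_real_
  out <- out[, c("pse", "s", "A", "jnd", "sse", "converged")]
  class(out) <- c("psych_fit", "data.frame")
  out
}

#' JND from a fitted scaled logistic density
#'
#' Default method `"hwhm"` takes the half-width at half the peak of the
#' fitted curve: solving f(L) = A/2 gives |L - mu| = s log(3 + 2 sqrt(2)),
#' so jnd = s log(3 + 2 sqrt(2)) (about 1.76 s). Method `"scale"` reports
#' the raw deviation s.
#'
#' @param fit A fitted object (anything with element `s`).
#' @param method `"hwhm"` or `"scale"`.
#' @return JND in probe-level frames.
#' @export
jnd_from_fit <- function(fit, method = c("hwhm", "scale")) {
  method <- match.arg(method)
  switch(method,
         hwhm = fit$s * log(3 + 2 * sqrt(2)),
         scale = fit$s)
}

#' Fit all participant x emotion profiles
#'
#' @param profiles Output of [build_profiles()].
#' @param jnd_method Passed to [fit_psychometric()].
#' @return Data frame with one row per participant x emotion: `pse`, `s`,
#'   `A`, `jnd`, `sse`, `converged`, plus `excluded`/`exclusion_reason`
#'   columns initialised by [apply_participant_exclusions()].
#' @export
fit_all_profiles <- function(profiles, jnd_method = "hwhm") {
  cells <- unique(profiles[, c("participant_id", "emotion")])
  fits <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- profiles[profiles$participant_id == cells$participant_id[i] &
                      profiles$emotion == cells$emotion[i], , drop = FALSE]
    cbind(cells[i, , drop = FALSE], fit_psychometric(sub, jnd_method))
  }))
  rownames(fits) <- NULL
  apply_participant_exclusions(fits)
}

#' Participant-level PSE exclusions
#'
#' A participant is excluded entirely (both emotion conditions) when either
#' condition's PSE falls below 5 or exceeds 16 — three levels beyond the most
#' extreme probes — or when either fit failed to converge. Idempotent.
#'
#' @param fits Data frame from [fit_all_profiles()] (or with the same
#'   columns).
#' @param pse_bounds Length-2 numeric; PSEs strictly outside these bounds
#'   trigger exclusion.
#' @return `fits` with logical `excluded` and character `exclusion_reason`.
#' @export
apply_participant_exclusions <- function(fits, pse_bounds = c(5, 16)) {
  stopifnot(length(pse_bounds) == 2, pse_bounds[1] < pse_bounds[2])
  bad_fit <- !fits$converged
  bad_pse <- !is.na(fits$pse) & (fits$pse < pse_bounds[1] | fits$pse > pse_bounds[2])
  flag <- bad_fit | bad_pse
  bad_ids <- unique(fits$participant_id[flag])
  fits$excluded <- fits$participant_id %in% bad_ids
  reason <- rep(NA_character_, nrow(fits))
  reason[fits$excluded] <- "participant-level exclusion"
  reason[bad_pse] <- "pse out of bounds"
  reason[bad_fit] <- "fit not converged"
  fits$exclusion_reason <- reason
  fits
}

#' Does the forward bias exceed the discrimination threshold?
#'
#' TRUE when the representational-momentum magnitude (PSE - 11) is strictly
#' greater than the JND, i.e. the remembered endpoint is displaced beyond
#' the observer's own discrimination precision.
#'
#' @param fit A fit row (elements `pse` and `jnd`).
#' @return Logical (vectorised over rows of a data frame input).
#' @export
rm_exceeds_jnd <- function(fit) {
  (fit$pse - 11) > fit$jnd
}
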