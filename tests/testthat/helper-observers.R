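# Shared fixtures built in code.

unbiased_observer <- function(...) {
  observer_params(delta_happy = 0, delta_angry = 0, sigma = 1,
                  criterion = 1.5, lapse = 0, ...)
}

# trial frame replicating one probe condition n times
one_trial_rep <- function(emotion, motion_level, n) {
  data.frame(emotion = emotion, probe_motion_level = motion_level)[rep(1, n), ,
                                                                   drop = FALSE]
}

# analytic proportion-"equal" profile over the probed levels
analytic_profile <- function(params, emotion = "happy_to_ambiguous") {
  data.frame(
    motion_level = 8:14,
    proportion = equal_probability(params, emotion, 8:14)
  )
}

# long-format dataset for the 2x2 mixed ANOVA with given cell means
make_mixed_data <- function(n1, n2, means = c(0, 0, 0, 0), sd = 1) {
  grp <- rep(c("g1", "g2"), c(n1, n2))
  id <- sprintf("s%02d", seq_along(grp))
  mu <- matrix(means, 2, 2, byrow = TRUE)  # rows: group; cols: within level
  gi <- as.integer(factor(grp))
  data.frame(
    participant_id = rep(id, 2),
    group = rep(grp, 2),
    emotion = rep(c("w1", "w2"), each = length(grp)),
    value = c(stats::rnorm(length(grp), mu[gi, 1], sd),
              stats::rnorm(length(grp), mu[gi, 2], sd))
  )
}

# independent mixed-ANOVA oracle via aov() with an Error() stratum
aov_mixed_oracle <- function(data) {
  data$group <- factor(data$group)
  data$emotion <- factor(data$emotion)
  data$participant_id <- factor(data$participant_id)
  fit <- stats::aov(value ~ group * emotion + Error(participant_id), data = data)
  s <- summary(fit)
  between <- s[["Error: participant_id"]][[1]]
  within <- s[["Error: Within"]][[1]]
  c(group = between["group", "F value"],
    within = within["emotion", "F value"],
    interaction = within["group:emotion", "F value"])
}
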