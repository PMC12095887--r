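#!/usr/bin/env Rscript
# Ambiguity-threshold task: interleaved two-up/two-down staircases per avatar
# for every simulated participant; per-avatar-sex thresholds and staircase JND.
library(rmfaces)

participants <- read.csv("results/participants.csv", stringsAsFactors = FALSE)
set.seed(20260904)

rows <- list()
for (i in seq_len(nrow(participants))) {
  # subjective ambiguity drawn around the morph midpoint per participant
  obs <- observer_params(cat_threshold = rnorm(1, 10.8, 0.8), cat_sigma = 1)
  out <- run_staircase_session(obs, c("M1", "M2", "F1", "F2"),
                               record_log = FALSE)
  for (sex in c("male", "female")) {
    avs <- if (sex == "male") c("M1", "M2") else c("F1", "F2")
    stairs <- out$stairs[vapply(out$stairs, function(s) s$avatar_id %in% avs,
                                logical(1))]
    rows[[length(rows) + 1]] <- data.frame(
      participant_id = participants$participant_id[i], avatar_sex = sex,
      threshold = ambiguity_threshold(stairs),
      jnd = staircase_jnd(stairs)
    )
  }
}
thr <- do.call(rbind, rows)
write.csv(thr, "results/ambiguity_thresholds.csv", row.names = FALSE)

for (sex in c("female", "male")) {
  d <- thr[thr$avatar_sex == sex, ]
  tt <- one_sample_t(d$threshold, mu0 = 11, tail = "two")
  cat(sprintf("%s avatars: threshold M = %.2f (SE %.2f), t(%d) = %.2f, p = %.4f; staircase JND M = %.2f\n",
              sex, mean(d$threshold), sd(d$threshold) / sqrt(nrow(d)),
              tt$df, tt$t, tt$p, mean(d$jnd)))
}
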