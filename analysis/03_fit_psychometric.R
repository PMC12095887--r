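#!/usr/bin/env Rscript
# PSE/JND estimation: RT exclusion, proportion-"equal" profiles, scaled
# logistic-density fits, participant-level exclusions, forward-bias tests.
library(rmfaces)

trials <- read_trials("results/trials.csv")
clean <- exclude_fast_trials(trials, 250)
cat(sprintf("fast-RT exclusion: %d of %d trials (%.2f%%)\n",
            attr(clean, "n_removed"), nrow(trials),
            100 * attr(clean, "n_removed") / nrow(trials)))

profiles <- build_profiles(clean)
fits <- fit_all_profiles(profiles, jnd_method = "hwhm")
write.csv(fits, "results/fits.csv", row.names = FALSE)

n_excl <- length(unique(fits$participant_id[fits$excluded]))
cat(sprintf("participants excluded (PSE < 5 or > 16, or failed fit): %d\n", n_excl))

retained <- fits[!fits$excluded, ]
for (em in sort(unique(retained$emotion))) {
  d <- retained[retained$emotion == em, ]
  tt <- one_sample_t(d$pse, mu0 = 11, tail = "greater")
  cat(sprintf("%s: PSE M = %.2f (SE %.2f), JND M = %.2f; forward bias t(%d) = %.2f, p = %.4f, d = %.3f\n",
              em, mean(d$pse), sd(d$pse) / sqrt(nrow(d)), mean(d$jnd),
              tt$df, tt$t, tt$p, tt$d))
}
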