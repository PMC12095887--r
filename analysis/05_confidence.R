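#!/usr/bin/env Rscript
# Second-order task: weighted confidence (proportion of "equal" errors times
# their mean confidence) per participant and emotion.
library(rmfaces)

trials <- read_trials("results/trials.csv")
clean <- exclude_fast_trials(trials, 250)
fits <- read.csv("results/fits.csv", stringsAsFactors = FALSE)
keep <- unique(fits$participant_id[!fits$excluded])

conf <- weighted_confidence_all(clean[clean$participant_id %in% keep, ])
write.csv(conf, "results/weighted_confidence.csv", row.names = FALSE)

for (em in sort(unique(conf$emotion))) {
  d <- conf[conf$emotion == em, ]
  cat(sprintf("%s: weighted confidence M = %.2f (SE %.2f)\n",
              em, mean(d$weighted_confidence),
              sd(d$weighted_confidence) / sqrt(nrow(d))))
}
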