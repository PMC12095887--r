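#!/usr/bin/env Rscript
# Simulate the synthetic cohort: 40 observers per schizotypy group, each run
# through the full 168-trial probe-judgement task, with questionnaire scores.
library(rmfaces)

dir.create("results", showWarnings = FALSE)
cfg <- cohort_config(n_per_group = 40, seed = 20260902)
cohort <- simulate_cohort(cfg)

write_trials(cohort$trials, "results/trials.csv")
write.csv(cohort$participants, "results/participants.csv", row.names = FALSE)

cat(sprintf("simulated %d participants (%d trials)\n",
            nrow(cohort$participants), nrow(cohort$trials)))
cat(sprintf("SPQ totals: M = %.1f, SD = %.1f, range %d-%d\n",
            mean(cohort$participants$spq_total),
            sd(cohort$participants$spq_total),
            min(cohort$participants$spq_total),
            max(cohort$participants$spq_total)))
alpha <- cronbach_alpha(cohort$spq_items)
cat(sprintf("Cronbach's alpha of the simulated SPQ items: %.2f\n", alpha))
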