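#!/usr/bin/env Rscript
# Group-level statistics: SPQ median split, 2x2 mixed ANOVAs on PSE, JND and
# weighted confidence, covariate ANCOVAs, correlations, and the chi-square on
# exceeding one's own JND.
library(rmfaces)

trials <- read_trials("results/trials.csv")
participants <- read.csv("results/participants.csv", stringsAsFactors = FALSE)

report <- run_pipeline(trials, participants, split = "median",
                       split_var = "spq_total")
print(report)

tidy <- do.call(rbind, lapply(
  list(pse = report$anova_pse, jnd = report$anova_jnd,
       confidence = report$anova_confidence),
  function(tab) as.data.frame(tab)
))
tidy$outcome <- rep(c("pse", "jnd", "weighted_confidence"), each = 3)
write.csv(tidy[, c("outcome", "effect", "df_num", "df_den", "F", "p",
                   "partial_eta_sq")],
          "results/anova_tables.csv", row.names = FALSE)

# chi-square: representational momentum beyond one's own JND, by group
for (em in names(report$rm_vs_jnd)) {
  x <- report$rm_vs_jnd[[em]]
  cat(sprintf("RM > JND vs group (%s): chi2(1) = %.2f, p = %.3f\n",
              em, x$chi2, x$p))
}

# covariate ANCOVAs on PSE (mean-centred, one covariate at a time)
retained <- report$fits[!report$fits$excluded, ]
pse_long <- data.frame(participant_id = retained$participant_id,
                       emotion = retained$emotion, value = retained$pse)
covs <- c("spq_total", "spq_cognitive_perceptual", "spq_interpersonal",
          "spq_disorganised", "pdi_total", "lshs_total",
          "sticsa_state", "sticsa_trait", "tmt_a", "letter_number")
anc <- do.call(rbind, lapply(covs, function(cv) {
  d <- merge(pse_long, participants[, c("participant_id", cv)],
             by = "participant_id")
  names(d)[names(d) == cv] <- "covariate"
  tab <- rm_ancova_2level(d, "covariate")
  data.frame(covariate = cv,
             F_interaction = tab$F[tab$effect == "within_x_covariate"],
             p_interaction = tab$p[tab$effect == "within_x_covariate"])
}))
write.csv(anc, "results/ancova_pse.csv", row.names = FALSE)
cat(sprintf("covariate x emotion interactions: %d of %d with p < .05\n",
            sum(anc$p_interaction < 0.05), nrow(anc)))

# Spearman correlations of PSE (happy-to-ambiguous) with trait measures
happy <- pse_long[pse_long$emotion == "happy_to_ambiguous", ]
m <- merge(happy, participants, by = "participant_id")
for (cv in c("spq_total", "pdi_total", "lshs_total")) {
  sr <- spearman_rho(m$value, m[[cv]])
  cat(sprintf("Spearman PSE ~ %s: rho = %.3f, p = %.3f\n", cv, sr$rho, sr$p))
}

# normality of the PSE distributions
for (em in sort(unique(pse_long$emotion))) {
  ks <- ks_normality(pse_long$value[pse_long$emotion == em])
  cat(sprintf("KS normality (%s): D = %.3f, p = %.3f\n", em, ks$D, ks$p))
}
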