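#' Run the full analysis pipeline
#'
#' End-to-end replay of the study's analysis chain on a trial table:
#' fast-RT exclusion, proportion-"equal" profiles, scaled logistic-density
#' fits (PSE/JND), participant-level PSE exclusions, weighted confidence,
#' group split, the 2 x 2 mixed ANOVAs on PSE, JND and weighted confidence,
#' one-sample forward-bias t tests per emotion, and the chi-square
#' association between exceeding one's own JND and group. Every stage logs
#' its counts.
#'
#' @param trials Trial table (schema of [read_trials()]); e.g.
#'   `simulate_cohort(config)$trials`.
#' @param participants Participant table with a `spq_total` column (and any
#'   covariates); defaults to splitting on `spq_total`.
#' @param rt_threshold_ms Fast-trial cutoff (ms).
#' @param pse_bounds Participant-exclusion bounds on the PSE.
#' @param jnd_method Passed to [fit_all_profiles()].
#' @param split `"median"` or `"tertile"` split of `split_var`.
#' @param split_var Participant column used for the group split.
#' @return List of class `rm_report`: `log` (named counts), `fits`,
#'   `confidence`, `groups`, `anova_pse`, `anova_jnd`, `anova_confidence`,
#'   `forward_bias` (per-emotion one-sample t), `rm_vs_jnd` (chi-square),
#'   `retained_participants`.
#' @export
run_pipeline <- function(trials, participants,
                         rt_threshold_ms = 250, pse_bounds = c(5, 16),
                         jnd_method = "hwhm",
                         split = c("median", "tertile"),
                         split_var = "spq_total") {
  split <- match.arg(split)
  validate_trials(trials)
  log <- list(n_trials_in = nrow(trials))

  trials <- exclude_fast_trials(trials, rt_threshold_ms)
  log$n_fast_removed <- attr(trials, "n_removed")
  log$pct_fast_removed <- 100 * log$n_fast_removed / log$n_trials_in

  profiles <- build_profiles(trials)
  fits <- fit_all_profiles(profiles, jnd_method)
  fits <- apply_participant_exclusions(fits, pse_bounds)
  log$n_participants_in <- length(unique(fits$participant_id))
  excluded_ids <- unique(fits$participant_id[fits$excluded])
  log$n_participants_excluded <- length(excluded_ids)
  retained <- fits[!fits$excluded, , drop = FALSE]
  keep_ids <- unique(retained$participant_id)

  conf <- weighted_confidence_all(
    trials[trials$participant_id %in% keep_ids, , drop = FALSE]
  )

  scores <- participants[[split_var]][match(keep_ids, participants$participant_id)]
  labels <- if (split == "median") median_split(scores) else tertile_split(scores)
  groups <- data.frame(participant_id = keep_ids, group = labels,
                       stringsAsFactors = FALSE)
  analysed <- groups[groups$group %in% c("high", "low"), , drop = FALSE]
  log$n_high <- sum(analysed$group == "high")
  log$n_low <- sum(analysed$group == "low")

  with_group <- function(df, value_col) {
    df <- merge(df, analysed, by = "participant_id")
    df$value <- df[[value_col]]
    df
  }
  pse_data <- with_group(retained, "pse")
  jnd_data <- with_group(retained, "jnd")
  conf_data <- with_group(conf, "weighted_confidence")

  anova_pse <- mixed_anova_2x2(pse_data)
  anova_jnd <- mixed_anova_2x2(jnd_data)
  anova_conf <- mixed_anova_2x2(conf_data)

  forward_bias <- lapply(split(retained, retained$emotion), function(d) {
    one_sample_t(d$pse, mu0 = 11, tail = "greater")
  })

  rm_vs_jnd <- lapply(split(pse_data, pse_data$emotion), function(d) {
    jnd <- jnd_data$value[match(paste(d$participant_id, d$emotion),
                                paste(jnd_data$participant_id, jnd_data$emotion))]
    exceeds <- (d$value - 11) > jnd
    hi <- d$group == "high"
    tryCatch(
      chi_square_2x2(sum(exceeds & hi), sum(!exceeds & hi),
                     sum(exceeds & !hi), sum(!exceeds & !hi)),
      error = function(e) list(chi2 = NA_real_, df = 1L, p = NA_real_,
                               note = conditionMessage(e))
    )
  })

  structure(
    list(log = log, fits = fits, confidence = conf, groups = groups,
         anova_pse = anova_pse, anova_jnd = anova_jnd,
         anova_confidence = anova_conf, forward_bias = forward_bias,
         rm_vs_jnd = rm_vs_jnd, retained_participants = keep_ids),
    class = "rm_report"
  )
}

#' @export
print.rm_report <- function(x, ...) {
  cat("Representational-momentum analysis report\n")
  cat(sprintf("  trials in: %d; fast-RT removed: %d (%.2f%%)\n",
              x$log$n_trials_in, x$log$n_fast_removed, x$log$pct_fast_removed))
  cat(sprintf("  participants: %d in, %d excluded; groups high/low: %d/%d\n",
              x$log$n_participants_in, x$log$n_participants_excluded,
              x$log$n_high, x$log$n_low))
  cat("\nPSE 2x2 mixed ANOVA:\n")
  print(as.data.frame(x$anova_pse), digits = 4)
  cat("\nWeighted-confidence 2x2 mixed ANOVA:\n")
  print(as.data.frame(x$anova_confidence), digits = 4)
  for (em in names(x$forward_bias)) {
    fb <- x$forward_bias[[em]]
    cat(sprintf("\nForward bias (%s): t(%d) = %.2f, p = %.4f, d = %.3f\n",
                em, fb$df, fb$t, fb$p, fb$d))
  }
  invisible(x)
}
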