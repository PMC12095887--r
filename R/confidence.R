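#' Weighted confidence for biased "equal" judgements
#'
#' Summarises second-order performance as the product of the proportion of
#' "equal" errors and the mean confidence of those errors. An "equal" error
#' is an "equal" response to a probe that differs from the animation
#' endpoint (motion level != 11); only these errors enter, since they index
#' confidence in the context of a perceptual bias. With pooled aggregation
#' (default) the proportion is taken over all different-probe trials and the
#' confidence mean over all such errors; with per-level aggregation the
#' product is computed per non-endpoint probe level and then averaged over
#' the six levels (levels with no trials are skipped). A participant with no
#' "equal" errors scores 0.
#'
#' @param trials Cleaned trial data frame with `participant_id`, `emotion`,
#'   `probe_motion_level`, `response`, `confidence`.
#' @param participant,emotion The cell to summarise.
#' @param aggregation `"pooled"` or `"per_level"`.
#' @return One-row data frame: `participant_id`, `emotion`,
#'   `prop_equal_errors`, `mean_conf_equal_errors`, `weighted_confidence`
#'   (in \[0, 4\]).
#' @export
weighted_confidence <- function(trials, participant, emotion,
                                aggregation = c("pooled", "per_level")) {
  aggregation <- match.arg(aggregation)
  sub <- trials[trials$participant_id == participant &
                  trials$emotion == emotion &
                  trials$probe_motion_level != 11, , drop = FALSE]
  if (nrow(sub) == 0) stop("no different-probe trials for this cell")
  err <- sub$response == "equal"

  if (aggregation == "pooled") {
    prop <- mean(err)
    mean_conf <- if (any(err)) mean(sub$confidence[err]) else NA_real_
    wc <- if (any(err)) prop * mean_conf else 0
  } else {
    per <- vapply(split(sub, sub$probe_motion_level), function(d) {
      e <- d$response == "equal"
      if (!any(e)) return(0)
      mean(e) * mean(d$confidence[e])
    }, numeric(1))
    prop <- mean(err)
    mean_conf <- if (any(err)) mean(sub$confidence[err]) else NA_real_
    wc <- mean(per)
  }
  data.frame(participant_id = participant, emotion = emotion,
             prop_equal_errors = prop, mean_conf_equal_errors = mean_conf,
             weighted_confidence = wc, stringsAsFactors = FALSE)
}

#' Weighted confidence for every participant x emotion cell
#'
#' @param trials Cleaned trial data frame.
#' @param aggregation Passed to [weighted_confidence()].
#' @return Data frame with one row per cell.
#' @export
weighted_confidence_all <- function(trials, aggregation = "pooled") {
  cells <- unique(trials[, c("participant_id", "emotion")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    weighted_confidence(trials, cells$participant_id[i], cells$emotion[i],
                        aggregation)
  }))
  rownames(out) <- NULL
  out
}
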