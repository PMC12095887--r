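#' Read and validate a trial table
#'
#' Validates the documented schema (participant_id, group, emotion,
#' avatar_sex, avatar_id, probe_motion_level, response, rt_ms, confidence)
#' with row-level diagnostics: responses must be "equal"/"different",
#' confidence an integer in 1..4, probe levels in 8..14, RTs positive.
#'
#' @param path CSV path (UTF-8, header row, "." decimal).
#' @return Validated data frame.
#' @export
read_trials <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials(trials)
  trials
}

#' @rdname read_trials
#' @param trials Trial data frame to write.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

validate_trials <- function(trials) {
  required <- c("participant_id", "emotion", "probe_motion_level",
                "response", "rt_ms", "confidence")
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0)
    stop("missing column(s): ", paste(missing, collapse = ", "))
  check <- function(bad, column, what) {
    if (any(bad))
      stop(sprintf("invalid %s in column '%s' at row(s) %s", what, column,
                   paste(utils::head(which(bad), 5), collapse = ", ")))
  }
  check(!trials$response %in% c("equal", "different"), "response",
        "response value (must be 'equal' or 'different')")
  check(!(trials$confidence %in% 1:4), "confidence",
        "confidence rating (must be an integer 1-4)")
  check(!(trials$probe_motion_level %in% 8:14), "probe_motion_level",
        "probe level (must be 8-14)")
  check(!is.finite(trials$rt_ms) | trials$rt_ms <= 0, "rt_ms",
        "response time (must be positive)")
  check(!trials$emotion %in% c("angry_to_ambiguous", "happy_to_ambiguous"),
        "emotion", "emotion condition")
  invisible(TRUE)
}

#' Mean absolute pixel-wise difference, as a percentage
#'
#' Mean over pixels (and channels) of |a - b| divided by the intensity
#' range, times 100. Used to check that equidistant probes differ from the
#' animation endpoint by comparable physical amounts.
#'
#' @param image_a,image_b Numeric arrays of identical dimensions, or paths
#'   to PNG files (read with the png package).
#' @param range Intensity range of the encoding (1 for \[0,1\] arrays as
#'   returned by png, 255 for 8-bit integer arrays).
#' @return Percentage in \[0, 100\].
#' @export
pixel_diff_percent <- function(image_a, image_b, range = 1) {
  if (is.character(image_a)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG files requires the 'png' package")
    image_a <- png::readPNG(image_a)
    image_b <- png::readPNG(image_b)
  }
  if (!identical(dim(image_a), dim(image_b)) ||
      length(image_a) != length(image_b))
    stop("image dimensions differ")
  stopifnot(range > 0)
  100 * mean(abs(image_a - image_b)) / range
}
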