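#' Score the SPQ from item responses
#'
#' Totals, dimension scores, and factor scores are all counts of "yes"
#' responses. The key map assigns each of the 74 items to one of nine
#' dimensions and each dimension to one or more of the three factors
#' (suspiciousness loads on both the cognitive-perceptual and interpersonal
#' factors, so factor scores can jointly exceed the total).
#'
#' @param items An n x 74 matrix (0/1, logical, or `"yes"`/`"no"`).
#' @param key Key map data frame with columns `item`, `dimension`, `factors`
#'   (comma-separated factor names); see [spq_synthetic_key()].
#' @return List with `total` (length n), `dimensions` (n x 9 matrix) and
#'   `factors` (n x 3 matrix).
#' @export
score_spq <- function(items, key = spq_synthetic_key()) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (is.character(items)) {
    items <- matrix(as.integer(items == "yes"), nrow = nrow(items),
                    dimnames = dimnames(items))
  }
  items <- matrix(as.integer(items), nrow = NROW(items),
                  dimnames = dimnames(items))
  if (ncol(items) != 74) stop("SPQ requires exactly 74 items, got ", ncol(items))
  stopifnot(all(items %in% c(0L, 1L)), nrow(key) == 74)

  dims <- sort(unique(key$dimension))
  dimensions <- sapply(dims, function(d) {
    rowSums(items[, key$item[key$dimension == d], drop = FALSE])
  })
  if (is.null(dim(dimensions))) dimensions <- t(dimensions)
  facs <- c("cognitive_perceptual", "interpersonal", "disorganised")
  factors <- sapply(facs, function(f) {
    in_f <- vapply(strsplit(key$factors, ","), function(x) f %in% x, logical(1))
    rowSums(items[, key$item[in_f], drop = FALSE])
  })
  if (is.null(dim(factors))) factors <- t(factors)
  list(total = rowSums(items), dimensions = dimensions, factors = factors)
}

#' Median split into high/low groups
#'
#' Scores above the sample median are labelled `"high"`, below `"low"`;
#' scores exactly at the median follow `ties` (default `"low"`).
#'
#' @param scores Numeric vector (>= 2 values, not all equal).
#' @param ties `"low"` or `"high"`.
#' @return Character vector of labels, same order as `scores`.
#' @export
median_split <- function(scores, ties = c("low", "high")) {
  ties <- match.arg(ties)
  stopifnot(length(scores) >= 2)
  if (max(scores) == min(scores)) stop("all scores equal; no split possible")
  med <- stats::median(scores)
  out <- ifelse(scores > med, "high", ifelse(scores < med, "low", ties))
  out
}

#' Tertile split into high/low groups, middle discarded
#'
#' Rank-based thirds via the sample tertiles; scores strictly below the
#' lower tertile are `"low"`, strictly above the upper tertile `"high"`,
#' and everything else (including boundary ties) `"middle"`, to be
#' discarded by the caller.
#'
#' @param scores Numeric vector.
#' @return Character vector of `"low"`/`"middle"`/`"high"` labels.
#' @export
tertile_split <- function(scores) {
  stopifnot(length(scores) >= 3)
  q <- stats::quantile(scores, c(1 / 3, 2 / 3), names = FALSE)
  ifelse(scores < q[1], "low", ifelse(scores > q[2], "high", "middle"))
}

#' Two-by-two mixed-design ANOVA
#'
#' Classical decomposition for one between-subjects factor (2 groups) and
#' one within-subjects factor (2 conditions per subject). The group effect
#' is tested against the between-subject error (subject means); the within
#' effect and the interaction are tested against the subject-by-condition
#' error via the per-subject difference scores, with unweighted
#' (type III) marginal means so unequal group sizes are handled as standard
#' ANOVA software does. All three effects have df (1, N - 2). Partial
#' eta-squared is SS_effect / (SS_effect + SS_error).
#'
#' @param data Long data frame.
#' @param y,subject,group,within Column names.
#' @return Data frame of class `anova_table`: one row per effect (`group`,
#'   `within`, `interaction`) with `SS`, `df_num`, `df_den`, `F`, `p`,
#'   `partial_eta_sq`.
#' @export
mixed_anova_2x2 <- function(data, y = "value", subject = "participant_id",
                            group = "group", within = "emotion") {
  g_levels <- sort(unique(data[[group]]))
  w_levels <- sort(unique(data[[within]]))
  if (length(g_levels) != 2 || length(w_levels) != 2)
    stop("mixed_anova_2x2 requires exactly 2 groups and 2 within levels")
  wide <- stats::reshape(
    data[, c(subject, group, within, y)],
    idvar = c(subject, group), timevar = within, direction = "wide"
  )
  y1 <- wide[[paste0(y, ".", w_levels[1])]]
  y2 <- wide[[paste0(y, ".", w_levels[2])]]
  if (anyNA(y1) || anyNA(y2)) stop("every subject needs both within-level values")
  grp <- wide[[group]]
  n1 <- sum(grp == g_levels[1]); n2 <- sum(grp == g_levels[2])
  N <- n1 + n2
  if (min(n1, n2) < 2) stop("need at least 2 subjects per group")

  m <- (y1 + y2) / 2          # subject means -> between-subject stratum
  d <- y1 - y2                # difference scores -> within stratum
  safe_F <- function(ss_eff, ms_err) {
    if (ss_eff == 0) 0 else ss_eff / ms_err   # zero effect beats a zero error
  }
  m1 <- mean(m[grp == g_levels[1]]); m2 <- mean(m[grp == g_levels[2]])
  ss_serr <- 2 * sum((m - ifelse(grp == g_levels[1], m1, m2))^2)
  ms_serr <- ss_serr / (N - 2)
  # group contrast on subject means (equals the pooled two-sample t^2)
  ss_group <- 2 * (m1 - m2)^2 / (1 / n1 + 1 / n2)
  F_group <- safe_F(ss_group, ms_serr)

  d1 <- mean(d[grp == g_levels[1]]); d2 <- mean(d[grp == g_levels[2]])
  ss_werr <- sum((d - ifelse(grp == g_levels[1], d1, d2))^2) / 2
  sigma2_d <- 2 * ss_werr / (N - 2)           # residual variance of d
  inv_n <- 1 / n1 + 1 / n2
  F_within <- safe_F((d1 + d2)^2 / inv_n, sigma2_d)  # unweighted marginal mean
  F_inter <- safe_F((d1 - d2)^2 / inv_n, sigma2_d)
  ms_werr <- ss_werr / (N - 2)

  eff <- c("group", "within", "interaction")
  Fv <- c(F_group, F_within, F_inter)
  ss_eff <- Fv * c(ms_serr, ms_werr, ms_werr)
  out <- data.frame(
    effect = eff, SS = ss_eff, df_num = 1L, df_den = N - 2L, F = Fv,
    p = stats::pf(Fv, 1, N - 2, lower.tail = FALSE),
    partial_eta_sq = Fv / (Fv + (N - 2)),
    stringsAsFactors = FALSE
  )
  attr(out, "errors") <- data.frame(
    stratum = c("between_subject", "within_subject"),
    SS = c(ss_serr, ss_werr), df = c(N - 2L, N - 2L),
    MS = c(ms_serr, ms_werr)
  )
  attr(out, "cells") <- data.frame(
    group = rep(g_levels, each = 2), within = rep(w_levels, 2),
    mean = c(mean(y1[grp == g_levels[1]]), mean(y2[grp == g_levels[1]]),
             mean(y1[grp == g_levels[2]]), mean(y2[grp == g_levels[2]])),
    n = rep(c(n1, n2), each = 2)
  )
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Repeated-measures ANCOVA with a 2-level within factor
#'
#' Mean-centres the covariate, then tests: the within (emotion) main effect
#' as the intercept of the regression of the within-subject difference
#' scores on the centred covariate; the covariate-by-within interaction as
#' the slope of that regression; and the covariate main effect as the slope
#' of the regression of the subject means on the centred covariate. All
#' tests have df (1, N - 2).
#'
#' @param data Long data frame (two rows per subject).
#' @param covariate Name of a numeric per-subject covariate column.
#' @param y,subject,within Column names.
#' @return `anova_table` with rows `within`, `covariate`,
#'   `within_x_covariate`.
#' @export
rm_ancova_2level <- function(data, covariate, y = "value",
                             subject = "participant_id", within = "emotion") {
  w_levels <- sort(unique(data[[within]]))
  stopifnot(length(w_levels) == 2)
  wide <- stats::reshape(
    data[, c(subject, covariate, within, y)],
    idvar = c(subject, covariate), timevar = within, direction = "wide"
  )
  y1 <- wide[[paste0(y, ".", w_levels[1])]]
  y2 <- wide[[paste0(y, ".", w_levels[2])]]
  x <- wide[[covariate]]
  if (stats::var(x) == 0) stop("zero-variance covariate")
  xc <- x - mean(x)
  N <- length(x)
  d <- y1 - y2
  m <- (y1 + y2) / 2

  t_from_lm <- function(resp, pred) {
    fit <- stats::lm(resp ~ pred)
    s <- summary(fit)$coefficients
    s[, "t value"]^2
  }
  Fd <- t_from_lm(d, xc)     # intercept -> within main; slope -> interaction
  Fm <- t_from_lm(m, xc)     # slope -> covariate main effect
  Fv <- c(Fd[1], Fm[2], Fd[2])
  out <- data.frame(
    effect = c("within", "covariate", "within_x_covariate"),
    df_num = 1L, df_den = N - 2L, F = Fv,
    p = stats::pf(Fv, 1, N - 2, lower.tail = FALSE),
    partial_eta_sq = Fv / (Fv + (N - 2)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("anova_table", "data.frame")
  out
}

#' One-sample t test with Cohen's d
#'
#' @param values Numeric vector (n >= 2, non-zero SD).
#' @param mu0 Null value.
#' @param tail `"two"`, `"greater"` (mean > mu0) or `"less"`.
#' @return List with `t`, `df`, `p`, `d` (Cohen's d = (mean - mu0)/sd).
#' @export
one_sample_t <- function(values, mu0 = 0, tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  n <- length(values)
  stopifnot(n >= 2)
  s <- stats::sd(values)
  if (s == 0) stop("zero standard deviation")
  t <- (mean(values) - mu0) / (s / sqrt(n))
  p <- switch(tail,
              two = 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE),
              greater = stats::pt(t, n - 1, lower.tail = FALSE),
              less = stats::pt(t, n - 1))
  list(t = t, df = n - 1, p = p, d = (mean(values) - mu0) / s)
}

#' Tukey-corrected pairwise comparisons of design cells
#'
#' Studentized-range adjusted p-values for all pairwise differences among
#' the cell means, using the Tukey-Kramer statistic
#' q = |m_i - m_j| / sqrt((MS_error / 2)(1/n_i + 1/n_j)).
#'
#' @param cell_means Named numeric vector of cell means (e.g. the 4 cells of
#'   the 2 x 2 design).
#' @param ms_error Error mean square the comparisons are tested against.
#' @param n Cell sizes (scalar or one per cell).
#' @param df_error Error degrees of freedom.
#' @return Data frame with one row per pair: `cell_a`, `cell_b`, `diff`,
#'   `q`, `p_adj`.
#' @export
tukey_posthoc <- function(cell_means, ms_error, n, df_error) {
  k <- length(cell_means)
  stopifnot(k >= 2, ms_error > 0, df_error >= 1)
  if (length(n) == 1) n <- rep(n, k)
  nm <- names(cell_means)
  if (is.null(nm)) nm <- paste0("cell", seq_len(k))
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    cell_a = nm[pairs[1, ]], cell_b = nm[pairs[2, ]],
    diff = cell_means[pairs[1, ]] - cell_means[pairs[2, ]],
    stringsAsFactors = FALSE
  )
  se <- sqrt((ms_error / 2) * (1 / n[pairs[1, ]] + 1 / n[pairs[2, ]]))
  out$q <- abs(out$diff) / se
  out$p_adj <- stats::ptukey(out$q, k, df_error, lower.tail = FALSE)
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation
#'
#' @param x,y Numeric vectors.
#' @return List with `rho` and `p` (asymptotic, ties-safe).
#' @export
spearman_rho <- function(x, y) {
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Pearson chi-square for a 2x2 table
#'
#' chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)); no continuity correction
#' by default, matching how small 2x2 association tests are usually
#' reported in this literature.
#'
#' @param a,b,c,d Cell counts (row 1: a, b; row 2: c, d).
#' @param correction Apply the Yates continuity correction.
#' @return List with `chi2`, `df` (1), `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d, correction = FALSE) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0))
  N <- sum(counts)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("zero margin in the 2x2 table")
  num <- abs(a * d - b * c)
  if (correction) num <- max(0, num - N / 2)
  chi2 <- N * num^2 / prod(margins)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the standardised values (sample mean and SD)
#' against the standard normal. Using estimated parameters makes the
#' reported p conservative relative to a fully specified null; this is the
#' documented default.
#'
#' @param values Numeric vector.
#' @return List with `D` and `p`.
#' @export
ks_normality <- function(values) {
  z <- (values - mean(values)) / stats::sd(values)
  ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
  list(D = unname(ks$statistic), p = ks$p.value)
}

#' Cronbach's alpha
#'
#' alpha = k/(k-1) (1 - sum of item variances / variance of the total).
#'
#' @param item_matrix n x k matrix of item scores.
#' @return Alpha coefficient.
#' @export
cronbach_alpha <- function(item_matrix) {
  item_matrix <- as.matrix(item_matrix)
  k <- ncol(item_matrix)
  stopifnot(k >= 2)
  item_vars <- apply(item_matrix, 2, stats::var)
  total_var <- stats::var(rowSums(item_matrix))
  if (total_var == 0) stop("zero total-score variance")
  k / (k - 1) * (1 - sum(item_vars) / total_var)
}
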