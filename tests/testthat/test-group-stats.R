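test_that("SPQ scoring counts yes responses with coherent factor sums", {
  key <- spq_synthetic_key()
  all_yes <- matrix(1L, 2, 74)
  sc <- score_spq(all_yes, key)
  expect_equal(sc$total, c(74, 74))
  sc0 <- score_spq(matrix(0L, 1, 74), key)
  expect_equal(sc0$total, 0)
  set.seed(12)
  items <- matrix(rbinom(5 * 74, 1, 0.3), 5, 74)
  sc2 <- score_spq(items, key)
  expect_true(all(sc2$factors <= sc2$total))
  expect_equal(unname(rowSums(sc2$dimensions)), sc2$total)
  expect_error(score_spq(items[, 1:50], key), "74")
  # yes/no character coding accepted
  ch <- matrix(ifelse(items == 1, "yes", "no"), 5, 74)
  expect_equal(score_spq(ch, key)$total, sc2$total)
})

test_that("median split honours the documented tie rule and is order-invariant", {
  expect_equal(median_split(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_equal(median_split(c(1, 2, 2, 3)), c("low", "low", "low", "high"))
  expect_equal(median_split(c(1, 2, 2, 3), ties = "high"),
               c("low", "high", "high", "high"))
  x <- c(5, 1, 9, 3, 7)
  perm <- sample(length(x))
  expect_equal(median_split(x)[perm], median_split(x[perm]))
  expect_error(median_split(c(2, 2, 2)), "equal")
})

test_that("tertile split discards the middle third with ordered groups", {
  lab <- tertile_split(1:9)
  expect_equal(sum(lab == "low"), 3L)
  expect_equal(sum(lab == "middle"), 3L)
  expect_equal(sum(lab == "high"), 3L)
  set.seed(31)
  x <- rnorm(30)
  lab <- tertile_split(x)
  expect_lt(max(x[lab == "low"]), min(x[lab == "high"]))
  # boundary ties go to the discarded middle group
  y <- c(1, 2, 2, 2, 3, 3, 3, 9, 10)
  laby <- tertile_split(y)
  expect_true(all(laby[y == 2] %in% c("low", "middle")))
})

test_that("mixed ANOVA equals the aov error-stratum oracle on balanced data", {
  set.seed(19)
  for (i in 1:5) {
    d <- make_mixed_data(6, 6, means = rnorm(4), sd = 1)
    mine <- mixed_anova_2x2(d)
    oracle <- aov_mixed_oracle(d)
    expect_equal(mine$F[mine$effect == "group"], unname(oracle["group"]),
                 tolerance = 1e-10)
    expect_equal(mine$F[mine$effect == "within"], unname(oracle["within"]),
                 tolerance = 1e-10)
    expect_equal(mine$F[mine$effect == "interaction"],
                 unname(oracle["interaction"]), tolerance = 1e-10)
    expect_equal(mine$df_den, rep(10L, 3))
    expect_true(all(mine$partial_eta_sq >= 0 & mine$partial_eta_sq <= 1))
  }
})

test_that("mixed ANOVA handles unbalanced groups with type-III marginals", {
  set.seed(23)
  d <- make_mixed_data(5, 9, means = c(0.4, -0.1, 0.2, 0.1), sd = 1)
  mine <- mixed_anova_2x2(d)
  # independent effects-coded regression oracle on the difference scores
  wide <- reshape(d, idvar = c("participant_id", "group"),
                  timevar = "emotion", direction = "wide")
  diff_score <- wide$value.w1 - wide$value.w2
  cc <- ifelse(wide$group == "g1", 1, -1)
  co <- summary(lm(diff_score ~ cc))$coefficients
  expect_equal(mine$F[mine$effect == "within"], co[1, "t value"]^2,
               tolerance = 1e-10)
  expect_equal(mine$F[mine$effect == "interaction"], co[2, "t value"]^2,
               tolerance = 1e-10)
  # group effect equals the pooled two-sample t^2 on subject means
  msub <- (wide$value.w1 + wide$value.w2) / 2
  tt <- t.test(msub ~ wide$group, var.equal = TRUE)
  expect_equal(mine$F[mine$effect == "group"], unname(tt$statistic)^2,
               tolerance = 1e-10)
  # interaction also agrees with aov (last sequential term = type III here)
  oracle <- aov_mixed_oracle(d)
  expect_equal(mine$F[mine$effect == "interaction"],
               unname(oracle["interaction"]), tolerance = 1e-10)
})

test_that("constant responses give zero F throughout", {
  d <- make_mixed_data(4, 4, means = c(0, 0, 0, 0), sd = 1)
  d$value <- 3
  mine <- mixed_anova_2x2(d)
  expect_equal(mine$F, rep(0, 3))
})

test_that("sums of squares are conserved on balanced data", {
  set.seed(29)
  d <- make_mixed_data(8, 8, means = rnorm(4), sd = 2)
  tab <- mixed_anova_2x2(d)
  err <- attr(tab, "errors")
  ss_total <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(tab$SS) + sum(err$SS), ss_total, tolerance = 1e-8)
})

test_that("interaction p agrees with a permutation oracle", {
  set.seed(37)
  d <- make_mixed_data(6, 6, means = c(0.8, -0.2, 0, 0), sd = 1)
  obs <- mixed_anova_2x2(d)
  obs_F <- obs$F[obs$effect == "interaction"]
  wide <- reshape(d, idvar = c("participant_id", "group"),
                  timevar = "emotion", direction = "wide")
  diff_score <- wide$value.w1 - wide$value.w2
  grp <- wide$group
  perm_F <- replicate(4000, {
    pg <- sample(grp)
    d1 <- mean(diff_score[pg == "g1"]); d2 <- mean(diff_score[pg == "g2"])
    s2 <- sum((diff_score - ifelse(pg == "g1", d1, d2))^2) / (length(grp) - 2)
    (d1 - d2)^2 / (s2 * (1 / sum(pg == "g1") + 1 / sum(pg == "g2")))
  })
  p_perm <- mean(perm_F >= obs_F)
  p_param <- obs$p[obs$effect == "interaction"]
  se <- sqrt(p_perm * (1 - p_perm) / 4000)
  expect_lt(abs(p_perm - p_param), max(4 * se, 0.03))
})

test_that("two-level ANCOVA matches the explicit difference-score regressions", {
  set.seed(41)
  n <- 20
  cov <- rnorm(n, 10, 3)
  d <- data.frame(
    participant_id = rep(sprintf("s%02d", 1:n), 2),
    covariate = rep(cov, 2),
    emotion = rep(c("w1", "w2"), each = n),
    value = c(rnorm(n, 0.3 + 0.1 * cov), rnorm(n, 0))
  )
  tab <- rm_ancova_2level(d, "covariate")
  wide <- reshape(d, idvar = c("participant_id", "covariate"),
                  timevar = "emotion", direction = "wide")
  dsc <- wide$value.w1 - wide$value.w2
  xc <- wide$covariate - mean(wide$covariate)
  co <- summary(lm(dsc ~ xc))$coefficients
  expect_equal(tab$F[tab$effect == "within"], co[1, "t value"]^2,
               tolerance = 1e-10)
  expect_equal(tab$F[tab$effect == "within_x_covariate"], co[2, "t value"]^2,
               tolerance = 1e-10)
  # centring leaves the interaction F unchanged
  d2 <- d; d2$covariate <- d2$covariate + 100
  tab2 <- rm_ancova_2level(d2, "covariate")
  expect_equal(tab2$F[tab2$effect == "within_x_covariate"],
               tab$F[tab$effect == "within_x_covariate"], tolerance = 1e-10)
  expect_error(rm_ancova_2level(transform(d, covariate = 1), "covariate"),
               "zero-variance")
})

test_that("orthogonal covariates produce near-null interaction rates", {
  set.seed(43)
  ps <- replicate(200, {
    n <- 16
    d <- data.frame(
      participant_id = rep(sprintf("s%02d", 1:n), 2),
      covariate = rep(rnorm(n), 2),
      emotion = rep(c("w1", "w2"), each = n),
      value = rnorm(2 * n)
    )
    tab <- rm_ancova_2level(d, "covariate")
    tab$p[tab$effect == "within_x_covariate"]
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 200) + 0.01)
})

test_that("one-sample t matches hand-computed formula values", {
  v <- c(10, 11, 12, 13, 14)
  out <- one_sample_t(v, mu0 = 11, tail = "two")
  s <- sd(v)
  expect_equal(out$t, (12 - 11) / (s / sqrt(5)))
  expect_equal(out$d, (12 - 11) / s)
  expect_equal(out$df, 4)
  # one-tailed p is half the two-tailed p when t > 0
  expect_equal(one_sample_t(v, 11, "greater")$p, out$p / 2)
  # symmetric values about mu0
  sym <- one_sample_t(c(9, 10, 12, 13), mu0 = 11)
  expect_equal(sym$t, 0); expect_equal(sym$d, 0)
  expect_error(one_sample_t(c(2, 2), 0), "zero")
  # cross-check against stats::t.test
  tt <- t.test(v, mu = 11)
  expect_equal(out$t, unname(tt$statistic))
  expect_equal(out$p, tt$p.value)
})

test_that("Tukey adjustment matches TukeyHSD on a one-way layout", {
  set.seed(47)
  g <- factor(rep(c("a", "b", "c", "d"), each = 8))
  y <- rnorm(32, mean = rep(c(0, 0.5, 1, 0.2), each = 8))
  fit <- aov(y ~ g)
  hsd <- TukeyHSD(fit)$g
  cm <- tapply(y, g, mean)
  mse <- sum(fit$residuals^2) / fit$df.residual
  mine <- tukey_posthoc(cm, mse, 8, fit$df.residual)
  key <- paste(mine$cell_b, mine$cell_a, sep = "-")
  expect_equal(mine$p_adj, unname(hsd[key, "p adj"]), tolerance = 1e-8)
  # identical means -> all adjusted p near 1; adjusted >= unadjusted
  flat <- tukey_posthoc(c(a = 1, b = 1, c = 1, d = 1), 1, 8, 28)
  expect_true(all(flat$p_adj > 0.999))
  praw <- 2 * pt(abs(mine$diff) / sqrt(mse * 2 / 8), fit$df.residual,
                 lower.tail = FALSE)
  expect_true(all(mine$p_adj >= praw - 1e-12))
})

test_that("Spearman correlation handles monotone and tied data", {
  x <- 1:10
  expect_equal(spearman_rho(x, x * 2 + 1)$rho, 1)
  expect_equal(spearman_rho(x, -x)$rho, -1)
  set.seed(53)
  xt <- sample(1:5, 30, replace = TRUE)
  yt <- sample(1:4, 30, replace = TRUE)
  # ties: rho equals Pearson correlation of average ranks
  expect_equal(spearman_rho(xt, yt)$rho, cor(rank(xt), rank(yt)),
               tolerance = 1e-12)
})

test_that("chi-square reproduces closed form and proportional-table null", {
  expect_equal(chi_square_2x2(10, 20, 5, 10)$chi2, 0)
  out <- chi_square_2x2(12, 8, 5, 15)
  N <- 40
  expect_equal(out$chi2, N * (12 * 15 - 8 * 5)^2 / (20 * 20 * 17 * 23))
  # agreement with stats::chisq.test without correction
  ct <- chisq.test(matrix(c(12, 5, 8, 15), 2), correct = FALSE)
  expect_equal(out$chi2, unname(ct$statistic))
  expect_equal(out$p, ct$p.value)
  expect_error(chi_square_2x2(0, 0, 3, 4), "margin")
})

test_that("KS normality check behaves sensibly", {
  set.seed(59)
  big <- rnorm(2000)
  out <- ks_normality(big)
  expect_gt(out$p, 0.05)
  expect_true(out$D >= 0 && out$D <= 1)
  two_point <- rep(c(0, 1), each = 25)
  expect_gt(ks_normality(two_point)$D, 0.25)
})

test_that("Cronbach's alpha matches the variance formula on a toy scale", {
  m <- cbind(c(1, 2, 3, 4, 5), c(2, 2, 3, 5, 4), c(1, 3, 3, 4, 6))
  by_hand <- 3 / 2 * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
  expect_equal(cronbach_alpha(m), by_hand)
  # perfectly correlated items -> 1
  perf <- cbind(1:6, 1:6, 1:6)
  expect_equal(cronbach_alpha(perf), 1)
  # invariant to adding a constant to one item
  m2 <- m; m2[, 2] <- m2[, 2] + 7
  expect_equal(cronbach_alpha(m2), cronbach_alpha(m))
  # many uncorrelated items -> near zero
  set.seed(61)
  u <- matrix(rnorm(500 * 10), 500, 10)
  expect_lt(abs(cronbach_alpha(u)), 0.15)
})
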