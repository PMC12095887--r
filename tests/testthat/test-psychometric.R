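test_that("fast-trial exclusion uses a strict 250 ms cutoff", {
  tr <- data.frame(rt_ms = c(100, 249, 250, 800))
  kept <- exclude_fast_trials(tr)
  expect_equal(kept$rt_ms, c(250, 800))
  expect_equal(attr(kept, "n_removed"), 2L)
  expect_error(exclude_fast_trials(data.frame(x = 1)), "rt_ms")
})

test_that("profiles aggregate the factorial into 12 trials per cell", {
  sched <- generate_schedule(seed = 2)
  sched <- sched[!sched$is_training, ]
  sched$participant_id <- "P1"
  sched$response <- "different"
  prof <- build_profiles(sched)
  # 2 avatar sexes x 2 identities x 3 repetitions = 12 per (emotion, level)
  expect_true(all(prof$n_trials == 12L))
  expect_true(all(prof$proportion == 0))
  expect_equal(nrow(prof), 14L)  # 2 emotions x 7 levels
})

test_that("profile proportions reproduce counts exactly", {
  set.seed(4)
  sched <- generate_schedule(seed = 4)
  sched$participant_id <- "P1"
  p <- observer_params()
  sim <- simulate_trials(p, sched)
  prof <- build_profiles(sim)
  expect_equal(prof$proportion, prof$n_equal / prof$n_trials)
  expect_true(all(prof$n_equal <= prof$n_trials))
})

test_that("scaled logistic density matches the closed form and is even", {
  # independent high-precision evaluation of the stated formula
  direct <- 4 * 0.8 * exp(-1) / (1 + exp(-1))^2
  expect_equal(scaled_logistic_density(12, mu = 11, s = 1, A = 0.8), direct,
               tolerance = 1e-12)
  expect_equal(scaled_logistic_density(11, mu = 11, s = 1, A = 0.8), 0.8)
  for (d in c(0.3, 1, 2.5))
    expect_equal(scaled_logistic_density(11 + d, 11, 1.3, 0.6),
                 scaled_logistic_density(11 - d, 11, 1.3, 0.6))
})

test_that("fit recovers the centre of a symmetric profile", {
  p <- unbiased_observer()
  fit <- fit_psychometric(analytic_profile(p))
  expect_true(fit$converged)
  expect_equal(fit$pse, 11, tolerance = 0.01)
})

test_that("fit matches a dense grid-search oracle on a noiseless biased profile", {
  p <- observer_params(delta_happy = 0.5, delta_angry = 0.5, sigma = 1,
                       criterion = 1.5, lapse = 0)
  prof <- analytic_profile(p)
  fit <- fit_psychometric(prof)
  # oracle: exhaustive grid over (mu, s, A)
  grid <- expand.grid(mu = seq(10, 13, 0.01), s = seq(0.5, 2, 0.05),
                      A = seq(0.5, 1, 0.02))
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    sum((scaled_logistic_density(prof$motion_level, grid$mu[i], grid$s[i],
                                 grid$A[i]) - prof$proportion)^2)
  }, numeric(1))
  best <- grid[which.min(sse), ]
  expect_equal(fit$pse, best$mu, tolerance = 0.05)
  expect_lte(fit$sse, min(sse) + 1e-6)
})

test_that("degenerate profiles are flagged as non-converged", {
  flat <- data.frame(motion_level = 8:14, proportion = rep(0.5, 7))
  expect_false(fit_psychometric(flat)$converged)
  short <- data.frame(motion_level = 8:11, proportion = c(0.1, 0.5, 0.9, 0.5))
  expect_false(fit_psychometric(short)$converged)
  empty <- data.frame(motion_level = 8:14, proportion = rep(NA_real_, 7))
  expect_false(fit_psychometric(empty)$converged)
})

test_that("hwhm JND solves the half-height equation and scales linearly", {
  # oracle: numeric root of f(L) = A/2 for mu = 0, s = 1, A = 1
  root <- uniroot(function(L) scaled_logistic_density(L, 0, 1, 1) - 0.5,
                  c(0.1, 5), tol = 1e-12)$root
  expect_equal(jnd_from_fit(list(s = 1), "hwhm"), root, tolerance = 1e-9)
  expect_equal(jnd_from_fit(list(s = 1), "hwhm"), log(3 + 2 * sqrt(2)))
  for (k in c(0.5, 2, 3.7))
    expect_equal(jnd_from_fit(list(s = k), "hwhm"),
                 k * jnd_from_fit(list(s = 1), "hwhm"))
  expect_equal(jnd_from_fit(list(s = 1.6), "scale"), 1.6)
})

test_that("participant exclusions are participant-wide and idempotent", {
  fits <- data.frame(
    participant_id = rep(c("A", "B", "C"), each = 2),
    emotion = rep(c("e1", "e2"), 3),
    pse = c(4.9, 11, 11, 11, 16.2, 11),
    converged = TRUE
  )
  out <- apply_participant_exclusions(fits)
  expect_true(all(out$excluded[out$participant_id == "A"]))  # one mu of 4.9
  expect_false(any(out$excluded[out$participant_id == "B"]))
  expect_true(all(out$excluded[out$participant_id == "C"]))  # 16.2 in one emotion
  expect_equal(apply_participant_exclusions(out)$excluded, out$excluded)
})

test_that("representational momentum beyond the JND uses a strict comparison", {
  expect_true(rm_exceeds_jnd(list(pse = 13.0, jnd = 1.5)))
  expect_false(rm_exceeds_jnd(list(pse = 11.3, jnd = 1.6)))
  expect_false(rm_exceeds_jnd(list(pse = 11.0, jnd = 0)))
})

test_that("recovered PSE is unbiased and monotone in the displacement", {
  deltas <- c(-0.5, 0, 0.5, 1.0)
  set.seed(11)
  mean_pse <- vapply(deltas, function(dl) {
    p <- observer_params(delta_happy = dl, delta_angry = dl, sigma = 1,
                         criterion = 1.5, lapse = 0)
    pses <- vapply(1:4, function(r) {
      tr <- data.frame(emotion = "happy_to_ambiguous",
                       probe_motion_level = rep(8:14, length.out = 3500),
                       participant_id = "x")
      sim <- simulate_trials(p, tr)
      prof <- build_profiles(sim)
      fit_psychometric(prof[prof$emotion == "happy_to_ambiguous", ])$pse
    }, numeric(1))
    mean(pses)
  }, numeric(1))
  expect_true(all(abs(mean_pse - (11 + deltas)) < 0.15))
  expect_true(all(diff(mean_pse) > 0))
})
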