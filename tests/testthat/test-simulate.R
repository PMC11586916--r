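test_that("simulator edge cases and determinism", {
  expect_equal(nrow(simulate_event_times(scen1_m1, 0)), 0)
  d1 <- generate_scenario_dataset(crm_scenario(1), seed = 99)
  d2 <- generate_scenario_dataset(crm_scenario(1), seed = 99)
  expect_identical(d1, d2)
})

test_that("competing exponentials: cause fractions and mean latent time", {
  set.seed(13)
  lat <- simulate_event_times(scen1_m1, 1e5)
  tot <- sum(scen1_rates1)            # 0.0025
  p1 <- scen1_rates1[1] / tot          # 0.4
  se_p <- sqrt(p1 * (1 - p1) / 1e5)
  expect_lt(abs(mean(lat$cause == 1) - p1), 3 * se_p)
  mu <- 1 / tot                        # 400 days
  expect_lt(abs(mean(lat$time) - mu), 3 * mu / sqrt(1e5))
  # latent times are Exponential(sum of rates): Kolmogorov-Smirnov check
  ks <- suppressWarnings(ks.test(lat$time, pexp, rate = tot))
  expect_gt(ks$p.value, 0.001)
})

test_that("defective Gompertz produces the closed-form cure fraction", {
  a <- 0.002; b <- -0.016
  m <- crm_model(crm_intensity("gompertz", c(a, b)), tau = 90)
  set.seed(14)
  lat <- simulate_event_times(m, 1e5)
  cure <- exp(-a / abs(b))
  se <- sqrt(cure * (1 - cure) / 1e5)
  expect_lt(abs(mean(is.infinite(lat$time)) - cure), 3 * se)
})

test_that("censoring mechanics: administrative truncation and random minimum", {
  lat <- data.frame(time = c(50, 120, Inf), cause = c(2L, 1L, NA))
  obs <- apply_censoring(lat, censoring_administrative(90))
  expect_equal(obs$time, c(50, 90, 90))
  expect_equal(obs$status, c(2L, 0L, 0L))
  # random censoring: observed is the minimum, status 0 when C < T
  set.seed(15)
  lat2 <- data.frame(time = rep(100, 2000), cause = 1L)
  obs2 <- apply_censoring(lat2, censoring_random(0.02))
  expect_true(all(obs2$time <= 100))
  expect_equal(obs2$status[obs2$time < 100], rep(0L, sum(obs2$time < 100)))
  expect_equal(mean(obs2$status == 0), 1 - exp(-0.02 * 100), tolerance = 0.05)
})

test_that("random censoring with no cap reproduces the closed-form censored fraction", {
  # per group: c / (c + sum of rates); pooled over equal-size groups
  c_rate <- 0.001
  p_cens <- mean(c(c_rate / (c_rate + sum(scen1_rates1)),
                   c_rate / (c_rate + sum(scen1_rates2))))
  sc <- crm_scenario(1, n1 = 200, n2 = 200,
                     censoring = censoring_random(c_rate))
  set.seed(16)
  frac <- mean(replicate(200, {
    mean(generate_scenario_dataset(sc)$status == 0)
  }))
  expect_lt(abs(frac - p_cens), 0.01)
  expect_lt(abs(100 * frac - 25), 2)   # about 25% censored
})

test_that("censored percentages across censoring rates match the closed form", {
  # pooled censored fraction mean of c / (c + sum rates) over the groups:
  # approximately 25, 40, 50, 63, 77 percent at these rates
  rates <- c(0.001, 0.002, 0.003, 0.005, 0.01)
  expected <- 100 * vapply(rates, function(c_rate) {
    mean(c(c_rate / (c_rate + sum(scen1_rates1)),
           c_rate / (c_rate + sum(scen1_rates2))))
  }, numeric(1))
  reference <- c(25, 40, 50, 63, 77)
  set.seed(19)
  for (i in seq_along(rates)) {
    sc <- crm_scenario(1, n1 = 200, n2 = 200,
                       censoring = censoring_random(rates[i]))
    pct <- 100 * mean(replicate(60, {
      mean(generate_scenario_dataset(sc)$status == 0)
    }))
    expect_lt(abs(pct - expected[i]), 2)
    expect_lt(abs(pct - reference[i]), 2)
  }
})

test_that("event and censoring streams are independent", {
  # the latent draw is unaffected by the censoring mechanism applied to it
  m <- exp_model(scen1_rates1)
  lat <- simulate_event_times(m, 5e4, seed = 17)
  o1 <- apply_censoring(lat, censoring_random(0.001), seed = 1)
  o2 <- apply_censoring(lat, censoring_random(0.01), seed = 2)
  expect_identical(o1$time[o1$status > 0], lat$time[o1$status > 0])
  expect_identical(o2$time[o2$status > 0], lat$time[o2$status > 0])
  # and the observed event-time marginal matches the conditional closed
  # form under independent exponential censoring: T | T < C ~ Exp(tot + c)
  tot <- sum(scen1_rates1)
  ks <- suppressWarnings(
    ks.test(o2$time[o2$status > 0], pexp, rate = tot + 0.01))
  expect_gt(ks$p.value, 0.001)
})

test_that("Nelson-Aalen cause-specific cumulative hazards track the generator", {
  skip_if_not_installed("survival")
  sc <- crm_scenario(3)
  set.seed(18)
  d <- simulate_crm_group(sc$model1, 2e4, censoring_administrative(90))
  for (j in 1:3) {
    fit <- survival::survfit(survival::Surv(time, status == j) ~ 1, data = d)
    idx <- findInterval(c(30, 60, 89), fit$time)
    na_est <- cumsum(fit$n.event / fit$n.risk)[idx]
    se <- sqrt(cumsum(fit$n.event / fit$n.risk^2))[idx]
    truth <- cum_intensity(sc$model1$transitions[[j]], c(30, 60, 89))
    expect_true(all(abs(na_est - truth) < 3 * se + 1e-8))
  }
})

test_that("simulate() method returns reproducible datasets", {
  out <- simulate(scen1_m1, nsim = 2, seed = 5, n = 50,
                  censoring = censoring_administrative(90))
  out2 <- simulate(scen1_m1, nsim = 2, seed = 5, n = 50,
                   censoring = censoring_administrative(90))
  expect_length(out, 2)
  expect_identical(out, out2)
  expect_false(identical(out[[1]], out[[2]]))
})
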