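test_that("log-likelihood matches closed-form hand computation", {
  m <- exp_model(c(0.01, 0.02, 0.03))
  d <- data.frame(time = c(10, 90), status = c(1L, 0L))
  expect_equal(crm_loglik(m, d),
               (-0.06 * 10 + log(0.01)) + (-0.06 * 90))
  expect_equal(crm_loglik(m, d[0, ]), 0)
  # additivity: doubling the data doubles the log-likelihood
  expect_equal(crm_loglik(m, rbind(d, d)), 2 * crm_loglik(m, d))
})

test_that("events at zero-intensity times give -Inf, flagged", {
  m <- crm_model(crm_intensity("exponential", 0),
                 crm_intensity("exponential", 0.01), tau = 90)
  d <- data.frame(time = 5, status = 1L)
  ll <- crm_loglik(m, d)
  expect_identical(as.numeric(ll), -Inf)
  expect_equal(attr(ll, "zero_intensity_events"), 1L)
})

test_that("random-censoring log-likelihood adds the censoring density term", {
  m1 <- crm_model(crm_intensity("exponential", 0.002), tau = 90)
  d <- data.frame(time = 100, status = 0L)
  cens <- censoring_random(0.01)
  expect_equal(crm_loglik(m1, d, cens),
               -0.002 * 100 + log(0.01) - 0.01 * 100)
  # no censored subjects: the term vanishes
  dev <- data.frame(time = c(3, 8), status = c(1L, 1L))
  expect_equal(crm_loglik(m1, dev, cens), crm_loglik(m1, dev))
  # additivity over subjects
  d2 <- rbind(d, dev)
  expect_equal(crm_loglik(m1, d2, cens),
               crm_loglik(m1, d, cens) + crm_loglik(m1, dev, cens))
})

test_that("exponential MLE equals the occurrence/exposure closed form", {
  d <- data.frame(time = c(rep(100, 20), rep(400, 20)),
                  status = c(rep(1L, 20), rep(0L, 20)))
  fit <- crm_fit(d, "exponential")
  expect_equal(unname(coef(fit)), 20 / 10000)  # 20 events, exposure 10000
  # holds on arbitrary simulated data, every transition
  set.seed(31)
  for (r in 1:10) {
    dd <- simulate_crm_group(scen1_m1, 300, censoring_random(0.002))
    f <- crm_fit(dd, rep("exponential", 3), censoring_random())
    for (j in 1:3) {
      expect_equal(unname(coef(f)[j]),
                   sum(dd$status == j) / sum(dd$time), tolerance = 1e-8)
    }
    # censoring rate: censored count over total exposure
    expect_equal(f$censoring$rate, sum(dd$status == 0) / sum(dd$time))
  }
})

test_that("zero-event states give a flagged boundary estimate", {
  d <- data.frame(time = c(50, 90), status = c(1L, 0L))
  expect_warning(fit <- crm_fit(d, rep("exponential", 3)), "no events")
  expect_equal(unname(coef(fit))[2:3], c(0, 0))
  expect_false(all(fit$converged))
  expect_true(fit$converged[1])
})

test_that("parameter recovery at n = 1e5 within 3 standard errors", {
  set.seed(52)
  n <- 1e5
  d <- simulate_crm_group(scen1_m1, n, censoring_administrative(90))
  f <- crm_fit(d, rep("exponential", 3))
  for (j in 1:3) {
    lam <- unname(coef(f)[j])
    se <- lam / sqrt(sum(d$status == j))
    expect_lt(abs(lam - scen1_rates1[j]), 3 * se)
  }
  # Gompertz: single-transition model, recover both parameters
  gm <- crm_model(crm_intensity("gompertz", c(0.002, -0.016)), tau = 90)
  dg <- simulate_crm_group(gm, n, censoring_administrative(90))
  fg <- crm_fit(dg, "gompertz")
  est <- unname(coef(fg))
  ll <- function(p) {
    tr <- crm_intensity("gompertz", c(exp(p[1]), p[2]))
    ev <- dg$status == 1L
    sum(log(intensity(tr, dg$time[ev]))) - sum(cum_intensity(tr, dg$time))
  }
  H <- optimHess(c(log(est[1]), est[2]), ll)
  se <- sqrt(diag(solve(-H)))
  expect_lt(abs(log(est[1]) - log(0.002)), 3 * se[1])
  expect_lt(abs(est[2] - (-0.016)), 3 * se[2])
})

test_that("event-process and censoring estimation separate", {
  set.seed(61)
  d <- simulate_crm_group(scen1_m2, 400, censoring_random(0.003))
  # profile fit (package): theta from event terms, psi from censoring terms
  f <- crm_fit(d, rep("exponential", 3), censoring_random())
  # joint numeric maximisation of the full separable log-likelihood
  nll <- function(p) {
    m <- exp_model(exp(p[1:3]))
    ev_ll <- crm_loglik(m, d)
    cens_ll <- sum(d$status == 0) * p[4] - exp(p[4]) * sum(d$time)
    -(ev_ll + cens_ll)
  }
  op <- optim(log(c(coef(f) + 1e-4, 0.004)), nll, method = "BFGS")
  expect_equal(unname(exp(op$par[1:3])), unname(coef(f)), tolerance = 1e-4)
  expect_equal(unname(exp(op$par[4])), f$censoring$rate, tolerance = 1e-4)
})
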