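make_two_exp <- function(seed, l1 = 0.002, l2 = 0.003, n = 300) {
  set.seed(seed)
  d1 <- simulate_crm_group(exp_model(l1), n, censoring_administrative(90))
  d2 <- simulate_crm_group(exp_model(l2), n, censoring_administrative(90))
  list(d1 = d1, d2 = d2)
}

test_that("constraint already active: constrained fit equals unconstrained", {
  dd <- make_two_exp(5)
  f1 <- crm_fit(dd$d1, "exponential")
  f2 <- crm_fit(dd$d2, "exponential")
  delta <- abs(unname(coef(f1)) - unname(coef(f2)))
  cf <- crm_fit_constrained(dd$d1, dd$d2, "exponential", delta)
  expect_equal(cf$model1$transitions[[1]]$params, unname(coef(f1)))
  expect_equal(cf$model2$transitions[[1]]$params, unname(coef(f2)))
  expect_equal(cf$joint_loglik, f1$event_loglik + f2$event_loglik)
})

test_that("k = 1 exponential constrained fit matches a 1-d profile grid oracle", {
  for (s in c(11, 12)) {
    dd <- make_two_exp(s)
    delta <- 0.0004
    cf <- crm_fit_constrained(dd$d1, dd$d2, "exponential", delta)
    D1 <- sum(dd$d1$status == 1); R1 <- sum(dd$d1$time)
    D2 <- sum(dd$d2$status == 1); R2 <- sum(dd$d2$time)
    ll <- function(a, b) D1 * log(a) - R1 * a + D2 * log(b) - R2 * b
    lam <- seq(1e-5, 0.02, length.out = 400001)
    oracle <- max(ll(lam, lam + delta), ll(lam + delta, lam))
    expect_equal(cf$joint_loglik, oracle, tolerance = 1e-6)
    expect_lte(cf$constraint_residual, 1e-6)
  }
})

test_that("constrained log-likelihood never exceeds the unconstrained optimum", {
  set.seed(77)
  for (r in 1:20) {
    sc <- crm_scenario(1, n1 = 150, n2 = 150)
    d <- generate_scenario_dataset(sc)
    g <- split(d, d$group)
    f1 <- crm_fit(g[[1]], sc$families)
    f2 <- crm_fit(g[[2]], sc$families)
    delta <- runif(1, 2e-4, 3e-3)
    cf <- crm_fit_constrained(g[[1]], g[[2]], sc$families, delta)
    expect_lte(cf$joint_loglik, f1$event_loglik + f2$event_loglik + 1e-10)
    expect_lte(cf$constraint_residual, 1e-6)
  }
})

test_that("constrained joint log-likelihood decreases as delta moves from d_hat", {
  dd <- make_two_exp(21)
  f1 <- crm_fit(dd$d1, "exponential"); f2 <- crm_fit(dd$d2, "exponential")
  d_hat <- abs(unname(coef(f1)) - unname(coef(f2)))
  grid_up <- d_hat + seq(0, 0.002, by = 5e-4)
  ll_up <- vapply(grid_up, function(D) {
    crm_fit_constrained(dd$d1, dd$d2, "exponential", D)$joint_loglik
  }, numeric(1))
  expect_true(all(diff(ll_up) <= 1e-10))
  grid_dn <- pmax(d_hat - seq(0, 0.0015, by = 5e-4), 1e-5)
  ll_dn <- vapply(grid_dn, function(D) {
    crm_fit_constrained(dd$d1, dd$d2, "exponential", D)$joint_loglik
  }, numeric(1))
  expect_true(all(diff(ll_dn) <= 1e-10))
})

test_that("Gompertz/Weibull constrained fit meets the constraint tolerance", {
  sc <- crm_scenario(4, n1 = 250, n2 = 250)
  d <- generate_scenario_dataset(sc, seed = 40)
  g <- split(d, d$group)
  cf <- crm_fit_constrained(g[[1]], g[[2]], sc$families, delta = 0.005)
  expect_lte(cf$constraint_residual, 1e-6)
  f1 <- crm_fit(g[[1]], sc$families); f2 <- crm_fit(g[[2]], sc$families)
  expect_lte(cf$joint_loglik, f1$event_loglik + f2$event_loglik)
  achieved <- max_pairwise_distance(cf$model1, cf$model2,
                                    window = cf$window)$value
  expect_lt(abs(achieved - 0.005), 2e-6)
})

test_that("null-model selection follows the d_hat vs delta dichotomy", {
  dd <- make_two_exp(31)
  f1 <- crm_fit(dd$d1, "exponential"); f2 <- crm_fit(dd$d2, "exponential")
  d_hat <- abs(unname(coef(f1)) - unname(coef(f2)))
  cf <- crm_fit_constrained(dd$d1, dd$d2, "exponential", d_hat * 2)
  sel_con <- select_null_estimates(f1, f2, cf, d_hat, delta = d_hat * 2)
  expect_identical(sel_con$branch, "constrained")
  sel_unc <- select_null_estimates(f1, f2, NULL, d_hat, delta = d_hat / 2)
  expect_identical(sel_unc$branch, "unconstrained")
  expect_identical(sel_unc$model1, f1$model)
  # boundary d_hat == delta goes to the unconstrained branch
  sel_bd <- select_null_estimates(f1, f2, NULL, d_hat, delta = d_hat)
  expect_identical(sel_bd$branch, "unconstrained")
  # the selected nulls either satisfy the constraint or equal the MLEs
  ach <- max_pairwise_distance(sel_con$model1, sel_con$model2)$value
  expect_gte(ach, d_hat * 2 - 1e-6)
})
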