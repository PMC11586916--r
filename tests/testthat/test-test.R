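scen1_data <- function(seed, n = 200, cens = censoring_administrative(90)) {
  generate_scenario_dataset(crm_scenario(1, n1 = n, n2 = n,
                                         censoring = cens), seed = seed)
}

test_that("test object is internally consistent and reproducible", {
  d <- scen1_data(3)
  t1 <- crm_similarity_test(d, rep("exponential", 3), delta = 0.0015,
                            B = 120, seed = 8)
  t2 <- crm_similarity_test(d, rep("exponential", 3), delta = 0.0015,
                            B = 120, seed = 8)
  expect_identical(t1$boot_stats, t2$boot_stats)
  expect_identical(t1$p_value, t2$p_value)
  expect_true(t1$p_value >= 0 && t1$p_value <= 1)
  expect_true(all(t1$boot_stats >= 0))
  expect_identical(t1$reject, t1$p_value < t1$alpha)
  expect_equal(t1$p_value, mean(t1$boot_stats <= t1$d_hat))
  expect_equal(t1$q_alpha,
               sort(t1$boot_stats)[ceiling(t1$alpha * t1$B)])
  expect_equal(t1$d_hat, max(t1$per_transition))
})

test_that("subject order does not change the statistic or the bootstrap", {
  d <- scen1_data(5)
  seeds <- 1:80
  t1 <- crm_similarity_test(d, rep("exponential", 3), delta = 0.001,
                            B = 80, boot_seeds = seeds)
  set.seed(4); perm <- sample(nrow(d))
  t2 <- crm_similarity_test(d[perm, ], rep("exponential", 3), delta = 0.001,
                            B = 80, boot_seeds = seeds)
  expect_equal(t1$d_hat, t2$d_hat)
  expect_equal(t1$boot_stats, t2$boot_stats)
})

test_that("consistency: similar groups with a generous threshold always reject", {
  m <- exp_model(scen1_rates1)
  set.seed(6)
  for (r in 1:3) {
    d <- two_group(simulate_crm_group(m, 5000, censoring_administrative(90)),
                   simulate_crm_group(m, 5000, censoring_administrative(90)))
    tst <- crm_similarity_test(d, rep("exponential", 3), delta = 0.005,
                               B = 100, seed = r)
    expect_true(tst$reject)
    expect_lt(tst$p_value, 0.05)
  }
})

test_that("p-values are monotone in delta under shared bootstrap seeds", {
  seeds_used <- c(101, 202, 303)
  for (s in seeds_used) {
    d <- scen1_data(s, n = 300, cens = censoring_random(0.001))
    shared <- derive_seeds(s, 150)
    ps <- vapply(c(0.0008, 0.001, 0.0015, 0.002), function(delta) {
      crm_similarity_test(d, rep("exponential", 3), delta = delta, B = 150,
                          censoring = censoring_random(),
                          boot_seeds = shared)$p_value
    }, numeric(1))
    expect_true(all(diff(ps) <= 0))
  }
})

test_that("bootstrap replicate is seeded and centred where it should be", {
  nulls <- list(model1 = scen1_m1, model2 = scen1_m1)
  cens <- list(censoring_administrative(90), censoring_administrative(90))
  d1 <- bootstrap_replicate(nulls, 400, 400, rep("exponential", 3), cens,
                            seed = 9)
  d2 <- bootstrap_replicate(nulls, 400, 400, rep("exponential", 3), cens,
                            seed = 9)
  expect_identical(d1, d2)
  # identical null models, huge n: d* near zero
  d3 <- bootstrap_replicate(nulls, 5e4, 5e4, rep("exponential", 3), cens,
                            seed = 10)
  expect_lt(d3, 2e-4)
  # self-consistency: the replicate mean is stable across independent runs
  ds_a <- vapply(1:60, function(s) {
    bootstrap_replicate(nulls, 400, 400, rep("exponential", 3), cens,
                        seed = s)
  }, numeric(1))
  ds_b <- vapply(601:1200, function(s) {
    bootstrap_replicate(nulls, 400, 400, rep("exponential", 3), cens,
                        seed = s)
  }, numeric(1))
  se <- sqrt(var(ds_a) / 60 + var(ds_b) / 600)
  expect_lt(abs(mean(ds_a) - mean(ds_b)), 3 * se)
})

test_that("intersection-union combination behaves as defined", {
  d <- scen1_data(12, n = 250)
  iup <- crm_iup_test(d, rep("exponential", 3), delta = 0.0015, B = 100,
                      seed = 2)
  pv <- vapply(iup$per_transition, `[[`, numeric(1), "p_value")
  expect_equal(iup$p_value, max(pv))
  expect_identical(iup$reject,
                   all(vapply(iup$per_transition, `[[`, logical(1), "reject")))
  expect_true(all(iup$p_value >= pv))
})

test_that("with a single transition the IUP and global tests coincide", {
  set.seed(44)
  d <- two_group(
    simulate_crm_group(exp_model(0.002), 400, censoring_administrative(90)),
    simulate_crm_group(exp_model(0.0025), 400, censoring_administrative(90)))
  seeds <- derive_seeds(7, 100)
  glob <- crm_similarity_test(d, "exponential", delta = 0.001, B = 100,
                              boot_seeds = seeds)
  iup <- crm_iup_test(d, "exponential", delta = 0.001, B = 100,
                      boot_seeds = matrix(seeds, nrow = 1))
  expect_equal(iup$per_transition[[1]]$d_hat, glob$d_hat)
  expect_equal(iup$p_value, glob$p_value)
  expect_identical(iup$reject, glob$reject)
})

test_that("minimal delta: sentinel, monotone rejection, and location", {
  # data from one common model: delta_hat must be at least d_hat and the
  # rejection set an upper tail of the grid (shared seeds)
  m <- exp_model(scen1_rates1)
  set.seed(50)
  d <- two_group(simulate_crm_group(m, 500, censoring_administrative(90)),
                 simulate_crm_group(m, 500, censoring_administrative(90)))
  grid <- seq(5e-4, 6e-3, by = 5e-4)
  md <- minimal_delta(d, rep("exponential", 3), grid, B = 120, seed = 3)
  expect_true(is.finite(md$delta_hat))
  expect_gte(md$delta_hat, md$d_hat)
  ev <- md$evaluated
  expect_true(all(ev$reject[ev$delta >= md$delta_hat]))
  expect_false(any(ev$reject[ev$delta < md$delta_hat]))
  # a grid with no rejecting value returns the +Inf sentinel
  md2 <- minimal_delta(d, rep("exponential", 3), c(1e-6, 2e-6), B = 120,
                       seed = 3)
  expect_identical(md2$delta_hat, Inf)
})

test_that("minimal delta shrinks stochastically with the sample size", {
  m <- exp_model(scen1_rates1)
  grid <- seq(5e-4, 1.5e-2, by = 5e-4)
  med <- vapply(c(100, 2000), function(n) {
    set.seed(n)
    dh <- replicate(4, {
      d <- two_group(simulate_crm_group(m, n, censoring_administrative(90)),
                     simulate_crm_group(m, n, censoring_administrative(90)))
      minimal_delta(d, rep("exponential", 3), grid, B = 60,
                    seed = n)$delta_hat
    })
    median(dh)
  }, numeric(1))
  expect_lt(med[2], med[1])
})
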