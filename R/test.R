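# The constrained-parametric-bootstrap similarity test.
#
# Steps, for observed two-group data and threshold delta:
#   (i)   unconstrained MLEs per group (and censoring rates, if random
#         censoring), observed statistic
#         d_hat = max_j sup_t |alpha_j1(t) - alpha_j2(t)|;
#   (ii)  constrained joint MLE under max_j sup = delta; the bootstrap
#         null models are the unconstrained fits if d_hat >= delta, the
#         constrained ones otherwise;
#   (iii) B parametric bootstrap datasets from the null models (censoring
#         regenerated from the fitted censoring rates, or truncated at tau
#         for administrative censoring), each refitted WITHOUT constraint,
#         giving replicates d_star;
#   (iv)  p-value = (1/B) sum I(d_star <= d_hat); reject when p < alpha.
#         The alpha-quantile (ceiling(alpha B)-th smallest d_star) is
#         reported for diagnostics; rejection for small d_hat certifies
#         similarity at level alpha.

test_window <- function(families, censoring, window) {
  tau <- if (censoring$kind == "administrative") censoring$tau else 90
  if (is.null(window)) window <- c(0, tau)
  # A Weibull transition can be fitted with shape < 1 (intensity unbounded
  # at 0) in any refit, so with a Weibull family the default window starts
  # at one day -- the resolution at which event times are recorded. A much
  # smaller lower endpoint would let the constrained fit satisfy the
  # boundary constraint through an intensity spike confined to a tiny
  # fraction of a day, which carries almost no likelihood information and
  # destabilises the bootstrap statistic.
  if (any(families == "weibull") && window[1] == 0) {
    window[1] <- min(1, window[2] / 90)
  }
  list(window = window, tau = tau)
}

# one bootstrap replicate: simulate both groups from the null parameter
# lists, refit unconstrained, return all per-transition sup-distances
boot_dstar_core <- function(families, null1, null2, n1, n2,
                            cens1, cens2, lo, hi, tau,
                            u1 = NULL, u2 = NULL) {
  k <- length(families)
  g1 <- sim_group_core(families, null1, n1, cens1,
                       u1$e, u1$c, u1$z, t0 = tau)
  g2 <- sim_group_core(families, null2, n2, cens2,
                       u2$e, u2$c, u2$z, t0 = tau)
  vals <- numeric(k)
  for (j in seq_len(k)) {
    p1 <- fit_transition_core(families[j], g1$time, g1$status == j)$params
    p2 <- fit_transition_core(families[j], g2$time, g2$status == j)$params
    vals[j] <- sup_dist_core(families[j], p1, families[j], p2, lo, hi)$value
  }
  vals
}

draw_unif_block <- function(n) {
  list(e = stats::runif(n), c = stats::runif(n), z = stats::runif(n))
}

# full algorithm on plain vectors; stat_j = NULL for the global statistic,
# or a transition index for the per-transition statistic (IUP building
# block, where only transition stat_j is constrained)
sim_test_core <- function(time1, status1, time2, status2, families,
                          delta, B, alpha, censoring, window,
                          boot_seeds, max_fail = 0.05, stat_j = NULL) {
  k <- length(families)
  n1 <- length(time1); n2 <- length(time2)
  w <- test_window(families, censoring, window)
  lo <- w$window[1]; hi <- w$window[2]; tau <- w$tau

  fit1 <- fit_group_core(time1, status1, k, families)
  fit2 <- fit_group_core(time2, status2, k, families)
  sups <- vapply(seq_len(k), function(j) {
    sup_dist_core(families[j], fit1$params[[j]], families[j],
                  fit2$params[[j]], lo, hi)$value
  }, numeric(1))
  d_hat <- if (is.null(stat_j)) max(sups) else sups[stat_j]

  if (censoring$kind == "random") {
    # censoring rates are always re-estimated per group from the data
    # (step (i) of the algorithm); any rate carried by `censoring`
    # describes the data-generating mechanism, not the fit
    cens1 <- censoring_random(fit_cens_core(time1, status1)$rate,
                              cap_tau = censoring$cap_tau)
    cens2 <- censoring_random(fit_cens_core(time2, status2)$rate,
                              cap_tau = censoring$cap_tau)
  } else {
    cens1 <- cens2 <- censoring
  }

  # null-generating parameters (constrained only when d_hat < delta)
  branch <- if (d_hat >= delta) "unconstrained" else "constrained"
  cfit <- NULL
  if (branch == "unconstrained") {
    null1 <- fit1$params; null2 <- fit2$params
  } else if (is.null(stat_j)) {
    cfit <- fit_constrained_core(time1, status1, time2, status2,
                                 families, delta, lo, hi)
    null1 <- cfit$par1; null2 <- cfit$par2
  } else {
    # single-transition constraint: other transitions stay unconstrained
    eq <- constrained_pair_core(families[stat_j], time1, status1 == stat_j,
                                time2, status2 == stat_j, delta, lo, hi,
                                start1 = fit1$params[[stat_j]],
                                start2 = fit2$params[[stat_j]])
    null1 <- fit1$params; null2 <- fit2$params
    null1[[stat_j]] <- eq$par1
    null2[[stat_j]] <- eq$par2
  }

  if (is.null(boot_seeds)) boot_seeds <- derive_seeds(NULL, B)
  d_star <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    set.seed(boot_seeds[b])
    u1 <- draw_unif_block(n1)
    u2 <- draw_unif_block(n2)
    vals <- tryCatch(
      boot_dstar_core(families, null1, null2, n1, n2, cens1, cens2,
                      lo, hi, tau, u1, u2),
      error = function(e) NULL)
    if (!is.null(vals)) {
      d_star[b] <- if (is.null(stat_j)) max(vals) else vals[stat_j]
    }
  }
  ok <- is.finite(d_star)
  if (mean(!ok) > max_fail) {
    stop(sprintf("%d of %d bootstrap replicates failed", sum(!ok), B),
         call. = FALSE)
  }
  d_star <- d_star[ok]
  Beff <- length(d_star)
  p_value <- mean(d_star <= d_hat)
  q_alpha <- sort(d_star)[max(1L, ceiling(alpha * Beff))]
  list(d_hat = d_hat, per_transition = sups, delta = delta,
       boot_stats = d_star, q_alpha = q_alpha, p_value = p_value,
       reject = p_value < alpha, alpha = alpha, B = Beff,
       n_failed = sum(!ok), branch = branch,
       fit1 = fit1, fit2 = fit2, cfit = cfit,
       null1 = null1, null2 = null2, cens1 = cens1, cens2 = cens2,
       window = c(lo, hi))
}

split_groups <- function(data, k) {
  check_dataset(data, k, two_groups = TRUE)
  g <- as.integer(data$group)
  list(time1 = as.numeric(data$time)[g == 1L],
       status1 = as.integer(data$status)[g == 1L],
       time2 = as.numeric(data$time)[g == 2L],
       status2 = as.integer(data$status)[g == 2L])
}

#' Similarity test for two parametric competing risks models
#'
#' Tests the null hypothesis that some pair of cause-specific transition
#' intensities of the two groups differs by at least `delta` in sup-norm,
#' against the alternative that all pairs differ by less than `delta`
#' (similarity). Rejection therefore *certifies similarity* at level
#' `alpha`. The reference distribution of the statistic
#' \eqn{\hat d = \max_j \sup_t |\hat\alpha_{0j}^{(1)}(t) -
#' \hat\alpha_{0j}^{(2)}(t)|} is obtained by a constrained parametric
#' bootstrap: data are regenerated from maximum-likelihood estimates that
#' are re-fitted under the null-boundary constraint (max distance exactly
#' `delta`) whenever the observed statistic is smaller than `delta`.
#'
#' @param data two-group data frame with columns `time` (days), `status`
#'   (0 = censored, 1..k), `group` (1 or 2).
#' @param families intensity family per transition, length k.
#' @param delta similarity threshold (> 0), per-day intensity units.
#' @param B number of bootstrap replicates.
#' @param alpha significance level in (0, 0.5).
#' @param censoring censoring mechanism; [censoring_random()] without a
#'   rate estimates per-group censoring rates from the data.
#' @param window sup-norm window `c(t_lo, t_hi)`; defaults to `[0, tau]`
#'   (lower endpoint moved off 0 when a Weibull family is involved).
#' @param seed integer seed; all bootstrap randomness derives from it.
#' @param boot_seeds optional integer vector of length `B` of per-replicate
#'   seeds (overrides `seed`); sharing these across calls couples the
#'   bootstrap draws, which [minimal_delta()] uses to make rejection
#'   monotone in `delta`.
#' @param max_fail maximum tolerated fraction of failed bootstrap refits
#'   (failures are dropped; exceeding this is an error).
#' @return an object of class `"crm_test"`; fields include `d_hat`,
#'   `delta`, `boot_stats`, `q_alpha`, `p_value`, `reject`, `branch`,
#'   `null_models`, the per-group fits, `alpha` and `B`.
#' @references The test rejects for small `d_hat`: the decision
#'   `p_value < alpha` is equivalent (up to the quantile convention) to
#'   `d_hat <= q_alpha`.
#' @examples
#' sc <- crm_scenario(1, n1 = 150, n2 = 150)
#' d <- generate_scenario_dataset(sc, seed = 11)
#' tst <- crm_similarity_test(d, rep("exponential", 3), delta = 0.0015,
#'                            B = 100, seed = 1)
#' tst
#' @export
crm_similarity_test <- function(data, families, delta, B = 250,
                                alpha = 0.05,
                                censoring = censoring_administrative(90),
                                window = NULL, seed = NULL,
                                boot_seeds = NULL, max_fail = 0.05) {
  families <- vapply(families, function(f) {
    match.arg(f, c("exponential", "gompertz", "weibull"))
  }, character(1))
  k <- length(families)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    stop("delta must be a single positive number", call. = FALSE)
  }
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must be in (0, 0.5)", call. = FALSE)
  gr <- split_groups(data, k)
  if (is.null(boot_seeds)) boot_seeds <- derive_seeds(seed, B)
  core <- sim_test_core(gr$time1, gr$status1, gr$time2, gr$status2,
                        families, delta, B, alpha, censoring, window,
                        boot_seeds, max_fail)
  as_crm_test(core, families, length(gr$time1), length(gr$time2),
              match.call())
}

as_crm_test <- function(core, families, n1, n2, call) {
  tau <- core$window[2]
  mk <- function(par) {
    crm_model(mapply(crm_intensity, families, par, SIMPLIFY = FALSE),
              tau = tau)
  }
  structure(list(
    d_hat = core$d_hat,
    delta = core$delta,
    per_transition = core$per_transition,
    boot_stats = core$boot_stats,
    q_alpha = core$q_alpha,
    p_value = core$p_value,
    reject = core$reject,
    alpha = core$alpha,
    B = core$B,
    n_failed = core$n_failed,
    branch = core$branch,
    null_models = list(model1 = mk(core$null1), model2 = mk(core$null2)),
    censoring = list(group1 = core$cens1, group2 = core$cens2),
    window = core$window,
    families = families,
    n = c(n1 = n1, n2 = n2),
    call = call
  ), class = "crm_test")
}

#' @export
print.crm_test <- function(x, ...) {
  cat("\n\tSimilarity test for parametric competing risks models\n\n")
  cat(sprintf("families: %s;  n = (%d, %d);  window [%g, %g] days\n",
              paste(x$families, collapse = ", "), x$n[1], x$n[2],
              x$window[1], x$window[2]))
  cat(sprintf("d_hat = %g, delta = %g, bootstrap B = %d (%s null fit)\n",
              x$d_hat, x$delta, x$B, x$branch))
  cat(sprintf("p-value = %.4g, alpha = %g, q_alpha = %g\n",
              x$p_value, x$alpha, x$q_alpha))
  cat(if (x$reject) {
    "=> similarity established (null of relevant difference rejected)\n"
  } else {
    "=> similarity NOT established\n"
  })
  invisible(x)
}

#' @export
summary.crm_test <- function(object, ...) {
  print(object)
  cat("per-transition sup-distances:\n")
  print(data.frame(transition = seq_along(object$per_transition),
                   sup_distance = object$per_transition),
        row.names = FALSE)
  if (object$n_failed > 0) {
    cat(sprintf("dropped bootstrap replicates: %d\n", object$n_failed))
  }
  invisible(object)
}

#' @export
plot.crm_test <- function(x, ...) {
  graphics::hist(x$boot_stats, breaks = 30, main = "Bootstrap statistics",
                 xlab = "d* (per-day intensity)", col = "grey85",
                 border = "white", ...)
  graphics::abline(v = x$d_hat, col = "firebrick", lwd = 2)
  graphics::abline(v = x$q_alpha, col = "steelblue", lwd = 2, lty = 2)
  graphics::legend("topright", bty = "n", lwd = 2, lty = c(1, 2),
                   col = c("firebrick", "steelblue"),
                   legend = c("observed d_hat", "bootstrap alpha-quantile"))
  invisible(x)
}

#' One constrained-bootstrap replicate
#'
#' Simulates a single two-group bootstrap dataset from given null models,
#' refits both groups without constraint and returns the bootstrap
#' statistic (maximum pairwise sup-norm distance of the refitted
#' intensities).
#'
#' @param null_models list with `model1`, `model2` ([crm_model()]s), e.g.
#'   from [select_null_estimates()].
#' @param n1,n2 group sizes.
#' @param families intensity family per transition.
#' @param censoring_models list of two censoring mechanisms (fixed rates).
#' @param window sup-norm window; defaults as in [crm_similarity_test()].
#' @param seed integer seed; same seed, same replicate.
#' @return scalar bootstrap statistic `d_star`.
#' @export
bootstrap_replicate <- function(null_models, n1, n2, families,
                                censoring_models, window = NULL,
                                seed = NULL) {
  families <- vapply(families, function(f) {
    match.arg(f, c("exponential", "gompertz", "weibull"))
  }, character(1))
  cens1 <- censoring_models[[1]]
  w <- test_window(families, cens1, window)
  if (!is.null(seed)) set.seed(seed)
  vals <- boot_dstar_core(families,
                          model_params(null_models$model1),
                          model_params(null_models$model2),
                          n1, n2, cens1, censoring_models[[2]],
                          w$window[1], w$window[2], w$tau)
  max(vals)
}
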