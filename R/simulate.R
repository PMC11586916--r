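# Event-history simulation for parametric competing risks models.
#
# Latent event times are drawn by inverting the all-cause cumulative
# hazard: A(T) = E with E ~ Exp(1). For all-exponential models the inverse
# is closed form; otherwise a vectorised bisection solves A(t) = E for all
# subjects simultaneously (the bracket upper end is doubled from tau until
# it covers every E). The event type is then drawn from the multinomial
# with probabilities alpha_j(T) / sum_j alpha_j(T). When the total
# cumulative hazard is bounded (defective Gompertz with negative shape)
# subjects with E beyond the bound never experience an event ("cured",
# latent time +Inf) and are censored downstream.
#
# All draws can be supplied as uniforms, which lets callers couple
# simulations across configurations (used for the shared-seed monotonicity
# of the minimal-threshold search).

sim_latent_core <- function(families, params, n,
                            u_event = NULL, u_cause = NULL, t0 = 90) {
  k <- length(families)
  if (n == 0L) {
    return(list(time = numeric(0), cause = integer(0)))
  }
  E <- if (is.null(u_event)) stats::rexp(n) else stats::qexp(u_event)
  uc <- if (is.null(u_cause)) stats::runif(n) else u_cause
  allexp <- all(families == "exponential")
  if (allexp) {
    rates <- vapply(params, `[[`, numeric(1), 1L)
    tot <- sum(rates)
    if (tot <= 0) {
      return(list(time = rep(Inf, n), cause = rep(NA_integer_, n)))
    }
    Tlat <- E / tot
    cum <- cumsum(rates / tot)
    cause <- findInterval(uc, cum[-k]) + 1L
    return(list(time = Tlat, cause = cause))
  }
  Ainf <- 0
  for (j in seq_len(k)) Ainf <- Ainf + fam_cumhaz_inf(families[j], params[[j]])
  Atot <- function(t) {
    A <- 0
    for (j in seq_len(k)) A <- A + fam_cumhaz(families[j], params[[j]], t)
    A
  }
  cured <- E >= Ainf
  Tlat <- rep(Inf, n)
  alive <- which(!cured)
  if (length(alive)) {
    Ea <- E[alive]
    hi <- rep(t0, length(alive))
    for (it in 1:64) {
      short <- Atot(hi) < Ea
      if (!any(short)) break
      hi[short] <- hi[short] * 2
    }
    lo <- rep(0, length(alive))
    for (it in 1:70) {  # 2^-70 of the bracket: below 1e-10 days
      mid <- (lo + hi) / 2
      below <- Atot(mid) < Ea
      lo[below] <- mid[below]
      hi[!below] <- mid[!below]
    }
    Tlat[alive] <- (lo + hi) / 2
  }
  cause <- rep(NA_integer_, n)
  if (length(alive)) {
    haz <- matrix(0, length(alive), k)
    for (j in seq_len(k)) {
      haz[, j] <- fam_hazard(families[j], params[[j]], Tlat[alive])
    }
    cum <- haz %*% upper.tri(diag(k), diag = TRUE)  # row-wise cumsum
    cum <- cum / cum[, k]
    cz <- integer(length(alive))
    ua <- uc[alive]
    for (j in seq_len(k)) {
      cz[cz == 0L & ua <= cum[, j]] <- j
    }
    cz[cz == 0L] <- k
    cause[alive] <- cz
  }
  list(time = Tlat, cause = cause)
}

censor_core <- function(Tlat, cause, cens, u_cens = NULL) {
  n <- length(Tlat)
  if (cens$kind == "administrative") {
    obs <- pmin(Tlat, cens$tau)
    status <- ifelse(Tlat <= cens$tau, cause, 0L)
    status[is.na(status)] <- 0L
    return(list(time = obs, status = as.integer(status)))
  }
  rate <- cens$rate
  if (is.null(rate)) stop("random censoring rate must be set for simulation",
                          call. = FALSE)
  if (rate > 0) {
    C <- if (is.null(u_cens)) stats::rexp(n, rate) else stats::qexp(u_cens, rate)
  } else {
    C <- rep(Inf, n)
  }
  if (!is.null(cens$cap_tau)) C <- pmin(C, cens$cap_tau)
  obs <- pmin(Tlat, C)
  status <- ifelse(Tlat <= C, cause, 0L)
  status[is.na(status)] <- 0L
  if (any(!is.finite(obs))) {
    # cured subject with no finite censoring time: close out at 10x the
    # window end so the record stays finite (only reachable with rate 0)
    obs[!is.finite(obs)] <- 10 * 90
    warning("cured subjects with no censoring; closed out administratively",
            call. = FALSE)
  }
  list(time = obs, status = as.integer(status))
}

#' Simulate latent competing-risks event times
#'
#' Draws `n` latent (uncensored) first-event times and event types from a
#' competing risks model: the time from the all-cause hazard by inversion
#' of the cumulative hazard, the type from the multinomial with
#' probabilities proportional to the cause-specific intensities at the
#' drawn time. For a defective model (Gompertz with negative shape) a
#' subject whose unit-exponential draw exceeds the total accumulated
#' hazard never has an event: its latent time is `Inf` and its cause `NA`
#' ("cured"); such subjects are always censored by [apply_censoring()].
#'
#' @param m a [crm_model()].
#' @param n number of subjects.
#' @param seed optional integer seed.
#' @return data frame with columns `time` (latent, possibly `Inf`) and
#'   `cause` (1..k, `NA` for cured).
#' @export
simulate_event_times <- function(m, n, seed = NULL) {
  stopifnot(inherits(m, "crm_model"))
  if (n < 0) stop("n must be nonnegative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- sim_latent_core(model_families(m), model_params(m), as.integer(n),
                         t0 = m$tau)
  data.frame(time = out$time, cause = out$cause)
}

#' Apply a censoring mechanism to latent event times
#'
#' Administrative censoring replaces latent times beyond `tau` by `tau`
#' with status 0; random censoring draws censoring times from the
#' censoring distribution and records `min(T, C)` with status 0 when
#' `C < T`. Cured subjects (latent time `Inf`) are always censored.
#'
#' @param latent data frame from [simulate_event_times()] (columns `time`,
#'   `cause`).
#' @param censoring a [censoring_administrative()] or [censoring_random()]
#'   object (the latter with a fixed `rate`).
#' @param seed optional integer seed (random censoring draws).
#' @return data frame with columns `time` (observed) and `status`
#'   (0 = censored).
#' @export
apply_censoring <- function(latent, censoring, seed = NULL) {
  stopifnot(inherits(censoring, "crm_censoring"))
  if (!is.null(seed)) set.seed(seed)
  out <- censor_core(as.numeric(latent$time),
                     as.integer(latent$cause), censoring)
  data.frame(time = out$time, status = out$status)
}

# one observed group in one call (plain core, used everywhere internally)
sim_group_core <- function(families, params, n, cens,
                           u_event = NULL, u_cause = NULL, u_cens = NULL,
                           t0 = 90) {
  lat <- sim_latent_core(families, params, n, u_event, u_cause, t0 = t0)
  censor_core(lat$time, lat$cause, cens, u_cens)
}

#' Simulate one observed group from a competing risks model
#'
#' Convenience wrapper chaining [simulate_event_times()] and
#' [apply_censoring()].
#'
#' @inheritParams simulate_event_times
#' @param censoring censoring mechanism (random censoring needs a fixed
#'   rate).
#' @return data frame with columns `id`, `time`, `status`.
#' @export
simulate_crm_group <- function(m, n, censoring, seed = NULL) {
  stopifnot(inherits(m, "crm_model"), inherits(censoring, "crm_censoring"))
  if (!is.null(seed)) set.seed(seed)
  out <- sim_group_core(model_families(m), model_params(m), as.integer(n),
                        censoring, t0 = m$tau)
  data.frame(id = seq_len(n), time = out$time, status = out$status)
}

#' @rdname simulate_crm_group
#' @param object a [crm_model()] (simulate method).
#' @param nsim number of datasets.
#' @param ... must contain `n` and `censoring` as above.
#' @return for `simulate()`: a list of `nsim` data frames.
#' @export
simulate.crm_model <- function(object, nsim = 1, seed = NULL, ...) {
  args <- list(...)
  if (is.null(args$n) || is.null(args$censoring)) {
    stop("simulate.crm_model needs n = and censoring = arguments",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim,
            simulate_crm_group(object, args$n, args$censoring),
            simplify = FALSE)
}
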