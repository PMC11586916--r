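#' Parametric cause-specific transition intensities
#'
#' Constructs a single parametric cause-specific transition intensity
#' (hazard) for one transition of a competing risks model. Three families
#' are supported:
#'
#' * `"exponential"`: constant intensity, `params = rate` (per day).
#' * `"gompertz"`: `params = c(scale, shape)`; intensity
#'   `scale * exp(shape * t)`. The shape may be negative, in which case the
#'   total accumulated hazard is bounded and the event-time distribution is
#'   defective (a "cure" fraction remains event-free).
#' * `"weibull"`: `params = c(scale, shape)`, both positive; intensity
#'   `(shape/scale) * (t/scale)^(shape - 1)`.
#'
#' Time is measured in days throughout; intensities are rates per day.
#'
#' A rate (or Gompertz scale) of zero is accepted as a degenerate boundary
#' case with identically zero intensity. It arises from maximum-likelihood
#' fits on data with no events of the given type and is flagged by the
#' fitting functions rather than rejected here.
#'
#' @param family one of `"exponential"`, `"gompertz"`, `"weibull"`
#'   (unambiguous abbreviations allowed).
#' @param params numeric parameter vector, see above.
#' @return an object of class `"crm_intensity"`.
#' @seealso [intensity()], [cum_intensity()], [crm_model()]
#' @examples
#' crm_intensity("exponential", 0.0011)
#' crm_intensity("gompertz", c(0.002, -0.016))
#' @export
crm_intensity <- function(family, params) {
  family <- match.arg(family, c("exponential", "gompertz", "weibull"))
  params <- as.numeric(params)
  npar <- crm_n_params(family)
  if (length(params) != npar) {
    stop(sprintf("family '%s' needs %d parameter(s), got %d",
                 family, npar, length(params)), call. = FALSE)
  }
  check_params(family, params)
  structure(list(family = family, params = params), class = "crm_intensity")
}

crm_n_params <- function(family) {
  switch(family, exponential = 1L, gompertz = 2L, weibull = 2L)
}

# Parameter-domain checks. Zero rate / zero Gompertz scale / infinite
# Weibull scale are boundary cases (identically zero intensity) kept legal
# so that zero-event ML fits remain representable.
check_params <- function(family, params) {
  bad <- switch(family,
    exponential = !is.finite(params[1]) || params[1] < 0,
    gompertz = !is.finite(params[1]) || params[1] < 0 || !is.finite(params[2]),
    weibull = is.na(params[1]) || params[1] <= 0 ||
      !is.finite(params[2]) || params[2] <= 0
  )
  if (bad) {
    stop(sprintf("invalid %s parameters (%s)", family,
                 paste(format(params), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# intensity value, vectorised over t; plain (family, params) core used in
# hot loops where constructing classed objects would dominate runtime
fam_hazard <- function(family, params, t) {
  switch(family,
    exponential = rep_len(params[1], length(t)),
    gompertz = params[1] * exp(params[2] * t),
    weibull = {
      sc <- params[1]
      if (!is.finite(sc)) {
        rep_len(0, length(t))
      } else {
        (params[2] / sc) * (t / sc)^(params[2] - 1)
      }
    }
  )
}

# cumulative intensity A(t) = int_0^t alpha(u) du, closed forms.
# expm1 keeps the Gompertz form accurate as shape -> 0 (no cancellation).
fam_cumhaz <- function(family, params, t) {
  switch(family,
    exponential = params[1] * t,
    gompertz = {
      b <- params[2]
      if (b == 0) params[1] * t else (params[1] / b) * expm1(b * t)
    },
    weibull = {
      sc <- params[1]
      if (!is.finite(sc)) rep_len(0, length(t)) else (t / sc)^params[2]
    }
  )
}

# A(Inf): finite only for the defective Gompertz (shape < 0) and for the
# degenerate zero-intensity boundaries
fam_cumhaz_inf <- function(family, params) {
  switch(family,
    exponential = if (params[1] > 0) Inf else 0,
    gompertz = {
      if (params[1] == 0) 0
      else if (params[2] < 0) -params[1] / params[2]
      else Inf
    },
    weibull = if (is.finite(params[1])) Inf else 0
  )
}

#' Evaluate a transition intensity
#'
#' @param ti a [crm_intensity()] object.
#' @param t vector of nonnegative times (days).
#' @return vector of intensity values (per day). For a Weibull intensity
#'   with shape < 1 evaluated at `t = 0` the value is infinite; a warning
#'   is raised so the caller can move the window endpoint away from zero.
#' @export
intensity <- function(ti, t) {
  stopifnot(inherits(ti, "crm_intensity"))
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  out <- fam_hazard(ti$family, ti$params, t)
  if (any(is.infinite(out))) {
    warning("infinite intensity (Weibull shape < 1 at t = 0); ",
            "use a window with t_lo > 0", call. = FALSE)
  }
  out
}

#' Evaluate a cumulative transition intensity
#'
#' Closed-form accumulated hazard \eqn{A(t) = \int_0^t \alpha(u)\,du}:
#' `rate * t` (exponential), `scale/shape * (exp(shape*t) - 1)` (Gompertz,
#' with the limit `scale * t` as the shape tends to 0), `(t/scale)^shape`
#' (Weibull).
#'
#' @inheritParams intensity
#' @return vector of accumulated hazards; `A(0) = 0`, nondecreasing in `t`.
#' @export
cum_intensity <- function(ti, t) {
  stopifnot(inherits(ti, "crm_intensity"))
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  fam_cumhaz(ti$family, ti$params, t)
}

#' @export
print.crm_intensity <- function(x, ...) {
  lab <- switch(x$family,
    exponential = sprintf("rate = %g", x$params[1]),
    gompertz = sprintf("scale = %g, shape = %g", x$params[1], x$params[2]),
    weibull = sprintf("scale = %g, shape = %g", x$params[1], x$params[2])
  )
  cat(sprintf("<crm_intensity> %s (%s)\n", x$family, lab))
  invisible(x)
}

#' Parametric competing risks model for one group
#'
#' Bundles k cause-specific transition intensities (one per absorbing
#' state) with the observation window `[0, tau]`.
#'
#' @param ... `k >= 1` [crm_intensity()] objects (or a single list of them).
#' @param tau end of the observation window in days (default 90).
#' @return an object of class `"crm_model"` with elements `transitions`
#'   (list of intensities) and `tau`.
#' @examples
#' m <- crm_model(
#'   crm_intensity("exponential", 0.001),
#'   crm_intensity("exponential", 0.0011),
#'   crm_intensity("exponential", 0.0004),
#'   tau = 90
#' )
#' all_cause_survival(m, c(0, 90))
#' @export
crm_model <- function(..., tau = 90) {
  trans <- list(...)
  if (length(trans) == 1L && !inherits(trans[[1]], "crm_intensity")) {
    trans <- trans[[1]]
  }
  if (length(trans) < 1L) stop("need at least one transition", call. = FALSE)
  ok <- vapply(trans, inherits, logical(1), what = "crm_intensity")
  if (!all(ok)) stop("all transitions must be crm_intensity objects", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("tau must be a positive number (days)", call. = FALSE)
  }
  structure(list(transitions = trans, tau = tau), class = "crm_model")
}

#' @export
print.crm_model <- function(x, ...) {
  cat(sprintf("<crm_model> k = %d transitions, window [0, %g] days\n",
              length(x$transitions), x$tau))
  for (j in seq_along(x$transitions)) {
    cat(sprintf("  state %d: ", j))
    print(x$transitions[[j]])
  }
  invisible(x)
}

# plain-list accessors used by the cores
model_families <- function(m) vapply(m$transitions, `[[`, character(1), "family")
model_params <- function(m) lapply(m$transitions, `[[`, "params")

#' All-cause (event-free) survival function
#'
#' Probability of not having experienced any of the k competing events by
#' time `t`: `exp(-sum_j A_j(t))` with `A_j` the cumulative cause-specific
#' intensities.
#'
#' @param m a [crm_model()].
#' @param t vector of nonnegative times (days).
#' @return survival probabilities in (0, 1], with `S(0) = 1`.
#' @export
all_cause_survival <- function(m, t) {
  stopifnot(inherits(m, "crm_model"))
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  A <- 0
  for (tr in m$transitions) A <- A + fam_cumhaz(tr$family, tr$params, t)
  exp(-A)
}
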