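#' Censoring mechanisms
#'
#' Two right-censoring mechanisms are supported.
#'
#' `censoring_administrative(tau)` describes Type I censoring: follow-up
#' ends at the fixed study time `tau` (days) and every subject still
#' event-free at `tau` is censored there.
#'
#' `censoring_random(rate)` describes independent random right-censoring
#' with a parametric censoring-time distribution (currently exponential).
#' The observed time is `min(T, C)`; a subject is censored (status 0) when
#' `C < T`. When `rate = NULL`, the rate is estimated from the data by the
#' fitting functions. By default random censoring times are *not*
#' additionally truncated at a study end: `cap_tau` re-enables a cap at
#' `tau` days if desired.
#'
#' @param tau fixed end of study in days.
#' @param rate exponential censoring rate (per day), or `NULL` to estimate.
#' @param family censoring-time family; only `"exponential"` is built in.
#' @param cap_tau optional administrative cap (days) applied on top of
#'   random censoring; `NULL` (default) for no cap.
#' @return an object of class `"crm_censoring"`.
#' @name censoring
#' @examples
#' censoring_administrative(90)
#' censoring_random(0.001)
NULL

#' @rdname censoring
#' @export
censoring_administrative <- function(tau = 90) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("tau must be a positive number of days", call. = FALSE)
  }
  structure(list(kind = "administrative", tau = tau),
            class = "crm_censoring")
}

#' @rdname censoring
#' @export
censoring_random <- function(rate = NULL, family = "exponential",
                             cap_tau = NULL) {
  family <- match.arg(family, "exponential")
  if (!is.null(rate)) {
    if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0) {
      stop("censoring rate must be a nonnegative number", call. = FALSE)
    }
  }
  structure(list(kind = "random", family = family, rate = rate,
                 cap_tau = cap_tau),
            class = "crm_censoring")
}

#' @export
print.crm_censoring <- function(x, ...) {
  if (x$kind == "administrative") {
    cat(sprintf("<crm_censoring> administrative at tau = %g days\n", x$tau))
  } else {
    r <- if (is.null(x$rate)) "estimated from data" else format(x$rate)
    cap <- if (is.null(x$cap_tau)) "" else sprintf(", capped at %g days", x$cap_tau)
    cat(sprintf("<crm_censoring> random (%s, rate %s%s)\n", x$family, r, cap))
  }
  invisible(x)
}

# censoring density / cdf (exponential only for now)
cens_log_density <- function(cens, t) {
  stats::dexp(t, rate = cens$rate, log = TRUE)
}

# parse "administrative:90" / "random:0.001" strings (CLI and configs)
parse_censoring <- function(spec) {
  if (inherits(spec, "crm_censoring")) return(spec)
  parts <- strsplit(as.character(spec), ":", fixed = TRUE)[[1]]
  kind <- match.arg(parts[1], c("administrative", "random"))
  val <- if (length(parts) > 1L) as.numeric(parts[2]) else NULL
  if (kind == "administrative") {
    censoring_administrative(if (is.null(val)) 90 else val)
  } else {
    censoring_random(val)
  }
}
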