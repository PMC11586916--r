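#' Per-transition similarity tests combined by intersection-union
#'
#' The comparator to the global test: each transition j is tested on its
#' own (null: the j-th pair of intensities differs by at least `delta[j]`
#' in sup-norm) using the same constrained parametric bootstrap machinery,
#' but with the boundary constraint imposed on transition j only and the
#' bootstrap statistic being that transition's sup-distance. By the
#' intersection-union principle, overall similarity is concluded only if
#' every individual null is rejected; the combined p-value is the maximum
#' of the individual p-values. This is conservative, increasingly so with
#' the number of transitions, which is what motivates the global statistic.
#'
#' @inheritParams crm_similarity_test
#' @param delta a single threshold applied to every transition, or a
#'   vector of k per-transition thresholds.
#' @return an object of class `"crm_iup"`: `per_transition` (list of
#'   individual test records), `p_value` (max), `reject` (all rejected),
#'   `alpha`, `B`.
#' @export
crm_iup_test <- function(data, families, delta, B = 250, alpha = 0.05,
                         censoring = censoring_administrative(90),
                         window = NULL, seed = NULL, boot_seeds = NULL,
                         max_fail = 0.05) {
  families <- vapply(families, function(f) {
    match.arg(f, c("exponential", "gompertz", "weibull"))
  }, character(1))
  k <- length(families)
  deltas <- if (length(delta) == 1L) rep(delta, k) else as.numeric(delta)
  if (length(deltas) != k || any(deltas <= 0)) {
    stop("delta must be one positive threshold or k of them", call. = FALSE)
  }
  gr <- split_groups(data, k)
  if (is.null(boot_seeds)) {
    boot_seeds <- matrix(derive_seeds(seed, k * B), nrow = k)
  }
  per <- vector("list", k)
  for (j in seq_len(k)) {
    core <- sim_test_core(gr$time1, gr$status1, gr$time2, gr$status2,
                          families, deltas[j], B, alpha, censoring, window,
                          boot_seeds[j, ], max_fail, stat_j = j)
    per[[j]] <- list(transition = j, d_hat = core$d_hat,
                     delta = deltas[j], p_value = core$p_value,
                     q_alpha = core$q_alpha, reject = core$reject,
                     branch = core$branch, B = core$B)
  }
  pv <- vapply(per, `[[`, numeric(1), "p_value")
  structure(list(
    per_transition = per,
    p_value = max(pv),
    reject = all(vapply(per, `[[`, logical(1), "reject")),
    alpha = alpha, B = B, deltas = deltas, families = families,
    n = c(n1 = length(gr$time1), n2 = length(gr$time2))
  ), class = "crm_iup")
}

#' @export
print.crm_iup <- function(x, ...) {
  cat("\n\tPer-transition similarity tests (intersection-union)\n\n")
  df <- data.frame(
    transition = vapply(x$per_transition, `[[`, integer(1), "transition"),
    d_hat = vapply(x$per_transition, `[[`, numeric(1), "d_hat"),
    delta = x$deltas,
    p_value = vapply(x$per_transition, `[[`, numeric(1), "p_value"),
    reject = vapply(x$per_transition, `[[`, logical(1), "reject")
  )
  print(df, row.names = FALSE)
  cat(sprintf("combined p-value (max) = %.4g; similarity %s\n", x$p_value,
              if (x$reject) "established" else "NOT established"))
  invisible(x)
}

#' Minimal similarity threshold with controlled Type I error
#'
#' Scans an increasing grid of thresholds and reports the smallest one at
#' which the similarity test rejects. Because rejection at a threshold
#' implies rejection at every larger threshold (the bootstrap statistics
#' are coupled across thresholds by sharing per-replicate seeds), the
#' sequential-rejection principle controls the Type I error at `alpha`
#' without multiplicity adjustment, and the search can proceed by
#' bisection.
#'
#' @inheritParams crm_similarity_test
#' @param delta_grid increasing vector of positive candidate thresholds.
#' @return an object of class `"crm_mindelta"`: `delta_hat` (smallest
#'   rejecting threshold, `Inf` if none rejects), `evaluated` (data frame
#'   of thresholds actually tested with p-values), `d_hat`, `alpha`.
#' @export
minimal_delta <- function(data, families, delta_grid, B = 250,
                          alpha = 0.05,
                          censoring = censoring_administrative(90),
                          window = NULL, seed = NULL, max_fail = 0.05) {
  delta_grid <- sort(as.numeric(delta_grid))
  if (any(delta_grid <= 0)) stop("delta_grid must be positive", call. = FALSE)
  if (is.unsorted(delta_grid, strictly = TRUE)) {
    delta_grid <- unique(delta_grid)
  }
  boot_seeds <- derive_seeds(seed, B)
  cache <- new.env(parent = emptyenv())
  run_at <- function(i) {
    key <- as.character(i)
    if (!is.null(cache[[key]])) return(cache[[key]])
    tst <- crm_similarity_test(data, families, delta_grid[i], B = B,
                               alpha = alpha, censoring = censoring,
                               window = window, boot_seeds = boot_seeds,
                               max_fail = max_fail)
    cache[[key]] <- tst
    tst
  }
  m <- length(delta_grid)
  top <- run_at(m)
  if (!top$reject) {
    evaluated <- data.frame(delta = delta_grid[m], p_value = top$p_value,
                            reject = FALSE)
    return(structure(list(delta_hat = Inf, evaluated = evaluated,
                          d_hat = top$d_hat, alpha = alpha,
                          delta_grid = delta_grid),
                     class = "crm_mindelta"))
  }
  lo <- 1L; hi <- m  # hi rejects; find the smallest rejecting index
  if (run_at(1L)$reject) {
    hi <- 1L
  } else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (run_at(mid)$reject) hi <- mid else lo <- mid
    }
  }
  idx <- sort(as.integer(ls(cache)))
  evaluated <- data.frame(
    delta = delta_grid[idx],
    p_value = vapply(idx, function(i) cache[[as.character(i)]]$p_value,
                     numeric(1)),
    reject = vapply(idx, function(i) cache[[as.character(i)]]$reject,
                    logical(1))
  )
  structure(list(delta_hat = delta_grid[hi], evaluated = evaluated,
                 d_hat = top$d_hat, alpha = alpha, delta_grid = delta_grid),
            class = "crm_mindelta")
}

#' @export
print.crm_mindelta <- function(x, ...) {
  cat("\n\tMinimal similarity threshold (sequential rejection)\n\n")
  cat(sprintf("observed d_hat = %g\n", x$d_hat))
  if (is.finite(x$delta_hat)) {
    cat(sprintf("smallest rejecting threshold: delta_hat = %g (alpha = %g)\n",
                x$delta_hat, x$alpha))
  } else {
    cat("no threshold on the grid rejects; delta_hat = Inf\n")
  }
  print(x$evaluated, row.names = FALSE)
  invisible(x)
}
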