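#' Deterministic child seed streams
#'
#' Fans one root seed out into `n` reproducible child seeds. Used for
#' per-replication and per-bootstrap-replicate streams, so any single
#' replicate can be re-run in isolation and study results do not depend
#' on the parallel worker count. Passing the same stream as `boot_seeds`
#' to several [crm_similarity_test()] calls couples their bootstrap draws.
#'
#' @param seed root seed (`NULL`: continue from the current RNG state).
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(2147483646L, n, replace = FALSE)
}

check_dataset <- function(data, k, two_groups = TRUE) {
  need <- c("time", "status", if (two_groups) "group")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  time <- as.numeric(data$time)
  status <- as.integer(data$status)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("times must be finite and positive", call. = FALSE)
  }
  if (any(is.na(status)) || any(status < 0L | status > k)) {
    stop(sprintf("status must lie in 0..%d", k), call. = FALSE)
  }
  if (two_groups) {
    g <- as.integer(data$group)
    if (any(is.na(g)) || !all(g %in% c(1L, 2L))) {
      stop("group must be 1 or 2", call. = FALSE)
    }
  }
  invisible(TRUE)
}
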