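#' Monte Carlo operating characteristics of the similarity test
#'
#' `run_study_cell()` runs `N` seeded replications of one study cell:
#' generate a two-group dataset from a scenario preset, apply the global
#' similarity test (or the per-transition intersection-union comparator)
#' at threshold `delta`, and record the rejection decision and censored
#' fraction. `run_study()` iterates over a grid of cells and returns a
#' results table.
#'
#' When the generating models sit on the null boundary (max distance equal
#' to `delta`) the rejection proportion estimates the maximal Type I
#' error; under the alternative (all distances below `delta`) it estimates
#' power. Every proportion is reported with its binomial Monte Carlo
#' standard error `sqrt(p(1-p)/N)` so that reduced-replication runs stay
#' interpretable.
#'
#' Replications are parallelised with pre-derived per-replication seeds,
#' so results are identical for any worker count.
#'
#' @param scenario a [crm_scenario()] (its `censoring`, `n1`, `n2` define
#'   the cell).
#' @param delta similarity threshold (vector of k thresholds allowed for
#'   `method = "iup"`).
#' @param N number of Monte Carlo replications.
#' @param B bootstrap replicates per test.
#' @param alpha significance level.
#' @param method `"global"` (max over transitions) or `"iup"`
#'   (per-transition tests combined by intersection-union).
#' @param seed root seed; per-replication seeds derive from it.
#' @param mc.cores parallel workers (forked; 1 = serial).
#' @return `run_study_cell()`: a one-row data frame with columns
#'   `scenario`, `n1`, `n2`, `censoring`, `delta`, `method`, `N`, `B`,
#'   `reject_prop`, `mc_se`, `censored_pct`, `failures`.
#' @examples
#' sc <- crm_scenario(2, n1 = 100, n2 = 100)
#' run_study_cell(sc, delta = 0.002, N = 20, B = 50, seed = 1)
#' @export
run_study_cell <- function(scenario, delta, N = 1000, B = 250,
                           alpha = 0.05, method = c("global", "iup"),
                           seed = 1, mc.cores = 1L) {
  stopifnot(inherits(scenario, "crm_scenario"))
  method <- match.arg(method)
  seeds <- derive_seeds(seed, 2L * N)
  rep_seeds <- seeds[seq_len(N)]
  boot_roots <- seeds[N + seq_len(N)]
  one_rep <- function(r) {
    d <- generate_scenario_dataset(scenario, seed = rep_seeds[r])
    res <- tryCatch({
      if (method == "global") {
        tst <- crm_similarity_test(d, scenario$families, delta, B = B,
                                   alpha = alpha,
                                   censoring = scenario$censoring,
                                   seed = boot_roots[r])
      } else {
        tst <- crm_iup_test(d, scenario$families, delta, B = B,
                            alpha = alpha, censoring = scenario$censoring,
                            seed = boot_roots[r])
      }
      c(reject = as.numeric(tst$reject),
        censored = mean(d$status == 0L), failed = 0)
    }, error = function(e) c(reject = NA_real_,
                             censored = mean(d$status == 0L), failed = 1))
    res
  }
  rows <- if (mc.cores > 1L) {
    parallel::mclapply(seq_len(N), one_rep, mc.cores = mc.cores)
  } else {
    lapply(seq_len(N), one_rep)
  }
  rows <- do.call(rbind, rows)
  ok <- !is.na(rows[, "reject"])
  p <- mean(rows[ok, "reject"])
  data.frame(
    scenario = scenario$label,
    n1 = scenario$n1, n2 = scenario$n2,
    censoring = format_censoring(scenario$censoring),
    delta = if (length(delta) == 1L) delta else paste(delta, collapse = "/"),
    method = method, N = sum(ok), B = B,
    reject_prop = p,
    mc_se = sqrt(p * (1 - p) / sum(ok)),
    censored_pct = 100 * mean(rows[, "censored"]),
    failures = sum(rows[, "failed"]),
    stringsAsFactors = FALSE
  )
}

format_censoring <- function(cens) {
  if (cens$kind == "administrative") {
    sprintf("administrative:%g", cens$tau)
  } else {
    sprintf("random:%g", if (is.null(cens$rate)) NA_real_ else cens$rate)
  }
}

#' @rdname run_study_cell
#' @param config study configuration: a list with elements `scenario`
#'   (1..4 or `"scenarioX"`), `n_pairs` (list of `c(n1, n2)`), `deltas`,
#'   `censoring` (censoring spec string, a [censoring()] object, or a list
#'   of them), `N`, `B`, `alpha`, `method` (one or both of
#'   `"global"`/`"iup"`), `seed`; typically read with
#'   [read_study_config()].
#' @param out optional path; when given the results table is written there
#'   as CSV.
#' @return `run_study()`: a data frame with one row per cell.
#' @export
run_study <- function(config, out = NULL, mc.cores = 1L) {
  cfg <- config
  n_pairs <- cfg$n_pairs %||% list(c(200, 200))
  deltas <- cfg$deltas %||% stop("config needs deltas", call. = FALSE)
  cens_list <- cfg$censoring %||% "administrative:90"
  if (inherits(cens_list, "crm_censoring") || is.character(cens_list) &&
      length(cens_list) == 1L) {
    cens_list <- list(cens_list)
  }
  methods <- cfg$method %||% "global"
  N <- cfg$N %||% 1000
  B <- cfg$B %||% 250
  alpha <- cfg$alpha %||% 0.05
  seed <- cfg$seed %||% 1
  rows <- list()
  cell_id <- 0L
  for (cens in cens_list) {
    cens <- parse_censoring(cens)
    for (np in n_pairs) {
      for (delta in deltas) {
        for (method in methods) {
          cell_id <- cell_id + 1L
          sc <- crm_scenario(cfg$scenario, n1 = np[1], n2 = np[2],
                             censoring = cens)
          rows[[cell_id]] <- run_study_cell(sc, delta, N = N, B = B,
                                            alpha = alpha, method = method,
                                            seed = seed + cell_id,
                                            mc.cores = mc.cores)
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(out)) {
    utils::write.csv(res, out, row.names = FALSE)
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a study configuration file
#'
#' Reads a YAML study configuration (see [run_study()] for the schema).
#'
#' @param path path to a YAML file.
#' @return the configuration list.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$n_pairs)) {
    cfg$n_pairs <- lapply(cfg$n_pairs, as.numeric)
  }
  cfg
}
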