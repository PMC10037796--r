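#' Percentile confidence interval
#'
#' Empirical `alpha/2` and `1 - alpha/2` quantiles of the replicate draws,
#' using linear interpolation of order statistics (the type-7 quantile
#' rule, R's default — documented as this package's percentile
#' convention).
#'
#' @param draws Numeric vector of replicate estimates (>= 2 finite values).
#' @param alpha Two-sided level (default 0.05: the 2.5 and 97.5
#'   percentiles).
#' @return Named vector `c(low, high)`.
#' @export
percentile_ci <- function(draws, alpha = 0.05) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 2) {
    stop("percentile_ci: need at least 2 finite draws", call. = FALSE)
  }
  q <- stats::quantile(draws, c(alpha / 2, 1 - alpha / 2),
                       names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Significance by the confidence-interval rule
#'
#' `TRUE` iff zero lies strictly outside `[ci_low, ci_high]`; an interval
#' touching zero counts as non-significant (boundary inclusive).
#'
#' @param estimate A one-row estimand tibble with `ci_low`, `ci_high`.
#' @return Logical.
#' @export
significance_flag <- function(estimate) {
  if (is.na(estimate$ci_low) || is.na(estimate$ci_high)) {
    stop("significance_flag: estimate carries no confidence interval",
         call. = FALSE)
  }
  estimate$ci_low > 0 || estimate$ci_high < 0
}

#' Bootstrap-then-impute pipeline
#'
#' For each of `B` replicates: resample `n` individuals with replacement,
#' run the single stochastic imputation on the resampled table (skipped
#' when it is complete), then evaluate the estimator. The reported point
#' estimate is the mean over replicates and the confidence interval the
#' 2.5/97.5 percentile of the replicate distribution; the original-sample
#' estimate is kept alongside for comparison. Replicate seeds are derived
#' from the master seed by fixed offsets, so a fixed master seed
#' reproduces the whole object and replicates are independent of execution
#' order.
#'
#' @param table Cohort table (may contain missing values).
#' @param estimator Function `(completed_table, seed) -> named numeric
#'   vector`, deterministic given its two arguments.
#' @param B Number of bootstrap replicates (>= 2; the headline analysis
#'   uses 1,000).
#' @param master_seed Integer master seed.
#' @param impute_spec [imputation_spec()] used on incomplete replicates.
#' @param alpha CI level.
#' @return A `bootstrap_result`: list with `estimates` (B x K matrix),
#'   `point` (replicate means), `ci` (2 x K), `original` (full-sample
#'   estimate), `failures`, `master_seed`, `B`.
#' @export
#' @examples
#' coh <- transform_outcomes(generate_cohort(sim_params(), 400, 1))
#' est <- function(tab, seed) {
#'   q <- fit_qbar(tab, "sbp")
#'   c(te_sbp = total_effect(q, tab)$point)
#' }
#' br <- bootstrap_pipeline(coh, est, B = 50, master_seed = 9)
#' br$point
#' br$ci
bootstrap_pipeline <- function(table, estimator, B = 1000L,
                               master_seed = 1L,
                               impute_spec = imputation_spec(),
                               alpha = 0.05) {
  if (B < 2) {
    stop("bootstrap_pipeline: B must be at least 2", call. = FALSE)
  }
  n <- nrow(table)
  imputed_count <- 0L

  run_one <- function(tab, seed) {
    completed <- if (anyNA(tab[, setdiff(names(tab), "id")])) {
      imputed_count <<- imputed_count + 1L
      impute_stochastic(tab, impute_spec, seed = seed)
    } else {
      tab
    }
    estimator(completed, seed)
  }

  original <- tryCatch(
    run_one(table, child_seed(master_seed, "bootstrap", 0L)),
    error = function(e) NULL)

  draws <- vector("list", B)
  failures <- 0L
  for (b in seq_len(B)) {
    seed_b <- child_seed(master_seed, "bootstrap", b)
    set.seed(seed_b)
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch(run_one(table[idx, , drop = FALSE], seed_b),
                    error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1L
    } else {
      draws[[b]] <- res
    }
  }
  if (failures > 0.05 * B) {
    stop("bootstrap_pipeline: ", failures, "/", B,
         " replicates failed (> 5%); aborting", call. = FALSE)
  }
  ok <- !vapply(draws, is.null, logical(1))
  est <- do.call(rbind, draws[ok])
  nonfinite <- colSums(!is.finite(est))
  if (any(nonfinite > 0)) {
    warning("bootstrap_pipeline: non-finite replicate estimates excluded ",
            "from percentiles for: ",
            paste(colnames(est)[nonfinite > 0], collapse = ", "),
            call. = FALSE)
  }
  point <- apply(est, 2, function(x) mean(x[is.finite(x)]))
  ci <- apply(est, 2, percentile_ci, alpha = alpha)
  structure(
    list(estimates = est, point = point, ci = ci, original = original,
         failures = failures, nonfinite = nonfinite,
         imputed_replicates = imputed_count,
         master_seed = as.integer(master_seed), B = as.integer(B),
         alpha = alpha),
    class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result: B = ", x$B, ", ", ncol(x$estimates),
      " estimand(s), ", x$failures, " failed replicate(s)>\n", sep = "")
  invisible(x)
}

#' Attach bootstrap intervals to a tidy estimand table
#'
#' Joins a [bootstrap_pipeline()] result (whose estimator returned values
#' keyed like [compute_estimands()]) back onto the tidy estimand layout:
#' point = replicate mean, percentile CI, replicate count.
#'
#' @param boot A `bootstrap_result`.
#' @param template Tidy estimand tibble from [compute_estimands()] run on
#'   the original data (provides the row metadata).
#' @return The template with `point`, `ci_low`, `ci_high`, `n_boot`
#'   replaced by the bootstrap summaries.
#' @export
summarize_bootstrap <- function(boot, template) {
  stopifnot(inherits(boot, "bootstrap_result"))
  keys <- colnames(boot$estimates)
  keep <- template$key %in% keys
  out <- template[keep, , drop = FALSE]
  m <- match(out$key, keys)
  out$point <- unname(boot$point[m])
  out$ci_low <- unname(boot$ci["low", m])
  out$ci_high <- unname(boot$ci["high", m])
  out$n_boot <- boot$B - boot$failures
  # an EP is a ratio with the TE in the denominator: when the bootstrapped
  # TE interval includes zero the replicate EPs are unstable (the mean can
  # even fall outside the percentile interval); keep the row, tag it
  if ("estimand" %in% names(out)) {
    ep_rows <- which(out$estimand %in% c("EP_G", "EP_Sigma", "EP_E"))
    for (i in ep_rows) {
      te_key <- paste("TE", out$outcome[i], out$scale[i], "", sep = "|")
      if (te_key %in% keys &&
          boot$ci["low", te_key] <= 0 && boot$ci["high", te_key] >= 0) {
        out$unstable[i] <- TRUE
      }
    }
  }
  out
}
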