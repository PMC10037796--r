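#' Specification for single stochastic imputation
#'
#' Chained-equations imputation with regression draws: binary columns are
#' filled by a logistic fit plus a Bernoulli draw of the fitted
#' probability, continuous columns by a least-squares fit plus a Gaussian
#' residual draw. One stochastic completion per call — uncertainty is
#' carried by the surrounding bootstrap, not by multiple imputation. This
#' is a deliberate simplification of full chained-equation samplers: no
#' posterior draw of the coefficients and no predictive mean matching.
#'
#' @param cycles Number of chained-equation sweeps (default 10).
#' @param visit_order `"increasing_missingness"` (default) or an explicit
#'   character vector of column names.
#' @param predictors Optional character vector restricting the predictor
#'   pool; default: all other dictionary data columns.
#' @return An `imputation_spec` list.
#' @export
imputation_spec <- function(cycles = 10L,
                            visit_order = "increasing_missingness",
                            predictors = NULL) {
  if (length(cycles) != 1 || is.na(cycles) || cycles < 1) {
    stop("imputation_spec: cycles must be a positive integer", call. = FALSE)
  }
  structure(list(cycles = as.integer(cycles), visit_order = visit_order,
                 predictors = predictors),
            class = "imputation_spec")
}

#' Single stochastic imputation of a cohort table
#'
#' Fills every missing value with one stochastic draw from chained
#' regression models (see [imputation_spec()]). Observed entries are never
#' altered; binary columns stay binary (Bernoulli draws, not rounded
#' expectations); a fixed seed reproduces the completion exactly.
#'
#' @param table Cohort table, possibly with `NA`s. `sex` must be fully
#'   observed (cohort inclusion requires known sex and vital status).
#' @param spec An [imputation_spec()].
#' @param seed Integer seed.
#' @return The completed table.
#' @export
#' @examples
#' p <- sim_params()
#' coh <- inject_missingness(generate_cohort(p, 300, 1), p, 1)
#' full <- impute_stochastic(coh, imputation_spec(cycles = 3), seed = 2)
#' anyNA(full)
impute_stochastic <- function(table, spec = imputation_spec(), seed = 1L) {
  stopifnot(inherits(spec, "imputation_spec"))
  if (anyNA(table$sex)) {
    stop("impute_stochastic: sex must be observed for all individuals",
         call. = FALSE)
  }
  # markers analysed on the log scale are imputed there (Gaussian draws are
  # coherent on that scale); their native columns are derived afterwards by
  # exponentiation and excluded from the chained models
  breg <- biomarker_registry()
  logm <- breg$name[breg$log_transform]
  derived_native <- intersect(
    logm[paste0("log_", logm) %in% names(table)], names(table))
  data_cols <- setdiff(names(table), c("id", derived_native))
  n_miss <- vapply(table[data_cols], function(x) sum(is.na(x)), integer(1))
  if (all(n_miss == 0) && !anyNA(table[derived_native])) {
    return(table)
  }
  if (all(n_miss > 0)) {
    stop("impute_stochastic: need at least one fully observed data column",
         call. = FALSE)
  }
  all_missing <- names(n_miss)[vapply(table[data_cols],
                                      function(x) all(is.na(x)), logical(1))]
  if (length(all_missing) > 0) {
    stop("impute_stochastic: column(s) entirely missing: ",
         paste(all_missing, collapse = ", "), call. = FALSE)
  }

  targets <- names(n_miss)[n_miss > 0]
  if (identical(spec$visit_order, "increasing_missingness")) {
    targets <- targets[order(n_miss[targets])]
  } else {
    ord <- intersect(spec$visit_order, targets)
    targets <- c(ord, setdiff(targets, ord))
  }
  pool <- if (is.null(spec$predictors)) data_cols else spec$predictors
  is_binary <- vapply(table[data_cols],
                      function(x) all(x %in% c(0, 1) | is.na(x)),
                      logical(1))

  set.seed(child_seed(seed, "imputation"))
  work <- table
  # initial fill: random draws from each column's observed values
  for (col in targets) {
    na_idx <- which(is.na(work[[col]]))
    obs <- work[[col]][!is.na(work[[col]])]
    work[[col]][na_idx] <- sample(obs, length(na_idx), replace = TRUE)
  }

  miss_idx <- lapply(stats::setNames(targets, targets),
                     function(col) which(is.na(table[[col]])))
  for (cycle in seq_len(spec$cycles)) {
    for (col in targets) {
      idx <- miss_idx[[col]]
      preds <- setdiff(pool, col)
      # drop constant predictors to keep the design full rank
      keep <- vapply(work[preds],
                     function(x) length(unique(x)) > 1, logical(1))
      preds <- preds[keep]
      form <- stats::reformulate(if (length(preds)) preds else "1",
                                 response = col)
      dat <- work
      dat[[col]][idx] <- table[[col]][idx]  # refit on observed rows only
      obs_rows <- !is.na(dat[[col]])
      if (is_binary[[col]]) {
        fit <- suppressWarnings(
          stats::glm(form, family = stats::binomial(),
                     data = dat[obs_rows, , drop = FALSE]))
        p <- stats::predict(fit, newdata = work[idx, , drop = FALSE],
                            type = "response")
        work[[col]][idx] <- stats::rbinom(length(idx), 1L, p)
      } else {
        fit <- stats::lm(form, data = dat[obs_rows, , drop = FALSE])
        mu <- stats::predict(fit, newdata = work[idx, , drop = FALSE])
        sd_res <- sqrt(sum(stats::residuals(fit)^2) /
                         max(1, fit$df.residual))
        work[[col]][idx] <- stats::rnorm(length(idx), mu, sd_res)
      }
    }
  }
  for (nm in derived_native) {
    idx <- which(is.na(table[[nm]]))
    work[[nm]][idx] <- exp(work[[paste0("log_", nm)]][idx])
  }
  work
}
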