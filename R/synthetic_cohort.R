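#' Generate a synthetic birth cohort
#'
#' Draws a complete cohort (no missing values) from the generative model in
#' [sim_params()]: sex at birth, two correlated early-environment
#' indicators whose conjunction defines deprivation, logistic mediators and
#' linear-Gaussian biomarkers (log-normal for the log-scale markers).
#'
#' @param params A [sim_params()] object.
#' @param n Number of cohort members (`n = 0` gives an empty table with the
#'   full column schema).
#' @param seed Integer seed; per-stage child seeds are derived internally so
#'   the same `(params, n, seed)` always reproduces the same table.
#' @return A tibble with columns `id`, `sex`, `mother_short_education`,
#'   `parent_manual_class`, `deprived`, the 21 registry mediators and the six
#'   biomarkers in native units.
#' @export
#' @examples
#' coh <- generate_cohort(sim_params(), n = 500, seed = 1)
#' mean(coh$sex)
generate_cohort <- function(params, n = params$n_default, seed = params$seed) {
  validate_sim_params(params)
  if (length(n) != 1 || is.na(n) || n < 0 || n != trunc(n)) {
    stop("generate_cohort: n must be a single non-negative integer",
         call. = FALSE)
  }
  n <- as.integer(n)

  set.seed(child_seed(seed, "environment"))
  sex <- stats::rbinom(n, 1L, params$p_male)
  p11 <- joint_p11(params$p_short_edu, params$p_manual,
                   params$edu_manual_odds_ratio)
  cells <- c(p11,
             params$p_short_edu - p11,
             params$p_manual - p11,
             1 - params$p_short_edu - params$p_manual + p11)
  draw <- sample.int(4L, n, replace = TRUE, prob = cells)
  mother_short_education <- as.integer(draw %in% c(1L, 2L))
  parent_manual_class <- as.integer(draw %in% c(1L, 3L))
  deprived <- mother_short_education * parent_manual_class

  set.seed(child_seed(seed, "mediators"))
  mm <- params$mediator_models
  meds <- lapply(seq_len(nrow(mm)), function(j) {
    stats::rbinom(n, 1L, stats::plogis(mm$alpha[j] + mm$beta[j] * sex +
                                         mm$gamma[j] * deprived))
  })
  names(meds) <- mm$name
  med_mat <- do.call(cbind, c(meds, list(deparse.level = 0)))
  if (n == 0L) med_mat <- matrix(integer(0), nrow = 0, ncol = nrow(mm))

  set.seed(child_seed(seed, "outcomes"))
  breg <- biomarker_registry()
  breg <- breg[breg$name %in% names(params$outcome_models), , drop = FALSE]
  outs <- lapply(breg$name, function(nm) {
    om <- params$outcome_models[[nm]]
    mu <- om$a + om$b * sex + om$c * deprived + om$d * sex * deprived
    if (length(om$w) > 0 && n > 0) {
      mu <- mu + drop(med_mat[, names(om$w), drop = FALSE] %*% om$w)
    }
    y <- mu + stats::rnorm(n, 0, om$sigma_y)
    if (breg$log_transform[breg$name == nm]) exp(y) else y
  })
  names(outs) <- breg$name

  tibble::as_tibble(c(
    list(id = seq_len(n), sex = sex,
         mother_short_education = mother_short_education,
         parent_manual_class = parent_manual_class, deprived = deprived),
    meds, outs))
}

#' True estimand values implied by the generative model
#'
#' Marginalizes the generative model analytically over the distribution of
#' deprivation and the mediators to obtain the true total effect, controlled
#' direct effect with the mediator set fixed, stratum-specific total effects,
#' additive interaction and eliminated proportions, per biomarker on its
#' analysis (native or log) scale and as z-scores using the closed-form
#' marginal SD. The true score-based controlled direct effect has no closed
#' form (the gender score is a fitted summary of the mediators), so it is
#' obtained as a Monte-Carlo plug-in: a large cohort is simulated, the
#' score-model logistic and the linear outcome model are fitted on it, and
#' the sex contrast is averaged; its Monte-Carlo SE comes from independent
#' batch splits.
#'
#' @param params A [sim_params()] object.
#' @param mc_n Cohort size for the Monte-Carlo score oracle (>= 1e5).
#' @param mc_seed Seed for the Monte-Carlo oracle.
#' @param include_cde_g Set to `FALSE` to skip the Monte-Carlo oracle and
#'   return closed-form quantities only.
#' @return A `sim_truth` tibble, one row per biomarker and scale
#'   (`native`, `z`), with columns `TE_true`, `CDE_Sigma_true`, `TE0_true`,
#'   `TE1_true`, `IE_true`, `EP_Sigma_true`, `EP_E_true`, `sd_y`, and (when
#'   requested) `CDE_G_true`, `CDE_G_mc_se`.
#' @export
compute_truth <- function(params, mc_n = 2e5, mc_seed = params$seed,
                          include_cde_g = TRUE) {
  validate_sim_params(params)
  if (include_cde_g && mc_n < 1e5) {
    stop("compute_truth: mc_n must be at least 1e5 for the score oracle",
         call. = FALSE)
  }
  pE <- joint_p11(params$p_short_edu, params$p_manual,
                  params$edu_manual_odds_ratio)
  mm <- params$mediator_models
  # sex gaps in mediator prevalence within each deprivation stratum
  gap0 <- stats::plogis(mm$alpha + mm$beta) - stats::plogis(mm$alpha)
  gap1 <- stats::plogis(mm$alpha + mm$beta + mm$gamma) -
    stats::plogis(mm$alpha + mm$gamma)
  names(gap0) <- names(gap1) <- mm$name

  breg <- biomarker_registry()
  breg <- breg[breg$name %in% names(params$outcome_models), , drop = FALSE]
  rows <- lapply(breg$name, function(nm) {
    om <- params$outcome_models[[nm]]
    w <- om$w
    wg0 <- if (length(w)) sum(w * gap0[names(w)]) else 0
    wg1 <- if (length(w)) sum(w * gap1[names(w)]) else 0
    TE0 <- om$b + wg0
    TE1 <- om$b + om$d + wg1
    TE <- (1 - pE) * TE0 + pE * TE1
    CDE_Sigma <- om$b + om$d * pE
    tibble::tibble(
      outcome = nm,
      TE_true = TE, CDE_Sigma_true = CDE_Sigma,
      TE0_true = TE0, TE1_true = TE1, IE_true = TE1 - TE0,
      EP_Sigma_true = (TE - CDE_Sigma) / TE,
      EP_E_true = (TE - TE0) / TE,
      sd_y = truth_marginal_sd(params, nm, pE))
  })
  out <- dplyr::bind_rows(rows)

  if (include_cde_g) {
    cde_g <- cde_g_oracle(params, mc_n, mc_seed)
    out$CDE_G_true <- cde_g$value[match(out$outcome, cde_g$outcome)]
    out$CDE_G_mc_se <- cde_g$mc_se[match(out$outcome, cde_g$outcome)]
  }

  native <- dplyr::mutate(out, scale = "native", .after = "outcome")
  zed <- native
  zed$scale <- "z"
  eff <- intersect(c("TE_true", "CDE_Sigma_true", "TE0_true", "TE1_true",
                     "IE_true", "CDE_G_true", "CDE_G_mc_se"), names(zed))
  for (cl in eff) zed[[cl]] <- zed[[cl]] / zed$sd_y
  res <- dplyr::bind_rows(native, zed)
  class(res) <- c("sim_truth", class(res))
  res
}

# closed-form marginal SD of an outcome on its generated scale:
# Var(Y) = E[Var(Y | S, E)] + Var(E[Y | S, E]) over the four (S,E) cells,
# mediators independent given (S, E)
truth_marginal_sd <- function(params, outcome, pE) {
  om <- params$outcome_models[[outcome]]
  mm <- params$mediator_models
  pm <- params$p_male
  cells <- expand.grid(s = 0:1, e = 0:1)
  cells$prob <- ifelse(cells$s == 1, pm, 1 - pm) *
    ifelse(cells$e == 1, pE, 1 - pE)
  w <- om$w
  stats <- vapply(seq_len(nrow(cells)), function(i) {
    s <- cells$s[i]; e <- cells$e[i]
    pj <- stats::plogis(mm$alpha + mm$beta * s + mm$gamma * e)
    names(pj) <- mm$name
    mu <- om$a + om$b * s + om$c * e + om$d * s * e +
      (if (length(w)) sum(w * pj[names(w)]) else 0)
    v <- om$sigma_y^2 +
      (if (length(w)) sum(w^2 * pj[names(w)] * (1 - pj[names(w)])) else 0)
    c(mu = mu, v = v)
  }, numeric(2))
  mu_bar <- sum(cells$prob * stats["mu", ])
  sqrt(sum(cells$prob * stats["v", ]) +
         sum(cells$prob * (stats["mu", ] - mu_bar)^2))
}

# Monte-Carlo plug-in for the score-based controlled direct effect: per
# independent batch, fit the gender-score logistic (complete set) and the
# linear Q(S, E, G) model, take b_S + b_SE * mean(E); average over batches
cde_g_oracle <- function(params, mc_n, mc_seed, batches = 8L) {
  per <- ceiling(mc_n / batches)
  breg <- biomarker_registry()
  breg <- breg[breg$name %in% names(params$outcome_models), , drop = FALSE]
  ests <- vapply(seq_len(batches), function(k) {
    coh <- generate_cohort(params, n = per,
                           seed = child_seed(mc_seed, "truth", k))
    coh <- transform_outcomes(coh)
    vs <- variable_set("custom", mediators = params$mediator_models$name)
    mod <- fit_gender_model(coh, vs)
    coh$gender_score <- predict_gender_score(mod, coh)
    vapply(breg$name, function(nm) {
      ycol <- breg$analysis_col[breg$name == nm]
      fit <- stats::lm(stats::reformulate(c("sex * deprived", "gender_score"),
                                          response = ycol), data = coh)
      cf <- stats::coef(fit)
      unname(cf["sex"] + cf["sex:deprived"] * mean(coh$deprived))
    }, numeric(1))
  }, numeric(nrow(breg)))
  if (!is.matrix(ests)) ests <- matrix(ests, nrow = nrow(breg))
  tibble::tibble(outcome = breg$name,
                 value = rowMeans(ests),
                 mc_se = apply(ests, 1, stats::sd) / sqrt(batches))
}

#' Mask cohort values under a missing-at-random model
#'
#' Applies per-column logistic missingness models whose predictors are
#' restricted to the always-observed design columns (sex and the early
#' environment indicators), so the induced missingness is MAR by
#' construction. Sex and the environment indicators themselves are never
#' masked.
#'
#' @param table A complete cohort table from [generate_cohort()].
#' @param params A [sim_params()]; `params$mar_params` gives per-column
#'   models as named coefficient vectors over `(intercept)` and the
#'   always-observed columns.
#' @param seed Integer seed.
#' @return The table with `NA`s injected.
#' @export
inject_missingness <- function(table, params, seed = params$seed) {
  protected <- c("id", "sex", "mother_short_education",
                 "parent_manual_class", "deprived")
  mar <- params$mar_params
  bad_target <- intersect(names(mar), protected)
  if (length(bad_target) > 0) {
    stop("inject_missingness: refusing to mask always-observed column(s): ",
         paste(bad_target, collapse = ", "), call. = FALSE)
  }
  allowed_pred <- c("(intercept)", "sex", "mother_short_education",
                    "parent_manual_class", "deprived")
  set.seed(child_seed(seed, "missingness"))
  n <- nrow(table)
  for (col in intersect(names(mar), names(table))) {
    cf <- mar[[col]]
    bad <- setdiff(names(cf), allowed_pred)
    if (length(bad) > 0) {
      stop("inject_missingness: MAR model for '", col,
           "' references maskable column(s) (would be MNAR): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    eta <- rep(ifelse("(intercept)" %in% names(cf), cf[["(intercept)"]], 0), n)
    for (pr in setdiff(names(cf), "(intercept)")) {
      eta <- eta + cf[[pr]] * table[[pr]]
    }
    miss <- stats::rbinom(n, 1L, stats::plogis(eta)) == 1L
    table[[col]][miss] <- NA
  }
  table
}
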