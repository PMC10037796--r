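#' Fit an outcome regression for g-computation
#'
#' Ordinary least squares for the conditional expectation Qbar of a
#' biomarker given sex, early-life deprivation and (optionally) the gender
#' score or the mediator set. Every model contains sex, deprivation and
#' their product; the score and the mediators enter as main effects only —
#' no sex-by-mediator products — so controlled direct effects do not depend
#' on where the mediators are fixed.
#'
#' @param table Complete (imputed) cohort table.
#' @param outcome Biomarker name from [biomarker_registry()] (its analysis
#'   column — log scale for the skewed markers — is modelled), or directly
#'   an analysis column name such as `"log_crp"`.
#' @param covariates `"none"` (spec S*E), `"score"` (S*E + G; requires a
#'   `gender_score` column), or `"mediators"` (S*E + Sigma over `varset`).
#' @param varset [variable_set()] naming the mediators when
#'   `covariates = "mediators"`.
#' @param scale `"original"` or `"z"`; on the z scale the outcome is
#'   standardized by this dataset's own mean and SD, which are stored.
#' @return An `outcome_model_qbar`: coefficients, covariate spec, scale and
#'   the training moments.
#' @export
#' @examples
#' coh <- transform_outcomes(generate_cohort(sim_params(), 1000, 1))
#' q <- fit_qbar(coh, "sbp")
#' q$coef
fit_qbar <- function(table, outcome,
                     covariates = c("none", "score", "mediators"),
                     varset = NULL, scale = c("original", "z")) {
  covariates <- match.arg(covariates)
  scale <- match.arg(scale)
  breg <- biomarker_registry()
  ycol <- if (outcome %in% breg$name) {
    breg$analysis_col[breg$name == outcome]
  } else {
    outcome
  }
  if (!ycol %in% names(table)) {
    stop("fit_qbar: outcome column '", ycol, "' not in table ",
         "(run transform_outcomes() first for log-scale markers)",
         call. = FALSE)
  }
  need <- c(ycol, "sex", "deprived")
  if (anyNA(table[, need])) {
    stop("fit_qbar: outcome, sex and deprived must be complete ",
         "(impute first)", call. = FALSE)
  }
  counts <- table(factor(table$sex, levels = 0:1),
                  factor(table$deprived, levels = 0:1))
  if (any(counts == 0)) {
    empty <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop("fit_qbar: empty (sex=", rownames(counts)[empty[1]], ", deprived=",
         colnames(counts)[empty[2]], ") cell; saturated sex-by-deprivation ",
         "model is rank deficient", call. = FALSE)
  }

  y <- table[[ycol]]
  mu <- mean(y)
  sigma <- stats::sd(y)
  if (scale == "z") {
    y <- standardize_outcome(y, mu, sigma)
  }

  extra <- switch(covariates,
    none = character(0),
    score = {
      if (!"gender_score" %in% names(table)) {
        stop("fit_qbar: covariates = 'score' needs a gender_score column ",
             "(see predict_gender_score())", call. = FALSE)
      }
      "gender_score"
    },
    mediators = {
      if (is.null(varset)) {
        stop("fit_qbar: covariates = 'mediators' needs a varset",
             call. = FALSE)
      }
      absent <- setdiff(varset$mediators, names(table))
      if (length(absent) > 0) {
        stop("fit_qbar: mediator column(s) not in table: ",
             paste(absent, collapse = ", "), call. = FALSE)
      }
      varset$mediators
    })

  dat <- table[, c("sex", "deprived", extra)]
  dat$.y <- y
  fit <- stats::lm(stats::reformulate(c("sex * deprived", extra),
                                      response = ".y"), data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("fit_qbar: rank-deficient design; aliased term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  structure(
    list(outcome = outcome, ycol = ycol, spec = covariates, scale = scale,
         coef = cf, mu = mu, sigma = sigma,
         mediators = if (covariates == "mediators") varset$mediators
                     else character(0),
         varset_name = if (!is.null(varset)) varset$name else NA_character_),
    class = "outcome_model_qbar")
}

#' @export
print.outcome_model_qbar <- function(x, ...) {
  cat("<outcome_model_qbar: ", x$ycol, " ~ sex * deprived",
      switch(x$spec, none = "", score = " + G",
             mediators = paste0(" + ", length(x$mediators), " mediators")),
      ", scale = ", x$scale, ">\n", sep = "")
  invisible(x)
}

#' Counterfactual scenario assignment
#'
#' Optional assignments for g-computation: sex `S`, deprivation `E`, gender
#' score `G`, and/or a full mediator reference profile `Sigma`. Columns not
#' assigned keep their observed (imputed) values. `G` and `Sigma` can never
#' both be assigned — they belong to different covariate specifications.
#'
#' @param S,E Optional 0/1 assignment.
#' @param G Optional score assignment in `[0, 1]`.
#' @param Sigma Optional named 0/1 vector (a [reference_profile()]).
#' @return A `scenario` list.
#' @export
scenario <- function(S = NULL, E = NULL, G = NULL, Sigma = NULL) {
  if (!is.null(G) && !is.null(Sigma)) {
    stop("scenario: G and Sigma cannot both be assigned", call. = FALSE)
  }
  for (v in list(S = S, E = E)) {
    if (!is.null(v) && !v %in% c(0, 1)) {
      stop("scenario: S and E assignments must be 0 or 1", call. = FALSE)
    }
  }
  if (!is.null(G) && (G < 0 || G > 1)) {
    stop("scenario: G must lie in [0, 1]", call. = FALSE)
  }
  structure(list(S = S, E = E, G = G, Sigma = Sigma), class = "scenario")
}

#' G-computation: mean predicted outcome under a scenario
#'
#' Predicts the outcome for every cohort member with the scenario
#' assignments substituted into the fitted Qbar model and averages over all
#' members — empirical standardization over the unassigned covariates.
#'
#' @param qbar An [fit_qbar()] model.
#' @param table The table to standardize over.
#' @param scen A [scenario()] (default: no assignment, returning the mean
#'   fitted value).
#' @return A single number on the model's scale.
#' @export
gcomp_mean <- function(qbar, table, scen = scenario()) {
  stopifnot(inherits(qbar, "outcome_model_qbar"))
  if (!inherits(scen, "scenario")) scen <- do.call(scenario, scen)
  if (!is.null(scen$G) && qbar$spec != "score") {
    stop("gcomp_mean: scenario assigns G but the model has no score term",
         call. = FALSE)
  }
  if (!is.null(scen$Sigma) && qbar$spec != "mediators") {
    stop("gcomp_mean: scenario assigns Sigma but the model has no mediator ",
         "terms", call. = FALSE)
  }
  n <- nrow(table)
  S <- if (is.null(scen$S)) table$sex else rep(scen$S, n)
  E <- if (is.null(scen$E)) table$deprived else rep(scen$E, n)
  cf <- qbar$coef
  pred <- cf[["(Intercept)"]] + cf[["sex"]] * S + cf[["deprived"]] * E +
    cf[["sex:deprived"]] * S * E
  if (qbar$spec == "score") {
    g <- if (is.null(scen$G)) table$gender_score else rep(scen$G, n)
    pred <- pred + cf[["gender_score"]] * g
  } else if (qbar$spec == "mediators") {
    for (m in qbar$mediators) {
      val <- if (is.null(scen$Sigma)) {
        table[[m]]
      } else {
        if (!m %in% names(scen$Sigma)) {
          stop("gcomp_mean: reference profile misses mediator '", m, "'",
               call. = FALSE)
        }
        rep(scen$Sigma[[m]], n)
      }
      pred <- pred + cf[[m]] * val
    }
  }
  mean(pred)
}

new_estimand_estimate <- function(estimand, outcome, scale, point,
                                  set = NA_character_,
                                  ci_low = NA_real_, ci_high = NA_real_,
                                  n_boot = NA_integer_, te = NA_real_,
                                  unstable = FALSE) {
  tibble::tibble(estimand = estimand, outcome = outcome, scale = scale,
                 set = set, point = point, ci_low = ci_low,
                 ci_high = ci_high, n_boot = n_boot, te = te,
                 unstable = unstable)
}

#' Total effect of being born male
#'
#' `TE = E[Y(S=1)] - E[Y(S=0)]` by g-computation under the saturated
#' sex-by-deprivation model.
#'
#' @param qbar A [fit_qbar()] model with `covariates = "none"`.
#' @param table Cohort table.
#' @return A one-row estimand tibble.
#' @export
total_effect <- function(qbar, table) {
  stopifnot(qbar$spec == "none")
  point <- gcomp_mean(qbar, table, scenario(S = 1)) -
    gcomp_mean(qbar, table, scenario(S = 0))
  new_estimand_estimate("TE", qbar$outcome, qbar$scale, point)
}

#' Controlled direct effect with the gender score fixed
#'
#' Sex contrast with every member's gender score set to `g0` (default 0.5,
#' the midpoint of the femininity-masculinity continuum). Because the model
#' carries no sex-by-score product, the choice of `g0` cancels in the
#' difference.
#'
#' @param qbar A [fit_qbar()] model with `covariates = "score"`.
#' @param table Cohort table.
#' @param g0 Score value in `[0, 1]`.
#' @return A one-row estimand tibble.
#' @export
controlled_direct_effect_score <- function(qbar, table, g0 = 0.5) {
  stopifnot(qbar$spec == "score")
  if (g0 < 0 || g0 > 1) {
    stop("controlled_direct_effect_score: g0 must lie in [0, 1]",
         call. = FALSE)
  }
  point <- gcomp_mean(qbar, table, scenario(S = 1, G = g0)) -
    gcomp_mean(qbar, table, scenario(S = 0, G = g0))
  new_estimand_estimate("CDE_G", qbar$outcome, qbar$scale, point,
                        set = qbar$varset_name)
}

#' Controlled direct effect with the mediator set fixed
#'
#' Sex contrast with all socio-behavioural mediators set to the reference
#' profile epsilon*. With mediator main effects only, the profile cancels
#' in the difference.
#'
#' @param qbar A [fit_qbar()] model with `covariates = "mediators"`.
#' @param table Cohort table.
#' @param ref Named 0/1 vector covering the model's mediators
#'   (a [reference_profile()]).
#' @return A one-row estimand tibble.
#' @export
controlled_direct_effect_mediators <- function(qbar, table, ref) {
  stopifnot(qbar$spec == "mediators")
  absent <- setdiff(qbar$mediators, names(ref))
  if (length(absent) > 0) {
    stop("controlled_direct_effect_mediators: reference profile misses: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  point <- gcomp_mean(qbar, table, scenario(S = 1, Sigma = ref)) -
    gcomp_mean(qbar, table, scenario(S = 0, Sigma = ref))
  new_estimand_estimate("CDE_Sigma", qbar$outcome, qbar$scale, point,
                        set = qbar$varset_name)
}

#' Total effect of sex within one early-environment stratum
#'
#' `TE^e = E[Y(S=1, E=e)] - E[Y(S=0, E=e)]`; with the saturated model this
#' equals the difference of the observed cell means.
#'
#' @param qbar A [fit_qbar()] model with `covariates = "none"`.
#' @param table Cohort table.
#' @param e Stratum (0 = advantaged-born, 1 = deprived-born).
#' @return A one-row estimand tibble (`TE0` or `TE1`).
#' @export
stratum_total_effect <- function(qbar, table, e) {
  stopifnot(qbar$spec == "none", e %in% c(0, 1))
  point <- gcomp_mean(qbar, table, scenario(S = 1, E = e)) -
    gcomp_mean(qbar, table, scenario(S = 0, E = e))
  new_estimand_estimate(paste0("TE", e), qbar$outcome, qbar$scale, point)
}

#' Effect of early-life deprivation within one sex
#'
#' `E[Y(S=s, E=1)] - E[Y(S=s, E=0)]`.
#'
#' @param qbar A [fit_qbar()] model with `covariates = "none"`.
#' @param table Cohort table.
#' @param s Sex stratum (1 = male-born).
#' @return A one-row estimand tibble.
#' @export
deprivation_effect_by_sex <- function(qbar, table, s) {
  stopifnot(qbar$spec == "none", s %in% c(0, 1))
  point <- gcomp_mean(qbar, table, scenario(S = s, E = 1)) -
    gcomp_mean(qbar, table, scenario(S = s, E = 0))
  new_estimand_estimate(paste0("DeprivationEffect", s), qbar$outcome,
                        qbar$scale, point)
}

#' Additive sex-by-deprivation interaction
#'
#' `IE = E[Y(1,1)] - E[Y(1,0)] - E[Y(0,1)] + E[Y(0,0)]`, the difference of
#' sex effects between deprived and advantaged strata (equivalently, of
#' deprivation effects between the sexes).
#'
#' @param qbar A [fit_qbar()] model with `covariates = "none"`.
#' @param table Cohort table.
#' @return A one-row estimand tibble.
#' @export
additive_interaction <- function(qbar, table) {
  stopifnot(qbar$spec == "none")
  point <- gcomp_mean(qbar, table, scenario(S = 1, E = 1)) -
    gcomp_mean(qbar, table, scenario(S = 1, E = 0)) -
    gcomp_mean(qbar, table, scenario(S = 0, E = 1)) +
    gcomp_mean(qbar, table, scenario(S = 0, E = 0))
  new_estimand_estimate("IE", qbar$outcome, qbar$scale, point)
}

#' Counterfactual cell mean
#'
#' `E[Y(S=s, E=e)]` by g-computation; equals the observed cell mean under
#' the saturated model.
#'
#' @param qbar A [fit_qbar()] model with `covariates = "none"`.
#' @param table Cohort table.
#' @param s,e Cell assignment.
#' @return A one-row estimand tibble.
#' @export
cell_mean <- function(qbar, table, s, e) {
  stopifnot(qbar$spec == "none", s %in% c(0, 1), e %in% c(0, 1))
  point <- gcomp_mean(qbar, table, scenario(S = s, E = e))
  new_estimand_estimate(paste0("CellMean", s, e), qbar$outcome, qbar$scale,
                        point)
}

#' Eliminated proportion of the total effect
#'
#' `EP = (TE - remaining) / TE`: the share of the sex difference that
#' disappears when the gendered pathway is blocked. Negative values mean
#' the gap widens. A total effect of exactly zero leaves EP undefined; the
#' result is then `NA` with attribute `undefined = TRUE` rather than an
#' error.
#'
#' @param te Total effect.
#' @param remaining Remaining effect (a CDE, or the stratum TE for the
#'   environment strategy).
#' @return Proportion (multiply by 100 for percent).
#' @export
#' @examples
#' eliminated_proportion(0.5, 0.6) # -0.2: the gap widens by 20%
eliminated_proportion <- function(te, remaining) {
  if (te == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  (te - remaining) / te
}

#' Compute the full estimand grid on one completed table
#'
#' Runs every estimand of the three analytic strategies on one complete
#' (imputed) table: total effects, stratum and deprivation effects, cell
#' means and additive interaction from the saturated sex-by-deprivation
#' model; score-based CDE/EP per variable set (the score model is refitted
#' on this table, so bootstrap replicates propagate score-estimation
#' uncertainty); mediator-set CDE/EP per variable set. This is the
#' estimator handed to [bootstrap_pipeline()].
#'
#' @param table Complete table (already through [transform_outcomes()]).
#' @param outcomes Biomarker names.
#' @param varsets List of [variable_set()]s for strategies (a) and (b).
#' @param strategies Subset of `c("a", "b", "c")`.
#' @param scales Subset of `c("original", "z")`.
#' @param g0 Score reference value.
#' @param ref_values Optional explicit reference profile values (named 0/1
#'   vector); default: modal category per mediator in this table.
#' @return Tidy tibble of estimand rows with a unique `key` column.
#' @export
compute_estimands <- function(table,
                              outcomes = biomarker_registry()$name,
                              varsets = list(variable_set("complete")),
                              strategies = c("a", "b", "c"),
                              scales = c("original", "z"),
                              g0 = 0.5, ref_values = NULL) {
  rows <- list()
  add <- function(x) rows[[length(rows) + 1]] <<- x

  score_cache <- list()
  for (vs in varsets) {
    if ("a" %in% strategies) {
      mod <- fit_gender_model(table, vs)
      score_cache[[vs$name]] <- predict_gender_score(mod, table)
    }
  }

  for (out in outcomes) {
    for (sc in scales) {
      q_se <- fit_qbar(table, out, "none", scale = sc)
      te_row <- total_effect(q_se, table)
      te <- te_row$point
      add(te_row)
      te0 <- stratum_total_effect(q_se, table, 0)
      te1 <- stratum_total_effect(q_se, table, 1)
      add(te0); add(te1)
      add(additive_interaction(q_se, table))
      add(deprivation_effect_by_sex(q_se, table, 0))
      add(deprivation_effect_by_sex(q_se, table, 1))
      for (s in 0:1) for (e in 0:1) add(cell_mean(q_se, table, s, e))
      if ("c" %in% strategies) {
        ep <- eliminated_proportion(te, te0$point)
        add(new_estimand_estimate("EP_E", out, sc, as.numeric(ep), te = te,
                                  unstable = isTRUE(attr(ep, "undefined"))))
      }
      for (vs in varsets) {
        if ("a" %in% strategies) {
          tab_g <- table
          tab_g$gender_score <- score_cache[[vs$name]]
          q_g <- fit_qbar(tab_g, out, "score", varset = vs, scale = sc)
          cde <- controlled_direct_effect_score(q_g, tab_g, g0)
          add(cde)
          ep <- eliminated_proportion(te, cde$point)
          add(new_estimand_estimate("EP_G", out, sc, as.numeric(ep),
                                    set = vs$name, te = te,
                                    unstable = isTRUE(attr(ep, "undefined"))))
        }
        if ("b" %in% strategies) {
          q_m <- fit_qbar(table, out, "mediators", varset = vs, scale = sc)
          ref <- if (is.null(ref_values)) {
            reference_profile(vs, table = table)
          } else {
            reference_profile(vs, values = ref_values)
          }
          cde <- controlled_direct_effect_mediators(q_m, table, ref)
          add(cde)
          ep <- eliminated_proportion(te, cde$point)
          add(new_estimand_estimate("EP_Sigma", out, sc, as.numeric(ep),
                                    set = vs$name, te = te,
                                    unstable = isTRUE(attr(ep, "undefined"))))
        }
      }
    }
  }
  res <- dplyr::bind_rows(rows)
  res$key <- paste(res$estimand, res$outcome, res$scale,
                   ifelse(is.na(res$set), "", res$set), sep = "|")
  res
}
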