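#' Fit a gender-diagnosis score model
#'
#' Models sex at birth by the socio-behavioural characteristics of a
#' variable set with a main-effects logistic regression ("gender
#' diagnosis"). The predicted probability of being male-born is the gender
#' score G, a continuum from 0 (predicted female) to 1 (predicted male).
#' Maximum likelihood is used whenever it is well behaved; on detected
#' separation or non-convergence the model is refitted with a small fixed
#' quadratic (ridge) penalty on the mediator coefficients and flagged.
#'
#' @param table Complete (imputed) cohort table with `sex` and all set
#'   mediators observed.
#' @param varset A [variable_set()].
#' @param penalty Ridge strength used only by the separation fallback.
#' @return A `gender_score_model`: list with `variable_set`, `intercept`,
#'   `coefficients`, `converged`, `separation`, `penalty`.
#' @export
#' @examples
#' coh <- generate_cohort(sim_params(), n = 2000, seed = 7)
#' m <- fit_gender_model(coh, variable_set("small"))
#' summary(predict_gender_score(m, coh))
fit_gender_model <- function(table, varset, penalty = 0.1) {
  stopifnot(inherits(varset, "variable_set"))
  meds <- varset$mediators
  absent <- setdiff(c("sex", meds), names(table))
  if (length(absent) > 0) {
    stop("fit_gender_model: missing column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  sub <- table[, c("sex", meds)]
  if (anyNA(sub)) {
    stop("fit_gender_model: sex and mediators must be complete ",
         "(run after imputation)", call. = FALSE)
  }
  if (sum(sub$sex == 1) < 2 || sum(sub$sex == 0) < 2) {
    stop("fit_gender_model: need at least 2 individuals of each sex",
         call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm(stats::reformulate(meds, response = "sex"),
               family = stats::binomial(), data = sub))
  mu <- stats::fitted(fit)
  separation <- !fit$converged || any(abs(stats::coef(fit)) > 15) ||
    any(mu > 1 - 1e-8) || any(mu < 1e-8)
  if (!separation) {
    cf <- stats::coef(fit)
    return(structure(
      list(variable_set = varset, intercept = unname(cf[1]),
           coefficients = cf[-1], converged = TRUE, separation = FALSE,
           penalty = 0),
      class = "gender_score_model"))
  }
  X <- cbind(1, as.matrix(sub[, meds]))
  cf <- ridge_logistic(X, sub$sex, lambda = penalty)
  structure(
    list(variable_set = varset, intercept = unname(cf[1]),
         coefficients = stats::setNames(cf[-1], meds), converged = TRUE,
         separation = TRUE, penalty = penalty),
    class = "gender_score_model")
}

# Newton-Raphson for the ridge-penalized logistic log-likelihood
#   l(b) - (lambda/2) * sum(b[-1]^2)   (intercept unpenalized)
ridge_logistic <- function(X, y, lambda, max_iter = 100, tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  b <- rep(0, p)
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(drop(X %*% b))
    grad <- drop(crossprod(X, y - mu)) - pen %*% b
    W <- mu * (1 - mu)
    H <- crossprod(X, X * W) + pen
    step <- solve(H, grad)
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  stats::setNames(drop(b), colnames(X))
}

#' @export
print.gender_score_model <- function(x, ...) {
  cat("<gender_score_model: set '", x$variable_set$name, "', ",
      length(x$coefficients), " mediators",
      if (x$separation) ", penalized (separation)" else "", ">\n", sep = "")
  invisible(x)
}

#' Predict gender scores
#'
#' Inverse-logit of the fitted linear predictor, one score per individual,
#' strictly inside (0, 1).
#'
#' @param model A `gender_score_model`.
#' @param table Table containing all model mediators.
#' @return Numeric vector of scores in (0, 1).
#' @export
predict_gender_score <- function(model, table) {
  stopifnot(inherits(model, "gender_score_model"))
  meds <- names(model$coefficients)
  absent <- setdiff(meds, names(table))
  if (length(absent) > 0) {
    stop("predict_gender_score: missing mediator column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  eta <- model$intercept +
    drop(as.matrix(table[, meds]) %*% model$coefficients)
  stats::plogis(eta)
}

#' Summarize gender scores by sex and early environment
#'
#' Mean score by sex with the male-female gap, in the total population and
#' within the deprived-born and advantaged-born strata (the layout of the
#' score block of the descriptive table).
#'
#' @param scores Numeric score vector.
#' @param S 0/1 sex vector (1 = male-born).
#' @param E 0/1 deprivation vector.
#' @return Tibble with columns `population`, `mean_male`, `mean_female`,
#'   `gap`.
#' @export
describe_scores_by_group <- function(scores, S, E) {
  if (length(scores) != length(S) || length(S) != length(E)) {
    stop("describe_scores_by_group: scores, S and E must have equal length",
         call. = FALSE)
  }
  one <- function(keep, label) {
    tibble::tibble(
      population = label,
      mean_male = mean(scores[keep & S == 1]),
      mean_female = mean(scores[keep & S == 0]),
      gap = mean(scores[keep & S == 1]) - mean(scores[keep & S == 0]))
  }
  dplyr::bind_rows(
    one(rep(TRUE, length(S)), "total"),
    one(E == 1, "deprived-born"),
    one(E == 0, "advantaged-born"))
}
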