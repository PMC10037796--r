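#' Generative parameters for the synthetic birth cohort
#'
#' Full specification of the data-generating process the synthetic cohort
#' follows: sex at birth S ~ Bernoulli(p_male); two correlated early-life
#' environment indicators (short maternal education, manual parental class)
#' with given marginals and odds ratio, whose conjunction defines early-life
#' deprivation E; each binary mediator drawn from a logistic model
#' logit P(M_j = 1) = alpha_j + beta_j S + gamma_j E (the "gender pressure"
#' paths S -> Sigma); each biomarker from a linear model
#' Y = a + b S + c E + d S:E + sum_j w_j M_j + Normal(0, sigma_y), generated
#' on the log scale for the right-skewed markers and then exponentiated.
#'
#' Defaults are calibrated to the magnitudes seen in mid-century British
#' birth-cohort data at ages 23-45: male prevalence 0.51, environment marginals
#' 0.75/0.73 with odds ratio 3 (deprivation prevalence about 0.6), mediator
#' sex gaps of 0.3-80 percentage points, biomarker sex effects of 0.1-0.75
#' SD and sex-by-deprivation interactions near -0.1 SD.
#'
#' @param n_default Default cohort size.
#' @param p_male Probability of being born male.
#' @param p_short_edu Marginal probability of short maternal education.
#' @param p_manual Marginal probability of manual parental social class.
#' @param edu_manual_odds_ratio Odds ratio linking the two indicators.
#' @param mediator_models Data frame with columns `name`, `alpha`, `beta`,
#'   `gamma` (logit scale). Defaults calibrated from the registry
#'   prevalences.
#' @param outcome_models Named list, one entry per biomarker, each a list
#'   with `a`, `b`, `c`, `d`, `w` (named vector over mediators), `sigma_y`.
#' @param mar_params Named list: maskable column -> named coefficient vector
#'   over `(intercept)` and always-observed columns.
#' @param seed Default master seed.
#' @return A validated object of class `sim_params`.
#' @export
#' @examples
#' p <- sim_params()
#' names(p$outcome_models)
sim_params <- function(n_default = 17000,
                       p_male = 0.51,
                       p_short_edu = 0.75,
                       p_manual = 0.73,
                       edu_manual_odds_ratio = 3,
                       mediator_models = default_mediator_models(),
                       outcome_models = default_outcome_models(),
                       mar_params = default_mar_params(),
                       seed = 58L) {
  p <- structure(
    list(n_default = n_default, p_male = p_male, p_short_edu = p_short_edu,
         p_manual = p_manual, edu_manual_odds_ratio = edu_manual_odds_ratio,
         mediator_models = mediator_models, outcome_models = outcome_models,
         mar_params = mar_params, seed = as.integer(seed)),
    class = "sim_params")
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  probs <- c(p_male = p$p_male, p_short_edu = p$p_short_edu,
             p_manual = p$p_manual)
  bad <- probs <= 0 | probs >= 1
  if (any(bad)) {
    stop("sim_params: probabilities must lie in (0,1): ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  }
  if (p$edu_manual_odds_ratio <= 0) {
    stop("sim_params: edu_manual_odds_ratio must be positive", call. = FALSE)
  }
  mm <- p$mediator_models
  stopifnot(all(c("name", "alpha", "beta", "gamma") %in% names(mm)))
  if (anyDuplicated(mm$name)) {
    stop("sim_params: duplicated mediator names", call. = FALSE)
  }
  for (nm in names(p$outcome_models)) {
    om <- p$outcome_models[[nm]]
    if (om$sigma_y <= 0) {
      stop("sim_params: sigma_y must be > 0 for outcome ", nm, call. = FALSE)
    }
    unknown <- setdiff(names(om$w), mm$name)
    if (length(unknown) > 0) {
      stop("sim_params: outcome ", nm, " references unknown mediator(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  invisible(p)
}

#' @rdname sim_params
#' @export
default_mediator_models <- function() {
  reg <- mediator_registry()
  pf <- reg$female_pct / 100
  pm <- reg$male_pct / 100
  # deprivation shifts (logit scale): social patterning of education, class,
  # diet, smoking, activity; zero where no plausible early-environment path
  gamma <- c(
    low_education_23 = 0.5, no_numeracy_problems_23 = -0.2,
    literacy_problems_23 = 0.3, does_not_read_23 = 0.3,
    drivers_license_33 = -0.3, savings_above_median_23 = -0.2,
    paid_work_23 = -0.1, manual_class_33 = 0.6,
    sees_friends_rarely_23 = 0.1, not_married_23 = -0.2, no_child_23 = -0.3,
    no_laundry_33 = 0, not_religious_23 = 0.1,
    smoking_23 = 0.3, smoking_33 = 0.3, alcohol_daily_23 = 0.1,
    alcohol_daily_33 = 0.1, fried_food_33 = 0.3, sport_23 = -0.2,
    no_sport_33 = 0.2, accident_23_33 = 0.2
  )
  tibble::tibble(
    name  = reg$name,
    alpha = stats::qlogis(pf),
    beta  = stats::qlogis(pm) - stats::qlogis(pf),
    gamma = unname(gamma[reg$name])
  )
}

#' @rdname sim_params
#' @export
default_outcome_models <- function() {
  list(
    sbp = list(
      a = 119.3, b = 12.4, c = 1.9, d = -0.3,
      w = c(sport_23 = -1.0, alcohol_daily_33 = 2.0, fried_food_33 = 1.5,
            smoking_33 = 0.5),
      sigma_y = 15),
    triglycerides = list( # generated on log(g/L)
      a = 0.25, b = 0.40, c = 0.12, d = -0.05,
      w = c(alcohol_daily_33 = 0.10, fried_food_33 = 0.08,
            no_sport_33 = 0.05, smoking_33 = 0.05),
      sigma_y = 0.55),
    ldl = list(
      a = 3.23, b = 0.33, c = 0.12, d = -0.07,
      w = c(fried_food_33 = 0.05, no_sport_33 = 0.03, smoking_33 = 0.02),
      sigma_y = 0.88),
    hba1c = list(
      a = 5.16, b = 0.11, c = 0.08, d = -0.01,
      w = c(fried_food_33 = 0.04, no_sport_33 = 0.02, smoking_33 = 0.03),
      sigma_y = 0.58),
    crp = list( # generated on log(mg/L)
      a = -0.06, b = -0.09, c = 0.31, d = -0.13,
      w = c(smoking_33 = 0.15, fried_food_33 = 0.10, no_sport_33 = 0.08),
      sigma_y = 1.25),
    cortisol = list( # generated on log(ug)
      a = 2.93, b = -0.045, c = 0.02, d = 0,
      w = c(smoking_33 = 0.02, sport_23 = -0.01),
      sigma_y = 0.5)
  )
}

#' @rdname sim_params
#' @export
default_mar_params <- function() {
  reg <- mediator_registry()
  # mediators ~10-12% missing, biomarkers ~25-35% (biomedical wave hardest
  # hit), slightly higher when deprived; predictors restricted to the
  # always-observed design columns
  med <- lapply(stats::setNames(reg$name, reg$name), function(nm) {
    c("(intercept)" = stats::qlogis(0.10), deprived = 0.2)
  })
  bio <- lapply(stats::setNames(biomarker_registry()$name,
                                biomarker_registry()$name), function(nm) {
    c("(intercept)" = stats::qlogis(0.25), deprived = 0.3, sex = 0.1)
  })
  c(med, bio)
}

# joint distribution of the two environment indicators with fixed marginals
# (p1, p2) and odds ratio `or`: returns P(edu=1, manual=1)
joint_p11 <- function(p1, p2, or) {
  if (abs(or - 1) < 1e-12) {
    return(p1 * p2)
  }
  # or = p11 p00 / (p10 p01) with p00 = 1 - p1 - p2 + p11, etc.
  a <- or - 1
  b <- -(1 + (p1 + p2) * (or - 1))
  cc <- or * p1 * p2
  disc <- b^2 - 4 * a * cc
  root <- (-b - sqrt(disc)) / (2 * a)
  if (root < max(0, p1 + p2 - 1) || root > min(p1, p2)) {
    root <- (-b + sqrt(disc)) / (2 * a)
  }
  root
}

# child seeds: one master seed, fixed per-stage offsets (documented contract:
# stage ids are stable across releases so runs are reproducible)
.stage_offsets <- c(environment = 1L, mediators = 2L, outcomes = 3L,
                    missingness = 4L, imputation = 5L, bootstrap = 6L,
                    truth = 7L, pipeline = 8L)

child_seed <- function(master, stage, index = 0L) {
  off <- .stage_offsets[[stage]]
  as.integer((as.numeric(master) * 48271 + off * 1000003 + index) %%
               2147483647)
}
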