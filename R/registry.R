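#' Socio-behavioural mediator registry
#'
#' The fixed registry of the 21 binary socio-behavioural characteristics
#' measured at ages 23 and 33, grouped into Bourdieu-style capital blocks
#' (cultural, economic, social) plus health behaviours. Each entry carries
#' reference prevalences (percent, by sex at birth) used to calibrate the
#' synthetic cohort generator; the displayed category is the one more
#' frequent among male-born members, so every male-female gap is positive.
#'
#' @return A tibble with columns `name`, `block`, `label`, `male_pct`,
#'   `female_pct`.
#' @export
#' @examples
#' mediator_registry()
mediator_registry <- function() {
  tibble::tribble(
    ~name,                     ~block,       ~label,                                  ~male_pct, ~female_pct,
    "low_education_23",        "cultural",   "Less than O level at 23",                    42.6,        35.9,
    "no_numeracy_problems_23", "cultural",   "No numeracy problems at 23",                 94.8,        94.5,
    "literacy_problems_23",    "cultural",   "Literacy problems at 23",                    12.6,         7.0,
    "does_not_read_23",        "cultural",   "Does not often read at 23",                  45.6,        32.6,
    "drivers_license_33",      "cultural",   "Driver's license at 33",                     92.5,        80.9,
    "savings_above_median_23", "economic",   "Personal savings > median at 23",            54.5,        45.7,
    "paid_work_23",            "economic",   "Paid work at 23",                            90.1,        68.5,
    "manual_class_33",         "economic",   "Manual social class at 33",                  50.8,        33.4,
    "sees_friends_rarely_23",  "social",     "Does not often see friends at 23",           35.6,        27.6,
    "not_married_23",          "social",     "Not married at 23",                          65.2,        45.7,
    "no_child_23",             "social",     "No child at 23",                             82.0,        66.6,
    "no_laundry_33",           "social",     "Does not do laundry at 33",                  86.0,         4.2,
    "not_religious_23",        "social",     "Not religious at 23",                        49.6,        32.5,
    "smoking_23",              "behaviours", "Smoking at 23",                              39.9,        38.3,
    "smoking_33",              "behaviours", "Smoking at 33",                              32.6,        32.0,
    "alcohol_daily_23",        "behaviours", "Alcohol every day at 23",                    31.4,         9.8,
    "alcohol_daily_33",        "behaviours", "Alcohol every day at 33",                    17.6,         7.0,
    "fried_food_33",           "behaviours", "Often eats fried food at 33",                56.6,        35.0,
    "sport_23",                "behaviours", "Often practices sport at 23",                59.3,        35.8,
    "no_sport_33",             "behaviours", "Does not practice sport at 33",              77.8,        77.4,
    "accident_23_33",          "behaviours", "Accident between 23 and 33",                 58.3,        24.8
  )
}

#' Biomarker registry
#'
#' The six biomarkers measured at 44-45 years, one per physiological system
#' of the allostatic-load framework. Right-skewed markers (triglycerides,
#' CRP, cortisol) are analysed on the natural-log scale; `analysis_col`
#' names the column the outcome models use.
#'
#' @return A tibble with columns `name`, `unit`, `system`, `log_transform`,
#'   `analysis_col`.
#' @export
biomarker_registry <- function() {
  out <- tibble::tribble(
    ~name,           ~unit,    ~system,          ~log_transform,
    "sbp",           "mmHg",   "cardiovascular", FALSE,
    "triglycerides", "g/L",    "metabolic",      TRUE,
    "ldl",           "mmol/L", "metabolic",      FALSE,
    "hba1c",         "%",      "metabolic",      FALSE,
    "crp",           "mg/L",   "inflammatory",   TRUE,
    "cortisol",      "ug",     "neuroendocrine", TRUE
  )
  out$analysis_col <- ifelse(out$log_transform, paste0("log_", out$name), out$name)
  out
}

#' Named variable sets for the mediator block
#'
#' @param name One of `"complete"` (all 21 registry mediators),
#'   `"behavioural"` (the 8 behaviour variables), `"small"` (4 social
#'   characteristics + 4 behaviours), or `"custom"`.
#' @param mediators For `name = "custom"`, a non-empty character vector of
#'   registry mediator names.
#' @return An object of class `variable_set`: a list with `name` and the
#'   ordered `mediators`.
#' @export
#' @examples
#' variable_set("small")
variable_set <- function(name = c("complete", "behavioural", "small", "custom"),
                         mediators = NULL) {
  name <- match.arg(name)
  reg <- mediator_registry()
  meds <- switch(name,
    complete    = reg$name,
    behavioural = reg$name[reg$block == "behaviours"],
    small       = c("low_education_23", "manual_class_33", "sees_friends_rarely_23",
                    "not_married_23", "no_sport_33", "fried_food_33",
                    "smoking_33", "alcohol_daily_33"),
    custom      = mediators
  )
  if (is.null(meds) || length(meds) == 0) {
    stop("variable_set: a variable set must contain at least one mediator",
         call. = FALSE)
  }
  unknown <- setdiff(meds, reg$name)
  if (length(unknown) > 0) {
    stop("variable_set: unknown mediator name(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, mediators = unname(meds)), class = "variable_set")
}

#' @export
print.variable_set <- function(x, ...) {
  cat("<variable_set '", x$name, "': ", length(x$mediators), " mediators>\n",
      sep = "")
  invisible(x)
}

#' Reference profile for mediator interventions
#'
#' Fixed mediator values used when the whole socio-behavioural set is set to
#' a common level in the controlled-direct-effect contrast. The default
#' profile assigns each mediator its modal category in the supplied data;
#' any published profile can be reproduced by passing explicit values.
#'
#' @param varset A [variable_set()].
#' @param table Optional cohort table used to compute modal categories.
#' @param values Optional named 0/1 vector overriding the modal rule.
#' @return Named numeric vector of 0/1 values covering exactly the set.
#' @export
reference_profile <- function(varset, table = NULL, values = NULL) {
  meds <- varset$mediators
  if (!is.null(values)) {
    missing_names <- setdiff(meds, names(values))
    if (length(missing_names) > 0) {
      stop("reference_profile: no value supplied for: ",
           paste(missing_names, collapse = ", "), call. = FALSE)
    }
    out <- values[meds]
    if (!all(out %in% c(0, 1))) {
      stop("reference_profile: values must be 0 or 1", call. = FALSE)
    }
    return(out)
  }
  if (is.null(table)) {
    stop("reference_profile: supply either `table` (modal rule) or `values`",
         call. = FALSE)
  }
  out <- vapply(meds, function(m) {
    x <- table[[m]]
    as.numeric(mean(x, na.rm = TRUE) >= 0.5)
  }, numeric(1))
  out
}
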