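# Reduced generative setups used across the suite: fewer mediators and
# outcomes keep each fit cheap while preserving every structural feature
# (sex-dependent mediators, deprivation effects, interaction, mediation).

small_params <- function(d_sbp = -0.3, w_on = TRUE) {
  reg_meds <- c("low_education_23", "manual_class_33", "not_married_23",
                "alcohol_daily_33", "fried_food_33", "smoking_33",
                "sport_23", "no_sport_33")
  mm <- default_mediator_models()
  mm <- mm[mm$name %in% reg_meds, ]
  sim_params(
    mediator_models = mm,
    outcome_models = list(
      sbp = list(a = 119.3, b = 12.4, c = 1.9, d = d_sbp,
                 w = if (w_on) c(sport_23 = -1, alcohol_daily_33 = 2,
                                 fried_food_33 = 1.5) else numeric(0),
                 sigma_y = 15),
      crp = list(a = -0.06, b = -0.09, c = 0.31, d = -0.13,
                 w = if (w_on) c(smoking_33 = 0.15, fried_food_33 = 0.1)
                     else numeric(0),
                 sigma_y = 1.25)),
    mar_params = list(
      low_education_23 = c("(intercept)" = qlogis(0.10), deprived = 0.2),
      fried_food_33 = c("(intercept)" = qlogis(0.10), deprived = 0.2),
      smoking_33 = c("(intercept)" = qlogis(0.10)),
      sbp = c("(intercept)" = qlogis(0.25), deprived = 0.3, sex = 0.1),
      crp = c("(intercept)" = qlogis(0.25), deprived = 0.3)))
}

small_varset <- function() {
  variable_set("custom", mediators = c("low_education_23", "manual_class_33",
                                       "not_married_23", "alcohol_daily_33",
                                       "fried_food_33", "smoking_33",
                                       "sport_23", "no_sport_33"))
}

# a table whose four sex-by-deprivation cells have exactly the given means
# (two members per cell, symmetric around the mean, so the cell mean is
# exact and every cell is non-empty)
cell_mean_table <- function(means, outcome = "y", spread = 0) {
  stopifnot(all(c("m_adv", "m_dep", "f_adv", "f_dep") %in% names(means)))
  grid <- expand.grid(sex = 0:1, deprived = 0:1)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$sex[i]; e <- grid$deprived[i]
    mu <- means[[paste0(ifelse(s == 1, "m_", "f_"),
                        ifelse(e == 1, "dep", "adv"))]]
    tibble::tibble(sex = s, deprived = e, y = mu + c(-spread, spread))
  })
  out <- dplyr::bind_rows(rows)
  names(out)[names(out) == "y"] <- outcome
  out$id <- seq_len(nrow(out))
  out
}
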