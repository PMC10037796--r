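test_that("saturated g-computation reproduces observed cell means exactly", {
  set.seed(3)
  n <- 200
  tab <- tibble::tibble(id = 1:n, sex = rbinom(n, 1, 0.5),
                        deprived = rbinom(n, 1, 0.5),
                        sbp = rnorm(n, 120, 10))
  q <- fit_qbar(tab, "sbp")
  for (s in 0:1) {
    for (e in 0:1) {
      obs <- mean(tab$sbp[tab$sex == s & tab$deprived == e])
      expect_equal(gcomp_mean(q, tab, scenario(S = s, E = e)), obs,
                   tolerance = 1e-10)
    }
  }
  # empty scenario: least-squares residuals average zero
  expect_equal(gcomp_mean(q, tab), mean(tab$sbp), tolerance = 1e-10)
  # z-scale fit is centred
  qz <- fit_qbar(tab, "sbp", scale = "z")
  expect_lt(abs(gcomp_mean(qz, tab)), 1e-10)

  one_cell <- tab[tab$sex == 1 | tab$deprived == 0, ]
  one_cell <- one_cell[!(one_cell$sex == 0 & one_cell$deprived == 0), ]
  expect_error(fit_qbar(one_cell, "sbp"), "empty")
})

test_that("g-computation agrees with a hand enumeration on a 12-row fixture", {
  tab <- tibble::tibble(
    id = 1:12,
    sex = c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
    deprived = c(0, 0, 1, 1, 0, 1, 0, 0, 1, 1, 0, 1),
    smoking_33 = c(1, 0, 1, 1, 0, 0, 1, 0, 0, 1, 1, 0),
    sbp = c(131, 128, 135, 140, 125, 133, 118, 121, 124, 126, 119, 122))
  vs <- variable_set("custom", "smoking_33")
  q <- fit_qbar(tab, "sbp", "mediators", varset = vs)
  cf <- q$coef
  # brute force: per-row prediction with S forced to 1
  pred <- cf[["(Intercept)"]] + cf[["sex"]] * 1 +
    cf[["deprived"]] * tab$deprived + cf[["sex:deprived"]] * tab$deprived +
    cf[["smoking_33"]] * tab$smoking_33
  expect_equal(gcomp_mean(q, tab, scenario(S = 1)), mean(pred),
               tolerance = 1e-12)
  expect_error(gcomp_mean(fit_qbar(tab, "sbp"), tab, scenario(G = 0.5)),
               "no score term")
})

test_that("total effect matches the truth and its stratum decomposition", {
  p <- small_params()
  tr <- compute_truth(p, include_cde_g = FALSE)
  n <- 50000
  coh <- transform_outcomes(generate_cohort(p, n, seed = 37))
  q <- fit_qbar(coh, "sbp")
  te <- total_effect(q, coh)$point
  truth <- tr$TE_true[tr$outcome == "sbp" & tr$scale == "native"]
  mc_se <- 2 * p$outcome_models$sbp$sigma_y / sqrt(n)
  expect_lt(abs(te - truth), 3 * mc_se)

  # decomposition identity of the saturated model
  te0 <- stratum_total_effect(q, coh, 0)$point
  te1 <- stratum_total_effect(q, coh, 1)$point
  pe <- mean(coh$deprived)
  expect_equal(te, (1 - pe) * te0 + pe * te1, tolerance = 1e-10)
  ie <- additive_interaction(q, coh)$point
  expect_equal(ie, te1 - te0, tolerance = 1e-10)
  dep1 <- deprivation_effect_by_sex(q, coh, 1)$point
  dep0 <- deprivation_effect_by_sex(q, coh, 0)$point
  expect_equal(ie, dep1 - dep0, tolerance = 1e-10)

  # outcome independent of sex: TE indistinguishable from zero
  p0 <- small_params(d_sbp = 0, w_on = FALSE)
  p0$outcome_models$sbp$b <- 0
  mm <- p0$mediator_models
  mm$beta <- 0
  p0$mediator_models <- mm
  coh0 <- generate_cohort(p0, 20000, seed = 41)
  te_null <- total_effect(fit_qbar(coh0, "sbp"), coh0)$point
  expect_lt(abs(te_null), 3 * 2 * 15 / sqrt(20000))
})

test_that("controlled direct effects are invariant to the fixing value", {
  p <- small_params()
  coh <- transform_outcomes(generate_cohort(p, 4000, seed = 43))
  vs <- small_varset()
  coh$gender_score <- predict_gender_score(fit_gender_model(coh, vs), coh)

  q_g <- fit_qbar(coh, "sbp", "score", varset = vs)
  cde_05 <- controlled_direct_effect_score(q_g, coh, 0.5)$point
  cde_09 <- controlled_direct_effect_score(q_g, coh, 0.9)$point
  expect_equal(cde_05, cde_09, tolerance = 1e-10)
  expect_error(controlled_direct_effect_score(q_g, coh, 1.5), "g0")

  q_m <- fit_qbar(coh, "sbp", "mediators", varset = vs)
  ref0 <- setNames(rep(0, length(vs$mediators)), vs$mediators)
  ref_modal <- reference_profile(vs, table = coh)
  cde_0 <- controlled_direct_effect_mediators(q_m, coh, ref0)$point
  cde_modal <- controlled_direct_effect_mediators(q_m, coh, ref_modal)$point
  expect_equal(cde_0, cde_modal, tolerance = 1e-10)
  expect_error(controlled_direct_effect_mediators(q_m, coh, ref0[-1]),
               "misses")
})

test_that("mediator-set CDE recovers its generative value", {
  p <- small_params()
  tr <- compute_truth(p, include_cde_g = FALSE)
  n <- 50000
  coh <- transform_outcomes(generate_cohort(p, n, seed = 47))
  vs <- small_varset()
  q_m <- fit_qbar(coh, "sbp", "mediators", varset = vs)
  ref <- reference_profile(vs, table = coh)
  cde <- controlled_direct_effect_mediators(q_m, coh, ref)$point
  truth <- tr$CDE_Sigma_true[tr$outcome == "sbp" & tr$scale == "native"]
  expect_lt(abs(cde - truth), 3 * 2 * p$outcome_models$sbp$sigma_y / sqrt(n))

  # inert mediators: CDE equals TE
  p_inert <- small_params(w_on = FALSE)
  coh_i <- transform_outcomes(generate_cohort(p_inert, 20000, seed = 53))
  q_se <- fit_qbar(coh_i, "sbp")
  q_mi <- fit_qbar(coh_i, "sbp", "mediators", varset = vs)
  te_i <- total_effect(q_se, coh_i)$point
  cde_i <- controlled_direct_effect_mediators(
    q_mi, coh_i, reference_profile(vs, table = coh_i))$point
  expect_lt(abs(cde_i - te_i), 0.5) # both estimate b: w = 0 generatively

  # d = 0: CDE_Sigma estimates b itself
  p_d0 <- small_params(d_sbp = 0)
  coh_d0 <- transform_outcomes(generate_cohort(p_d0, 50000, seed = 59))
  q_d0 <- fit_qbar(coh_d0, "sbp", "mediators", varset = vs)
  cde_d0 <- controlled_direct_effect_mediators(
    q_d0, coh_d0, reference_profile(vs, table = coh_d0))$point
  expect_lt(abs(cde_d0 - p_d0$outcome_models$sbp$b),
            3 * 2 * 15 / sqrt(50000))
})

test_that("score-inert outcomes give CDE_G equal to TE", {
  # G coefficient 0 happens when the outcome ignores the mediators
  p <- small_params(w_on = FALSE)
  coh <- transform_outcomes(generate_cohort(p, 8000, seed = 61))
  vs <- small_varset()
  coh$gender_score <- predict_gender_score(fit_gender_model(coh, vs), coh)
  q_se <- fit_qbar(coh, "sbp")
  q_g <- fit_qbar(coh, "sbp", "score", varset = vs)
  te <- total_effect(q_se, coh)$point
  cde <- controlled_direct_effect_score(q_g, coh)$point
  # estimated G coefficient is noise around 0; contrast stays close to TE
  expect_lt(abs(cde - te), 1.5)

  # exact version: force the score coefficient to zero
  q_zero <- q_g
  q_zero$coef[["gender_score"]] <- 0
  q_zero$coef[["sex"]] <- q_se$coef[["sex"]]
  q_zero$coef[["sex:deprived"]] <- q_se$coef[["sex:deprived"]]
  expect_equal(controlled_direct_effect_score(q_zero, coh)$point, te,
               tolerance = 1e-10)
})

test_that("eliminated proportion follows the sign conventions", {
  expect_equal(eliminated_proportion(0.5, 0.5), 0)
  expect_equal(eliminated_proportion(0.5, 0), 1)
  # remaining effect larger than the total: the gap widens (negative EP)
  expect_equal(eliminated_proportion(0.5, 0.6), -0.2, tolerance = 1e-12)
  ep0 <- eliminated_proportion(0, 0.3)
  expect_true(is.na(ep0))
  expect_true(attr(ep0, "undefined"))
})

test_that("printed interaction-table blocks are internally consistent", {
  # z-scored log-triglycerides cell means: stratum sex effect
  trig <- cell_mean_table(c(m_adv = 0.27, m_dep = 0.39,
                            f_adv = -0.48, f_dep = -0.28),
                          outcome = "y")
  q <- fit_qbar(trig, "y")
  expect_equal(stratum_total_effect(q, trig, 0)$point, 0.75,
               tolerance = 1e-10)
  expect_equal(additive_interaction(q, trig)$point, -0.08,
               tolerance = 1e-10)

  # z-scored log-CRP cell means
  crp <- cell_mean_table(c(m_adv = -0.14, m_dep = 0.00,
                           f_adv = -0.10, f_dep = 0.15))
  qc <- fit_qbar(crp, "y")
  expect_equal(stratum_total_effect(qc, crp, 1)$point, -0.15,
               tolerance = 1e-10)
  expect_equal(additive_interaction(qc, crp)$point, -0.11,
               tolerance = 1e-10)
  expect_equal(deprivation_effect_by_sex(qc, crp, 0)$point, 0.25,
               tolerance = 1e-10)

  # SBP original-scale male cells: deprivation effect
  sbp <- cell_mean_table(c(m_adv = 132.0, m_dep = 133.6,
                           f_adv = 119.3, f_dep = 121.3))
  qs <- fit_qbar(sbp, "y")
  expect_equal(deprivation_effect_by_sex(qs, sbp, 1)$point, 1.6,
               tolerance = 1e-10)
  # identical cell means: every contrast vanishes
  flat <- cell_mean_table(c(m_adv = 1, m_dep = 1, f_adv = 1, f_dep = 1),
                          spread = 0.5)
  qf <- fit_qbar(flat, "y")
  expect_equal(stratum_total_effect(qf, flat, 0)$point, 0,
               tolerance = 1e-10)
  expect_equal(additive_interaction(qf, flat)$point, 0, tolerance = 1e-10)
})

test_that("the full estimand grid is keyed, complete and scale coherent", {
  p <- small_params()
  coh <- transform_outcomes(generate_cohort(p, 3000, seed = 67))
  est <- compute_estimands(coh, outcomes = c("sbp", "crp"),
                           varsets = list(small_varset()))
  expect_false(any(duplicated(est$key)))
  for (out in c("sbp", "crp")) {
    for (sc in c("original", "z")) {
      keys <- est$key[est$outcome == out & est$scale == sc]
      expect_true(all(c("TE", "TE0", "TE1", "IE", "EP_E", "CDE_G", "EP_G",
                        "CDE_Sigma", "EP_Sigma") %in%
                        est$estimand[est$outcome == out &
                                       est$scale == sc]))
    }
  }
  # EPs are ratios, identical across scales
  ep_o <- est$point[est$estimand == "EP_Sigma" & est$outcome == "sbp" &
                      est$scale == "original"]
  ep_z <- est$point[est$estimand == "EP_Sigma" & est$outcome == "sbp" &
                      est$scale == "z"]
  expect_equal(ep_o, ep_z, tolerance = 1e-10)
})
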