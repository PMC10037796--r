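test_that("generation is deterministic and the empty cohort keeps the schema", {
  p <- small_params()
  a <- generate_cohort(p, 300, seed = 11)
  b <- generate_cohort(p, 300, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(p, 300, seed = 12)))

  empty <- generate_cohort(p, 0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("id", "sex", "mother_short_education",
                    "parent_manual_class", "deprived",
                    p$mediator_models$name, "sbp", "crp") %in% names(empty)))

  expect_error(generate_cohort(p, -1), "non-negative")
  expect_error(sim_params(p_male = 1.2), "probabilities")
})

test_that("empirical prevalences match the generative model within 3 binomial SEs", {
  p <- sim_params()
  n <- 100000
  coh <- generate_cohort(p, n, seed = 21)
  se <- function(pr) sqrt(pr * (1 - pr) / n)
  expect_lt(abs(mean(coh$sex) - p$p_male), 3 * se(p$p_male))
  expect_lt(abs(mean(coh$mother_short_education) - p$p_short_edu),
            3 * se(p$p_short_edu))
  expect_lt(abs(mean(coh$parent_manual_class) - p$p_manual),
            3 * se(p$p_manual))

  # mediator prevalences, conditioning on the realized (S, E) mix
  mm <- p$mediator_models
  for (j in seq_len(nrow(mm))) {
    pr <- mean(plogis(mm$alpha[j] + mm$beta[j] * coh$sex +
                        mm$gamma[j] * coh$deprived))
    expect_lt(abs(mean(coh[[mm$name[j]]]) - pr), 3 * se(pr))
  }
})

test_that("deprivation is exactly the conjunction and all cells are populated", {
  coh <- generate_cohort(sim_params(), 5000, seed = 31)
  expect_identical(coh$deprived,
                   coh$mother_short_education * coh$parent_manual_class)
  expect_true(all(table(coh$sex, coh$deprived) > 0))
  # odds ratio between the two indicators close to its target
  tab <- table(coh$mother_short_education, coh$parent_manual_class)
  or_hat <- tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])
  expect_gt(or_hat, 2)
  expect_lt(or_hat, 4.5)
})

test_that("closed-form truths satisfy their identities and degenerate cases", {
  p <- small_params()
  tr <- compute_truth(p, include_cde_g = FALSE)
  for (sc in c("native", "z")) {
    t1 <- tr[tr$scale == sc, ]
    expect_equal(t1$IE_true, t1$TE1_true - t1$TE0_true, tolerance = 1e-12)
    expect_equal(t1$EP_Sigma_true,
                 (t1$TE_true - t1$CDE_Sigma_true) / t1$TE_true,
                 tolerance = 1e-12)
    expect_equal(t1$EP_E_true, (t1$TE_true - t1$TE0_true) / t1$TE_true,
                 tolerance = 1e-12)
  }
  # EPs are scale invariant
  expect_equal(tr$EP_Sigma_true[tr$scale == "native"],
               tr$EP_Sigma_true[tr$scale == "z"], tolerance = 1e-12)

  # no interaction, no mediation: TE = b, EP_Sigma = 0
  p0 <- small_params(d_sbp = 0, w_on = FALSE)
  p0$outcome_models$crp$d <- 0
  p0$outcome_models$crp$w <- numeric(0)
  t0 <- compute_truth(p0, include_cde_g = FALSE)
  t0n <- t0[t0$scale == "native", ]
  expect_equal(t0n$TE_true[t0n$outcome == "sbp"], 12.4, tolerance = 1e-12)
  expect_equal(t0n$EP_Sigma_true, c(0, 0), tolerance = 1e-12)

  # pure interaction: b = 0, w = 0, d != 0 -> IE = d, TE0 = 0
  p1 <- small_params(d_sbp = -2, w_on = FALSE)
  p1$outcome_models$sbp$b <- 0
  t1 <- compute_truth(p1, include_cde_g = FALSE)
  row <- t1[t1$scale == "native" & t1$outcome == "sbp", ]
  expect_equal(row$IE_true, -2, tolerance = 1e-12)
  expect_equal(row$TE0_true, 0, tolerance = 1e-12)
})

test_that("closed-form TE matches a brute-force potential-outcome simulation", {
  p <- small_params()
  tr <- compute_truth(p, include_cde_g = FALSE)
  n <- 4e5
  # potential outcomes: same individuals under S=1 and S=0, exposure
  # assignment overridden before mediators and outcomes are drawn
  sim_mean <- function(s_val, seed) {
    coh <- generate_cohort(p, n, seed = seed)
    mm <- p$mediator_models
    set.seed(seed + 1)
    om <- p$outcome_models$sbp
    meds <- lapply(seq_len(nrow(mm)), function(j) {
      rbinom(n, 1, plogis(mm$alpha[j] + mm$beta[j] * s_val +
                            mm$gamma[j] * coh$deprived))
    })
    names(meds) <- mm$name
    y <- om$a + om$b * s_val + om$c * coh$deprived +
      om$d * s_val * coh$deprived
    for (w_nm in names(om$w)) y <- y + om$w[[w_nm]] * meds[[w_nm]]
    mean(y + rnorm(n, 0, om$sigma_y))
  }
  te_mc <- sim_mean(1, 41) - sim_mean(0, 43)
  mc_se <- sqrt(2) * p$outcome_models$sbp$sigma_y / sqrt(n) * 1.2
  expect_lt(abs(te_mc - tr$TE_true[tr$scale == "native" &
                                     tr$outcome == "sbp"]),
            3 * mc_se)
})

test_that("score-based CDE oracle is finite, reproducible and near CDE_Sigma", {
  p <- small_params()
  tr <- compute_truth(p, mc_n = 1e5, mc_seed = 7)
  tr2 <- compute_truth(p, mc_n = 1e5, mc_seed = 7)
  expect_identical(tr$CDE_G_true, tr2$CDE_G_true)
  nat <- tr[tr$scale == "native", ]
  expect_true(all(is.finite(nat$CDE_G_true)))
  expect_true(all(nat$CDE_G_mc_se > 0))
  # the fitted score compresses the mediators; the score-based CDE stays in
  # the neighbourhood of the mediator-set CDE (same pathway being blocked)
  expect_lt(abs(nat$CDE_G_true[nat$outcome == "sbp"] -
                  nat$CDE_Sigma_true[nat$outcome == "sbp"]), 1.5)
  expect_error(compute_truth(p, mc_n = 1e4), "1e5")
})

test_that("MAR masking hits the modelled rates and never touches sex or environment", {
  p <- small_params()
  coh <- generate_cohort(p, 50000, seed = 51)
  masked <- inject_missingness(coh, p, seed = 52)
  expect_identical(masked, inject_missingness(coh, p, seed = 52))

  for (col in c("sex", "mother_short_education", "parent_manual_class",
                "deprived")) {
    expect_false(anyNA(masked[[col]]))
  }
  n <- nrow(coh)
  for (col in names(p$mar_params)) {
    cf <- p$mar_params[[col]]
    eta <- rep(cf[["(intercept)"]], n)
    for (pr in setdiff(names(cf), "(intercept)")) {
      eta <- eta + cf[[pr]] * coh[[pr]]
    }
    rate <- mean(plogis(eta))
    expect_lt(abs(mean(is.na(masked[[col]])) - rate),
              3 * sqrt(rate * (1 - rate) / n))
  }

  # -Inf intercepts: nothing is masked
  p0 <- p
  p0$mar_params <- lapply(p$mar_params, function(cf) {
    cf[["(intercept)"]] <- -Inf
    cf
  })
  expect_identical(inject_missingness(coh, p0, seed = 53), coh)

  # a MAR model referencing a maskable column would be MNAR
  p_bad <- p
  p_bad$mar_params$sbp <- c("(intercept)" = -1, crp = 0.5)
  expect_error(inject_missingness(coh, p_bad, seed = 54), "MNAR")
  p_bad2 <- p
  p_bad2$mar_params$sex <- c("(intercept)" = -1)
  expect_error(inject_missingness(coh, p_bad2, seed = 55),
               "always-observed")
})
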