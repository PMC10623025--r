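test_that("balanced one-way layout: LS means are cell means and F is the ANOVA F", {
  set.seed(11)
  n_per <- 30
  rec <- null_records(4 * n_per)
  rec$season_birth <- factor(rep(c("summer", "rainy", "autumn", "winter"),
                                 each = n_per),
                             levels = levels(rec$season_birth))
  rec$period_birth <- factor(1)
  rec$sire_code <- 1L # single sire: term dropped
  rec$afc <- rnorm(4 * n_per) + rep(c(0, 1, 2, 3), each = n_per)
  fit <- fit_fixed_model(model_spec("afc"), rec)
  cell <- tapply(rec$afc, rec$season_birth, mean)
  lsm <- fit$lsmeans$season
  expect_equal(lsm$lsmean[match(names(cell), lsm$level)], as.vector(cell))
  a1 <- anova(lm(afc ~ season_birth, data = rec))
  expect_equal(fit$anova$F[fit$anova$term == "season"],
               a1$`F value`[1])
  expect_equal(fit$anova$code[fit$anova$term == "season"], "***")
})

test_that("LS means are invariant to which level carries the constraint", {
  set.seed(4)
  rec <- null_records(120)
  rec$afc <- rnorm(120) + as.integer(rec$period_birth)
  fit1 <- fit_fixed_model(model_spec("afc"), rec)
  rec2 <- rec
  rec2$period_birth <- factor(rec2$period_birth,
                              levels = rev(levels(rec2$period_birth)))
  fit2 <- fit_fixed_model(model_spec("afc"), rec2)
  m1 <- fit1$lsmeans$period
  m2 <- fit2$lsmeans$period
  expect_equal(m1$lsmean[match(m2$level, m1$level)], m2$lsmean)
  expect_equal(sort(fit1$anova$F), sort(fit2$anova$F))
})

test_that("covariate slope confidence interval covers the truth", {
  set.seed(21)
  hits <- 0
  for (i in 1:50) {
    rec <- null_records(100)
    rec$afc <- rnorm(100, 1200, 100)
    rec$fsp <- 2 * rec$afc + rnorm(100, 0, 50)
    fit <- fit_fixed_model(model_spec("fsp"), rec, lsmeans = FALSE)
    ci <- confint(fit$fit, "afc")
    if (ci[1] <= 2 && 2 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 44) # nominal 95% coverage over 50 replicates
})

test_that("Method III equals the balanced half-sib ANOVA identity", {
  set.seed(31)
  s <- 12; n <- 8
  rec <- half_sib_records(s, n, sigma2_s = 2, sigma2_e = 5)
  comp <- henderson3_components(model_spec("afc"), rec)
  a <- anova(lm(afc ~ factor(sire_code), data = rec))
  ms_sire <- a$`Mean Sq`[1]
  ms_within <- a$`Mean Sq`[2]
  expect_equal(comp$sigma2_s_raw, (ms_sire - ms_within) / n,
               tolerance = 1e-10)
  expect_equal(comp$sigma2_e, ms_within, tolerance = 1e-10)
  expect_equal(comp$k, n) # balanced effective progeny-group size
})

test_that("a duplicated trait yields cov_s = sigma2_s and cov_e = sigma2_e", {
  set.seed(32)
  rec <- half_sib_records(10, 6, sigma2_s = 1, sigma2_e = 3)
  rec$fsp <- rec$afc
  rec$afc2 <- rec$afc
  # use the AFC template for both so no covariate is involved
  comp <- henderson3_components(model_spec("afc"), rec, trait2 = "afc2")
  expect_equal(comp$cov_s, comp$sigma2_s_raw, tolerance = 1e-10)
  expect_equal(comp$cov_e, comp$sigma2_e, tolerance = 1e-10)
})

test_that("Method III recovers variance components on unbalanced designs", {
  set.seed(33)
  reps <- 60
  est_s <- est_e <- numeric(reps)
  for (r in seq_len(reps)) {
    sizes <- sample(3:15, 30, replace = TRUE)
    sire <- rep(seq_along(sizes), sizes)
    n <- length(sire)
    u <- rnorm(30, 0, 1)
    rec <- data.frame(
      afc = 5 + u[sire] + rnorm(n, 0, sqrt(3)),
      sire_code = sire, animal_code = seq_len(n),
      period_birth = factor(1), season_birth = factor("winter"))
    comp <- henderson3_components(model_spec("afc"), rec)
    est_s[r] <- comp$sigma2_s_raw
    est_e[r] <- comp$sigma2_e
  }
  expect_lt(abs(mean(est_s) - 1), 0.1)
  expect_lt(abs(mean(est_e) - 3), 0.3)
})

test_that("half-sib heritability arithmetic and truncation behave", {
  est <- phs_heritability(1, 3, k = 20, s = 50, N = 1000)
  expect_equal(est$h2, 1)
  expect_equal(est$t, 0.25)
  est0 <- phs_heritability(0, 3, k = 20, s = 50, N = 1000)
  expect_equal(est0$h2, 0)
  expect_gt(est$se_h2, 0)
  expect_error(phs_heritability(0, 0, 20, 50, 1000), "positive")
})

test_that("sire-component correlations handle trivial and constructed cases", {
  set.seed(35)
  rec <- half_sib_records(15, 8, sigma2_s = 1.5, sigma2_e = 2)
  rec$afc2 <- rec$afc
  specs <- list(afc = model_spec("afc"), afc2 = model_spec("afc"))
  specs$afc2$trait <- "afc2"
  out <- phs_correlations(specs, rec)
  expect_equal(out$r_g["afc", "afc2"], 1, tolerance = 1e-8)
  expect_equal(out$r_p["afc", "afc2"], 1, tolerance = 1e-8)

  # independent traits: average |r_g| small over replicates
  set.seed(36)
  vals <- replicate(30, {
    rec <- half_sib_records(80, 10, sigma2_s = 1, sigma2_e = 2)
    rec$tr2 <- half_sib_records(80, 10, sigma2_s = 1, sigma2_e = 2)$afc
    comp <- henderson3_components(model_spec("afc"), rec, trait2 = "tr2")
    if (comp$sigma2_s_raw > 0 && comp$sigma2_s2_raw > 0)
      comp$cov_s / sqrt(comp$sigma2_s_raw * comp$sigma2_s2_raw)
    else NA_real_
  })
  expect_lt(mean(abs(vals), na.rm = TRUE), 0.15)
})
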