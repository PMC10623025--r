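test_that("pedigree simulation produces the configured family structure", {
  p1 <- sim_params(traits = "afc", n_sires = 1, n_dams = 1, seed = 1)
  ped <- simulate_pedigree(p1)
  expect_equal(nrow(ped), 3)

  p8 <- sim_params(traits = "afc", n_sires = 8, n_dams = 120, seed = 2)
  ped8 <- simulate_pedigree(p8)
  off <- ped8[!is.na(ped8$sire), ]
  expect_equal(nrow(off), 120)
  expect_equal(length(unique(off$sire)), 8)
  expect_true(all(table(off$sire) > 3)) # Spearman-comparison scenario

  expect_identical(simulate_pedigree(p8), simulate_pedigree(p8))
  p_alt <- sim_params(traits = "afc", n_sires = 8, n_dams = 120, seed = 3)
  expect_false(identical(simulate_pedigree(p8), simulate_pedigree(p_alt)))
})

test_that("founder breeding values reproduce the true genetic covariance", {
  G0 <- matrix(c(100, 60, 60, 100), 2)
  R0 <- diag(c(100, 100))
  p <- sim_params(traits = c("afc", "fsp"), n_sires = 5000, n_dams = 5000,
                  progeny_per_mating = 1, G0 = G0, R0 = R0, seed = 4)
  ped <- simulate_pedigree(p)
  herd <- simulate_phenotypes(ped, p)
  founders <- herd$pedigree$code[herd$pedigree$sire_code == 0]
  emp <- cov(herd$true_bv[founders, ])
  expect_equal(emp, G0, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("offspring on mid-parent regression recovers the implied heritability", {
  G0 <- matrix(50); R0 <- matrix(50) # h2 = 0.5
  p <- sim_params(traits = "afc", n_sires = 2000, n_dams = 2000,
                  progeny_per_mating = 2, G0 = G0, R0 = R0, seed = 5,
                  season_effect = 0, period_trend = 0)
  herd <- simulate_herd(p)
  ph <- herd$phenotypes
  rp <- herd$pedigree
  off <- ph[ph$animal_code %in% rp$code[rp$sire_code > 0], ]
  sire_bv <- herd$true_bv[rp$sire_code[match(off$animal_code, rp$code)], 1]
  dam_ph <- ph$afc[match(rp$dam_code[match(off$animal_code, rp$code)],
                         ph$animal_code)]
  # offspring phenotype on dam phenotype: slope = h2 / 2
  b <- coef(lm(off$afc ~ dam_ph))[2]
  expect_equal(unname(b), 0.25, tolerance = 0.1 * 0.5 / 0.25)
  # offspring BV = mid-parent BV + Mendelian noise with variance G0/2
  off_bv <- herd$true_bv[off$animal_code, 1]
  dam_bv <- herd$true_bv[rp$dam_code[match(off$animal_code, rp$code)], 1]
  ms <- off_bv - (sire_bv + dam_bv) / 2
  expect_equal(var(ms), 25, tolerance = 0.08)
})

test_that("near-zero residual variance separates families by sire merit", {
  # family means still carry dam-BV averages, so the separation shows as a
  # near-perfect rank correlation with sire merit rather than exact order
  G0 <- matrix(100); R0 <- matrix(1e-4)
  p <- sim_params(traits = "afc", n_sires = 20, n_dams = 400, G0 = G0,
                  R0 = R0, seed = 6, season_effect = 0, period_trend = 0)
  herd <- simulate_herd(p)
  ph <- herd$phenotypes
  off <- ph[!is.na(ph$sire_code), ]
  fam <- tapply(off$afc, off$sire_code, mean)
  sire_bv <- herd$true_bv[as.integer(names(fam)), 1]
  expect_gt(cor(as.vector(fam), sire_bv, method = "spearman"), 0.8)
})

test_that("descriptive statistics match their definitions", {
  x1 <- two_point_sample(1227.73, 179.45)
  x2 <- two_point_sample(148.37, 94.21)
  rec <- data.frame(afc = c(x1, NA), fsp = c(x2, NA), pl = c(5, 5, 5))
  st <- descriptive_statistics(rec, traits = c("afc", "fsp", "pl"))
  expect_equal(round(st$cv[st$trait == "afc"], 2), 14.62)
  expect_equal(round(st$cv[st$trait == "fsp"], 2), 63.50)
  expect_equal(st$n[st$trait == "afc"], 2)
  expect_equal(st$cv[st$trait == "pl"], 0)
  expect_equal(st$sd[st$trait == "pl"], 0)
  expect_equal(st$se, st$sd / sqrt(st$n))
})

test_that("the default herd emulates the field scale", {
  herd <- simulate_herd(sim_params(seed = 9))
  expect_equal(nrow(herd$phenotypes), 964)
  st <- descriptive_statistics(herd$phenotypes)
  sc <- default_trait_scales()
  m <- st$mean[match(sc$trait, st$trait)]
  # with 8 sires the herd mean carries sire-sampling noise of a fraction
  # of a phenotypic SD, so compare on the SD scale
  expect_true(all(abs(m - sc$mean) / sc$sd < 0.3))
  s <- st$sd[match(sc$trait, st$trait)]
  expect_true(all(s / sc$sd > 0.8 & s / sc$sd < 1.25))
  # implied heritabilities of the default architecture are in (0, 1)
  p <- sim_params()
  h2 <- diag(p$G0) / (diag(p$G0) + diag(p$R0))
  expect_true(all(h2 > 0 & h2 < 1))
})

test_that("phenotypes round-trip through the CSV writers", {
  herd <- simulate_herd(sim_params(traits = c("afc", "pl"), n_sires = 4,
                                   n_dams = 20, seed = 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(herd$phenotypes, path)
  back <- read_phenotypes(path)
  expect_equal(back$afc, herd$phenotypes$afc, tolerance = 1e-12)
  expect_equal(back$animal_code, herd$phenotypes$animal_code)
  expect_equal(as.character(back$season_calving),
               as.character(herd$phenotypes$season_calving))
})
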