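test_that("HPD interval is the shortest window over order statistics", {
  expect_equal(unname(hpd_interval(1:100, 0.95)), c(1, 95))
  # skewed sample: shorter than the equal-tailed interval, equals brute force
  set.seed(41)
  x <- rexp(500)
  hpd <- hpd_interval(x, 0.95)
  eq_tail <- quantile(x, c(0.025, 0.975))
  expect_lt(diff(hpd), diff(unname(eq_tail)))
  expect_equal(unname(hpd), brute_hpd(x, 0.95))
  # empirical coverage of the returned interval
  u <- runif(1000)
  h <- hpd_interval(u, 0.95)
  expect_gte(mean(u >= h[1] & u <= h[2]), 0.95)
  expect_error(hpd_interval(1:100, 1.5), "coverage")
  expect_error(hpd_interval(c(1, 2), 0.5), "too few")
})

test_that("HPD equals the brute-force shortest window on varied chains", {
  set.seed(42)
  chains <- list(rnorm(200), rexp(300), rbeta(250, 2, 8),
                 c(rnorm(100), rnorm(50, 5)))
  for (x in chains)
    expect_equal(unname(hpd_interval(x, 0.9)), brute_hpd(x, 0.9))
})

test_that("effective sample size behaves for iid, AR(1) and constant chains", {
  set.seed(43)
  ess_iid <- effective_sample_size(rnorm(5000))
  expect_gte(ess_iid, 0.8 * 5000)
  expect_lte(ess_iid, 1.05 * 5000)

  rho <- 0.9
  x <- as.numeric(arima.sim(list(ar = rho), n = 20000))
  ratio <- effective_sample_size(x) / 20000
  target <- (1 - rho) / (1 + rho)
  expect_lt(abs(ratio - target) / target, 0.30)

  expect_warning(ess_c <- effective_sample_size(rep(2, 100)), "zero-variance")
  expect_equal(ess_c, 100)
  expect_error(effective_sample_size(1:5), "at least 10")
})

test_that("Geweke z is calibrated, detects drift, and is antisymmetric", {
  set.seed(44)
  z <- replicate(1000, geweke_z(rnorm(6000)))
  rate <- mean(abs(z) > 1.96)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)

  drift <- seq(0, 5, length.out = 1000) + rnorm(1000, 0, 0.1)
  expect_gt(abs(geweke_z(drift)), 3)

  x <- rnorm(968) # window length divides evenly into batches
  expect_equal(geweke_z(x, 0.5, 0.5), -geweke_z(rev(x), 0.5, 0.5))
  expect_error(geweke_z(rnorm(20), frac_a = 0.1), "at least 10")
})

test_that("posterior summaries reproduce the SD/ESS Monte-Carlo error convention", {
  expect_equal(mc_error(8667.5, 145.8), 717.70, tolerance = 1e-3)
  expect_equal(round(mc_error(0.17009, 47.7), 5), 0.02463)
  set.seed(45)
  s <- summarize_chain(rnorm(2000, 10, 2))
  expect_equal(s$mce, s$sd / sqrt(s$ess))
  expect_true(s$hpd_lower < 10 && 10 < s$hpd_upper)
  expect_lt(abs(s$mode - 10), 0.5)
  # constant chain: degenerate summary
  sc <- suppressWarnings(summarize_chain(rep(3.5, 50)))
  expect_equal(sc$sd, 0)
  expect_equal(sc$mce, 0)
  expect_equal(sc$hpd_lower, 3.5)
  expect_equal(sc$hpd_upper, 3.5)
  expect_error(summarize_chain(1:5), "at least 10")
})

test_that("derived parameters follow the per-draw transforms and additivity", {
  # single constructed draw: G0 = [[1,.5],[.5,1]], R0 = I
  res <- structure(list(
    G = matrix(rep(c(1, 0.5, 1), each = 12), nrow = 12,
               dimnames = list(NULL, c("g_x_x", "g_y_x", "g_y_y"))),
    R = matrix(rep(c(1, 0, 1), each = 12), nrow = 12,
               dimnames = list(NULL, c("r_x_x", "r_y_x", "r_y_y"))),
    iteration = 1:12, traits = c("x", "y"), n_stored = 12L),
    class = "gibbs_result")
  d <- derive_parameters(res)
  sm <- setNames(d$summary$mean, d$summary$parameter)
  expect_equal(unname(sm["h2_x"]), 0.5)
  expect_equal(unname(sm["h2_y"]), 0.5)
  expect_equal(unname(sm["rg_y_x"]), 0.5)
  expect_equal(unname(sm["rp_y_x"]), 0.25)

  # degenerate one-draw-style chain with the component magnitudes summing
  res2 <- structure(list(
    G = matrix(21689, 12, 1, dimnames = list(NULL, "g_afc_afc")),
    R = matrix(14045, 12, 1, dimnames = list(NULL, "r_afc_afc")),
    iteration = 1:12, traits = "afc", n_stored = 12L),
    class = "gibbs_result")
  d2 <- derive_parameters(res2)
  sm2 <- setNames(d2$summary$mean, d2$summary$parameter)
  expect_equal(unname(sm2["s2_p_afc"]), 35734)

  # duplicated trait: r_g = r_p = 1 on every draw
  set.seed(46)
  g <- abs(rnorm(20, 5))
  res3 <- structure(list(
    G = cbind(g_a_a = g, g_b_a = g, g_b_b = g),
    R = cbind(r_a_a = g * 2, r_b_a = g * 2, r_b_b = g * 2),
    iteration = 1:20, traits = c("a", "b"), n_stored = 20L),
    class = "gibbs_result")
  d3 <- derive_parameters(res3)
  expect_equal(d3$n_excluded, 0)
  expect_equal(nrow(d3$chains), 20)
  expect_true(all(abs(d3$chains$rg_b_a - 1) < 1e-12))
  expect_true(all(abs(d3$chains$rp_b_a - 1) < 1e-12))
  # additivity holds draw-wise and in the posterior means
  expect_equal(d3$chains$s2_p_a, d3$chains$s2_g_a + d3$chains$s2_e_a)
})

test_that("non-PD draws are excluded with a count", {
  res <- structure(list(
    G = rbind(c(1, 0.5, 1), c(1, 1.5, 1), c(1, 0.2, 1)),
    R = rbind(c(1, 0, 1), c(1, 0, 1), c(1, 0, 1)),
    iteration = 1:3, traits = c("x", "y"), n_stored = 3L),
    class = "gibbs_result")
  colnames(res$G) <- c("g_x_x", "g_y_x", "g_y_y")
  colnames(res$R) <- c("r_x_x", "r_y_x", "r_y_y")
  d <- suppressWarnings(derive_parameters(res))
  expect_equal(d$n_excluded, 1)
  expect_equal(nrow(d$chains), 2)
})
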