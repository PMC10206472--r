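test_that("REML components on a balanced identity layout match ANOVA", {
  d <- balanced_oneway(s = 8, m = 5, seed = 7)
  fit <- fit_pmm(y ~ 1, d, criterion = "REML")
  oracle <- anova_components(d$y, d$species)
  expect_equal(fit$sigma2_e, oracle$sigma2_e, tolerance = 1e-6)
  expect_equal(fit$sigma2_p, oracle$sigma2_p, tolerance = 1e-6)
  expect_equal(fit$H2, oracle$sigma2_p /
                 (oracle$sigma2_p + oracle$sigma2_e), tolerance = 1e-6)
})

test_that("fit agrees with lme4 for identity species covariance", {
  skip_if_not_installed("lme4")
  d <- withr::with_seed(11, {
    g <- sample(sprintf("sp%02d", 1:10), 60, replace = TRUE)
    x <- rnorm(60)
    data.frame(species = g, x = x,
               y = rnorm(10)[as.integer(factor(g))] * 1.5 + 0.7 * x +
                 rnorm(60))
  })
  fit <- fit_pmm(y ~ x, d, criterion = "REML")
  ref <- lme4::lmer(y ~ x + (1 | species), d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$sigma2_p, vc$vcov[1], tolerance = 1e-5)
  expect_equal(fit$sigma2_e, vc$vcov[2], tolerance = 1e-5)
  expect_equal(fit$loglik_reml, as.numeric(stats::logLik(ref)),
               tolerance = 1e-6)
  expect_equal(fit$beta$estimate, unname(lme4::fixef(ref)),
               tolerance = 1e-5)

  fit_ml <- fit_pmm(y ~ x, d, criterion = "ML")
  ref_ml <- lme4::lmer(y ~ x + (1 | species), d, REML = FALSE)
  expect_equal(fit_ml$loglik_ml, as.numeric(stats::logLik(ref_ml)),
               tolerance = 1e-6)
})

test_that("profiled likelihood at the optimum dominates a brute-force grid", {
  ds <- sim_dataset(seed = 13, n_species = 20, eggs_per_species = 3)
  for (crit in c("REML", "ML")) {
    fit <- fit_pmm(y ~ parasitic, ds$eggs, A = ds$A, criterion = crit)
    at_opt <- if (crit == "REML") fit$loglik_reml else fit$loglik_ml
    grid <- c(0, exp(seq(log(1e-6), log(1e6), length.out = 300)))
    ll <- pmm_profile_loglik(y ~ parasitic, ds$eggs, A = ds$A,
                             theta = grid, criterion = crit)
    expect_gte(at_opt, max(ll) - 1e-6)
  }
})

test_that("pure-noise data on a star-like design hits the zero boundary", {
  d <- withr::with_seed(3, data.frame(
    species = rep(sprintf("sp%02d", 1:12), each = 4),
    y = rnorm(48)))
  fit <- fit_pmm(y ~ 1, d, criterion = "REML")
  expect_true(fit$boundary)
  expect_lt(fit$H2, 0.05)
  if (fit$sigma2_p == 0) expect_identical(heritability(fit), 0)
})

test_that("non-identifiable designs are refused", {
  d <- data.frame(species = sprintf("sp%02d", 1:10), y = rnorm(10))
  expect_error(fit_pmm(y ~ 1, d), "not identifiable")
  # ...but a phylogenetic covariance makes single-observation species fine
  tree <- simulate_tree(10, seed = 2)
  d$species <- tree$tip.label
  expect_s3_class(fit_pmm(y ~ 1, d, A = phylo_covariance(tree)$A),
                  "pmm_fit")
})

test_that("REML variance components ignore fixed-effect reparameterization", {
  ds <- sim_dataset(seed = 17, n_species = 25, eggs_per_species = 3)
  ds$eggs$x <- withr::with_seed(1, rnorm(nrow(ds$eggs)))
  f1 <- fit_pmm(y ~ x, ds$eggs, A = ds$A)
  ds$eggs$x <- ds$eggs$x + 100
  f2 <- fit_pmm(y ~ x, ds$eggs, A = ds$A)
  expect_equal(f1$sigma2_p, f2$sigma2_p, tolerance = 1e-6)
  expect_equal(f1$sigma2_e, f2$sigma2_e, tolerance = 1e-6)
  expect_equal(f1$H2, f2$H2, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(f1$beta$estimate[1], f2$beta$estimate[1])))
})

test_that("heritability recovers the generating value and is monotone", {
  levels_h2 <- c(0, 0.25, 0.5, 0.75, 0.95)
  means <- vapply(levels_h2, function(h2) {
    ests <- vapply(1:30, function(i) {
      ds <- sim_dataset(seed = 1000 * round(100 * h2) + i,
                        n_species = 30, eggs_per_species = 3,
                        sigma2_p = h2, sigma2_e = 1 - h2)
      heritability(fit_pmm(y ~ 1, ds$eggs, A = ds$A))
    }, numeric(1))
    mean(ests)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_lt(max(abs(means - levels_h2)), 0.1)
})

test_that("likelihood-ratio test is coherent on nested models", {
  ds <- sim_dataset(seed = 23, n_species = 25, eggs_per_species = 3,
                    beta_parasitism = 2)
  lrt <- lrt_fixed_effect(y ~ parasitic, y ~ 1, ds$eggs, A = ds$A)
  expect_gte(lrt$chi2, 0)
  expect_equal(lrt$df, 1L)
  expect_gte(lrt$fit_full$loglik_ml, lrt$fit_reduced$loglik_ml - 1e-8)
  expect_lt(lrt$p, 0.05)  # strong true effect

  # identical specs degenerate to chi-square 0, p = 1
  same <- lrt_fixed_effect(y ~ parasitic, y ~ parasitic, ds$eggs, A = ds$A)
  expect_equal(same$chi2, 0, tolerance = 1e-6)
  expect_identical(same$p, 1)
  expect_identical(same$df, 0L)

  expect_equal(stats::pchisq(3.841, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)
  expect_error(lrt_fixed_effect(y ~ 1, y ~ parasitic, ds$eggs, A = ds$A),
               "not nested")
})

test_that("Pearson correlation and Fisher-z interval behave as advertised", {
  x <- 1:20
  perfect <- pearson_ci(x, 2 * x + 1)
  expect_equal(perfect$r, 1)
  ind <- withr::with_seed(8, pearson_ci(rnorm(500), rnorm(500)))
  expect_lt(abs(ind$r), 0.1)
  expect_true(ind$ci_low < 0 && ind$ci_high > 0)
  expect_error(pearson_ci(1:3, 1:3), "at least 4")
  expect_error(pearson_ci(rep(1, 10), 1:10), "zero variance")
})

test_that("Fisher-z interval attains ~95% coverage at rho = 0.5, n = 30", {
  rho <- 0.5
  cover <- withr::with_seed(314, {
    vapply(1:1000, function(i) {
      z <- matrix(rnorm(60), ncol = 2)
      x <- z[, 1]; y <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
      ci <- pearson_ci(x, y)
      ci$ci_low <= rho && rho <= ci$ci_high
    }, logical(1))
  })
  p_hat <- mean(cover)
  half <- 1.96 * sqrt(0.95 * 0.05 / 1000)
  expect_gt(p_hat, 0.95 - half - 0.01)
  expect_lt(p_hat, 0.95 + half + 0.01)
})
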