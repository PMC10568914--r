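short_cfg <- function(seed = 1L, ...) {
  mcmc_config(iterations = 12000L, burn_in = 6000L, thin = 3L, seed = seed,
              ...)
}

test_that("config contract: retained draws and validation", {
  cfg <- mcmc_config()
  expect_identical(cfg$retained, 5000L)
  expect_identical(mcmc_config(iterations = 1000, burn_in = 400,
                               thin = 7)$retained, 85L)
  expect_error(mcmc_config(burn_in = 2e5), "burn_in < iterations")
  expect_error(mcmc_config(thin = 0), "thin")
})

test_that("same seed and config give bitwise-identical chains", {
  ad <- fixture_counts("ad")
  pr <- fixture_priors("ad")
  f1 <- sample_posterior(ad, pr, short_cfg(seed = 99L))
  f2 <- sample_posterior(ad, pr, short_cfg(seed = 99L))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$acceptance, f2$acceptance)
  f3 <- sample_posterior(ad, pr, short_cfg(seed = 100L))
  expect_false(identical(f1$draws, f3$draws))
  expect_identical(nrow(f1$draws[[1]]), 2000L)
  expect_identical(colnames(f1$draws[[1]]),
                   c("prev", "se_MoCA", "se_MMSE", "se_ADAS-cog",
                     "sp_MoCA", "sp_MMSE", "sp_ADAS-cog",
                     "covd_MoCA.MMSE", "covn_MoCA.MMSE"))
})

test_that("every retained draw is admissible with finite log-posterior", {
  ad <- fixture_counts("ad")
  pr <- fixture_priors("ad")
  fit <- sample_posterior(ad, pr, short_cfg(seed = 3L))
  expect_true(all(is.finite(fit$logpost[[1]])))
  d <- fit$draws[[1]]
  expect_true(all(d[, 1:7] >= 0 & d[, 1:7] <= 1))
  bd <- cov_bounds(d[, "se_MoCA"], d[, "se_MMSE"])
  bn <- cov_bounds(d[, "sp_MoCA"], d[, "sp_MMSE"])
  expect_true(all(d[, "covd_MoCA.MMSE"] >= bd[, "lower"] &
                  d[, "covd_MoCA.MMSE"] <= bd[, "upper"]))
  expect_true(all(d[, "covn_MoCA.MMSE"] >= bn[, "lower"] &
                  d[, "covn_MoCA.MMSE"] <= bn[, "upper"]))
})

test_that("all-zero tables are rejected", {
  panel <- test_panel(c("A", "B"))
  pr <- weakly_informative_priors(panel)
  zero <- cross_counts(panel, rep(0L, 4))
  expect_error(sample_posterior(zero, pr, short_cfg()), "all-zero")
})

test_that("near-perfect single test reduces to the Beta conjugate posterior", {
  # two tests pinned at Se = Sp = 1 by near-point-mass priors make the
  # count table a plain binomial: posterior for prevalence is
  # Beta(a + x, b + n - x) in closed form
  panel <- test_panel(c("A", "B"))
  a <- 3; b <- 9; x <- 37L; n <- 150L
  pin <- beta_spec(1e6, 1)
  pr <- prior_set(panel, beta_spec(a, b),
                  se = list(pin, pin), sp = list(pin, pin))
  cnt <- cross_counts(panel, c(x, 0L, 0L, n - x))
  fit <- sample_posterior(cnt, pr, short_cfg(seed = 5L))
  draws <- as.matrix(fit)[, "prev"]
  mcse <- sd(draws) / sqrt(ess(draws))
  expect_lt(abs(mean(draws) - (a + x) / (a + b + n)), 3 * mcse)
})

test_that("multi-chain runs are independent and mix to the same posterior", {
  ad <- fixture_counts("ad")
  pr <- fixture_priors("ad")
  fit <- sample_posterior(ad, pr, short_cfg(seed = 12L, chains = 2L))
  expect_length(fit$draws, 2L)
  expect_false(identical(fit$draws[[1]], fit$draws[[2]]))
  dg <- diagnostics(fit, lags = c(1L, 5L, 10L))
  expect_true(all(dg$rhat < 1.05))
})

test_that("draws export to a plain-text table", {
  ad <- fixture_counts("ad")
  pr <- fixture_priors("ad")
  fit <- sample_posterior(ad, pr, mcmc_config(iterations = 2000,
                                              burn_in = 1000, thin = 5,
                                              seed = 8))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, tmp)
  back <- read.csv(tmp, check.names = FALSE)
  expect_identical(nrow(back), 200L)
  expect_identical(names(back)[1], "chain")
  expect_equal(back$prev, as.matrix(fit)[, "prev"])
})

test_that("the sampler agrees with an independent JAGS fit of the same model", {
  ad <- fixture_counts("ad")
  pr <- fixture_priors("ad")
  mine <- summarize_posterior(
    sample_posterior(ad, pr, mcmc_config(iterations = 60000,
                                         burn_in = 20000, thin = 8,
                                         seed = 31)))$params

  library(rjags)
  model <- "
  model {
    x[1:8] ~ dmulti(p[1:8], n)
    for (c in 1:8) {
      for (k in 1:3) {
        a[c,k] <- t[c,k]*se[k] + (1-t[c,k])*(1-se[k])
        b[c,k] <- t[c,k]*(1-sp[k]) + (1-t[c,k])*sp[k]
      }
      s[c] <- 2*equals(t[c,1], t[c,2]) - 1
      p[c] <- pi * (a[c,1]*a[c,2] + s[c]*covd) * a[c,3] +
              (1-pi) * (b[c,1]*b[c,2] + s[c]*covn) * b[c,3]
    }
    pi ~ dbeta(pr_a, pr_b)
    for (k in 1:3) { se[k] ~ dbeta(sea[k], seb[k]); sp[k] ~ dbeta(spa[k], spb[k]) }
    covd ~ dunif(max(-se[1]*se[2], -(1-se[1])*(1-se[2])),
                 min(se[1]*(1-se[2]), (1-se[1])*se[2]))
    covn ~ dunif(max(-sp[1]*sp[2], -(1-sp[1])*(1-sp[2])),
                 min(sp[1]*(1-sp[2]), (1-sp[1])*sp[2]))
  }"
  pa <- blcda:::prior_args(pr)
  set.seed(1)
  jm <- jags.model(textConnection(model),
                   data = list(x = unname(ad$counts), n = ad$n,
                               t = pattern_matrix(3),
                               pr_a = pa$prev_ab[1], pr_b = pa$prev_ab[2],
                               sea = pa$se_a, seb = pa$se_b,
                               spa = pa$sp_a, spb = pa$sp_b),
                   n.chains = 1, quiet = TRUE)
  update(jm, 4000, progress.bar = "none")
  sm <- coda.samples(jm, c("pi", "se", "sp", "covd", "covn"),
                     n.iter = 20000, thin = 4, progress.bar = "none")
  jags_mean <- summary(sm)$statistics[, "Mean"]
  map <- c(prev = "pi", se_MoCA = "se[1]", se_MMSE = "se[2]",
           `se_ADAS-cog` = "se[3]", sp_MoCA = "sp[1]", sp_MMSE = "sp[2]",
           `sp_ADAS-cog` = "sp[3]", covd_MoCA.MMSE = "covd",
           covn_MoCA.MMSE = "covn")
  for (p in names(map)) {
    expect_lt(abs(mine$mean[mine$parameter == p] - jags_mean[[map[[p]]]]),
              0.012)
  }
})
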