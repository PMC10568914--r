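panel2 <- test_panel(c("A", "B"))

test_that("posterior summaries match a sort-based oracle", {
  vals <- as.numeric(1:1000) / 1000  # a 1..1000 grid on the unit scale
  m <- matrix(rep(vals, 5), ncol = 5,
              dimnames = list(NULL, c("prev", "se_A", "se_B", "sp_A", "sp_B")))
  s <- summarize_posterior(fake_chains(list(m), panel2))
  expect_equal(s$params$mean, rep(500.5 / 1000, 5))
  srt <- sort(vals)
  q <- function(p) { # type-7 quantile, hand-rolled
    h <- (length(srt) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    srt[lo] + (h - lo) * (srt[hi] - srt[lo])
  }
  expect_equal(s$params$lower, rep(q(0.025), 5))
  expect_equal(s$params$median, rep(q(0.5), 5))
  expect_equal(s$params$upper, rep(q(0.975), 5))
  expect_true(all(s$params$lower <= s$params$median &
                  s$params$median <= s$params$upper))

  const <- matrix(0.3, nrow = 50, ncol = 5,
                  dimnames = list(NULL, colnames(m)))
  sc <- summarize_posterior(fake_chains(list(const), panel2))
  expect_equal(sc$params$mean, rep(0.3, 5))
  expect_equal(sc$params$lower, rep(0.3, 5))
  expect_equal(sc$params$upper, rep(0.3, 5))
})

test_that("Youden's index is Se + Sp - 1 and reproduces the published values", {
  expect_equal(youden_index(1, 1), 1)
  expect_equal(youden_index(0.922, 0.907), 0.829)
  expect_equal(youden_index(0.757, 0.721), 0.478)
  expect_error(youden_index(1.2, 0.5), "probabilities")
  # all six published test-by-analysis pairs, exactly
  for (an in c("ad", "mci")) {
    pp <- paper_printed[[an]]
    for (t in names(pp$se))
      expect_equal(youden_index(pp$se[[t]], pp$sp[[t]]), pp$youden[[t]],
                   tolerance = 1e-12)
  }
})

test_that("posterior predictive cells are calibrated under the true model", {
  scen <- default_scenario(n = 5000, seed = 41)
  counts <- simulate_panel(scen)
  pr <- weakly_informative_priors(cognitive_panel())
  cfg <- mcmc_config(iterations = 8000, burn_in = 4000, thin = 4, seed = 42,
                     constrain_youden = TRUE)
  fit <- sample_posterior(counts, pr, cfg)
  ppc <- posterior_predictive_cells(fit)
  expect_true(all(ppc$p_exceed > 0.01 & ppc$p_exceed < 0.99))
  expect_equal(sum(ppc$expected), counts$n, tolerance = 1e-6)

  # expected counts sum to n draw by draw
  draws <- unname(as.matrix(fit))
  one <- accuracy_params(cognitive_panel(), draws[1, 1], draws[1, 2:4],
                         draws[1, 5:7], draws[1, 8], draws[1, 9],
                         validate = FALSE)
  expect_equal(sum(counts$n * cell_probabilities(one)), counts$n)
})

test_that("a forced-independence fit of dependent data fails the cell check", {
  # a 3-test independence latent class model is just-identified, so it can
  # absorb pairwise dependence by shifting the accuracy parameters; to
  # expose the mis-specification the accuracies are pinned at their
  # generating values and only the dependence is denied
  se_true <- c(0.85, 0.85, 0.9); sp_true <- c(0.9, 0.9, 0.9); prev <- 0.3
  params <- accuracy_params(cognitive_panel(), prev, se_true, sp_true,
                            cov_d = 0.10, cov_n = 0.08)
  counts <- simulate_panel(simulation_scenario(params, n = 8000, seed = 43))
  ind_panel <- test_panel(c("MoCA", "MMSE", "ADAS-cog"),
                          positive_direction = c("lower", "lower", "higher"))
  ind_counts <- cross_counts(ind_panel, unname(counts$counts))
  pin <- function(p) beta_spec(p * 4000, (1 - p) * 4000)
  pr <- prior_set(ind_panel, pin(prev),
                  se = lapply(se_true, pin), sp = lapply(sp_true, pin))
  fit <- sample_posterior(ind_counts, pr,
                          mcmc_config(iterations = 8000, burn_in = 4000,
                                      thin = 4, seed = 44))
  ppc <- posterior_predictive_cells(fit)
  expect_true(any(ppc$p_exceed < 0.01 | ppc$p_exceed > 0.99))
})

test_that("the combined report has the documented layout and round-trips", {
  ad <- fixture_counts("ad")
  pr <- fixture_priors("ad")
  cfg <- mcmc_config(iterations = 3000, burn_in = 1000, thin = 5, seed = 45)
  s_ad <- summarize_posterior(sample_posterior(ad, pr, cfg))
  s_mci <- summarize_posterior(
    sample_posterior(fixture_counts("mci"), fixture_priors("mci"), cfg))
  rep <- accuracy_report(list(AD = s_ad, MCI = s_mci))
  # 2 prevalence + 12 se/sp rows, plus 6 youden rows
  expect_identical(sum(rep$parameter %in%
                         c("prevalence", "sensitivity", "specificity")), 14L)
  expect_identical(sum(rep$parameter == "youden"), 6L)

  tmp_csv <- withr::local_tempfile(fileext = ".csv")
  tmp_txt <- withr::local_tempfile(fileext = ".txt")
  write_report(rep, tmp_csv, tmp_txt, configs = list(AD = cfg, MCI = cfg))
  back <- read.csv(tmp_csv)
  expect_equal(back$mean, rep$mean)  # full precision round trip
  txt <- readLines(tmp_txt)
  expect_true(any(grepl("3000 iterations, 1000 burn-in, thin 5", txt)))
})
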