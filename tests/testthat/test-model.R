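test_that("covariance bounds follow from non-negative pair joints", {
  expect_equal(cov_bounds(0.5, 0.5), c(lower = -0.25, upper = 0.25))
  expect_equal(cov_bounds(1.0, 0.7), c(lower = 0, upper = 0))
  expect_equal(cov_bounds(0.9, 0.8), c(lower = -0.02, upper = 0.08))
  expect_error(cov_bounds(1.2, 0.5), "probabilities")

  # brute force: a covariance is admissible iff all four joint cells of the
  # pair are non-negative
  set.seed(1)
  for (i in 1:200) {
    p <- runif(2)
    b <- cov_bounds(p[1], p[2])
    expect_lte(b[1], 0); expect_gte(b[2], 0)
    for (cv in seq(-0.5, 0.5, by = 0.01)) {
      cells <- c(p[1] * p[2] + cv, p[1] * (1 - p[2]) - cv,
                 (1 - p[1]) * p[2] - cv, (1 - p[1]) * (1 - p[2]) + cv)
      expect_identical(all(cells >= -1e-12),
                       cv >= b[1] - 1e-12 && cv <= b[2] + 1e-12)
    }
  }
})

test_that("cell probabilities: degenerate, worked and normalized cases", {
  panel <- cognitive_panel()
  perfect <- accuracy_params(panel, 1, se = c(1, 1, 1), sp = c(0.5, 0.5, 0.5))
  p <- cell_probabilities(perfect)
  expect_equal(unname(p["111"]), 1)
  expect_equal(sum(p[-1]), 0)

  ind <- accuracy_params(panel, 0.5, se = c(0.8, 0.7, 0.9),
                         sp = c(0.9, 0.8, 0.95))
  expect_equal(cell_probability(ind, c(1, 1, 1)),
               0.5 * 0.8 * 0.7 * 0.9 + 0.5 * 0.1 * 0.2 * 0.05)
  expect_equal(cell_probability(ind, "111"), 0.2525)

  # with zero covariances the conditional-independence product form holds
  pm <- pattern_matrix(3)
  prod_form <- sapply(seq_len(8), function(r) {
    t <- pm[r, ]
    0.5 * prod(ifelse(t == 1, c(0.8, 0.7, 0.9), 1 - c(0.8, 0.7, 0.9))) +
      0.5 * prod(ifelse(t == 1, 1 - c(0.9, 0.8, 0.95), c(0.9, 0.8, 0.95)))
  })
  expect_equal(unname(cell_probabilities(ind)), prod_form)

  bad <- accuracy_params(panel, 0.5, se = c(0.9, 0.8, 0.9),
                         sp = c(0.9, 0.9, 0.9), cov_d = 0.2, cov_n = 0,
                         validate = FALSE)
  expect_error(cell_probabilities(bad), "negative cell probability")
  expect_error(accuracy_params(panel, 0.5, se = c(0.9, 0.8, 0.9),
                               sp = c(0.9, 0.9, 0.9), cov_d = 0.2),
               "outside admissible")
})

test_that("cell probabilities match the brute-force latent class oracle", {
  set.seed(20)
  panels <- list(
    cognitive_panel(),
    test_panel(paste0("T", 1:2), dependent_pairs = list(c(1L, 2L))),
    test_panel(paste0("T", 1:4),
               dependent_pairs = list(c(1L, 3L), c(2L, 4L))),
    test_panel(paste0("T", 1:3))  # fully independent
  )
  for (panel in panels) {
    for (i in 1:500) {
      params <- random_params(panel)
      p <- cell_probabilities(params)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= 0 & p <= 1))
      expect_equal(unname(p), unname(oracle_cell_probs(params)),
                   tolerance = 1e-12)
    }
  }
})

test_that("margins equal pi*Se + (1-pi)*(1-Sp) with or without dependence", {
  set.seed(21)
  panel <- cognitive_panel()
  pm <- pattern_matrix(3)
  for (i in 1:200) {
    params <- random_params(panel)
    p <- cell_probabilities(params)
    for (k in 1:3) {
      marg <- sum(p[pm[, k] == 1])
      expect_equal(unname(marg),
                   unname(params$prevalence * params$se[k] +
                            (1 - params$prevalence) * (1 - params$sp[k])),
                   tolerance = 1e-12)
    }
  }
})

test_that("log-likelihood: single-cell, sparsity and oracle agreement", {
  panel <- test_panel(c("A", "B"))
  # pi = 0.5 with two perfect tests puts probability 0.5 on pattern 11
  params <- accuracy_params(panel, 0.5, se = c(1, 1), sp = c(1, 1))
  cnt <- cross_counts(panel, c(10L, 0L, 0L, 0L))
  expect_equal(log_likelihood(params, cnt), 10 * log(0.5))

  # zero-count cells contribute nothing even when their probability is 0
  cnt2 <- cross_counts(panel, c(7L, 0L, 0L, 3L))
  expect_equal(log_likelihood(params, cnt2), 7 * log(0.5) + 3 * log(0.5))
  cnt3 <- cross_counts(panel, c(7L, 1L, 0L, 3L))
  expect_identical(log_likelihood(params, cnt3), -Inf)

  # Table 1 counts at the prior-mean point with zero covariances
  ad <- fixture_counts("ad")
  pr <- fixture_priors("ad")
  pmean <- function(s) s$alpha / (s$alpha + s$beta)
  pt <- accuracy_params(cognitive_panel(), pmean(pr$prevalence),
                        se = sapply(pr$se, pmean), sp = sapply(pr$sp, pmean))
  expect_equal(log_likelihood(pt, ad), oracle_loglik(pt, ad),
               tolerance = 1e-12)

  wrong <- cross_counts(test_panel(c("X", "Y", "Z")), unname(ad$counts))
  expect_error(log_likelihood(pt, wrong), "different panels")
})

test_that("log-posterior decomposes into oracle likelihood plus prior terms", {
  panel <- cognitive_panel()
  ad <- fixture_counts("ad")
  pr <- fixture_priors("ad")
  set.seed(22)
  for (i in 1:100) {
    params <- random_params(panel)
    expected <- oracle_loglik(params, ad) +
      oracle_dbeta_log(params$prevalence, pr$prevalence$alpha,
                       pr$prevalence$beta) +
      sum(sapply(panel$tests, function(t)
        oracle_dbeta_log(params$se[t], pr$se[[t]]$alpha, pr$se[[t]]$beta) +
        oracle_dbeta_log(params$sp[t], pr$sp[[t]]$alpha, pr$sp[[t]]$beta))) -
      2 * log(2)  # Uniform(-1, 1) covariance prior, two covariances
    expect_equal(log_posterior(params, ad, pr), expected, tolerance = 1e-9)
  }

  # flat accuracy priors: posterior - likelihood is constant in them
  flat <- prior_set(panel, beta_spec(1, 1),
                    se = replicate(3, beta_spec(1, 1), simplify = FALSE),
                    sp = replicate(3, beta_spec(1, 1), simplify = FALSE))
  set.seed(23)
  d1 <- random_params(panel); d2 <- random_params(panel)
  expect_equal(log_posterior(d1, ad, flat) - log_likelihood(d1, ad),
               log_posterior(d2, ad, flat) - log_likelihood(d2, ad),
               tolerance = 1e-9)

  # covariance outside its admissible region scores -Inf
  out <- accuracy_params(panel, 0.5, se = c(0.9, 0.8, 0.9),
                         sp = c(0.9, 0.9, 0.9), cov_d = 0.2, cov_n = 0,
                         validate = FALSE)
  expect_identical(log_posterior(out, ad, pr), -Inf)
})

test_that("the compiled density agrees with the R density", {
  panel <- cognitive_panel()
  ad <- fixture_counts("ad")
  pr <- fixture_priors("ad")
  pm <- pattern_matrix(3)
  pa <- blcda:::prior_args(pr)
  set.seed(24)
  for (i in 1:50) {
    params <- random_params(panel)
    theta <- c(params$prevalence, unname(params$se), unname(params$sp),
               params$cov_d, params$cov_n)
    lp_cpp <- blcda:::blcda_logpost_cpp(
      as.numeric(ad$counts), pm, blcda:::pair_matrix0(panel), pa$prev_ab,
      pa$se_a, pa$se_b, pa$sp_a, pa$sp_b, pa$cov_lower, pa$cov_upper,
      theta, FALSE)
    expect_equal(lp_cpp, log_posterior(params, ad, pr), tolerance = 1e-9)
  }
})
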