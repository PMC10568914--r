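# Independent brute-force oracles used across the suite.
# These deliberately avoid the package's closed-form cell formula: each
# class's joint is assembled from an explicit 2x2 table for the dependent
# pair and per-test margins, then mixed over the latent class.

oracle_class_joint <- function(pm, margins, pairs, covs) {
  p <- rep(1, nrow(pm))
  used <- integer(0)
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    m1 <- margins[pr[1]]; m2 <- margins[pr[2]]
    # explicit 2x2 joint, rows = result of test pr[1] (1, 0), cols = pr[2]
    joint <- matrix(c(m1 * m2 + covs[i],        m1 * (1 - m2) - covs[i],
                      (1 - m1) * m2 - covs[i],  (1 - m1) * (1 - m2) + covs[i]),
                    2, 2, byrow = TRUE,
                    dimnames = list(c("1", "0"), c("1", "0")))
    p <- p * joint[cbind(as.character(pm[, pr[1]]), as.character(pm[, pr[2]]))]
    used <- c(used, pr)
  }
  for (k in setdiff(seq_len(ncol(pm)), used))
    p <- p * ifelse(pm[, k] == 1L, margins[k], 1 - margins[k])
  p
}

oracle_cell_probs <- function(params) {
  pm <- pattern_matrix(length(params$panel$tests))
  pairs <- params$panel$dependent_pairs
  params$prevalence *
    oracle_class_joint(pm, unname(params$se), pairs, params$cov_d) +
    (1 - params$prevalence) *
    oracle_class_joint(pm, 1 - unname(params$sp), pairs, params$cov_n)
}

oracle_loglik <- function(params, counts) {
  p <- oracle_cell_probs(params)
  x <- unname(counts$counts)
  if (any(x > 0 & p <= 0)) return(-Inf)
  sum(x[x > 0] * log(p[x > 0]))
}

# hand-coded Beta log-density (lgamma form), independent of stats::dbeta
oracle_dbeta_log <- function(x, a, b) {
  (a - 1) * log(x) + (b - 1) * log(1 - x) +
    lgamma(a + b) - lgamma(a) - lgamma(b)
}

# random admissible parameter draws for a given panel
random_params <- function(panel, rng_min = 0.02, rng_max = 0.98) {
  K <- length(panel$tests)
  se <- runif(K, rng_min, rng_max)
  sp <- runif(K, rng_min, rng_max)
  cd <- cn <- numeric(length(panel$dependent_pairs))
  for (i in seq_along(panel$dependent_pairs)) {
    pr <- panel$dependent_pairs[[i]]
    bd <- cov_bounds(se[pr[1]], se[pr[2]])
    bn <- cov_bounds(sp[pr[1]], sp[pr[2]])
    cd[i] <- runif(1, bd[1], bd[2])
    cn[i] <- runif(1, bn[1], bn[2])
  }
  accuracy_params(panel, runif(1, rng_min, rng_max), se, sp, cd, cn)
}

# minimal chains object wrapping given draw matrices (for summary tests)
fake_chains <- function(draws_list, panel) {
  structure(list(draws = draws_list,
                 logpost = lapply(draws_list, function(m) rep(0, nrow(m))),
                 acceptance = NULL,
                 config = mcmc_config(iterations = 10L, burn_in = 0L,
                                      thin = 1L),
                 panel = panel, counts = NULL, priors = NULL),
            class = "blcda_chains")
}

paper_printed <- list(
  ad = list(prev = 0.200, prev_ci = c(0.176, 0.226),
            se = c(MoCA = 0.912, MMSE = 0.874, `ADAS-cog` = 0.922),
            sp = c(MoCA = 0.901, MMSE = 0.922, `ADAS-cog` = 0.907),
            se_ci = list(MoCA = c(0.884, 0.938), MMSE = c(0.849, 0.897),
                         `ADAS-cog` = c(0.882, 0.955)),
            sp_ci = list(MoCA = c(0.881, 0.920), MMSE = c(0.906, 0.937),
                         `ADAS-cog` = c(0.888, 0.925)),
            youden = c(MoCA = 0.813, MMSE = 0.796, `ADAS-cog` = 0.829)),
  mci = list(prev = 0.248, prev_ci = c(0.214, 0.285),
             se = c(MoCA = 0.845, MMSE = 0.757, `ADAS-cog` = 0.869),
             sp = c(MoCA = 0.769, MMSE = 0.721, `ADAS-cog` = 0.835),
             se_ci = list(MoCA = c(0.822, 0.867), MMSE = c(0.720, 0.792),
                          `ADAS-cog` = c(0.800, 0.929)),
             sp_ci = list(MoCA = c(0.743, 0.795), MMSE = c(0.696, 0.747),
                          `ADAS-cog` = c(0.803, 0.866)),
             youden = c(MoCA = 0.614, MMSE = 0.478, `ADAS-cog` = 0.704)))
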