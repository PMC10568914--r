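#' MCMC protocol settings
#'
#' Defaults follow the reference protocol: 100,000 iterations, the first
#' 50,000 as a burn-in that doubles as the step-size adaptation phase, and
#' every 10th post-burn-in iteration retained, i.e. 5,000 draws per chain.
#'
#' @param iterations Total iterations per chain.
#' @param burn_in Iterations discarded (and used for adaptation).
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param chains Number of independent chains (1 by default; use >= 2 to
#'   enable the split-chain scale-reduction diagnostic).
#' @param seed Integer seed; chain i uses `seed + i - 1`.
#' @param adapt_batch Iterations per step-size adaptation batch.
#' @param target_accept Acceptance rate the adaptation aims for (0.44, the
#'   usual scalar random-walk target).
#' @param constrain_youden If `TRUE`, restrict every test to Se + Sp > 1.
#'   Off by default: with informative accuracy priors the mirror mode of the
#'   latent class likelihood (pi <-> 1 - pi, Se <-> 1 - Sp) carries
#'   negligible mass. Turn on with weak symmetric priors, where the mirror
#'   mode is a genuine label-switching hazard.
#' @return An object of class `blcda_config`.
#' @export
mcmc_config <- function(iterations = 100000L, burn_in = 50000L, thin = 10L,
                        chains = 1L, seed = 1L, adapt_batch = 50L,
                        target_accept = 0.44, constrain_youden = FALSE) {
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin); chains <- as.integer(chains)
  stopifnot(iterations > 0L, burn_in >= 0L, burn_in < iterations,
            thin > 0L, chains > 0L, adapt_batch > 0L,
            target_accept > 0, target_accept < 1)
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 chains = chains, seed = as.integer(seed),
                 adapt_batch = as.integer(adapt_batch),
                 target_accept = target_accept,
                 constrain_youden = isTRUE(constrain_youden),
                 retained = (iterations - burn_in) %/% thin),
            class = "blcda_config")
}

param_names <- function(panel) {
  pairs <- panel$dependent_pairs
  lab <- vapply(pairs, function(p)
    paste(panel$tests[p], collapse = "."), "")
  c("prev", paste0("se_", panel$tests), paste0("sp_", panel$tests),
    if (length(pairs)) paste0("covd_", lab),
    if (length(pairs)) paste0("covn_", lab))
}

prior_args <- function(priors) {
  list(prev_ab = c(priors$prevalence$alpha, priors$prevalence$beta),
       se_a = vapply(priors$se, function(s) s$alpha, 0),
       se_b = vapply(priors$se, function(s) s$beta, 0),
       sp_a = vapply(priors$sp, function(s) s$alpha, 0),
       sp_b = vapply(priors$sp, function(s) s$beta, 0),
       cov_lower = as.numeric(priors$cov_lower),
       cov_upper = as.numeric(priors$cov_upper))
}

pair_matrix0 <- function(panel) {
  P <- length(panel$dependent_pairs)
  m <- matrix(0L, P, 2)
  for (i in seq_len(P)) m[i, ] <- panel$dependent_pairs[[i]] - 1L
  m
}

#' Draw from the posterior of the latent class model
#'
#' Runs the Metropolis-within-Gibbs sampler: each probability parameter is
#' updated by a random-walk proposal on the logit scale, each within-class
#' covariance by a random walk scaled to its currently admissible interval;
#' proposals outside the admissible region are rejected, which realises the
#' truncation of the nominal Uniform covariance prior. Step sizes adapt
#' toward `target_accept` during burn-in and are frozen afterwards. Chains
#' are initialized from prior draws (covariances at 0) and are bitwise
#' reproducible given `config$seed`.
#'
#' @param counts A [cross_counts()] table.
#' @param priors A [prior_set()] over the same panel.
#' @param config An [mcmc_config()].
#' @return An object of class `blcda_chains`: list with `draws` (a list of
#'   per-chain matrices, retained draws by parameter), `logpost`,
#'   `acceptance` (per parameter and chain), `config`, `panel`, `counts`,
#'   `priors`.
#' @examples
#' \donttest{
#' fit <- sample_posterior(fixture_counts("ad"), fixture_priors("ad"),
#'                         mcmc_config(iterations = 2000, burn_in = 1000,
#'                                     thin = 2, seed = 7))
#' summarize_posterior(fit)
#' }
#' @export
sample_posterior <- function(counts, priors, config = mcmc_config()) {
  stopifnot(inherits(counts, "blcda_counts"),
            inherits(priors, "blcda_priors"),
            inherits(config, "blcda_config"))
  if (!identical(counts$panel$tests, priors$panel$tests))
    stop("counts and priors refer to different panels")
  if (counts$n == 0L || all(counts$counts == 0L))
    stop("cannot fit an all-zero count table")
  panel <- counts$panel
  K <- length(panel$tests); P <- length(panel$dependent_pairs)
  pm <- pattern_matrix(K)
  pa <- prior_args(priors)
  nm <- param_names(panel)

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    init <- NULL
    for (try in seq_len(100L)) {
      cand <- c(stats::rbeta(1, pa$prev_ab[1], pa$prev_ab[2]),
                stats::rbeta(K, pa$se_a, pa$se_b),
                stats::rbeta(K, pa$sp_a, pa$sp_b),
                rep(0, 2 * P))
      if (config$constrain_youden &&
          any(cand[1 + 1:K] + cand[1 + K + 1:K] <= 1)) next
      lp0 <- blcda_logpost_cpp(as.numeric(counts$counts), pm,
                               pair_matrix0(panel), pa$prev_ab,
                               pa$se_a, pa$se_b, pa$sp_a, pa$sp_b,
                               pa$cov_lower, pa$cov_upper, cand,
                               config$constrain_youden)
      if (is.finite(lp0)) { init <- cand; break }
    }
    if (is.null(init))
      stop("no admissible initial state found after 100 prior draws")
    out <- blcda_mcmc_cpp(as.numeric(counts$counts), pm, pair_matrix0(panel),
                          pa$prev_ab, pa$se_a, pa$se_b, pa$sp_a, pa$sp_b,
                          pa$cov_lower, pa$cov_upper, init,
                          config$iterations, config$burn_in, config$thin,
                          config$adapt_batch, config$target_accept,
                          config$constrain_youden)
    colnames(out$draws) <- nm
    names(out$acceptance) <- nm
    out
  }

  runs <- lapply(seq_len(config$chains), function(i) run_chain(config$seed + i - 1L))
  structure(list(draws = lapply(runs, `[[`, "draws"),
                 logpost = lapply(runs, `[[`, "logpost"),
                 acceptance = lapply(runs, `[[`, "acceptance"),
                 config = config, panel = panel,
                 counts = counts, priors = priors),
            class = "blcda_chains")
}

#' @export
print.blcda_chains <- function(x, ...) {
  cat(sprintf("Posterior chains: %d chain(s) x %d retained draws (%d params)\n",
              length(x$draws), nrow(x$draws[[1]]), ncol(x$draws[[1]])))
  cat("Protocol:", x$config$iterations, "iterations,", x$config$burn_in,
      "burn-in, thin", x$config$thin, ", seed", x$config$seed, "\n")
  invisible(x)
}

#' Pool retained draws across chains
#'
#' @param x A `blcda_chains` object.
#' @param ... Unused.
#' @return A matrix, one column per parameter.
#' @export
as.matrix.blcda_chains <- function(x, ...) do.call(rbind, x$draws)

#' Export retained draws to a plain-text table
#'
#' One column per parameter, one row per retained draw (chains stacked, with
#' a `chain` column), readable by any posterior-analysis tool.
#'
#' @param chains A `blcda_chains` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(chains, path) {
  stopifnot(inherits(chains, "blcda_chains"))
  tab <- do.call(rbind, lapply(seq_along(chains$draws), function(i)
    data.frame(chain = i, chains$draws[[i]], check.names = FALSE)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
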