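#' A data-generating scenario for the latent class model
#'
#' Bundles generating [accuracy_params()] with a sample size, a seed, and
#' optional class-conditional continuous score settings per test (normal
#' components by default, location/scale per latent class).
#'
#' @param params Generating [accuracy_params()].
#' @param n Number of subjects (>= 0).
#' @param seed Integer seed.
#' @param scores Optional named list (by test) of lists with elements
#'   `mean_d`, `sd_d`, `mean_n`, `sd_n` giving the score distribution in the
#'   diseased and non-diseased class.
#' @return An object of class `blcda_scenario`.
#' @export
simulation_scenario <- function(params, n, seed = 1L, scores = NULL) {
  stopifnot(inherits(params, "blcda_params"), n >= 0)
  if (!is.null(scores)) {
    if (!all(names(scores) %in% params$panel$tests))
      stop("score settings name tests outside the panel")
    ok <- vapply(scores, function(s)
      all(c("mean_d", "sd_d", "mean_n", "sd_n") %in% names(s)), TRUE)
    if (!all(ok))
      stop("each score setting needs mean_d, sd_d, mean_n, sd_n")
  }
  structure(list(params = params, n = as.integer(n), seed = as.integer(seed),
                 scores = scores),
            class = "blcda_scenario")
}

#' A realistic three-test screening scenario
#'
#' Default generating conditions used in the package's recovery studies: a
#' 20% prevalence two-class population screened with three correlated tests
#' of sensitivity around 0.9, matching the accuracy range of cognitive
#' screening instruments, with a modest positive within-class covariance
#' for the first pair.
#'
#' @param n Subjects (default 20000).
#' @param seed Integer seed.
#' @return A [simulation_scenario()].
#' @export
default_scenario <- function(n = 20000L, seed = 1L) {
  simulation_scenario(
    accuracy_params(cognitive_panel(), 0.2,
                    se = c(0.9, 0.87, 0.92), sp = c(0.9, 0.92, 0.91),
                    cov_d = 0.03, cov_n = 0.02),
    n = n, seed = seed)
}

#' Simulate a cross-classified count table
#'
#' Draws the 2^K cell counts from a single multinomial with the
#' [cell_probabilities()] of the generating parameters.
#'
#' @param scenario A [simulation_scenario()].
#' @return A [cross_counts()] table with `n` subjects.
#' @export
simulate_panel <- function(scenario) {
  stopifnot(inherits(scenario, "blcda_scenario"))
  p <- cell_probabilities(scenario$params)
  set.seed(scenario$seed)
  cnt <- if (scenario$n == 0L) rep(0L, length(p))
         else as.integer(stats::rmultinom(1, scenario$n, p))
  cross_counts(scenario$params$panel, stats::setNames(cnt, names(p)))
}

# 2x2 joint of a dependent pair given class, from margins + covariance;
# cells ordered (1,1), (1,0), (0,1), (0,0)
pair_joint <- function(m_i, m_j, cv) {
  c(m_i * m_j + cv, m_i * (1 - m_j) - cv,
    (1 - m_i) * m_j - cv, (1 - m_i) * (1 - m_j) + cv)
}

#' Simulate subject-level data
#'
#' Latent status is Bernoulli(prevalence); within each class the dependent
#' pairs' results come from their 2x2 joint (margins plus additive
#' covariance, exactly the construction of [cell_probabilities()]) and the
#' remaining tests are independent Bernoulli draws. When the scenario
#' carries score settings, a continuous score per configured test is drawn
#' from the class-conditional normal component.
#'
#' @param scenario A [simulation_scenario()].
#' @return A data.frame with `status`, one 0/1 result column per test, and
#'   `<test>_score` columns when scores are configured.
#' @export
simulate_subjects <- function(scenario) {
  stopifnot(inherits(scenario, "blcda_scenario"))
  params <- scenario$params
  panel <- params$panel
  K <- length(panel$tests)
  n <- scenario$n
  set.seed(scenario$seed)
  status <- stats::rbinom(n, 1L, params$prevalence)
  res <- matrix(0L, n, K, dimnames = list(NULL, panel$tests))
  in_pair <- unlist(panel$dependent_pairs)
  for (i in seq_along(panel$dependent_pairs)) {
    pr <- panel$dependent_pairs[[i]]
    for (cls in 0:1) {
      idx <- which(status == cls)
      if (!length(idx)) next
      m <- if (cls == 1L) params$se[pr] else 1 - params$sp[pr]
      cv <- if (cls == 1L) params$cov_d[i] else params$cov_n[i]
      joint <- pair_joint(m[1], m[2], cv)
      cell <- sample.int(4L, length(idx), replace = TRUE, prob = joint)
      res[idx, pr[1]] <- as.integer(cell <= 2L)
      res[idx, pr[2]] <- as.integer(cell %in% c(1L, 3L))
    }
  }
  for (k in setdiff(seq_len(K), in_pair)) {
    pk <- ifelse(status == 1L, params$se[k], 1 - params$sp[k])
    res[, k] <- stats::rbinom(n, 1L, pk)
  }
  out <- data.frame(status = status, res, check.names = FALSE)
  for (t in names(scenario$scores %||% list())) {
    s <- scenario$scores[[t]]
    out[[paste0(t, "_score")]] <-
      ifelse(status == 1L,
             stats::rnorm(n, s$mean_d, s$sd_d),
             stats::rnorm(n, s$mean_n, s$sd_n))
  }
  out
}

#' Aggregate subject-level results into a count table
#'
#' @param subjects Output of [simulate_subjects()].
#' @param panel The generating [test_panel()].
#' @return A [cross_counts()] table.
#' @export
tabulate_subjects <- function(subjects, panel) {
  stopifnot(inherits(panel, "blcda_panel"))
  pm <- pattern_matrix(length(panel$tests))
  pat <- apply(as.matrix(subjects[panel$tests]), 1, paste, collapse = "")
  cnt <- vapply(rownames(pm), function(p) sum(pat == p), 0)
  cross_counts(panel, as.integer(cnt))
}

#' Simulation-based parameter recovery study
#'
#' For each replicate: simulate a count table from the scenario, fit the
#' model, and record posterior means and interval coverage of the
#' generating values. Fits use the identifiability constraint Se + Sp > 1
#' unless the supplied config says otherwise, since with weak symmetric
#' priors the mirror mode of the likelihood is a label-switching hazard.
#'
#' @param scenario A [simulation_scenario()]; replicate r uses seed
#'   `scenario$seed + r - 1` for data generation and fitting.
#' @param priors A [prior_set()] (typically weakly informative).
#' @param config An [mcmc_config()]; `constrain_youden` is turned on unless
#'   explicitly set via `constrain`.
#' @param replicates Number of replicates.
#' @param constrain Override for the identifiability constraint.
#' @return An object of class `blcda_recovery`: `table` has one row per
#'   parameter with the generating value, mean posterior mean, bias and
#'   coverage of the 95% interval; `failures` records replicates whose fit
#'   errored; `per_replicate` the raw posterior means.
#' @export
recovery_study <- function(scenario, priors, config = mcmc_config(),
                           replicates = 20L, constrain = TRUE) {
  stopifnot(inherits(scenario, "blcda_scenario"),
            inherits(priors, "blcda_priors"), replicates >= 1L)
  panel <- scenario$params$panel
  nm <- param_names(panel)
  P <- length(panel$dependent_pairs)
  truth <- c(scenario$params$prevalence, scenario$params$se,
             scenario$params$sp,
             if (P) scenario$params$cov_d, if (P) scenario$params$cov_n)
  names(truth) <- nm
  means <- matrix(NA_real_, replicates, length(nm),
                  dimnames = list(NULL, nm))
  covered <- matrix(NA, replicates, length(nm), dimnames = list(NULL, nm))
  failures <- character(0)
  for (r in seq_len(replicates)) {
    res <- tryCatch({
      sc <- scenario
      sc$seed <- scenario$seed + r - 1L
      counts <- simulate_panel(sc)
      cfg <- config
      cfg$seed <- config$seed + r - 1L
      cfg$constrain_youden <- isTRUE(constrain)
      fit <- sample_posterior(counts, priors, cfg)
      summarize_posterior(fit)$params
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r,
                                      conditionMessage(res)))
      next
    }
    at <- match(nm, res$parameter)
    means[r, ] <- res$mean[at]
    covered[r, ] <- truth >= res$lower[at] & truth <= res$upper[at]
  }
  ok <- !is.na(means[, 1])
  tab <- data.frame(parameter = nm, truth = unname(truth),
                    mean_estimate = colMeans(means[ok, , drop = FALSE]),
                    bias = colMeans(means[ok, , drop = FALSE]) - unname(truth),
                    coverage = colMeans(covered[ok, , drop = FALSE]),
                    replicates = sum(ok), row.names = NULL)
  structure(list(table = tab, failures = failures, per_replicate = means),
            class = "blcda_recovery")
}

#' @export
print.blcda_recovery <- function(x, ...) {
  tab <- x$table
  tab[c("truth", "mean_estimate", "bias", "coverage")] <-
    lapply(tab[c("truth", "mean_estimate", "bias", "coverage")], round, 4)
  print(tab, row.names = FALSE)
  if (length(x$failures))
    cat("Failed replicates:\n", paste(" ", x$failures, collapse = "\n"), "\n")
  invisible(x)
}
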