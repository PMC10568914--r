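#' Beta prior specification
#'
#' @param alpha,beta Positive shape parameters.
#' @return An object of class `beta_spec`.
#' @examples
#' beta_spec(2.819, 16.021)
#' @export
beta_spec <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) ||
      length(alpha) != 1L || length(beta) != 1L ||
      !is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0)
    stop("alpha and beta must be positive finite scalars")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "beta_spec")
}

#' @export
print.beta_spec <- function(x, ...) {
  s <- beta_summary(x)
  cat(sprintf("Beta(%g, %g): mean %.4f, sd %.4f", x$alpha, x$beta,
              s$mean, sqrt(s$variance)))
  if (!is.na(s$mode)) cat(sprintf(", mode %.4f", s$mode))
  cat("\n")
  invisible(x)
}

#' Closed-form summaries of a Beta prior
#'
#' @param spec A [beta_spec()].
#' @return A list with `mean`, `mode` (`NA` when alpha <= 1 or beta <= 1,
#'   where no interior mode exists), `variance`, and `quantile`, the quantile
#'   function (regularized incomplete Beta inverse).
#' @examples
#' beta_summary(beta_spec(2.819, 16.021))$mode  # ~0.108
#' @export
beta_summary <- function(spec) {
  stopifnot(inherits(spec, "beta_spec"))
  a <- spec$alpha; b <- spec$beta
  list(mean = a / (a + b),
       mode = if (a > 1 && b > 1) (a - 1) / (a + b - 2) else NA_real_,
       variance = a * b / ((a + b)^2 * (a + b + 1)),
       quantile = function(p) stats::qbeta(p, a, b))
}

#' Elicit a Beta prior from a central value and a percentile
#'
#' Solves for the Beta(alpha, beta) whose stated central statistic (mode or
#' mean) equals `central` and whose `percentile` quantile equals `bound`.
#' This is the usual way informative accuracy priors are built from
#' literature summaries ("most likely 90%, 95% sure it exceeds 80%"), the
#' convention popularized by BetaBuster in diagnostic-test modelling.
#'
#' The family is parameterized by a concentration s > 0: for a mode m,
#' alpha = 1 + m s and beta = 1 + (1 - m) s; for a mean, alpha = m s and
#' beta = (1 - m) s. The quantile at fixed `percentile` is monotone in s,
#' so the root is found by bisection to |quantile error| < 1e-6.
#'
#' @param central Central value in (0, 1).
#' @param central_kind `"mode"` (default) or `"mean"`.
#' @param bound Probability the `percentile` quantile must equal.
#' @param percentile Which quantile `bound` pins down (default 0.95).
#' @return A [beta_spec()].
#' @examples
#' elicit_beta(0.9, "mode", bound = 0.8, percentile = 0.05)
#' @export
elicit_beta <- function(central, central_kind = c("mode", "mean"), bound,
                        percentile = 0.95) {
  central_kind <- match.arg(central_kind)
  stopifnot(is.numeric(central), length(central) == 1L,
            is.numeric(bound), length(bound) == 1L,
            is.numeric(percentile), length(percentile) == 1L)
  if (central <= 0 || central >= 1) stop("central must be in (0, 1)")
  if (bound <= 0 || bound >= 1) stop("bound must be in (0, 1)")
  if (percentile <= 0 || percentile >= 1)
    stop("percentile must be in (0, 1)")
  shapes <- function(s) {
    if (central_kind == "mode") c(1 + central * s, 1 + (1 - central) * s)
    else c(central * s, (1 - central) * s)
  }
  qfun <- function(s) {
    ab <- shapes(s)
    stats::qbeta(percentile, ab[1], ab[2])
  }
  # As s -> Inf the quantile tends to `central`; as s -> 0 it tends to the
  # flat-limit quantile. The map s -> quantile need not be monotone when the
  # bound sits beyond the central value on its own tail, so scan for every
  # sign change and keep the most concentrated (largest-s) solution.
  f <- function(ls) qfun(exp(ls)) - bound
  grid <- seq(-12, 35, length.out = 241)
  fg <- vapply(grid, f, 0)
  flips <- which(is.finite(fg[-1]) & is.finite(fg[-length(fg)]) &
                   fg[-1] * fg[-length(fg)] <= 0)
  if (!length(flips))
    stop("infeasible elicitation: no Beta with ", central_kind, " ",
         central, " has its ", percentile, " quantile at ", bound)
  root <- stats::uniroot(f, grid[c(max(flips), max(flips) + 1L)],
                         tol = .Machine$double.eps^0.5)$root
  ab <- shapes(exp(root))
  out <- beta_spec(ab[1], ab[2])
  err <- abs(stats::qbeta(percentile, out$alpha, out$beta) - bound)
  if (err > 1e-6)
    stop("elicitation did not converge: quantile error ", format(err))
  out
}

#' Prior set for a latent class accuracy model
#'
#' Beta priors for prevalence and each test's sensitivity and specificity,
#' plus a bounded-uniform prior for each dependent pair's within-class
#' covariance. The covariance prior is nominally Uniform(lower, upper) but
#' its density is zero (log-density -Inf) outside the admissible region
#' [cov_bounds()] implied by the current accuracy parameters, which is how a
#' rejection-based sampler treats it.
#'
#' @param panel A [test_panel()].
#' @param prevalence A [beta_spec()].
#' @param se,sp Lists (or unnamed lists in panel order) of one [beta_spec()]
#'   per test; names must match the panel when given.
#' @param cov_lower,cov_upper Nominal support of the covariance priors,
#'   recycled across dependent pairs; defaults Uniform(-1, 1).
#' @return An object of class `blcda_priors`.
#' @examples
#' p <- test_panel(c("A", "B"), dependent_pairs = list(c("A", "B")))
#' prior_set(p, beta_spec(1, 1),
#'           se = list(beta_spec(9, 1), beta_spec(9, 1)),
#'           sp = list(beta_spec(9, 1), beta_spec(9, 1)))
#' @export
prior_set <- function(panel, prevalence, se, sp, cov_lower = -1,
                      cov_upper = 1) {
  stopifnot(inherits(panel, "blcda_panel"), inherits(prevalence, "beta_spec"))
  K <- length(panel$tests)
  fix <- function(x, what) {
    if (inherits(x, "beta_spec")) x <- list(x)
    if (length(x) != K) stop("need one ", what, " prior per test")
    if (!all(vapply(x, inherits, TRUE, "beta_spec")))
      stop(what, " priors must be beta_spec objects")
    if (!is.null(names(x)) && any(nzchar(names(x)))) {
      if (!setequal(names(x), panel$tests))
        stop(what, " prior names do not match the panel")
      x <- x[panel$tests]
    }
    stats::setNames(x, panel$tests)
  }
  P <- length(panel$dependent_pairs)
  cov_lower <- rep(as.numeric(cov_lower), length.out = max(P, 1L))[seq_len(P)]
  cov_upper <- rep(as.numeric(cov_upper), length.out = max(P, 1L))[seq_len(P)]
  if (P && any(cov_lower >= cov_upper))
    stop("covariance prior must have lower < upper")
  structure(list(panel = panel, prevalence = prevalence,
                 se = fix(se, "sensitivity"), sp = fix(sp, "specificity"),
                 cov_lower = cov_lower, cov_upper = cov_upper),
            class = "blcda_priors")
}

#' @export
print.blcda_priors <- function(x, ...) {
  fmt <- function(s) sprintf("Beta(%g, %g)", s$alpha, s$beta)
  cat("Prevalence:", fmt(x$prevalence), "\n")
  for (t in x$panel$tests)
    cat(sprintf("%-10s Se %s  Sp %s\n", t, fmt(x$se[[t]]), fmt(x$sp[[t]])))
  for (i in seq_along(x$panel$dependent_pairs)) {
    pr <- x$panel$dependent_pairs[[i]]
    cat(sprintf("Covariance %s--%s: Uniform(%g, %g), truncated to the admissible region\n",
                x$panel$tests[pr[1]], x$panel$tests[pr[2]],
                x$cov_lower[i], x$cov_upper[i]))
  }
  invisible(x)
}

#' Read / write a prior configuration file
#'
#' A human-editable YAML file with entries `prevalence: [alpha, beta]`,
#' `sensitivity:` and `specificity:` maps from test name to `[alpha, beta]`,
#' and an optional `covariance:` list of `{tests: [A, B], lower, upper}`
#' records (one per dependent pair; defaults to -1 and 1 when omitted).
#'
#' @param path File to read or write.
#' @param panel The [test_panel()] the priors refer to.
#' @return `read_priors()` returns a [prior_set()]; `write_priors()` returns
#'   `path` invisibly.
#' @export
read_priors <- function(path, panel) {
  stopifnot(inherits(panel, "blcda_panel"))
  y <- yaml::read_yaml(path)
  need <- c("prevalence", "sensitivity", "specificity")
  if (!all(need %in% names(y)))
    stop("prior file must define: ", paste(need, collapse = ", "))
  as_spec <- function(v, what) {
    if (length(v) != 2L) stop("prior '", what, "' must be [alpha, beta]")
    beta_spec(v[[1]], v[[2]])
  }
  se <- lapply(panel$tests, function(t) {
    if (is.null(y$sensitivity[[t]])) stop("no sensitivity prior for ", t)
    as_spec(y$sensitivity[[t]], t)
  })
  sp <- lapply(panel$tests, function(t) {
    if (is.null(y$specificity[[t]])) stop("no specificity prior for ", t)
    as_spec(y$specificity[[t]], t)
  })
  P <- length(panel$dependent_pairs)
  lower <- rep(-1, P); upper <- rep(1, P)
  for (rec in y$covariance %||% list()) {
    idx <- sort(match(unlist(rec$tests), panel$tests))
    at <- which(vapply(panel$dependent_pairs, identical, TRUE, as.integer(idx)))
    if (!length(at))
      stop("covariance entry for (", paste(rec$tests, collapse = ", "),
           ") does not match a dependent pair of the panel")
    lower[at] <- rec$lower %||% -1
    upper[at] <- rec$upper %||% 1
  }
  prior_set(panel, as_spec(y$prevalence, "prevalence"), se, sp, lower, upper)
}

#' @rdname read_priors
#' @param priors A [prior_set()] to serialize.
#' @export
write_priors <- function(priors, path) {
  stopifnot(inherits(priors, "blcda_priors"))
  ab <- function(s) c(s$alpha, s$beta)
  y <- list(
    prevalence = ab(priors$prevalence),
    sensitivity = lapply(priors$se, ab),
    specificity = lapply(priors$sp, ab),
    covariance = lapply(seq_along(priors$panel$dependent_pairs), function(i) {
      pr <- priors$panel$dependent_pairs[[i]]
      list(tests = as.list(priors$panel$tests[pr]),
           lower = priors$cov_lower[i], upper = priors$cov_upper[i])
    }))
  if (!length(y$covariance)) y$covariance <- NULL
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weakly informative accuracy priors
#'
#' The soft-identification prior set used by the package's simulation
#' recovery studies: every sensitivity and specificity gets the same Beta
#' prior with mode 0.90 and 5th percentile 0.70 ("the test is informative,
#' most likely around 90% accurate, very probably above 70%"), prevalence
#' is Uniform(0, 1), and covariances keep the nominal Uniform(-1, 1).
#'
#' A latent class model with a conditionally dependent pair has more
#' parameters than the count table has degrees of freedom, so fully flat
#' priors leave a ridge in the posterior and no amount of data pins the
#' accuracy parameters down; this prior supplies the minimal direction
#' information without favouring any particular test.
#'
#' @param panel A [test_panel()].
#' @return A [prior_set()].
#' @export
weakly_informative_priors <- function(panel) {
  acc <- elicit_beta(0.90, "mode", bound = 0.70, percentile = 0.05)
  prior_set(panel, beta_spec(1, 1),
            se = replicate(length(panel$tests), acc, simplify = FALSE),
            sp = replicate(length(panel$tests), acc, simplify = FALSE))
}
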