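#' Admissible covariance range for a conditionally dependent pair
#'
#' Within one latent class, two binary results with marginal success
#' probabilities `p_i` and `p_j` and additive covariance c have joint cell
#' probabilities `p_i p_j + c`, `p_i (1-p_j) - c`, `(1-p_i) p_j - c`,
#' `(1-p_i)(1-p_j) + c`. Requiring all four to be non-negative gives
#' `lower = max(-p_i p_j, -(1-p_i)(1-p_j))` and
#' `upper = min(p_i (1-p_j), (1-p_i) p_j)`, so the range always contains 0.
#'
#' For the diseased class the margins are the pair's sensitivities; for the
#' non-diseased class, passing the specificities gives the same range as
#' passing `1 - Sp` (the bounds are invariant under jointly complementing
#' both margins).
#'
#' @param p_i,p_j Marginal probabilities in `[0, 1]` (vectorized).
#' @return For scalar input, `c(lower, upper)`; for vector input a
#'   two-column matrix.
#' @examples
#' cov_bounds(0.5, 0.5)  # -0.25, 0.25
#' cov_bounds(0.9, 0.8)  # -0.02, 0.08
#' @export
cov_bounds <- function(p_i, p_j) {
  if (anyNA(p_i) || anyNA(p_j) || any(p_i < 0 | p_i > 1 | p_j < 0 | p_j > 1))
    stop("margins must be probabilities in [0, 1]")
  lower <- pmax(-p_i * p_j, -(1 - p_i) * (1 - p_j))
  upper <- pmin(p_i * (1 - p_j), (1 - p_i) * p_j)
  if (length(lower) == 1L) c(lower = lower, upper = upper)
  else cbind(lower = lower, upper = upper)
}

#' Parameters of the latent class accuracy model
#'
#' @param panel A [test_panel()].
#' @param prevalence True prevalence pi in `[0, 1]`.
#' @param se,sp Per-test sensitivities and specificities, in panel order or
#'   named by test.
#' @param cov_d,cov_n Per dependent pair, the additive covariance of the
#'   pair's results among the diseased (`cov_d`) and non-diseased (`cov_n`);
#'   default 0 (conditional independence). Must respect [cov_bounds()] of
#'   the pair's sensitivities resp. specificities.
#' @param validate If `TRUE` (default), reject covariances outside their
#'   admissible range at construction. `validate = FALSE` lets such points be
#'   represented so that density functions can score them (-Inf).
#' @return An object of class `blcda_params`.
#' @examples
#' accuracy_params(cognitive_panel(), 0.2,
#'                 se = c(0.9, 0.87, 0.92), sp = c(0.9, 0.92, 0.91),
#'                 cov_d = 0.03, cov_n = 0.02)
#' @export
accuracy_params <- function(panel, prevalence, se, sp, cov_d = 0, cov_n = 0,
                            validate = TRUE) {
  stopifnot(inherits(panel, "blcda_panel"))
  K <- length(panel$tests)
  P <- length(panel$dependent_pairs)
  fix <- function(x, what) {
    if (length(x) != K) stop("need one ", what, " per test")
    if (!is.null(names(x)) && any(nzchar(names(x)))) {
      if (!setequal(names(x), panel$tests))
        stop(what, " names do not match the panel")
      x <- x[panel$tests]
    }
    stats::setNames(as.numeric(x), panel$tests)
  }
  se <- fix(se, "sensitivity"); sp <- fix(sp, "specificity")
  probs <- c(prevalence, se, sp)
  if (anyNA(probs) || any(probs < 0 | probs > 1))
    stop("prevalence, se and sp must be probabilities in [0, 1]")
  cov_d <- rep(as.numeric(cov_d), length.out = max(P, 1L))[seq_len(P)]
  cov_n <- rep(as.numeric(cov_n), length.out = max(P, 1L))[seq_len(P)]
  for (i in seq_len(if (validate) P else 0L)) {
    pr <- panel$dependent_pairs[[i]]
    bd <- cov_bounds(se[pr[1]], se[pr[2]])
    bn <- cov_bounds(sp[pr[1]], sp[pr[2]])
    if (cov_d[i] < bd[1] - 1e-12 || cov_d[i] > bd[2] + 1e-12)
      stop(sprintf("cov_d[%d] = %g outside admissible (%g, %g)",
                   i, cov_d[i], bd[1], bd[2]))
    if (cov_n[i] < bn[1] - 1e-12 || cov_n[i] > bn[2] + 1e-12)
      stop(sprintf("cov_n[%d] = %g outside admissible (%g, %g)",
                   i, cov_n[i], bn[1], bn[2]))
  }
  structure(list(panel = panel, prevalence = as.numeric(prevalence),
                 se = se, sp = sp, cov_d = cov_d, cov_n = cov_n),
            class = "blcda_params")
}

#' @export
print.blcda_params <- function(x, ...) {
  cat(sprintf("Latent class parameters: prevalence %.4f\n", x$prevalence))
  for (t in x$panel$tests)
    cat(sprintf("  %-10s Se %.4f  Sp %.4f\n", t, x$se[t], x$sp[t]))
  for (i in seq_along(x$panel$dependent_pairs)) {
    pr <- x$panel$dependent_pairs[[i]]
    cat(sprintf("  cov %s--%s: diseased %.4f, non-diseased %.4f\n",
                x$panel$tests[pr[1]], x$panel$tests[pr[2]],
                x$cov_d[i], x$cov_n[i]))
  }
  invisible(x)
}

# Within-class probability of every result pattern given class margins
# m (probability of a positive result per test) and pair covariances cv:
# product of marginal terms, with each dependent pair's product replaced by
# m_i(t_i) m_j(t_j) + s(t_i, t_j) * cv, s = +1 when t_i == t_j else -1.
class_pattern_probs <- function(pm, m, pairs, cv) {
  term <- sweep(pm, 2, m, "*") + sweep(1 - pm, 2, 1 - m, "*")
  p <- rep(1, nrow(pm))
  in_pair <- integer(0)
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    s <- ifelse(pm[, pr[1]] == pm[, pr[2]], 1, -1)
    p <- p * (term[, pr[1]] * term[, pr[2]] + s * cv[i])
    in_pair <- c(in_pair, pr)
  }
  for (k in setdiff(seq_len(ncol(pm)), in_pair)) p <- p * term[, k]
  p
}

#' Cell probabilities of the joint test results
#'
#' Mixes the within-class pattern probabilities over the latent class:
#' `P(pattern) = pi * P(pattern | diseased) + (1 - pi) * P(pattern | healthy)`,
#' where within each class the dependent pair contributes
#' `margin_i margin_j + s * cov` (s = +1 when the pair's results agree,
#' -1 otherwise) and the remaining tests enter independently. Diseased-class
#' margins are `Se` for a positive result; non-diseased margins are `1 - Sp`.
#'
#' @param params An [accuracy_params()] object.
#' @return Named vector of 2^K probabilities in the [pattern_matrix()] order;
#'   they sum to 1.
#' @examples
#' p <- accuracy_params(cognitive_panel(), 0.5, se = c(0.8, 0.7, 0.9),
#'                      sp = c(0.9, 0.8, 0.95))
#' cell_probabilities(p)["111"]  # 0.2525
#' @export
cell_probabilities <- function(params) {
  stopifnot(inherits(params, "blcda_params"))
  pm <- pattern_matrix(length(params$panel$tests))
  pairs <- params$panel$dependent_pairs
  pd <- class_pattern_probs(pm, params$se, pairs, params$cov_d)
  pn <- class_pattern_probs(pm, 1 - params$sp, pairs, params$cov_n)
  p <- params$prevalence * pd + (1 - params$prevalence) * pn
  bad <- which(p < -1e-12)
  if (length(bad))
    stop("negative cell probability for pattern(s): ",
         paste(rownames(pm)[bad], collapse = ", "),
         " (covariance outside the admissible region)")
  stats::setNames(pmin(pmax(p, 0), 1), rownames(pm))
}

#' @rdname cell_probabilities
#' @param pattern A binary K-vector (or pattern string such as `"101"`).
#' @return `cell_probability()` returns the single probability of `pattern`.
#' @export
cell_probability <- function(params, pattern) {
  p <- cell_probabilities(params)
  key <- if (is.character(pattern)) pattern
         else paste(as.integer(pattern), collapse = "")
  if (!key %in% names(p)) stop("unknown pattern: ", key)
  unname(p[key])
}

#' Multinomial log-likelihood of a count table
#'
#' `sum(count_c * log P_c(params))` over the 2^K cells, omitting the
#' count-only multinomial coefficient (constant in the parameters). Cells
#' with zero count contribute exactly 0 whatever their probability; a cell
#' with positive count and zero probability yields `-Inf`.
#'
#' @param params An [accuracy_params()] object.
#' @param counts A [cross_counts()] object over the same panel.
#' @return A scalar log-likelihood.
#' @export
log_likelihood <- function(params, counts) {
  stopifnot(inherits(params, "blcda_params"), inherits(counts, "blcda_counts"))
  if (!identical(params$panel$tests, counts$panel$tests))
    stop("params and counts refer to different panels")
  p <- cell_probabilities(params)
  pos <- counts$counts > 0
  if (any(pos & p <= 0)) return(-Inf)
  sum(counts$counts[pos] * log(p[pos]))
}

#' Log posterior density of the latent class model
#'
#' Log-likelihood plus Beta log-densities for prevalence and each Se/Sp,
#' plus the covariance log-priors: each covariance contributes
#' `-log(upper - lower)` of its nominal uniform support while inside the
#' admissible region (and inside that support), and `-Inf` outside either.
#'
#' @inheritParams log_likelihood
#' @param priors A [prior_set()] over the same panel.
#' @return A scalar log-density (up to the constant multinomial coefficient).
#' @export
log_posterior <- function(params, counts, priors) {
  stopifnot(inherits(priors, "blcda_priors"))
  if (!identical(params$panel$tests, priors$panel$tests))
    stop("params and priors refer to different panels")
  lp <- 0
  for (i in seq_along(params$panel$dependent_pairs)) {
    pr <- params$panel$dependent_pairs[[i]]
    bd <- cov_bounds(params$se[pr[1]], params$se[pr[2]])
    bn <- cov_bounds(params$sp[pr[1]], params$sp[pr[2]])
    ok <- params$cov_d[i] >= max(bd[1], priors$cov_lower[i]) &&
          params$cov_d[i] <= min(bd[2], priors$cov_upper[i]) &&
          params$cov_n[i] >= max(bn[1], priors$cov_lower[i]) &&
          params$cov_n[i] <= min(bn[2], priors$cov_upper[i])
    if (!ok) return(-Inf)
    lp <- lp - log(priors$cov_upper[i] - priors$cov_lower[i]) * 2
  }
  lp <- lp + log_likelihood(params, counts)
  lp <- lp + stats::dbeta(params$prevalence, priors$prevalence$alpha,
                          priors$prevalence$beta, log = TRUE)
  for (t in params$panel$tests) {
    lp <- lp + stats::dbeta(params$se[[t]], priors$se[[t]]$alpha,
                            priors$se[[t]]$beta, log = TRUE)
    lp <- lp + stats::dbeta(params$sp[[t]], priors$sp[[t]]$alpha,
                            priors$sp[[t]]$beta, log = TRUE)
  }
  unname(lp)
}
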