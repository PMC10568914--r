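#' Youden's index
#'
#' `J = Se + Sp - 1`: 1 for a perfect test, 0 for an uninformative one.
#' Applied here to posterior mean sensitivity and specificity.
#'
#' @param se_mean,sp_mean Probabilities in `[0, 1]`.
#' @return `se_mean + sp_mean - 1`.
#' @examples
#' youden_index(0.922, 0.907)  # 0.829
#' @export
youden_index <- function(se_mean, sp_mean) {
  if (any(se_mean < 0 | se_mean > 1 | sp_mean < 0 | sp_mean > 1))
    stop("inputs must be probabilities in [0, 1]")
  se_mean + sp_mean - 1
}

#' Summarise posterior chains
#'
#' Pools retained draws across chains and reports, per parameter, the
#' posterior mean, median, equal-tailed 95% credible interval (2.5th and
#' 97.5th percentiles, type-7 quantiles) and effective sample size; plus,
#' per test, Youden's index computed from the posterior means of Se and Sp
#' (and, as an extra, the posterior mean and interval of the draw-wise
#' Se + Sp - 1).
#'
#' @param chains A `blcda_chains` object.
#' @param level Credible level (default 0.95, equal-tailed).
#' @return An object of class `blcda_summary`: list with `params` (a
#'   data.frame parameter/mean/median/lower/upper/ess), `youden` (per test),
#'   `config`, `panel`.
#' @export
summarize_posterior <- function(chains, level = 0.95) {
  stopifnot(inherits(chains, "blcda_chains"), level > 0, level < 1)
  draws <- as.matrix(chains)
  if (!nrow(draws)) stop("empty chains")
  a <- (1 - level) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(a, 0.5, 1 - a),
              names = FALSE)
  params <- data.frame(parameter = colnames(draws),
                       mean = unname(colMeans(draws)),
                       median = qs[2, ], lower = qs[1, ], upper = qs[3, ],
                       ess = vapply(seq_len(ncol(draws)), function(j)
                         ess(lapply(chains$draws, function(m)
                           m[, j, drop = FALSE])), 0),
                       row.names = NULL)
  tests <- chains$panel$tests
  se_m <- params$mean[match(paste0("se_", tests), params$parameter)]
  sp_m <- params$mean[match(paste0("sp_", tests), params$parameter)]
  jdraws <- draws[, paste0("se_", tests), drop = FALSE] +
    draws[, paste0("sp_", tests), drop = FALSE] - 1
  jq <- apply(jdraws, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  youden <- data.frame(test = tests,
                       youden = youden_index(se_m, sp_m),
                       draw_mean = unname(colMeans(jdraws)),
                       draw_lower = jq[1, ], draw_upper = jq[2, ],
                       row.names = NULL)
  structure(list(params = params, youden = youden, level = level,
                 config = chains$config, panel = chains$panel),
            class = "blcda_summary")
}

#' @export
print.blcda_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior summary (means and %g%% equal-tailed intervals)\n",
              100 * x$level))
  tab <- x$params
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  cat("\nYouden indices (from posterior mean Se, Sp):\n")
  yt <- x$youden[c("test", "youden")]
  yt$youden <- round(yt$youden, digits)
  print(yt, row.names = FALSE)
  invisible(x)
}

#' Posterior-predictive check of the cell counts
#'
#' For every cell of the observed table, the expected count `n * P_c` is
#' evaluated at each retained draw. Reported are the posterior mean expected
#' count and the fraction of draws whose expected count exceeds the observed
#' count; fractions near 0 or 1 flag cells the model cannot reproduce.
#'
#' @param chains A `blcda_chains` object.
#' @param counts The observed [cross_counts()]; defaults to the table the
#'   chains were fit to.
#' @return A data.frame with pattern, observed, expected (posterior mean)
#'   and `p_exceed`.
#' @export
posterior_predictive_cells <- function(chains, counts = chains$counts) {
  stopifnot(inherits(chains, "blcda_chains"), inherits(counts, "blcda_counts"))
  if (!identical(chains$panel$tests, counts$panel$tests))
    stop("chains and counts refer to different panels")
  draws <- as.matrix(chains)
  panel <- chains$panel
  K <- length(panel$tests); P <- length(panel$dependent_pairs)
  exp_counts <- matrix(NA_real_, nrow(draws), 2^K)
  for (d in seq_len(nrow(draws))) {
    th <- unname(draws[d, ])
    pars <- accuracy_params(panel, th[1], th[1 + 1:K], th[1 + K + 1:K],
                            cov_d = if (P) th[1 + 2 * K + seq_len(P)] else 0,
                            cov_n = if (P) th[1 + 2 * K + P + seq_len(P)] else 0,
                            validate = FALSE)
    exp_counts[d, ] <- counts$n * cell_probabilities(pars)
  }
  data.frame(pattern = names(counts$counts),
             observed = unname(counts$counts),
             expected = colMeans(exp_counts),
             p_exceed = colMeans(sweep(exp_counts, 2, counts$counts, ">")),
             row.names = NULL)
}

#' Combined results table for one or more analyses
#'
#' One row per (analysis, test, parameter) with posterior mean and interval,
#' plus a prevalence row per analysis and a Youden row per test; the layout
#' of a forest-plot style results figure, in machine-readable form.
#'
#' @param summaries A named list of [summarize_posterior()] results (names
#'   label the analyses, e.g. `list(AD = ..., MCI = ...)`).
#' @return An object of class `blcda_report`: data.frame with columns
#'   analysis, test, parameter, mean, lower, upper.
#' @export
accuracy_report <- function(summaries) {
  if (inherits(summaries, "blcda_summary")) summaries <- list(summaries)
  if (is.null(names(summaries)))
    names(summaries) <- paste0("analysis", seq_along(summaries))
  stopifnot(length(summaries) >= 1,
            all(vapply(summaries, inherits, TRUE, "blcda_summary")))
  rows <- lapply(names(summaries), function(an) {
    s <- summaries[[an]]
    p <- s$params
    pick <- function(name) p[match(name, p$parameter), ]
    out <- data.frame(analysis = an, test = "", parameter = "prevalence",
                      mean = pick("prev")$mean, lower = pick("prev")$lower,
                      upper = pick("prev")$upper)
    for (t in s$panel$tests) {
      for (role in c("se", "sp")) {
        r <- pick(paste0(role, "_", t))
        out <- rbind(out, data.frame(
          analysis = an, test = t,
          parameter = if (role == "se") "sensitivity" else "specificity",
          mean = r$mean, lower = r$lower, upper = r$upper))
      }
    }
    y <- s$youden
    out <- rbind(out, data.frame(analysis = an, test = y$test,
                                 parameter = "youden", mean = y$youden,
                                 lower = y$draw_lower, upper = y$draw_upper))
    out
  })
  structure(do.call(rbind, c(rows, list(make.row.names = FALSE))),
            class = c("blcda_report", "data.frame"))
}

#' Render a report and its results table to files
#'
#' Writes the machine-readable table as CSV at full precision and a
#' plain-text report including the MCMC protocol used.
#'
#' @param report An [accuracy_report()].
#' @param csv_path,txt_path Output paths (`NULL` to skip one of them).
#' @param configs Optional named list of [mcmc_config()]s to record.
#' @return The report, invisibly.
#' @export
write_report <- function(report, csv_path = NULL, txt_path = NULL,
                         configs = NULL) {
  stopifnot(inherits(report, "blcda_report"))
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w"); on.exit(close(con))
    writeLines("Latent class accuracy results", con)
    writeLines(strrep("=", 30), con)
    for (an in unique(report$analysis)) {
      writeLines(paste0("\n[", an, "]"), con)
      sub <- report[report$analysis == an, ]
      for (i in seq_len(nrow(sub))) {
        r <- sub[i, ]
        writeLines(sprintf("  %-10s %-12s %.3f (%.3f-%.3f)",
                           r$test, r$parameter, r$mean, r$lower, r$upper), con)
      }
      cfg <- configs[[an]]
      if (!is.null(cfg))
        writeLines(sprintf("  protocol: %d iterations, %d burn-in, thin %d, %d chain(s), seed %d",
                           cfg$iterations, cfg$burn_in, cfg$thin,
                           cfg$chains, cfg$seed), con)
    }
  }
  invisible(report)
}
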