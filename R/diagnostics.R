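# Sample autocorrelation, averaged across chains when several are given.
chain_list <- function(x) {
  if (inherits(x, "blcda_chains")) return(x$draws)
  if (is.numeric(x) && is.null(dim(x))) return(list(matrix(x, ncol = 1)))
  if (is.matrix(x)) return(list(x))
  if (is.list(x)) return(x)
  stop("cannot interpret ", class(x)[1], " as MCMC draws")
}

#' Effective sample size of one parameter's draws
#'
#' Uses the standard truncated autocorrelation sum: per chain,
#' `n / (1 + 2 * sum(rho_k))` with the sum cut at the first non-positive
#' autocorrelation; ESS is summed over chains.
#'
#' @param x Numeric vector of draws, or a matrix/list of per-chain vectors.
#' @return A scalar ESS.
#' @export
ess <- function(x) {
  chains <- chain_list(x)
  sum(vapply(chains, function(m) {
    v <- as.numeric(m)
    n <- length(v)
    if (n < 3L || stats::var(v) == 0) return(as.numeric(n))
    rho <- as.numeric(stats::acf(v, lag.max = min(n - 1L, 1000L),
                                 plot = FALSE)$acf)[-1]
    cut <- which(rho <= 0)
    if (length(cut)) rho <- rho[seq_len(cut[1] - 1L)]
    n / (1 + 2 * sum(rho))
  }, 0))
}

split_rhat <- function(chains_mat_list, j) {
  halves <- list()
  for (m in chains_mat_list) {
    v <- m[, j]
    h <- length(v) %/% 2L
    halves <- c(halves, list(v[seq_len(h)], v[h + seq_len(h)]))
  }
  n <- length(halves[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence diagnostics for posterior chains
#'
#' Reports the autocorrelation function at chosen lags, effective sample
#' sizes, per-chain trace summaries, and (when two or more chains were run)
#' the split-chain scale-reduction factor. The `converged` flag requires
#' ESS >= `min_ess` for every parameter and, when computable, scale
#' reduction < `max_rhat`.
#'
#' @param chains A `blcda_chains` object (or a draws matrix / list of them).
#' @param lags Lags at which to report the ACF.
#' @param min_ess,max_rhat Thresholds backing the `converged` flag.
#' @return A list of class `blcda_diagnostics` with elements `acf` (lags by
#'   parameters matrix), `ess`, `rhat` (NA with a single chain), `trace`
#'   (per chain and parameter mean/sd), `acceptance` (when available) and
#'   `converged`.
#' @export
diagnostics <- function(chains, lags = c(1L, 5L, 10L, 20L, 50L),
                        min_ess = 400, max_rhat = 1.05) {
  mats <- chain_list(chains)
  n <- nrow(mats[[1]])
  if (n < 1L) stop("empty chains")
  lags <- sort(unique(as.integer(lags)))
  if (max(lags) >= n)
    stop("chain of length ", n, " is too short for lag ", max(lags))
  npar <- ncol(mats[[1]])
  nm <- colnames(mats[[1]])
  if (is.null(nm)) nm <- paste0("par", seq_len(npar))

  acf_mat <- matrix(NA_real_, length(lags), npar,
                    dimnames = list(paste0("lag", lags), nm))
  for (j in seq_len(npar)) {
    per_chain <- vapply(mats, function(m) {
      if (stats::var(m[, j]) == 0) return(rep(0, length(lags)))
      a <- stats::acf(m[, j], lag.max = max(lags), plot = FALSE)$acf
      as.numeric(a)[lags + 1L]
    }, numeric(length(lags)))
    acf_mat[, j] <- rowMeans(matrix(per_chain, nrow = length(lags)))
  }

  ess_v <- vapply(seq_len(npar), function(j)
    ess(lapply(mats, function(m) m[, j, drop = FALSE])), 0)
  names(ess_v) <- nm

  rhat <- if (length(mats) >= 2L)
    stats::setNames(vapply(seq_len(npar), function(j)
      split_rhat(mats, j), 0), nm)
  else stats::setNames(rep(NA_real_, npar), nm)

  trace <- do.call(rbind, lapply(seq_along(mats), function(i)
    data.frame(chain = i, parameter = nm,
               mean = colMeans(mats[[i]]),
               sd = apply(mats[[i]], 2, stats::sd),
               row.names = NULL)))

  converged <- all(ess_v >= min_ess) &&
    (all(is.na(rhat)) || all(rhat < max_rhat, na.rm = TRUE))

  structure(list(acf = acf_mat, ess = ess_v, rhat = rhat, trace = trace,
                 acceptance = if (inherits(chains, "blcda_chains"))
                   chains$acceptance,
                 converged = converged),
            class = "blcda_diagnostics")
}

#' @export
print.blcda_diagnostics <- function(x, ...) {
  cat("ESS per parameter:\n"); print(round(x$ess, 1))
  if (!all(is.na(x$rhat))) {
    cat("Split-chain scale reduction:\n"); print(round(x$rhat, 3))
  }
  cat("Converged:", x$converged, "\n")
  invisible(x)
}
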