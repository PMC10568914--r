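#' Packaged example data: cross-classified counts and priors
#'
#' The package ships, as plain-text fixtures, the observed data of a
#' published three-test neuropsychological screening analysis: the
#' cross-classified MoCA/MMSE/ADAS-cog results of 1289 subjects dichotomized
#' at Alzheimer's-disease cutoffs (`"ad"`) and of the 1111-subject
#' MCI-vs-normal subsample at MCI cutoffs (`"mci"`), together with the
#' informative Beta priors used for each analysis and the Uniform(-1, 1)
#' covariance priors for the conditionally dependent MoCA-MMSE pair.
#'
#' @param analysis `"ad"` or `"mci"`.
#' @return `fixture_counts()` a [cross_counts()] table; `fixture_priors()` a
#'   [prior_set()]; `fixture_path()` the path of the underlying file.
#' @examples
#' fixture_counts("ad")$n   # 1289
#' fixture_priors("mci")
#' @export
fixture_counts <- function(analysis = c("ad", "mci")) {
  analysis <- match.arg(analysis)
  file <- c(ad = "table1_ad_counts.csv", mci = "table2_mci_counts.csv")[analysis]
  read_counts(fixture_path(file), cognitive_panel())
}

#' @rdname fixture_counts
#' @export
fixture_priors <- function(analysis = c("ad", "mci")) {
  analysis <- match.arg(analysis)
  file <- c(ad = "priors_ad.yaml", mci = "priors_mci.yaml")[analysis]
  read_priors(fixture_path(file), cognitive_panel())
}

#' @rdname fixture_counts
#' @param file Fixture file name.
#' @export
fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "blcda", mustWork = FALSE)
  if (!nzchar(p)) stop("no packaged fixture named ", file)
  p
}
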