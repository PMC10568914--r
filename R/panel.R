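#' Describe a battery of binary diagnostic tests
#'
#' A test panel records the tests whose joint results are cross-classified,
#' the direction in which each underlying score codes "positive", and which
#' pairs of tests are modelled as conditionally dependent within each latent
#' class.
#'
#' @param tests Character vector of unique test names, length K >= 2. The
#'   order fixes the pattern convention used throughout the package: test 1
#'   is the most significant bit of the result pattern (see
#'   [pattern_matrix()]).
#' @param positive_direction Per-test direction, `"lower"` if a low score
#'   codes positive (e.g. MoCA, MMSE) or `"higher"` (e.g. ADAS-cog).
#'   Recycled if length 1.
#' @param dependent_pairs List of length-2 vectors (test names or indices)
#'   naming pairs that are conditionally dependent given the latent class.
#'   Pairs are unordered, must not repeat, and must be disjoint (a test may
#'   appear in at most one pair).
#'
#' @return An object of class `blcda_panel`.
#' @examples
#' cognitive_panel()
#' test_panel(c("A", "B"), dependent_pairs = list(c("A", "B")))
#' @export
test_panel <- function(tests, positive_direction = "lower",
                       dependent_pairs = list()) {
  tests <- as.character(tests)
  if (length(tests) < 2L) stop("a panel needs at least two tests")
  if (anyDuplicated(tests)) stop("test names must be unique")
  positive_direction <- match.arg(rep(positive_direction,
                                      length.out = length(tests)),
                                  c("lower", "higher"), several.ok = TRUE)
  pairs <- lapply(dependent_pairs, function(p) {
    if (is.character(p)) p <- match(p, tests)
    p <- as.integer(p)
    if (length(p) != 2L || anyNA(p) || any(p < 1L | p > length(tests)) ||
        p[1] == p[2])
      stop("each dependent pair must name two distinct tests in the panel")
    sort(p)
  })
  if (length(pairs)) {
    key <- vapply(pairs, paste, "", collapse = ":")
    if (anyDuplicated(key)) stop("dependent pairs must not repeat")
    if (anyDuplicated(unlist(pairs)))
      stop("dependent pairs must be disjoint: a test may appear in one pair only")
  }
  structure(list(tests = tests,
                 positive_direction = stats::setNames(positive_direction, tests),
                 dependent_pairs = pairs),
            class = "blcda_panel")
}

#' @export
print.blcda_panel <- function(x, ...) {
  cat("Test panel (K =", length(x$tests), "):",
      paste(x$tests, collapse = ", "), "\n")
  for (p in x$dependent_pairs)
    cat("  conditionally dependent:", x$tests[p[1]], "--", x$tests[p[2]], "\n")
  invisible(x)
}

#' The MoCA / MMSE / ADAS-cog screening panel
#'
#' The three-test battery analysed in the packaged example data: MoCA and
#' MMSE score lower with impairment, ADAS-cog higher, and MoCA and MMSE are
#' modelled as conditionally dependent within each latent class.
#'
#' @return A `blcda_panel` with K = 3.
#' @export
cognitive_panel <- function() {
  test_panel(c("MoCA", "MMSE", "ADAS-cog"),
             positive_direction = c("lower", "lower", "higher"),
             dependent_pairs = list(c("MoCA", "MMSE")))
}

#' Result-pattern enumeration for K tests
#'
#' Patterns are ordered by descending binary value with test 1 as the most
#' significant bit: for K = 3 the rows are 111, 110, 101, 100, 011, 010,
#' 001, 000 (1 = positive). Pattern `(t1, ..., tK)` sits at row
#' `sum(t_k * 2^(K-k)) + 1` counting from the bottom, i.e. row
#' `2^K - sum(t_k * 2^(K-k))`.
#'
#' @param K Number of tests.
#' @return A `2^K` by `K` integer 0/1 matrix.
#' @examples
#' pattern_matrix(2)
#' @export
pattern_matrix <- function(K) {
  K <- as.integer(K)
  stopifnot(K >= 1L)
  m <- as.matrix(rev(expand.grid(rev(lapply(seq_len(K), function(i) 1:0)))))
  m <- matrix(as.integer(m), ncol = K,
              dimnames = list(apply(m, 1, paste, collapse = ""), NULL))
  m
}

#' Cross-classified test-result counts
#'
#' Bundles a panel with the 2^K multinomial cell counts of its joint test
#' results, in the fixed pattern order of [pattern_matrix()].
#'
#' @param panel A [test_panel()].
#' @param counts Non-negative integer vector of length 2^K in pattern order,
#'   optionally named by pattern strings such as `"101"` (names are checked
#'   when present).
#' @param n Expected total; defaults to `sum(counts)` and is verified.
#' @return An object of class `blcda_counts` with elements `panel`, `counts`
#'   (named) and `n`.
#' @examples
#' cross_counts(test_panel(c("A", "B")), c(10, 2, 3, 85))
#' @export
cross_counts <- function(panel, counts, n = sum(counts)) {
  stopifnot(inherits(panel, "blcda_panel"))
  K <- length(panel$tests)
  pm <- pattern_matrix(K)
  if (length(counts) != nrow(pm))
    stop("expected ", nrow(pm), " cell counts, got ", length(counts))
  if (anyNA(counts) || any(counts < 0))
    stop("cell counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("cell counts must be integers")
  counts <- as.integer(round(counts))
  if (!is.null(names(counts)) && !identical(names(counts), rownames(pm))) {
    if (!setequal(names(counts), rownames(pm)))
      stop("count names do not enumerate the ", nrow(pm), " patterns")
    counts <- counts[rownames(pm)]
  }
  names(counts) <- rownames(pm)
  if (sum(counts) != n)
    stop("counts sum to ", sum(counts), ", expected n = ", n)
  structure(list(panel = panel, counts = counts, n = as.integer(n)),
            class = "blcda_counts")
}

#' @export
print.blcda_counts <- function(x, ...) {
  cat("Cross-classified counts, n =", x$n, "\n")
  print(data.frame(pattern = names(x$counts), count = unname(x$counts)),
        row.names = FALSE)
  invisible(x)
}

#' Read a cross-classified count table
#'
#' The native long format is a CSV/TSV with one 0/1 column per test (named
#' as in the panel) and a `count` column, one row per pattern. The `wide`
#' format mirrors the 2 x 4 layout used for three-test tables in screening
#' reports: a first column with the 1/0 value of test 1 and four columns
#' named `11`, `10`, `01`, `00` giving the (test 2, test 3) result
#' combination.
#'
#' @param path File to read.
#' @param panel The [test_panel()] the table refers to.
#' @param format `"long"` (default) or `"wide"` (K = 3 only).
#' @param sep Field separator, `","` by default; `"\t"` for TSV.
#' @return A [cross_counts()] object.
#' @export
read_counts <- function(path, panel, format = c("long", "wide"), sep = ",") {
  stopifnot(inherits(panel, "blcda_panel"))
  format <- match.arg(format)
  K <- length(panel$tests)
  pm <- pattern_matrix(K)
  tab <- utils::read.csv(path, sep = sep, check.names = FALSE)
  if (format == "wide") {
    if (K != 3L) stop("wide format is defined for K = 3 panels only")
    need <- c("11", "10", "01", "00")
    if (!all(need %in% names(tab)) || nrow(tab) != 2L)
      stop("wide format needs 2 rows and columns 11, 10, 01, 00")
    row1 <- as.integer(tab[[1]])
    if (!setequal(row1, 0:1)) stop("first column must contain values 1 and 0")
    long <- expand.grid(t3 = 1:0, t2 = 1:0, t1 = 1:0)[, 3:1]
    long$count <- unlist(lapply(1:0, function(v) {
      as.numeric(tab[match(v, row1), need])
    }))
    names(long)[1:3] <- panel$tests
    tab <- long
  }
  if (!all(panel$tests %in% names(tab)) || !"count" %in% names(tab))
    stop("long format needs one column per test (",
         paste(panel$tests, collapse = ", "), ") and a 'count' column")
  res <- as.matrix(tab[panel$tests])
  if (anyNA(res) || !all(res %in% c(0, 1)))
    stop("test-result columns must be 0/1")
  pat <- apply(res, 1, paste, collapse = "")
  if (anyDuplicated(pat))
    stop("duplicate pattern row(s): ", paste(unique(pat[duplicated(pat)]),
                                             collapse = ", "))
  missing <- setdiff(rownames(pm), pat)
  if (length(missing))
    stop("missing pattern row(s): ", paste(missing, collapse = ", "))
  cnt <- tab$count[match(rownames(pm), pat)]
  bad <- which(is.na(cnt) | cnt < 0 | abs(cnt - round(cnt)) > 1e-8)
  if (length(bad))
    stop("invalid count in pattern row(s): ",
         paste(rownames(pm)[bad], collapse = ", "))
  cross_counts(panel, cnt)
}

#' Write a cross-classified count table
#'
#' Writes the long format understood by [read_counts()]; zero cells are
#' kept so that `read_counts(write_counts(x))` is the identity.
#'
#' @param counts A [cross_counts()] object.
#' @param path Output file.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, sep = ",") {
  stopifnot(inherits(counts, "blcda_counts"))
  pm <- pattern_matrix(length(counts$panel$tests))
  tab <- as.data.frame(pm)
  names(tab) <- counts$panel$tests
  tab$count <- unname(counts$counts)
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
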