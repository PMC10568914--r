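#' Continuous scores with reference labels
#'
#' @param scores Numeric score per subject.
#' @param labels Binary reference status per subject (0/1, logical, or a
#'   factor with two levels where the second is taken as diseased).
#' @param direction `"lower"` if a low score codes positive (MoCA/MMSE
#'   style) or `"higher"` (ADAS-cog style).
#' @return An object of class `blcda_scores`.
#' @export
score_panel <- function(scores, labels, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  scores <- as.numeric(scores)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length")
  if (anyNA(scores) || anyNA(labels) || !all(labels %in% 0:1))
    stop("labels must be binary and scores complete")
  if (length(unique(labels)) < 2L)
    stop("both classes must be represented")
  structure(list(scores = scores, labels = labels, direction = direction),
            class = "blcda_scores")
}

positive_calls <- function(panel, cutpoint) {
  if (panel$direction == "lower") panel$scores < cutpoint
  else panel$scores > cutpoint
}

se_sp_at <- function(panel, cutpoint) {
  pos <- positive_calls(panel, cutpoint)
  c(se = mean(pos[panel$labels == 1L]),
    sp = mean(!pos[panel$labels == 0L]))
}

#' Empirical ROC points of a score panel
#'
#' One candidate rule per midpoint between adjacent distinct observed
#' scores, plus the two extreme rules (everyone positive / everyone
#' negative, represented by infinite cutpoints). A subject is positive when
#' its score falls strictly on the positive side of the cutpoint, so
#' midpoints make the rule unambiguous for tied scores.
#'
#' @param panel A [score_panel()].
#' @return A data.frame with columns cutpoint, se, sp, youden, ordered with
#'   the positive region growing.
#' @export
roc_points <- function(panel) {
  stopifnot(inherits(panel, "blcda_scores"))
  u <- sort(unique(panel$scores))
  mids <- if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  cuts <- if (panel$direction == "lower") c(-Inf, mids, Inf)
          else c(Inf, mids, -Inf)
  acc <- t(vapply(cuts, se_sp_at, c(se = 0, sp = 0), panel = panel))
  data.frame(cutpoint = cuts, se = acc[, "se"], sp = acc[, "sp"],
             youden = acc[, "se"] + acc[, "sp"] - 1, row.names = NULL)
}

render_rule <- function(panel, cutpoint) {
  if (!is.finite(cutpoint)) {
    all_pos <- (panel$direction == "lower") == (cutpoint == Inf)
    return(if (all_pos) "all positive" else "all negative")
  }
  above <- panel$scores[panel$scores > cutpoint]
  thr <- if (length(above)) min(above) else cutpoint
  if (panel$direction == "lower") paste("<", format(thr))
  else paste(">=", format(thr))
}

#' Youden-optimal cutoff of a continuous score
#'
#' Selects the [roc_points()] rule maximizing Youden's index. Ties in the
#' maximal index are broken in favour of higher sensitivity, then of the
#' cutpoint extending the positive region furthest. The midpoint cutpoint is
#' canonical; the rendered decision rule uses the smallest observed score
#' strictly above the cutpoint, so an integer-scored test with cutpoint 21.5
#' renders as `"< 22"` under a lower-is-positive convention and a cutpoint
#' of 12.8 renders as `">= 13"` under higher-is-positive.
#'
#' @param panel A [score_panel()].
#' @return An object of class `blcda_cutoff`: list with `cutpoint`,
#'   `decision_rule`, `se`, `sp`, `youden`, `direction`.
#' @examples
#' p <- score_panel(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0), "lower")
#' optimal_cutoff(p)  # cutpoint 3.5, rule "< 4", youden 1
#' @export
optimal_cutoff <- function(panel) {
  stopifnot(inherits(panel, "blcda_scores"))
  roc <- roc_points(panel)
  best <- roc[roc$youden >= max(roc$youden) - 1e-12, ]
  best <- best[best$se >= max(best$se) - 1e-12, ]
  ext <- if (panel$direction == "lower") which.max(best$cutpoint)
         else which.min(best$cutpoint)
  best <- best[ext, ]
  structure(list(cutpoint = best$cutpoint,
                 decision_rule = render_rule(panel, best$cutpoint),
                 se = best$se, sp = best$sp, youden = best$youden,
                 direction = panel$direction),
            class = "blcda_cutoff")
}

#' @export
print.blcda_cutoff <- function(x, ...) {
  cat(sprintf("Optimal cutpoint %s (rule \"%s\", %s is positive): se %.3f, sp %.3f, Youden %.3f\n",
              format(x$cutpoint), x$decision_rule,
              if (x$direction == "lower") "low score" else "high score",
              x$se, x$sp, x$youden))
  invisible(x)
}

#' Read a two-column score file
#'
#' CSV with columns `score` and `label` (0/1).
#'
#' @param path File to read.
#' @param direction Passed to [score_panel()].
#' @return A [score_panel()].
#' @export
read_scores <- function(path, direction = c("lower", "higher")) {
  tab <- utils::read.csv(path)
  if (!all(c("score", "label") %in% names(tab)))
    stop("score file needs columns 'score' and 'label'")
  score_panel(tab$score, tab$label, match.arg(direction))
}
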