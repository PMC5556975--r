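#' Variable importance over primary and surrogate roles
#'
#' Sums, over every internal node, the SSE improvement attributable to each
#' predictor in its role as either the primary splitter (the node's realised
#' improvement) or a retained surrogate (the improvement the surrogate's own
#' split achieves on that node's cases). Raw sums are scaled so the best
#' performer scores 100 and the others decreasingly less; a predictor that
#' never splits and is never a surrogate scores 0. Because surrogates accrue
#' importance, a variable masked by a correlated competitor can rank highly
#' without ever appearing as a node splitter.
#'
#' @param tree An `rtree` from [grow_tree()].
#' @return A tibble with one row per predictor supplied to the tree:
#'   `predictor`, `raw_importance` (SSE units), `scaled_importance` (0-100),
#'   `rank` (ties share the smaller rank). For a root-only tree all
#'   importances are zero and no scaling is applied.
#' @export
#' @examples
#' d <- data.frame(y = c(rep(0, 10), rep(10, 10)),
#'                 a = rep(0:1, each = 10), b = rep(0:1, each = 10))
#' fit <- grow_tree(d, "y", c("a", "b"), cv = FALSE)
#' variable_importance(fit)   # b mirrors a through its surrogate role
variable_importance <- function(tree) {
  raw <- setNames(numeric(length(tree$predictors)), tree$predictors)
  for (node in tree$nodes) {
    if (is.null(node$split)) next
    raw[node$split$predictor] <- raw[node$split$predictor] +
      node$split$improvement
    for (s in node$surrogates) {
      raw[s$rule$predictor] <- raw[s$rule$predictor] + s$rule$improvement
    }
  }
  scaled <- if (max(raw) > 0) 100 * raw / max(raw) else raw
  tibble(
    predictor = names(raw),
    raw_importance = unname(raw),
    scaled_importance = unname(scaled),
    rank = as.integer(rank(-unname(raw), ties.method = "min"))
  ) %>%
    arrange(.data$rank, match(.data$predictor, tree$predictors))
}
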