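## Surrogate splits: backup rules that mimic the primary split's left/right
## assignment, used to route cases whose primary predictor is missing. The
## quality of a surrogate is Breiman's predictive association
##   lambda = (min(pL, pR) - (1 - agreement)) / min(pL, pR),
## where pL, pR are the primary split's left/right proportions and agreement is
## the fraction of cases (observed on both predictors) the surrogate sends to
## the same side as the primary. lambda <= 0 means the surrogate does no better
## than always guessing the majority side, and it is discarded.

## Best mimicking threshold for a numeric surrogate candidate.
## primary_left: logical vector; x: candidate values (no NAs).
best_mimic_numeric <- function(x, primary_left) {
  n <- length(x)
  if (n < 2L) return(NULL)
  o <- order(x, method = "radix")
  xs <- x[o]; ls <- primary_left[o]
  nl <- cumsum(ls)                       # primary-left cases within x <= cut
  i <- seq_len(n - 1L)
  tot_l <- nl[n]
  ## forward orientation: x <= t -> left
  match_fwd <- nl[i] + ((n - i) - (tot_l - nl[i]))
  valid <- xs[i] < xs[i + 1L]
  if (!any(valid)) return(NULL)
  match_rev <- n - match_fwd
  match_fwd[!valid] <- -1L; match_rev[!valid] <- -1L
  bf <- which.max(match_fwd); br <- which.max(match_rev)
  if (match_fwd[bf] >= match_rev[br]) {
    list(threshold = (xs[bf] + xs[bf + 1L]) / 2, matches = match_fwd[bf],
         reversed = FALSE)
  } else {
    list(threshold = (xs[br] + xs[br + 1L]) / 2, matches = match_rev[br],
         reversed = TRUE)
  }
}

## Best mimicking level subset for a categorical candidate: each level goes to
## the side it agrees with most often (exact optimum, ties to the left).
best_mimic_categorical <- function(x, primary_left) {
  x <- as.character(x)
  tab_l <- tapply(primary_left, x, sum)
  tab_n <- tapply(primary_left, x, length)
  lev <- names(tab_n)
  if (length(lev) < 2L) return(NULL)
  go_left <- tab_l >= (tab_n - tab_l)
  if (all(go_left) || !any(go_left)) return(NULL)  # degenerate: one side only
  matches <- sum(pmax(tab_l, tab_n - tab_l))
  list(left_categories = lev[go_left], matches = matches, reversed = FALSE)
}

#' Find surrogate splits for a primary split
#'
#' For every predictor other than the primary's, finds the binary split that
#' best mimics the primary split's left/right assignment of the node's cases,
#' scores it by Breiman's predictive association, and returns the surrogates
#' with positive association in decreasing order, truncated to
#' `controls$max_surrogates`. A surrogate identical to the primary splitter
#' attains association (and agreement) 1; a candidate that cannot beat the
#' majority-side baseline is discarded.
#'
#' @param data Data frame with the node's cases.
#' @param dependent Name of the dependent variable (used only to record each
#'   surrogate's own SSE improvement, the quantity that accrues to it in
#'   variable-importance scoring).
#' @param primary A `split_rule` as returned by [best_split()].
#' @param predictors Candidate predictor names (the primary's predictor is
#'   skipped automatically).
#' @param controls A [tree_controls()] object.
#'
#' @return A list of surrogate records, each with elements `rule`
#'   (a `split_rule` carrying the surrogate's own improvement), `association`,
#'   `agreement` and `reversed` (whether the rule's sides are swapped when
#'   routing). The list may be empty.
#' @export
find_surrogates <- function(data, dependent, primary, predictors,
                            controls = tree_controls()) {
  y <- data[[dependent]]
  px <- data[[primary$predictor]]
  pside <- rule_side(primary, px)
  obs <- !is.na(pside)
  if (!any(obs)) return(list())
  p_l <- mean(pside[obs] == "L")
  p_r <- 1 - p_l
  p_min <- min(p_l, p_r)
  if (p_min <= 0) return(list())
  max_s <- controls$max_surrogates
  if (is.null(max_s)) max_s <- max(length(predictors) - 1L, 0L)

  out <- list()
  for (p in setdiff(predictors, primary$predictor)) {
    x <- data[[p]]
    keep <- obs & !is.na(x)
    m <- sum(keep)
    if (m < 2L) next
    pl_vec <- pside[keep] == "L"
    cand <- if (is.numeric(x)) best_mimic_numeric(x[keep], pl_vec)
            else best_mimic_categorical(x[keep], pl_vec)
    if (is.null(cand)) next
    agreement <- cand$matches / m
    lambda <- (p_min - (1 - agreement)) / p_min
    if (lambda <= 0) next
    rule <- if (is.numeric(x)) {
      new_split_rule(p, "numeric-threshold", threshold = cand$threshold)
    } else {
      new_split_rule(p, "category-subset", left_categories = cand$left_categories)
    }
    rule$improvement <- rule_improvement(rule, x, y, reversed = cand$reversed)
    out[[length(out) + 1L]] <- list(rule = rule, association = lambda,
                                    agreement = agreement,
                                    reversed = isTRUE(cand$reversed))
  }
  if (!length(out)) return(out)
  ## decreasing association; ties keep the earlier predictor (stable order)
  ord <- order(-vapply(out, `[[`, numeric(1), "association"))
  head(out[ord], max_s)
}
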