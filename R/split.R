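## Least-squares split search.
##
## Impurity is within-node SSE (sum of squared deviations from the node mean),
## so the improvement of a binary split is sse(parent) - sse(left) - sse(right),
## computed over the cases on which the candidate predictor is observed.
## Candidate thresholds for numeric predictors are midpoints between
## consecutive distinct observed values; cases with value <= threshold go left.
## Categorical predictors use the exact least-squares shortcut: levels are
## ordered by their mean outcome and only the k-1 ordered cuts are scanned.

node_sse <- function(y) {
  if (length(y) == 0L) return(0)
  sum((y - mean(y))^2)
}

## Scan all admissible thresholds of a numeric predictor.
## Returns NULL or list(threshold, improvement, n_left, n_right).
scan_numeric <- function(x, y, min_child) {
  ok <- !is.na(x)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L || n < 2L * min_child) return(NULL)
  o <- order(x, method = "radix")
  xs <- x[o]; ys <- y[o]
  cs <- cumsum(ys); css <- cumsum(ys * ys)
  tot <- cs[n]; tot2 <- css[n]
  i <- seq_len(n - 1L)
  n_r <- n - i
  sse_l <- css[i] - cs[i]^2 / i
  sse_r <- (tot2 - css[i]) - (tot - cs[i])^2 / n_r
  sse_p <- tot2 - tot^2 / n
  imp <- sse_p - (sse_l + sse_r)
  valid <- (xs[i] < xs[i + 1L]) & (i >= min_child) & (n_r >= min_child)
  if (!any(valid)) return(NULL)
  imp[!valid] <- -Inf
  b <- which.max(imp)          # first maximum = smallest threshold (tie rule)
  list(threshold = (xs[b] + xs[b + 1L]) / 2,
       improvement = max(imp[b], 0),
       n_left = b, n_right = n - b)
}

## Scan ordered-level cuts of a categorical predictor.
## Returns NULL or list(left_categories, improvement, n_left, n_right).
scan_categorical <- function(x, y, min_child) {
  x <- as.character(x)
  ok <- !is.na(x)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L || n < 2L * min_child) return(NULL)
  mu <- vapply(split(y, x), mean, numeric(1))
  ## order levels by mean outcome, then lexicographically for determinism
  lev <- names(mu)[order(mu, names(mu), method = "radix")]
  k <- length(lev)
  if (k < 2L) return(NULL)
  cnt <- vapply(split(y, x)[lev], length, integer(1))
  s <- vapply(split(y, x)[lev], sum, numeric(1))
  s2 <- vapply(split(y, x)[lev], function(v) sum(v * v), numeric(1))
  cn <- cumsum(cnt); cs <- cumsum(s); cs2 <- cumsum(s2)
  tot_n <- cn[k]; tot <- cs[k]; tot2 <- cs2[k]
  i <- seq_len(k - 1L)
  n_l <- cn[i]; n_r <- tot_n - n_l
  sse_l <- cs2[i] - cs[i]^2 / n_l
  sse_r <- (tot2 - cs2[i]) - (tot - cs[i])^2 / n_r
  sse_p <- tot2 - tot^2 / tot_n
  imp <- sse_p - (sse_l + sse_r)
  valid <- (n_l >= min_child) & (n_r >= min_child)
  if (!any(valid)) return(NULL)
  imp[!valid] <- -Inf
  b <- which.max(imp)
  list(left_categories = lev[seq_len(b)],
       improvement = max(imp[b], 0),
       n_left = n_l[b], n_right = n_r[b])
}

new_split_rule <- function(predictor, kind, threshold = NULL,
                           left_categories = NULL, improvement = 0) {
  structure(
    list(predictor = predictor, kind = kind, threshold = threshold,
         left_categories = left_categories, improvement = improvement),
    class = "split_rule"
  )
}

#' @export
print.split_rule <- function(x, ...) {
  if (x$kind == "numeric-threshold") {
    cat(sprintf("%s <= %g (improvement %.4g)\n", x$predictor, x$threshold,
                x$improvement))
  } else {
    cat(sprintf("%s in {%s} (improvement %.4g)\n", x$predictor,
                paste(x$left_categories, collapse = ", "), x$improvement))
  }
  invisible(x)
}

#' Find the best least-squares split of a node
#'
#' Searches all predictors for the admissible binary split that maximises the
#' decrease in within-node SSE, the least-squares purity criterion. A split is
#' admissible when both children keep at least
#' `ceiling(min_child_fraction * n_root)` cases; a node is splittable only when
#' it holds at least `ceiling(min_parent_fraction * n_root)` cases and is not
#' pure. Ties in improvement are broken towards the predictor supplied earlier,
#' then towards the smaller threshold.
#'
#' Cases with the candidate predictor missing are set aside during the scan of
#' that predictor (the improvement is computed on the observed cases); a
#' predictor that is entirely missing is skipped.
#'
#' @param data A data frame holding the node's cases.
#' @param dependent Name of the numeric dependent variable (non-missing).
#' @param predictors Character vector of candidate predictor names.
#' @param controls A [tree_controls()] object.
#' @param n_root Size of the root sample the fractions refer to; defaults to
#'   `nrow(data)` (i.e. the node *is* the root).
#'
#' @return A `split_rule` (predictor, kind, threshold or left-category set,
#'   improvement in SSE units), or `NULL` when no admissible split exists.
#' @export
#' @examples
#' d <- data.frame(y = c(rep(0, 10), rep(10, 10)), x = rep(0:1, each = 10))
#' best_split(d, "y", "x", tree_controls())
best_split <- function(data, dependent, predictors,
                       controls = tree_controls(), n_root = nrow(data)) {
  missing_cols <- setdiff(c(dependent, predictors), names(data))
  if (length(missing_cols)) {
    abort(paste0("unknown column(s): ", paste(missing_cols, collapse = ", ")),
          class = "proshift_config_error")
  }
  y <- data[[dependent]]
  if (length(y) == 0L) return(NULL)
  if (anyNA(y)) abort("dependent variable has missing values",
                      class = "proshift_input_error")
  if (length(y) < min_parent_n(controls, n_root)) return(NULL)
  if (node_sse(y) <= .Machine$double.eps * length(y)) return(NULL)  # pure
  mc <- min_child_n(controls, n_root)

  best <- NULL
  for (p in predictors) {
    x <- data[[p]]
    if (all(is.na(x))) next
    cand <- if (is.numeric(x)) scan_numeric(x, y, mc) else scan_categorical(x, y, mc)
    if (is.null(cand) || cand$improvement <= 0) next
    if (is.null(best) || cand$improvement > best$improvement) {
      best <- cand
      best$predictor <- p
      best$kind <- if (is.numeric(x)) "numeric-threshold" else "category-subset"
    }
  }
  if (is.null(best)) return(NULL)
  new_split_rule(best$predictor, best$kind,
                 threshold = best$threshold,
                 left_categories = best$left_categories,
                 improvement = best$improvement)
}

## Side assignment for a split rule: "L"/"R"/NA per case.
rule_side <- function(rule, x, reversed = FALSE) {
  side <- if (rule$kind == "numeric-threshold") {
    ifelse(is.na(x), NA_character_, ifelse(x <= rule$threshold, "L", "R"))
  } else {
    xc <- as.character(x)
    ifelse(is.na(xc), NA_character_,
           ifelse(xc %in% rule$left_categories, "L", "R"))
  }
  if (reversed) side <- c(L = "R", R = "L")[side]
  unname(side)
}

## SSE improvement a given rule achieves on (x, y), over observed-x cases.
rule_improvement <- function(rule, x, y, reversed = FALSE) {
  side <- rule_side(rule, x, reversed)
  ok <- !is.na(side)
  if (!any(ok)) return(0)
  y <- y[ok]; side <- side[ok]
  max(node_sse(y) - node_sse(y[side == "L"]) - node_sse(y[side == "R"]), 0)
}
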