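## Tree growth. Nodes are numbered breadth-first with the root as node 0.
## Cases missing the primary splitter are routed by the first surrogate (in
## decreasing association order) whose predictor is observed; cases missing
## all surrogates too go with the larger child (ties to the left), so every
## case reaches exactly one terminal and child sizes always sum to the parent.

route_node <- function(node, data, rows) {
  side <- rule_side(node$split, data[[node$split$predictor]][rows])
  if (anyNA(side) && length(node$surrogates)) {
    for (s in node$surrogates) {
      nas <- which(is.na(side))
      if (!length(nas)) break
      s_side <- rule_side(s$rule, data[[s$rule$predictor]][rows[nas]],
                          reversed = s$reversed)
      side[nas] <- s_side
    }
  }
  if (anyNA(side)) {
    n_l <- sum(side == "L", na.rm = TRUE)
    n_r <- sum(side == "R", na.rm = TRUE)
    side[is.na(side)] <- if (n_r > n_l) "R" else "L"
  }
  list(left = rows[side == "L"], right = rows[side == "R"])
}

#' Grow a least-squares regression tree with surrogate splits
#'
#' Recursively partitions the data by improvement-maximising binary splits
#' (see [best_split()]), records surrogate splits at every internal node (see
#' [find_surrogates()]), and routes incomplete cases by primary, then
#' surrogate, then majority rule. Growth stops at pure nodes, nodes below the
#' minimum parent fraction, nodes with no admissible split, or `max_depth`.
#'
#' The root variance stored on the tree is the population (divide-by-n)
#' variance of the dependent variable, so that the resubstitution risk of a
#' root-only tree equals the root variance exactly and the explained-variance
#' statistic of [explained_variance()] is 1 minus risk over root variance.
#'
#' @param data Cohort data frame, one row per participant. Rows with a missing
#'   dependent value are dropped with a warning.
#' @param dependent Name of the numeric dependent variable (e.g. the total
#'   change score).
#' @param predictors Character vector of predictor names; order breaks ties.
#' @param controls A [tree_controls()] object.
#' @param root_split Optional predictor name on which the first (root) split
#'   is anchored, mirroring designs in which the sample is first classified by
#'   clinical status before the data-driven splits; the anchored split must
#'   still be admissible, otherwise the tree falls back to the best split.
#' @param cv Logical; also compute the ten-fold cross-validated risk via
#'   [cv_risk()] (seeded by `controls$seed`)? Default `TRUE`.
#'
#' @return An object of class `rtree`: a list with `nodes` (list of node
#'   records: `id`, `depth`, `n`, `mean`, `sse`, `split`, `surrogates`,
#'   `children`, `parent`), `dependent`, `predictors`, `controls`, `n_root`,
#'   `root_variance`, `risk_resubstitution`, and (when `cv`) `risk_cv`,
#'   `risk_cv_se`. Use [tidy()] / [glance()] for tabular views.
#' @export
#' @examples
#' d <- data.frame(y = c(rep(0, 10), rep(10, 10)), x = rep(c("a", "b"), each = 10))
#' fit <- grow_tree(d, "y", "x", tree_controls(cv_folds = 2), cv = FALSE)
#' glance(fit)
grow_tree <- function(data, dependent, predictors,
                      controls = tree_controls(), root_split = NULL,
                      cv = TRUE) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    abort("empty input table", class = "proshift_input_error")
  }
  missing_cols <- setdiff(c(dependent, predictors, root_split), names(data))
  if (length(missing_cols)) {
    abort(paste0("unknown column(s): ", paste(missing_cols, collapse = ", ")),
          class = "proshift_config_error")
  }
  if (!length(predictors)) {
    abort("at least one predictor is required", class = "proshift_input_error")
  }
  drop <- is.na(data[[dependent]])
  if (any(drop)) {
    warn(sprintf("dropping %d row(s) with missing dependent '%s'",
                 sum(drop), dependent))
    data <- data[!drop, , drop = FALSE]
    if (!nrow(data)) abort("no rows with observed dependent variable",
                           class = "proshift_input_error")
  }

  n_root <- nrow(data)
  y <- data[[dependent]]
  nodes <- list()
  ## FIFO queue of (id, rows, depth); ids are assigned at enqueue time, which
  ## yields breadth-first numbering with root = 0.
  queue <- list(list(id = 0L, rows = seq_len(n_root), depth = 0L, parent = NA_integer_))
  next_id <- 1L

  while (length(queue)) {
    item <- queue[[1L]]; queue <- queue[-1L]
    rows <- item$rows
    yy <- y[rows]
    node <- list(id = item$id, depth = item$depth, parent = item$parent,
                 n = length(rows), mean = mean(yy), sse = node_sse(yy),
                 split = NULL, surrogates = list(), children = NULL)

    can_split <- item$depth < controls$max_depth &&
      node$n >= min_parent_n(controls, n_root) &&
      node$sse > .Machine$double.eps * node$n
    if (can_split) {
      sub <- data[rows, , drop = FALSE]
      rule <- NULL
      if (item$id == 0L && !is.null(root_split)) {
        rule <- best_split(sub, dependent, root_split, controls, n_root = n_root)
      }
      if (is.null(rule)) {
        rule <- best_split(sub, dependent, predictors, controls, n_root = n_root)
      }
      if (!is.null(rule)) {
        node$split <- rule
        node$surrogates <- find_surrogates(sub, dependent, rule, predictors,
                                           controls)
        routed <- route_node(node, data, rows)
        node$children <- c(next_id, next_id + 1L)
        queue[[length(queue) + 1L]] <- list(id = next_id, rows = routed$left,
                                            depth = item$depth + 1L,
                                            parent = item$id)
        queue[[length(queue) + 1L]] <- list(id = next_id + 1L,
                                            rows = routed$right,
                                            depth = item$depth + 1L,
                                            parent = item$id)
        next_id <- next_id + 2L
      }
    }
    nodes[[item$id + 1L]] <- node
  }

  tree <- structure(
    list(nodes = nodes, dependent = dependent, predictors = predictors,
         controls = controls, root_split = root_split, n_root = n_root,
         root_variance = node_sse(y) / n_root,
         risk_resubstitution = tree_risk(nodes, n_root),
         risk_cv = NULL, risk_cv_se = NULL),
    class = "rtree"
  )
  if (cv && controls$cv_folds >= 2L && n_root >= controls$cv_folds) {
    cvr <- cv_risk(data, dependent, predictors, no_prune(controls),
                   root_split = root_split)
    tree$risk_cv <- cvr$risk_cv
    tree$risk_cv_se <- cvr$risk_cv_se
  }
  if (controls$prune) tree <- prune_1se(tree, data)
  tree
}

tree_risk <- function(nodes, n_root) {
  term <- Filter(function(nd) is.null(nd$children), nodes)
  sum(vapply(term, `[[`, numeric(1), "sse")) / n_root
}

terminal_ids <- function(tree) {
  vapply(Filter(function(nd) is.null(nd$children), tree$nodes), `[[`,
         integer(1), "id")
}

#' @export
print.rtree <- function(x, ...) {
  n_term <- length(terminal_ids(x))
  cat(sprintf("Regression tree: %s ~ %s\n", x$dependent,
              paste(x$predictors, collapse = " + ")))
  cat(sprintf("  n = %d, %d nodes (%d terminal), depth %d\n", x$n_root,
              length(x$nodes), n_term,
              max(vapply(x$nodes, `[[`, integer(1), "depth"))))
  cat(sprintf("  resubstitution risk = %.4g (root variance %.4g)\n",
              x$risk_resubstitution, x$root_variance))
  if (!is.null(x$risk_cv)) {
    cat(sprintf("  cross-validated risk = %.4g (SE %.4g)\n", x$risk_cv,
                x$risk_cv_se))
  }
  invisible(x)
}

## Route every row of `data` down the tree. Returns list(terminal = terminal
## node id per row, membership = list mapping node id -> row indices).
route_cases <- function(tree, data) {
  n <- nrow(data)
  membership <- vector("list", length(tree$nodes))
  membership[[1L]] <- seq_len(n)
  terminal <- integer(n)
  for (node in tree$nodes) {
    rows <- membership[[node$id + 1L]]
    if (is.null(rows)) rows <- integer(0)
    if (is.null(node$children)) {
      terminal[rows] <- node$id
      next
    }
    if (!length(rows)) {
      membership[[node$children[1L] + 1L]] <- integer(0)
      membership[[node$children[2L] + 1L]] <- integer(0)
      next
    }
    routed <- route_node(node, data, rows)
    membership[[node$children[1L] + 1L]] <- routed$left
    membership[[node$children[2L] + 1L]] <- routed$right
  }
  list(terminal = terminal, membership = membership)
}

#' Predict from a fitted regression tree
#'
#' Each case is routed to a terminal node (primary split, then surrogates in
#' decreasing association order, then majority rule) and receives that node's
#' mean of the dependent variable.
#'
#' @param object An `rtree` from [grow_tree()].
#' @param newdata Data frame of cases to predict.
#' @param ... Unused.
#' @return Numeric vector of terminal-node means, one per row of `newdata`.
#' @export
predict.rtree <- function(object, newdata, ...) {
  routed <- route_cases(object, newdata)
  means <- vapply(object$nodes, `[[`, numeric(1), "mean")
  means[routed$terminal + 1L]
}
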