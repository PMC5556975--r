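## Cost-complexity (weakest-link) pruning with the cross-validated 1-SE rule:
## the reported subtree is the smallest one whose CV risk is within
## `prune_se_factor` standard errors of the minimum CV risk. Pruning is off by
## default throughout the package, matching the convention of reporting the
## full tree so that small clusters with subtle shifts are not collapsed away.

no_prune <- function(controls) { controls$prune <- FALSE; controls }

## Per-node aggregates under a collapse pattern: number of effective leaves
## and summed terminal SSE beneath every node (nodes under a collapsed
## ancestor keep NA).
collapse_stats <- function(nodes, collapsed) {
  n <- length(nodes)
  leaves <- rep(NA_real_, n); sse_under <- rep(NA_real_, n)
  for (i in rev(seq_len(n))) {          # ids are BFS, so children come later
    nd <- nodes[[i]]
    if (is.null(nd$children) || collapsed[i]) {
      leaves[i] <- 1; sse_under[i] <- nd$sse
    } else {
      l <- nd$children[1L] + 1L; r <- nd$children[2L] + 1L
      leaves[i] <- leaves[l] + leaves[r]
      sse_under[i] <- sse_under[l] + sse_under[r]
    }
  }
  list(leaves = leaves, sse_under = sse_under)
}

## TRUE for nodes living under (strictly below) a collapsed node.
below_collapsed <- function(nodes, collapsed) {
  out <- logical(length(nodes))
  for (nd in nodes) {
    if (!is.na(nd$parent)) {
      p <- nd$parent + 1L
      out[nd$id + 1L] <- out[p] || collapsed[p]
    }
  }
  out
}

## Collapse weakest links while their link strength g <= beta.
## g(t) = (R(t) - R(T_t)) / (leaves(T_t) - 1), in risk (SSE/n_root) units.
prune_to_beta <- function(nodes, n_root, beta, collapsed = NULL) {
  if (is.null(collapsed)) collapsed <- logical(length(nodes))
  eps <- 1e-12
  repeat {
    st <- collapse_stats(nodes, collapsed)
    hidden <- below_collapsed(nodes, collapsed)
    g <- rep(NA_real_, length(nodes))
    for (nd in nodes) {
      i <- nd$id + 1L
      if (is.null(nd$children) || collapsed[i] || hidden[i]) next
      g[i] <- (nd$sse - st$sse_under[i]) / n_root / (st$leaves[i] - 1)
    }
    if (all(is.na(g))) break
    m <- min(g, na.rm = TRUE)
    if (m > beta + eps) break
    collapsed[!is.na(g) & g <= m + eps] <- TRUE
  }
  collapsed
}

## Sequence of weakest-link alphas and collapse patterns, from the full tree
## down to the root.
alpha_sequence <- function(nodes, n_root) {
  collapsed <- logical(length(nodes))
  seqs <- list(list(alpha = 0, collapsed = collapsed))
  eps <- 1e-12
  repeat {
    st <- collapse_stats(nodes, collapsed)
    hidden <- below_collapsed(nodes, collapsed)
    g <- rep(NA_real_, length(nodes))
    for (nd in nodes) {
      i <- nd$id + 1L
      if (is.null(nd$children) || collapsed[i] || hidden[i]) next
      g[i] <- (nd$sse - st$sse_under[i]) / n_root / (st$leaves[i] - 1)
    }
    if (all(is.na(g))) break
    m <- min(g, na.rm = TRUE)
    collapsed[!is.na(g) & g <= m + eps] <- TRUE
    seqs[[length(seqs) + 1L]] <- list(alpha = m, collapsed = collapsed)
  }
  seqs
}

## Predict treating collapsed nodes as terminals.
predict_collapsed <- function(tree, data, collapsed) {
  n <- nrow(data)
  membership <- vector("list", length(tree$nodes))
  membership[[1L]] <- seq_len(n)
  pred <- numeric(n)
  for (node in tree$nodes) {
    rows <- membership[[node$id + 1L]]
    if (is.null(rows)) rows <- integer(0)
    if (is.null(node$children) || collapsed[node$id + 1L]) {
      pred[rows] <- node$mean
      next
    }
    if (!length(rows)) next
    routed <- route_node(node, data, rows)
    membership[[node$children[1L] + 1L]] <- routed$left
    membership[[node$children[2L] + 1L]] <- routed$right
  }
  pred
}

## Rebuild an rtree keeping only nodes not strictly below a collapse point,
## with fresh breadth-first ids.
materialize_pruned <- function(tree, collapsed) {
  keep_sub <- function(old_id) {
    nd <- tree$nodes[[old_id + 1L]]
    nd_new <- nd
    if (collapsed[old_id + 1L] || is.null(nd$children)) {
      nd_new$split <- NULL; nd_new$surrogates <- list(); nd_new$children <- NULL
    }
    nd_new
  }
  ## BFS over the retained structure
  out <- list()
  queue <- list(list(old = 0L, parent = NA_integer_, depth = 0L))
  next_id <- 1L; i <- 1L
  ids <- integer(0)
  while (i <= length(queue)) {
    item <- queue[[i]]
    nd <- keep_sub(item$old)
    new_id <- i - 1L
    nd$id <- new_id; nd$parent <- item$parent; nd$depth <- item$depth
    if (!is.null(nd$children)) {
      old_children <- tree$nodes[[item$old + 1L]]$children
      nd$children <- c(next_id, next_id + 1L)
      queue[[length(queue) + 1L]] <- list(old = old_children[1L],
                                          parent = new_id, depth = item$depth + 1L)
      queue[[length(queue) + 1L]] <- list(old = old_children[2L],
                                          parent = new_id, depth = item$depth + 1L)
      next_id <- next_id + 2L
    }
    out[[new_id + 1L]] <- nd
    i <- i + 1L
  }
  tree$nodes <- out
  tree$risk_resubstitution <- tree_risk(out, tree$n_root)
  tree
}

#' Prune a regression tree by the cross-validated 1-SE rule
#'
#' Builds the weakest-link cost-complexity subtree sequence of the fitted
#' tree, estimates each subtree's risk by seeded k-fold cross-validation
#' (growing and pruning a tree inside every fold, matching subtrees across
#' folds through the geometric means of consecutive complexity parameters),
#' and returns the smallest subtree whose CV risk is within
#' `prune_se_factor` standard errors of the minimum. When the tree's controls
#' have `prune = FALSE` the input tree is returned unchanged, unless `force`
#' is set.
#'
#' @param tree An `rtree` from [grow_tree()].
#' @param data The data frame the tree was fitted on.
#' @param force Prune even when the tree's controls say `prune = FALSE`.
#' @return An `rtree` (possibly the input, unchanged). A pruned tree carries
#'   the CV risk curve in `attr(, "cv_curve")`.
#' @export
prune_1se <- function(tree, data, force = FALSE) {
  if (!tree$controls$prune && !force) return(tree)
  seqs <- alpha_sequence(tree$nodes, tree$n_root)
  K <- length(seqs)
  if (K == 1L) return(tree)              # root-only tree
  alphas <- vapply(seqs, `[[`, numeric(1), "alpha")
  betas <- c(sqrt(alphas[-K] * alphas[-1L]), Inf)

  controls <- no_prune(tree$controls)
  n <- nrow(data)
  k_folds <- min(controls$cv_folds, n)
  folds <- cv_fold_assignment(data[[tree$dependent]], k_folds,
                              controls$seed, controls$stratify_folds)
  sq_err <- matrix(0, nrow = n, ncol = K)
  for (f in seq_len(k_folds)) {
    test <- folds == f
    fit <- grow_tree(data[!test, , drop = FALSE], tree$dependent,
                     tree$predictors, controls, root_split = tree$root_split,
                     cv = FALSE)
    collapsed <- NULL
    for (k in seq_len(K)) {
      collapsed <- prune_to_beta(fit$nodes, fit$n_root, betas[k], collapsed)
      pred <- predict_collapsed(fit, data[test, , drop = FALSE], collapsed)
      sq_err[test, k] <- (data[[tree$dependent]][test] - pred)^2
    }
  }
  risk_cv <- colMeans(sq_err)
  se_cv <- apply(sq_err, 2L, stats::sd) / sqrt(n)
  best <- which.min(risk_cv)
  chosen <- max(which(risk_cv <= risk_cv[best] +
                        tree$controls$prune_se_factor * se_cv[best]))
  pruned <- materialize_pruned(tree, seqs[[chosen]]$collapsed)
  pruned$risk_cv <- risk_cv[chosen]
  pruned$risk_cv_se <- se_cv[chosen]
  attr(pruned, "cv_curve") <- tibble(
    subtree = seq_len(K), alpha = alphas, beta = betas,
    n_leaves = vapply(seqs, function(s) {
      sum(collapse_stats(tree$nodes, s$collapsed)$leaves[1L])
    }, numeric(1)),
    risk_cv = risk_cv, risk_cv_se = se_cv, selected = seq_len(K) == chosen
  )
  pruned
}
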