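#' Control parameters for regression-tree growth
#'
#' The defaults mirror the usual CRT specification for small quality-of-life
#' trials: a node may be split only when it holds at least 10% of the root
#' sample, children must keep at least 5%, trees are validated by ten-fold
#' cross-validation, and the full (unpruned) tree is reported unless pruning
#' is switched on, in which case the 1-SE cost-complexity rule is applied.
#'
#' Minimum node sizes are fractions of the root sample converted with
#' `ceiling()` (10% of 75 participants means nodes of fewer than 8 cases are
#' not split).
#'
#' @param min_parent_fraction Minimum node size, as a fraction of the root
#'   sample, for a node to be considered for splitting. Default 0.10.
#' @param min_child_fraction Minimum size of each child, as a fraction of the
#'   root sample. Default 0.05. Must satisfy
#'   `0 < min_child_fraction <= min_parent_fraction < 1`.
#' @param cv_folds Number of cross-validation folds (>= 2). Default 10.
#' @param prune Logical; apply 1-SE cost-complexity pruning? Default `FALSE`
#'   (the full tree is reported).
#' @param prune_se_factor Multiple of the standard error used by the pruning
#'   rule. Default 1 (the 1-SE rule).
#' @param max_surrogates Maximum number of surrogate splits retained per node.
#'   Default: number of predictors minus one.
#' @param max_depth Maximum tree depth (root = depth 0). Default `Inf`.
#' @param seed Integer seed driving fold assignment (and nothing else).
#' @param stratify_folds Logical; if `TRUE`, folds are balanced across
#'   outcome quantiles instead of assigned by plain random shuffling.
#'   Default `FALSE`.
#'
#' @return A list of class `tree_controls`.
#' @export
#' @examples
#' tree_controls(min_parent_fraction = 0.1, cv_folds = 10)
tree_controls <- function(min_parent_fraction = 0.10,
                          min_child_fraction = 0.05,
                          cv_folds = 10L,
                          prune = FALSE,
                          prune_se_factor = 1,
                          max_surrogates = NULL,
                          max_depth = Inf,
                          seed = 42L,
                          stratify_folds = FALSE) {
  if (!(min_child_fraction > 0 && min_child_fraction <= min_parent_fraction &&
        min_parent_fraction < 1)) {
    abort("need 0 < min_child_fraction <= min_parent_fraction < 1",
          class = "proshift_config_error")
  }
  if (cv_folds < 2) {
    abort("cv_folds must be >= 2", class = "proshift_config_error")
  }
  if (!is.null(max_surrogates) && max_surrogates < 0) {
    abort("max_surrogates must be >= 0", class = "proshift_config_error")
  }
  structure(
    list(
      min_parent_fraction = min_parent_fraction,
      min_child_fraction = min_child_fraction,
      cv_folds = as.integer(cv_folds),
      prune = isTRUE(prune),
      prune_se_factor = prune_se_factor,
      max_surrogates = max_surrogates,
      max_depth = max_depth,
      seed = as.integer(seed),
      stratify_folds = isTRUE(stratify_folds)
    ),
    class = "tree_controls"
  )
}

min_parent_n <- function(controls, n_root) ceiling(controls$min_parent_fraction * n_root)
min_child_n <- function(controls, n_root) ceiling(controls$min_child_fraction * n_root)
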