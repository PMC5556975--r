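#' Tidy a regression tree into a node table
#'
#' @param x An `rtree`.
#' @param ... Unused.
#' @return A tibble with one row per node: ids, structure, node statistics
#'   and the primary split (predictor, kind, threshold or left categories,
#'   improvement) plus the surrogate count.
#' @exportS3Method generics::tidy
#' @export
tidy.rtree <- function(x, ...) {
  purrr::map_dfr(x$nodes, function(nd) {
    tibble(
      node_id = nd$id,
      parent = nd$parent,
      depth = nd$depth,
      terminal = is.null(nd$children),
      n = nd$n,
      mean = nd$mean,
      sse = nd$sse,
      split_predictor = if (is.null(nd$split)) NA_character_
                        else nd$split$predictor,
      split_kind = if (is.null(nd$split)) NA_character_ else nd$split$kind,
      threshold = if (!is.null(nd$split) &&
                        nd$split$kind == "numeric-threshold") {
        nd$split$threshold
      } else NA_real_,
      left_categories = list(if (!is.null(nd$split)) nd$split$left_categories),
      improvement = if (is.null(nd$split)) NA_real_ else nd$split$improvement,
      n_surrogates = length(nd$surrogates),
      child_left = if (is.null(nd$children)) NA_integer_ else nd$children[1L],
      child_right = if (is.null(nd$children)) NA_integer_ else nd$children[2L]
    )
  })
}

#' One-row model summary of a regression tree
#'
#' @param x An `rtree`.
#' @param ... Unused.
#' @return A tibble with the sample size, tree size, resubstitution and
#'   cross-validated risks, root variance, and the error/explained variance
#'   proportions.
#' @exportS3Method generics::glance
#' @export
glance.rtree <- function(x, ...) {
  fit <- explained_variance(x$risk_resubstitution, x$root_variance)
  tibble(
    n = x$n_root,
    n_nodes = length(x$nodes),
    n_terminal = length(terminal_ids(x)),
    depth = max(vapply(x$nodes, `[[`, integer(1), "depth")),
    risk_resubstitution = x$risk_resubstitution,
    risk_cv = x$risk_cv %||% NA_real_,
    risk_cv_se = x$risk_cv_se %||% NA_real_,
    root_variance = x$root_variance,
    error_variance = fit$error_variance,
    explained_variance = fit$explained_variance
  )
}
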