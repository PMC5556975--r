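## Delimited-text I/O for cohort tables and structured tree exports.

#' Read a cohort table from delimited text
#'
#' One row per participant, header row, empty cells as missing. When a column
#' map is supplied, the mapped source columns must exist (validated before any
#' computation) and are renamed to the package's canonical names; mapped score
#' columns must parse as numbers, and a failing cell is reported with its row.
#'
#' @param path Path to the file.
#' @param col_map Optional named character vector `c(canonical = "source")`
#'   renaming input columns to canonical names.
#' @param delim Field delimiter. Default `","`.
#' @param numeric_cols Columns (canonical names) checked to be numeric;
#'   default: every mapped column except `id`, `arm`, and `dh_week8`.
#' @return A tibble; per-column missingness is reported via `message()`.
#' @export
read_cohort <- function(path, col_map = NULL, delim = ",",
                        numeric_cols = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "proshift_input_error")
  }
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           na = c("", "NA"), progress = FALSE)
  if (!is.null(col_map)) {
    missing_cols <- setdiff(unname(col_map), names(tab))
    if (length(missing_cols)) {
      abort(paste0("mapped column(s) absent from header: ",
                   paste(missing_cols, collapse = ", ")),
            class = "proshift_config_error")
    }
    names(tab)[match(unname(col_map), names(tab))] <- names(col_map)
    if (is.null(numeric_cols)) {
      numeric_cols <- setdiff(names(col_map), c("id", "arm", "dh_week8"))
    }
  }
  for (col in intersect(numeric_cols, names(tab))) {
    if (is.numeric(tab[[col]])) next
    parsed <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.na(tab[[col]]) & is.na(parsed))
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' in column '%s', data row %d",
                    tab[[col]][bad[1L]], col, bad[1L]),
            class = "proshift_input_error")
    }
    tab[[col]] <- parsed
  }
  n_miss <- vapply(tab, function(x) sum(is.na(x)), integer(1))
  if (any(n_miss > 0)) {
    message("missing values per column: ",
            paste(sprintf("%s=%d", names(n_miss)[n_miss > 0],
                          n_miss[n_miss > 0]), collapse = ", "))
  }
  tab
}

#' Write a cohort to delimited text
#'
#' For a [simulate_trial()] result the participant table is written to
#' `path`; the per-tooth evidence and the hidden truth labels go to sidecar
#' files (`*_teeth.csv`, `*_truth.csv`) so the analysis input never carries
#' the generator's ground truth.
#'
#' @param cohort A data frame or `synthetic_cohort`.
#' @param path Output path for the participant table.
#' @param sidecars Write the teeth/truth sidecars for synthetic cohorts?
#'   Default `TRUE`.
#' @param delim Field delimiter. Default `","`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sidecars = TRUE, delim = ",") {
  p <- if (inherits(cohort, "synthetic_cohort")) cohort$participants
       else as_tibble(cohort)
  readr::write_delim(p, path, delim = delim, na = "")
  if (inherits(cohort, "synthetic_cohort") && sidecars) {
    stem <- sub("\\.[A-Za-z0-9]+$", "", path)
    readr::write_delim(cohort$teeth, paste0(stem, "_teeth.csv"), delim = delim,
                       na = "")
    readr::write_delim(cohort$truth, paste0(stem, "_truth.csv"), delim = delim,
                       na = "")
  }
  invisible(path)
}

split_to_list <- function(rule) {
  if (is.null(rule)) return(NULL)
  out <- list(predictor = rule$predictor, kind = rule$kind,
              improvement = rule$improvement)
  if (rule$kind == "numeric-threshold") out$threshold <- rule$threshold
  else out$left_categories <- as.list(rule$left_categories)
  out
}

#' Export a tree as structured text (JSON)
#'
#' One object per node carrying `id`, `n`, `mean`, `sse`, the split rule,
#' the surrogate list (rule, association, agreement) and the child ids, plus
#' a header with the fit-level quantities.
#'
#' @param tree An `rtree`.
#' @param path Optional path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
export_tree <- function(tree, path = NULL) {
  nodes <- lapply(tree$nodes, function(nd) {
    list(id = nd$id, depth = nd$depth, n = nd$n, mean = nd$mean,
         sse = nd$sse, split = split_to_list(nd$split),
         surrogates = lapply(nd$surrogates, function(s) {
           list(rule = split_to_list(s$rule), association = s$association,
                agreement = s$agreement, reversed = s$reversed)
         }),
         children = if (is.null(nd$children)) NULL else as.list(nd$children))
  })
  obj <- list(dependent = tree$dependent, predictors = as.list(tree$predictors),
              n = tree$n_root, root_variance = tree$root_variance,
              risk_resubstitution = tree$risk_resubstitution,
              risk_cv = tree$risk_cv, risk_cv_se = tree$risk_cv_se,
              nodes = nodes)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA,
                           pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Render a tree in DOT (graphviz) format
#'
#' @param tree An `rtree`.
#' @param path Optional path to write the DOT source to.
#' @return The DOT source as a character scalar, invisibly when `path` is
#'   given.
#' @export
tree_to_dot <- function(tree, path = NULL) {
  lines <- c("digraph tree {", "  node [shape=box, fontname=\"Helvetica\"];")
  for (nd in tree$nodes) {
    label <- sprintf("node %d\\nn = %d\\nmean = %.2f", nd$id, nd$n, nd$mean)
    lines <- c(lines, sprintf("  n%d [label=\"%s\"];", nd$id, label))
    if (!is.null(nd$split)) {
      cond <- if (nd$split$kind == "numeric-threshold") {
        sprintf("%s <= %.4g", nd$split$predictor, nd$split$threshold)
      } else {
        sprintf("%s in {%s}", nd$split$predictor,
                paste(nd$split$left_categories, collapse = ","))
      }
      lines <- c(lines,
                 sprintf("  n%d -> n%d [label=\"%s\"];", nd$id,
                         nd$children[1L], cond),
                 sprintf("  n%d -> n%d [label=\"otherwise\"];", nd$id,
                         nd$children[2L]))
    }
  }
  dot <- paste(c(lines, "}"), collapse = "\n")
  if (is.null(path)) return(dot)
  writeLines(dot, path)
  invisible(dot)
}
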