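#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis: where the cohort comes from
#' (a file or the synthetic generator), the tree specification, the MID, and
#' the optional output directory. All referenced columns are validated
#' against the input header before any computation.
#'
#' @param input Path to a cohort file, a data frame, or `NULL` to simulate
#'   with `generator`.
#' @param generator A [generator_config()] used when `input` is `NULL`.
#' @param dependent Dependent variable. Default `"total_change"`.
#' @param predictors Predictors; default clinical status plus the five
#'   subscale change scores.
#' @param root_split Predictor anchoring the first split; default
#'   `"dh_week8"`, mirroring the design in which the sample is first
#'   classified by clinical status. Set `NULL` for a fully data-driven root.
#' @param controls A [tree_controls()].
#' @param mid Minimally important difference. Default 22.
#' @param status Clinical-status column. Default `"dh_week8"`.
#' @param col_map Optional column map for [read_cohort()].
#' @param then_cols,ideals_cols Length-2 character vectors naming the
#'   (then, pre) and (ideal follow-up, ideal baseline) columns, or `NULL` to
#'   skip the contrast.
#' @param output_dir Directory for the report bundle files, or `NULL` to
#'   return results only.
#' @param seed Seed recorded in the manifest and passed to the generator /
#'   fold assignment.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            generator = generator_config(),
                            dependent = "total_change",
                            predictors = c("dh_week8",
                                           paste0(dheq_subscales, "_change")),
                            root_split = "dh_week8",
                            controls = tree_controls(),
                            mid = 22,
                            status = "dh_week8",
                            col_map = NULL,
                            then_cols = c("then_total", "total_screening"),
                            ideals_cols = c("ideal_total_week8",
                                            "ideal_total_screening"),
                            output_dir = NULL,
                            seed = 42L) {
  if (mid <= 0) abort("mid must be positive", class = "proshift_config_error")
  structure(
    list(input = input, generator = generator, dependent = dependent,
         predictors = predictors, root_split = root_split,
         controls = controls, mid = mid, status = status, col_map = col_map,
         then_cols = then_cols, ideals_cols = ideals_cols,
         output_dir = output_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `controls` and
#' `generator` may be nested maps of [tree_controls()] / [generator_config()]
#' arguments. Keys not present keep their defaults.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after the file (flags win over the file).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  raw[names(over)] <- over
  if (!is.null(raw$controls) && !inherits(raw$controls, "tree_controls")) {
    raw$controls <- do.call(tree_controls, raw$controls)
  }
  if (!is.null(raw$generator) &&
      !inherits(raw$generator, "generator_config")) {
    raw$generator <- do.call(generator_config, raw$generator)
  }
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "proshift_stage_error", parent = e)
  })
}

#' Run the end-to-end response-shift pipeline
#'
#' Loads or simulates the cohort, grows the (optionally status-anchored)
#' regression tree on the change score, computes variable importance, the
#' per-node response-shift summary, participant-level recalibration labels,
#' the model-fit statistics and — when the columns are present — the
#' then-test and ideals contrasts plus the total-change one-sample test.
#' With an output directory set, the bundle (tree JSON, DOT source,
#' importance, node summary, labels, design statistics, run manifest) is
#' written as delimited text / JSON; reruns with the same configuration and
#' seed are identical.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `rs_pipeline` with elements `cohort`, `tree`,
#'   `importance`, `node_summary`, `recalibration`, `fit`, `design_tests`,
#'   `manifest` (and `pruned_tree` when pruning is on).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- stage("load", {
    if (is.null(config$input)) {
      gen <- config$generator
      if (is.null(gen$seed)) gen$seed <- config$seed
      simulate_trial(gen)$participants
    } else if (is.data.frame(config$input)) {
      as_tibble(config$input)
    } else {
      read_cohort(config$input, col_map = config$col_map)
    }
  })
  if (nrow(cohort) < 2L) {
    warn("cohort has fewer than two participants; outputs are degenerate")
  }
  needed <- unique(c(config$dependent, config$predictors, config$status,
                     config$root_split))
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("configured column(s) absent from cohort: ",
                 paste(missing_cols, collapse = ", ")),
          class = "proshift_config_error")
  }

  controls <- config$controls
  controls$seed <- config$seed
  tree <- stage("fit", {
    ctl <- controls; ctl$prune <- FALSE
    grow_tree(cohort, config$dependent, config$predictors, ctl,
              root_split = config$root_split)
  })
  pruned <- NULL
  if (controls$prune) {
    pruned <- stage("prune", prune_1se(tree, cohort, force = TRUE))
  }
  reported <- if (is.null(pruned)) tree else pruned
  imp <- stage("importance", variable_importance(reported))
  nodes <- stage("shift", node_rs_summary(reported, cohort,
                                          status = config$status,
                                          mid = config$mid))
  recal <- stage("shift", classify_recalibration(cohort,
                                                 status = config$status,
                                                 change = config$dependent,
                                                 mid = config$mid))
  fit <- stage("fit_stats", model_fit(reported))

  design <- list()
  design$total_change <- stage("design", recalibration_test(
    cohort[[config$dependent]][!is.na(cohort[[config$dependent]])],
    contrast = "total_change"))
  if (!is.null(config$then_cols) &&
      all(config$then_cols %in% names(cohort)) &&
      sum(stats::complete.cases(cohort[config$then_cols])) >= 2L) {
    design$then_test <- stage("design", then_test(cohort, config$then_cols[1L],
                                                  config$then_cols[2L]))
  }
  if (!is.null(config$ideals_cols) &&
      all(config$ideals_cols %in% names(cohort)) &&
      sum(stats::complete.cases(cohort[config$ideals_cols])) >= 2L) {
    design$ideals <- stage("design", ideals_test(cohort,
                                                 config$ideals_cols[1L],
                                                 config$ideals_cols[2L]))
  }

  manifest <- list(
    package = "proshift",
    version = as.character(utils::packageVersion("proshift")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    dependent = config$dependent,
    predictors = config$predictors,
    root_split = config$root_split,
    mid = config$mid,
    controls = unclass(controls),
    input = if (is.null(config$input)) "synthetic"
            else if (is.data.frame(config$input)) "in-memory"
            else config$input,
    generator = if (is.null(config$input)) {
      g <- unclass(config$generator)
      if (is.null(g$seed)) g$seed <- config$seed
      lapply(g, function(v) if (is.null(v)) NA else v)
    } else NULL
  )

  bundle <- structure(
    list(cohort = cohort, tree = tree, pruned_tree = pruned,
         importance = imp, node_summary = nodes, recalibration = recal,
         fit = fit, design_tests = bind_rows(design), manifest = manifest),
    class = "rs_pipeline"
  )
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) readr::write_csv(x, file.path(dir, f), na = "")
  w(bundle$cohort, "cohort.csv")
  export_tree(bundle$tree, file.path(dir, "tree.json"))
  tree_to_dot(bundle$tree, file.path(dir, "tree.dot"))
  if (!is.null(bundle$pruned_tree)) {
    export_tree(bundle$pruned_tree, file.path(dir, "tree_pruned.json"))
    curve <- attr(bundle$pruned_tree, "cv_curve")
    if (!is.null(curve)) w(curve, "cv_curve.csv")
  }
  w(bundle$importance, "importance.csv")
  w(bundle$node_summary, "node_summary.csv")
  w(bundle$recalibration, "recalibration.csv")
  w(bundle$fit, "model_fit.csv")
  if (nrow(bundle$design_tests)) w(bundle$design_tests, "design_tests.csv")
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.rs_pipeline <- function(x, ...) {
  cat("Response-shift pipeline result\n")
  cat(sprintf("  cohort: %d participants\n", nrow(x$cohort)))
  print(x$tree)
  cat(sprintf("  explained variance: %.1f%%\n",
              100 * x$fit$explained_variance))
  down <- x$recalibration
  cat(sprintf("  recalibration: %.1f%% downward, %.1f%% upward (MID %g)\n",
              100 * mean(down$rs_direction == "downward"),
              100 * mean(down$rs_direction == "upward"),
              down$rs_mid[1L]))
  invisible(x)
}
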