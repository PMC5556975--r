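## Operationalization of response shift for dentine hypersensitivity (DH):
## recalibration is read off discordance between week-8 clinical DH status and
## the direction of the DHEQ total change score, judged against the DHEQ's
## minimally important difference (MID) of 22 points; reprioritization is read
## off changes in the importance ranks of the five subscales between trees
## anchored at the two time points.

dh_levels <- c("DH-", "DH+")

#' Classify clinical dentine-hypersensitivity status from per-tooth evidence
#'
#' A tooth is sensitive when its tactile threshold is at most 20 g (Yeaple
#' probe) and its evaporative Schiff score is at least 2. A participant is
#' DH-positive when at least two *non-adjacent* sensitive teeth are present.
#' Teeth are identified by FDI two-digit numbers; adjacency means the same
#' quadrant and consecutive tooth numbers, so e.g. 14 and 25 (different
#' quadrants) are never adjacent while 14 and 15 are.
#'
#' @param teeth Data frame of per-tooth evidence with columns `position`
#'   (FDI two-digit integer), `tactile_g` (grams, positive), `schiff`
#'   (integer 0-3), and optionally `id` identifying the participant. With an
#'   `id` column the classification is per participant; otherwise the whole
#'   table is treated as one participant's dentition.
#' @param tactile_max Sensitivity threshold for the tactile stimulus, in
#'   grams. Default 20.
#' @param schiff_min Sensitivity threshold for the Schiff score. Default 2.
#'
#' @return A tibble with one row per participant: `id` (when supplied),
#'   `dh_status` (factor `"DH+"`/`"DH-"`), `n_sensitive`.
#' @export
#' @examples
#' teeth <- data.frame(position = c(14, 25), tactile_g = c(15, 15), schiff = c(2, 2))
#' classify_clinical_status(teeth)   # non-adjacent quadrants: DH+
classify_clinical_status <- function(teeth, tactile_max = 20, schiff_min = 2) {
  teeth <- as_tibble(teeth)
  req <- c("position", "tactile_g", "schiff")
  missing_cols <- setdiff(req, names(teeth))
  if (length(missing_cols)) {
    abort(paste0("teeth table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "proshift_config_error")
  }
  if (any(!teeth$schiff %in% 0:3)) {
    abort("schiff scores must lie in 0..3", class = "proshift_input_error")
  }
  if (any(teeth$tactile_g <= 0)) {
    abort("tactile thresholds must be positive grams",
          class = "proshift_input_error")
  }
  if (!"id" %in% names(teeth)) teeth$id <- 1L
  out <- teeth %>%
    group_by(.data$id) %>%
    summarise(
      n_sensitive = sum(.data$tactile_g <= tactile_max &
                          .data$schiff >= schiff_min),
      dh_positive = has_nonadjacent_pair(
        .data$position[.data$tactile_g <= tactile_max &
                         .data$schiff >= schiff_min]),
      .groups = "drop"
    ) %>%
    mutate(dh_status = factor(ifelse(.data$dh_positive, "DH+", "DH-"),
                              levels = dh_levels)) %>%
    select("id", "dh_status", "n_sensitive")
  out
}

## Any pair of FDI positions in different quadrants, or in the same quadrant
## with tooth numbers differing by more than one?
has_nonadjacent_pair <- function(positions) {
  positions <- unique(as.integer(positions))
  if (length(positions) < 2L) return(FALSE)
  quad <- positions %/% 10L
  num <- positions %% 10L
  for (i in seq_along(positions)[-1L]) {
    for (j in seq_len(i - 1L)) {
      if (quad[i] != quad[j] || abs(num[i] - num[j]) > 1L) return(TRUE)
    }
  }
  FALSE
}

#' Classify recalibration from clinical status and the total change score
#'
#' Applies the discordance rules: a participant with clinical DH at follow-up
#' whose total score *fell* has shifted internal standards downward; a
#' participant without clinical DH whose total score *rose* has shifted them
#' upward. Concordant participants are labelled `none`, either
#' `consistent_improved` (no DH, score fell or unchanged) or
#' `consistent_worse` (DH present, score rose or unchanged). The `important`
#' flag marks changes of at least `mid` points in absolute value; note that
#' the direction labels do not require exceeding the MID, which is reported
#' separately so either convention can be applied.
#'
#' @param data Data frame with one row per participant.
#' @param status Column holding week-8 clinical status (`"DH+"`/`"DH-"`,
#'   character or factor). Default `dh_week8`.
#' @param change Column holding the total change score (follow-up minus
#'   screening; negative = better quality of life). Default `total_change`.
#' @param mid Minimally important difference in score points. Default 22.
#'
#' @return The input with columns `rs_direction` (`downward`/`upward`/`none`),
#'   `rs_consistency` (`shifted`/`consistent_improved`/`consistent_worse`),
#'   `rs_important` (logical) and `rs_mid` appended.
#' @export
classify_recalibration <- function(data, status = "dh_week8",
                                   change = "total_change", mid = 22) {
  if (mid <= 0) abort("mid must be positive", class = "proshift_config_error")
  missing_cols <- setdiff(c(status, change), names(data))
  if (length(missing_cols)) {
    abort(paste0("unknown column(s): ", paste(missing_cols, collapse = ", ")),
          class = "proshift_config_error")
  }
  st <- as.character(data[[status]])
  bad <- !is.na(st) & !st %in% dh_levels
  if (any(bad)) {
    abort(paste0("clinical status must be 'DH+' or 'DH-'; found: ",
                 paste(unique(st[bad]), collapse = ", ")),
          class = "proshift_input_error")
  }
  ch <- data[[change]]
  as_tibble(data) %>%
    mutate(
      rs_direction = factor(case_when(
        st == "DH+" & ch < 0 ~ "downward",
        st == "DH-" & ch > 0 ~ "upward",
        TRUE ~ "none"
      ), levels = c("downward", "upward", "none")),
      rs_consistency = factor(case_when(
        st == "DH+" & ch < 0 ~ "shifted",
        st == "DH-" & ch > 0 ~ "shifted",
        st == "DH-" ~ "consistent_improved",
        TRUE ~ "consistent_worse"
      ), levels = c("shifted", "consistent_improved", "consistent_worse")),
      rs_important = abs(ch) >= mid,
      rs_mid = mid
    )
}

#' Per-node response-shift summary of a fitted tree
#'
#' Routes the cohort down the tree and summarises every node (internal and
#' terminal): size, share of the root sample, mean change score, the
#' recalibration composition of its members and the share whose change meets
#' the MID. This supports statements of the form "X% of the sample sits in a
#' downward-shift node with changes beyond the MID".
#'
#' @param tree An `rtree` fitted with the change score as dependent variable.
#' @param data The cohort the tree was fitted on (must carry the status
#'   column).
#' @inheritParams classify_recalibration
#' @return A tibble with one row per node: `node_id`, `terminal`, `n`,
#'   `pct_of_sample`, `mean_change`, `pct_downward`, `pct_upward`,
#'   `pct_consistent`, `pct_important`, `pct_downward_important`,
#'   `modal_label`.
#' @export
node_rs_summary <- function(tree, data, status = "dh_week8", mid = 22) {
  if (!status %in% names(data)) {
    abort(paste0("status column '", status, "' not found"),
          class = "proshift_input_error")
  }
  lab <- classify_recalibration(data, status = status,
                                change = tree$dependent, mid = mid)
  routed <- route_cases(tree, data)
  ch <- data[[tree$dependent]]
  rows_of <- routed$membership
  purrr::map_dfr(tree$nodes, function(node) {
    rows <- rows_of[[node$id + 1L]]
    n <- length(rows)
    dirs <- lab$rs_direction[rows]
    tibble(
      node_id = node$id,
      terminal = is.null(node$children),
      n = n,
      pct_of_sample = 100 * n / tree$n_root,
      mean_change = if (n) mean(ch[rows]) else NA_real_,
      pct_downward = if (n) 100 * mean(dirs == "downward") else NA_real_,
      pct_upward = if (n) 100 * mean(dirs == "upward") else NA_real_,
      pct_consistent = if (n) 100 * mean(dirs == "none") else NA_real_,
      pct_important = if (n) 100 * mean(lab$rs_important[rows]) else NA_real_,
      pct_downward_important = if (n) {
        100 * mean(dirs == "downward" & lab$rs_important[rows])
      } else NA_real_,
      modal_label = if (n) names(which.max(table(dirs))) else NA_character_
    )
  })
}

#' Model-fit statistics: explained and error variance
#'
#' For a scale dependent variable the tree's risk estimate is the within-node
#' variance; divided by the root-node (population) variance it gives the
#' proportion of variance due to error, and one minus that is the proportion
#' of variance the tree explains.
#'
#' @param risk_value Within-node variance of the reported tree
#'   (resubstitution risk), >= 0.
#' @param root_variance Population variance of the dependent variable at the
#'   root, > 0.
#' @return A one-row tibble: `risk_value`, `root_variance`, `error_variance`,
#'   `explained_variance`.
#' @export
#' @examples
#' explained_variance(214.268, 1018.822)   # error 0.21, explained 0.79
explained_variance <- function(risk_value, root_variance) {
  if (!is.numeric(root_variance) || root_variance <= 0) {
    abort("root_variance must be positive", class = "proshift_input_error")
  }
  if (risk_value < 0) {
    abort("risk_value must be non-negative", class = "proshift_input_error")
  }
  err <- risk_value / root_variance
  tibble(risk_value = risk_value, root_variance = root_variance,
         error_variance = err, explained_variance = 1 - err)
}

#' Model fit of a fitted tree
#'
#' Convenience wrapper applying [explained_variance()] to a tree's own
#' resubstitution risk and root variance.
#'
#' @param tree An `rtree`.
#' @return See [explained_variance()]; with CV columns appended when present.
#' @export
model_fit <- function(tree) {
  out <- explained_variance(tree$risk_resubstitution, tree$root_variance)
  out$risk_cv <- tree$risk_cv %||% NA_real_
  out$risk_cv_se <- tree$risk_cv_se %||% NA_real_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reprioritization report from two importance tables
#'
#' Joins the variable-importance tables of trees anchored at two time points
#' and flags every predictor whose rank changed; both scaled scores are kept
#' so the magnitude of the reordering stays visible. Which dependent/predictor
#' configuration anchors each time point is the caller's design choice.
#'
#' @param imp_t1,imp_t2 Importance tables from [variable_importance()]
#'   covering the same predictor set.
#' @return A tibble: `predictor`, `rank_t1`, `rank_t2`, `scaled_t1`,
#'   `scaled_t2`, `rank_delta` (= `rank_t1 - rank_t2`), `flagged`.
#' @export
reprioritization_report <- function(imp_t1, imp_t2) {
  if (!setequal(imp_t1$predictor, imp_t2$predictor)) {
    abort("importance tables cover different predictor sets",
          class = "proshift_input_error")
  }
  imp_t1 %>%
    select("predictor", rank_t1 = "rank", scaled_t1 = "scaled_importance") %>%
    left_join(
      imp_t2 %>%
        select("predictor", rank_t2 = "rank",
               scaled_t2 = "scaled_importance"),
      by = "predictor"
    ) %>%
    mutate(rank_delta = .data$rank_t1 - .data$rank_t2,
           flagged = .data$rank_delta != 0L) %>%
    arrange(.data$rank_t1)
}
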