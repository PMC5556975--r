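#' DHEQ instrument model
#'
#' The Dentine Hypersensitivity Experience Questionnaire has 34 items scored
#' on a 7-point Likert scale across five subscales (restrictions, coping,
#' social, emotional, identity); higher scores mean worse quality of life.
#'
#' @param n_items Number of items. Default 34.
#' @param scale_min,scale_max Item response range. Defaults 1 and 7.
#' @return Named numeric vector `c(min = , max = )` of achievable totals
#'   (34 to 238 for the standard instrument).
#' @export
#' @examples
#' dheq_range()
dheq_range <- function(n_items = 34L, scale_min = 1L, scale_max = 7L) {
  c(min = n_items * scale_min, max = n_items * scale_max)
}

#' @rdname dheq_range
#' @format `dheq_subscales` names the five DHEQ subscales in their standard
#'   order.
#' @export
dheq_subscales <- c("restrictions", "coping", "social", "emotional",
                    "identity")
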