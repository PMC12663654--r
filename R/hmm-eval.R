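#' Sensitivity and precision of a domain HMM
#'
#' Scores a detection set against labeled positive and negative protein
#' sets, per taxonomic group and overall. True positives are positives
#' present in the detection set; false negatives are positives missed;
#' false positives are negatives detected; true negatives are negatives
#' not detected. Sensitivity (recall) is `TP / (TP + FN)`; precision
#' `TP / (TP + FP)` is reported only when `TP + FP > 0` and is `NA`
#' (undefined) otherwise. Percentages are given to one decimal (rounded
#' half-up).
#'
#' @param detections Character vector of detected protein ids (at the
#'   caller's search threshold; this function never runs the search).
#' @param truth Tibble with columns `id`, `label` (`"positive"` /
#'   `"negative"`) and optionally `group` (taxonomic group). Positive and
#'   negative sets must be disjoint.
#' @return Tibble with one row per group plus an `overall` row: `group`,
#'   `tp`, `fn`, `fp`, `tn`, `sensitivity_pct`, `precision_pct`.
#' @export
#' @examples
#' truth <- tibble::tibble(id = letters[1:6],
#'                         label = rep(c("positive", "negative"), each = 3))
#' evaluate_detection(c("a", "b"), truth)
evaluate_detection <- function(detections, truth) {
  stopifnot(all(c("id", "label") %in% names(truth)),
            all(truth$label %in% c("positive", "negative")))
  pos <- truth$id[truth$label == "positive"]
  neg <- truth$id[truth$label == "negative"]
  if (length(intersect(pos, neg)) > 0L) {
    stop("positive and negative sets overlap", call. = FALSE)
  }
  if (!"group" %in% names(truth)) truth$group <- "all"
  score <- function(df) {
    p <- df$id[df$label == "positive"]
    n <- df$id[df$label == "negative"]
    tp <- sum(p %in% detections)
    fn <- length(p) - tp
    fp <- sum(n %in% detections)
    tn <- length(n) - fp
    tibble::tibble(
      tp = tp, fn = fn, fp = fp, tn = tn,
      sensitivity_pct = if (tp + fn > 0) {
        round_half_up(100 * tp / (tp + fn), 1)
      } else NA_real_,
      precision_pct = if (tp + fp > 0) {
        round_half_up(100 * tp / (tp + fp), 1)
      } else NA_real_
    )
  }
  per_group <- truth |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ score(.x)) |>
    dplyr::ungroup()
  empty <- per_group$group[per_group$tp + per_group$fn == 0]
  if (length(empty) > 0L) {
    message("group(s) with empty positive set (sensitivity undefined): ",
            paste(empty, collapse = ", "))
  }
  dplyr::bind_rows(per_group,
                   dplyr::mutate(score(truth), group = "overall")) |>
    dplyr::relocate("group")
}
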