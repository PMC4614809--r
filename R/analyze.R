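.one_model_mode <- function(records, what) {
  if (dplyr::n_distinct(records$model) != 1) {
    stop(what, " expects records from a single model", call. = FALSE)
  }
  if (dplyr::n_distinct(records$mode) != 1) {
    stop(what, " expects records from a single axis mode", call. = FALSE)
  }
  invisible(records)
}

# first strict sign change along the flexion-extension grid; exact zeros
# between opposite signs count as a crossing at the zero itself
.find_crossing <- function(fe, r) {
  s <- sign(r)
  nz <- which(s != 0)
  if (length(nz) < 2) return(NULL)
  flips <- which(s[nz[-1]] != s[nz[-length(nz)]])
  if (length(flips) == 0) return(NULL)
  i <- nz[flips[1]]; j <- nz[flips[1] + 1]
  if (j > i + 1) {
    # zeros sit between the bracketing nonzero values
    mean(fe[(i + 1):(j - 1)])
  } else {
    fe[i] + (fe[j] - fe[i]) * r[i] / (r[i] - r[j])
  }
}

#' Classify muscle function over a sweep
#'
#' Assigns each muscle x degree-of-freedom a functional label from its
#' normalized moment arms across the flexion-extension grid:
#' `obligatory-positive` if above `+epsilon` at every posture (e.g. an
#' obligatory extensor / adductor / lateral rotator), `obligatory-negative`
#' if below `-epsilon` everywhere, `switching` if the sign changes between
#' adjacent grid postures (the crossing angle is linearly interpolated
#' between the bracketing pair), and `negligible` if the magnitude never
#' reaches `epsilon`. Muscles that flirt with zero on one side only (never
#' crossing `-epsilon`, say) are labelled with the side they act on.
#'
#' @param records `marm_records` for one model and one mode, covering at
#'   least two postures per muscle x dof.
#' @param epsilon Negligibility threshold on the normalized moment arm
#'   (femur lengths), default 0.005.
#' @return A tibble of class `marm_labels` with columns `model, muscle, dof,
#'   label, crossing_angle_deg, min_norm, max_norm` (`crossing_angle_deg` is
#'   `NA` unless `label == "switching"`).
#' @export
#' @examples
#' toy <- make_hinge_toy()
#' rec <- run_sweep(toy, sweep_protocol(abd_offset = 0))
#' classify_function(rec)
classify_function <- function(records, epsilon = 0.005) {
  .one_model_mode(records, "classify_function()")
  if (!is.finite(epsilon) || epsilon < 0) {
    stop("`epsilon` must be a nonnegative number", call. = FALSE)
  }
  grp <- dplyr::group_by(dplyr::arrange(records, .data$fe_deg),
                         .data$model, .data$muscle, .data$dof)
  sizes <- dplyr::summarise(grp, n = dplyr::n(), .groups = "drop")
  if (any(sizes$n < 2)) {
    stop("classification needs >= 2 postures per muscle and dof",
         call. = FALSE)
  }
  out <- dplyr::summarise(
    grp,
    label = {
      r <- .data$moment_arm_norm
      if (max(abs(r)) < epsilon) "negligible"
      else if (all(r > epsilon)) "obligatory-positive"
      else if (all(r < -epsilon)) "obligatory-negative"
      else if (!is.null(.find_crossing(.data$fe_deg, r))) "switching"
      else if (min(r) > -epsilon) "obligatory-positive"
      else "obligatory-negative"
    },
    crossing_angle_deg = {
      cr <- .find_crossing(.data$fe_deg, .data$moment_arm_norm)
      if (is.null(cr)) NA_real_ else cr
    },
    min_norm = min(.data$moment_arm_norm),
    max_norm = max(.data$moment_arm_norm),
    .groups = "drop")
  out$crossing_angle_deg[out$label != "switching"] <- NA_real_
  out <- dplyr::arrange(out, .data$model, .data$muscle,
                        match(.data$dof, DOFS))
  class(out) <- c("marm_labels", class(out))
  attr(out, "epsilon") <- epsilon
  out
}

#' Functional-group sums and means over a sweep
#'
#' At each posture and degree of freedom, muscles are split by the sign of
#' their normalized moment arm and the two sides are summed separately:
#' `summed_positive` is the summed extensor / adductor / lateral-rotator
#' moment arm, `summed_negative_magnitude` the summed flexor / abductor /
#' medial-rotator magnitude. Because muscle function can switch with posture,
#' the split is per posture rather than by a fixed muscle roster.
#' `mean_positive` and `mean_negative_magnitude` average the positive part
#' and negative-part magnitude over all muscle x posture cells with equal
#' weights (constant within each model x dof).
#'
#' @param records `marm_records` for one model and one mode.
#' @return A tibble of class `marm_summary`, one row per dof x posture, with
#'   columns `model, mode, dof, fe_deg, abd_deg, lar_deg, summed_positive,
#'   summed_negative_magnitude, mean_positive, mean_negative_magnitude`.
#' @export
summarize_groups <- function(records) {
  if (nrow(records) == 0) stop("no records to summarize", call. = FALSE)
  .one_model_mode(records, "summarize_groups()")
  per_posture <- dplyr::summarise(
    dplyr::group_by(records, .data$model, .data$mode, .data$dof,
                    .data$fe_deg, .data$abd_deg, .data$lar_deg),
    summed_positive = sum(pmax(.data$moment_arm_norm, 0)),
    summed_negative_magnitude = sum(pmax(-.data$moment_arm_norm, 0)),
    .groups = "drop")
  means <- dplyr::summarise(
    dplyr::group_by(records, .data$model, .data$mode, .data$dof),
    mean_positive = mean(pmax(.data$moment_arm_norm, 0)),
    mean_negative_magnitude = mean(pmax(-.data$moment_arm_norm, 0)),
    .groups = "drop")
  out <- dplyr::left_join(per_posture, means,
                          by = c("model", "mode", "dof"))
  out <- dplyr::arrange(out, .data$model, match(.data$dof, DOFS),
                        .data$fe_deg)
  class(out) <- c("marm_summary", class(out))
  out
}

#' Contrast functional-group summaries between cohorts
#'
#' Compares summed moment arms between cohorts of models (e.g. bipeds versus
#' quadrupeds): per degree of freedom and posture, the cohort mean and
#' standard deviation of the summed positive and negative-magnitude values
#' across models; and per degree of freedom, the cohort means of the
#' per-model sweep means.
#'
#' @param summaries One `marm_summary`, or several stacked with
#'   `dplyr::bind_rows()`, covering all models to contrast.
#' @param cohorts Data frame with columns `model` and `cohort` assigning
#'   every model to a cohort. A model without an assignment is an error
#'   naming the model.
#' @return An object of class `marm_contrast`: list with `by_posture`
#'   (cohort x dof x posture means and sds of the summed values) and
#'   `overall` (cohort x dof means of per-model means).
#' @export
compare_cohorts <- function(summaries, cohorts) {
  if (!all(c("model", "cohort") %in% names(cohorts))) {
    stop("`cohorts` needs columns `model` and `cohort`", call. = FALSE)
  }
  missing <- setdiff(unique(summaries$model), cohorts$model)
  if (length(missing)) {
    stop("no cohort assignment for model(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::inner_join(as_tibble(summaries),
                              as_tibble(cohorts)[, c("model", "cohort")],
                              by = "model")
  by_posture <- dplyr::summarise(
    dplyr::group_by(joined, .data$cohort, .data$dof, .data$fe_deg,
                    .data$abd_deg, .data$lar_deg),
    n_models = dplyr::n_distinct(.data$model),
    mean_summed_positive = mean(.data$summed_positive),
    sd_summed_positive = stats::sd(.data$summed_positive),
    mean_summed_negative_magnitude = mean(.data$summed_negative_magnitude),
    sd_summed_negative_magnitude = stats::sd(.data$summed_negative_magnitude),
    .groups = "drop")
  per_model <- dplyr::distinct(joined, .data$cohort, .data$model, .data$dof,
                               .data$mean_positive,
                               .data$mean_negative_magnitude)
  overall <- dplyr::summarise(
    dplyr::group_by(per_model, .data$cohort, .data$dof),
    n_models = dplyr::n_distinct(.data$model),
    mean_positive = mean(.data$mean_positive),
    mean_negative_magnitude = mean(.data$mean_negative_magnitude),
    .groups = "drop")
  structure(list(by_posture = by_posture, overall = overall),
            class = "marm_contrast")
}

#' @export
print.marm_contrast <- function(x, ...) {
  cat("<marm_contrast>\n-- by posture --\n")
  print(x$by_posture, ...)
  cat("-- overall (cohort means of per-model means) --\n")
  print(x$overall, ...)
  invisible(x)
}

#' Corrected-versus-legacy difference table
#'
#' Quantifies the impact of the historical pelvis-fixed-axes error: for every
#' muscle x dof x posture present in both modes, the difference
#' `delta = corrected - legacy`, plus the per-dof maximum absolute difference
#' and the posture attaining it. Flexion-extension differences are zero by
#' construction (that axis was never wrong); nonzero FE deltas indicate a
#' corrupted record table.
#'
#' @param records `marm_records` containing both modes on the same grid.
#' @return An object of class `marm_diff`: list with `differences` (tibble
#'   with `delta` and `delta_norm` columns) and `max_by_dof`.
#' @export
diff_modes <- function(records) {
  modes <- unique(records$mode)
  if (!all(c("corrected", "legacy") %in% modes)) {
    stop("`records` must contain both corrected and legacy modes",
         call. = FALSE)
  }
  key <- c("model", "muscle", "dof", "fe_deg", "abd_deg", "lar_deg")
  wide <- tidyr::pivot_wider(
    as_tibble(records)[, c(key, "mode", "moment_arm", "moment_arm_norm")],
    names_from = "mode", values_from = c("moment_arm", "moment_arm_norm"))
  if (anyNA(wide$moment_arm_corrected) || anyNA(wide$moment_arm_legacy)) {
    stop("corrected and legacy records are on mismatched grids",
         call. = FALSE)
  }
  diffs <- dplyr::mutate(
    wide,
    delta = .data$moment_arm_corrected - .data$moment_arm_legacy,
    delta_norm = .data$moment_arm_norm_corrected -
      .data$moment_arm_norm_legacy)
  diffs <- dplyr::arrange(diffs, .data$model, .data$muscle,
                          match(.data$dof, DOFS), .data$fe_deg)
  max_by_dof <- dplyr::slice_max(
    dplyr::group_by(diffs, .data$dof), abs(.data$delta), n = 1,
    with_ties = FALSE)
  max_by_dof <- dplyr::ungroup(
    dplyr::transmute(max_by_dof, .data$dof, .data$model, .data$muscle,
                     .data$fe_deg, .data$abd_deg, .data$lar_deg,
                     max_abs_delta = abs(.data$delta),
                     max_abs_delta_norm = abs(.data$delta_norm)))
  structure(list(differences = diffs, max_by_dof = max_by_dof),
            class = "marm_diff")
}

#' @export
print.marm_diff <- function(x, ...) {
  cat("<marm_diff> corrected - legacy over",
      nrow(x$differences), "cells\n-- max |delta| per dof --\n")
  print(x$max_by_dof, ...)
  invisible(x)
}
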