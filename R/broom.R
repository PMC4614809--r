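#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cohort contrast
#'
#' @param x A `marm_contrast` from [compare_cohorts()].
#' @param ... Unused.
#' @return The per-posture contrast tibble.
#' @export
tidy.marm_contrast <- function(x, ...) x$by_posture

#' One-row-per-cohort summary of a cohort contrast
#'
#' @param x A `marm_contrast`.
#' @param ... Unused.
#' @return The overall tibble: cohort means of the per-model sweep means.
#' @export
glance.marm_contrast <- function(x, ...) x$overall

#' Tidy a corrected-versus-legacy difference report
#'
#' @param x A `marm_diff` from [diff_modes()].
#' @param ... Unused.
#' @return The per-cell difference tibble.
#' @export
tidy.marm_diff <- function(x, ...) x$differences

#' One-row summary of a corrected-versus-legacy difference report
#'
#' @param x A `marm_diff`.
#' @param ... Unused.
#' @return A one-row tibble with the overall and per-dof maximum absolute
#'   differences.
#' @export
glance.marm_diff <- function(x, ...) {
  by_dof <- stats::setNames(x$max_by_dof$max_abs_delta, x$max_by_dof$dof)
  tibble(n_cells = nrow(x$differences),
         max_abs_delta = max(abs(x$differences$delta)),
         max_abs_delta_fe = unname(by_dof["FE"]),
         max_abs_delta_abd = unname(by_dof["ABD"]),
         max_abs_delta_lar = unname(by_dof["LAR"]))
}

#' One-row summary of a sweep record table
#'
#' @param x A `marm_records` tibble.
#' @param ... Unused.
#' @return A one-row tibble: counts of muscles, dofs, postures, modes and
#'   records, plus the largest normalized moment-arm magnitude.
#' @export
glance.marm_records <- function(x, ...) {
  tibble(n_models = dplyr::n_distinct(x$model),
         n_muscles = dplyr::n_distinct(x$muscle),
         n_dofs = dplyr::n_distinct(x$dof),
         n_postures = dplyr::n_distinct(paste(x$fe_deg, x$abd_deg,
                                              x$lar_deg)),
         n_modes = dplyr::n_distinct(x$mode),
         n_records = nrow(x),
         max_abs_norm = max(abs(x$moment_arm_norm)))
}
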