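#' Define a posture-sweep protocol
#'
#' Replicates the sampling protocol of comparative hip moment-arm studies:
#' the femur is held at a fixed abduction offset (10 degrees of abduction by
#' default) while flexion-extension is varied in fixed increments (15 degrees
#' by default). Because positive abduction-adduction means adduction here,
#' the 10-degree abduction offset is stored as `abd_deg = -10`.
#'
#' @param fe_min,fe_max Flexion-extension range in degrees
#'   (default -90 to +90; negative = flexion).
#' @param fe_step Grid increment in degrees (default 15).
#' @param abd_offset Degrees of *abduction* held throughout the sweep
#'   (default 10, i.e. `abd_deg = -10`).
#' @param lar_offset Long-axis rotation offset in degrees (default 0,
#'   positive = lateral).
#' @param dofs Degrees of freedom to evaluate (default all three).
#' @param modes Axis conventions to evaluate (default `"corrected"`; use
#'   `c("corrected", "legacy")` for difference analyses).
#' @return An object of class `sweep_protocol`.
#' @export
#' @examples
#' sweep_protocol()                       # the default 13-posture grid
#' sweep_protocol(modes = c("corrected", "legacy"))
sweep_protocol <- function(fe_min = -90, fe_max = 90, fe_step = 15,
                           abd_offset = 10, lar_offset = 0,
                           dofs = DOFS, modes = "corrected") {
  if (!is.finite(fe_step) || fe_step <= 0) {
    stop("`fe_step` must be > 0", call. = FALSE)
  }
  if (fe_min > fe_max) stop("`fe_min` must be <= `fe_max`", call. = FALSE)
  dofs <- match.arg(dofs, DOFS, several.ok = TRUE)
  modes <- match.arg(modes, c("corrected", "legacy"), several.ok = TRUE)
  structure(
    list(fe_min = fe_min, fe_max = fe_max, fe_step = fe_step,
         abd_deg = -abd_offset, lar_deg = lar_offset,
         dofs = dofs, modes = modes),
    class = "sweep_protocol")
}

#' @export
print.sweep_protocol <- function(x, ...) {
  n <- floor((x$fe_max - x$fe_min) / x$fe_step) + 1
  cat("<sweep_protocol> FE ", x$fe_min, "..", x$fe_max, " step ", x$fe_step,
      " (", n, " postures), abd_deg = ", x$abd_deg, ", lar_deg = ",
      x$lar_deg, "\n  dofs: ", paste(x$dofs, collapse = ", "),
      "; modes: ", paste(x$modes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Run a posture sweep over a limb model
#'
#' Evaluates the moment arm of every muscle, for every requested degree of
#' freedom and axis convention, at every flexion-extension grid posture of
#' the protocol, and normalizes by femur length. Output order is
#' deterministic: (model, muscle, dof, fe_deg, mode).
#'
#' @param model A `limb_model`.
#' @param protocol A [sweep_protocol()].
#' @param method `"excursion"` (tendon excursion) or `"geometric"` (exact).
#' @param h_deg Central-difference half-step in degrees for the excursion
#'   method.
#' @return A tibble of class `marm_records`, one row per muscle x dof x
#'   posture x mode, with columns `model, muscle, dof, fe_deg, abd_deg,
#'   lar_deg, mode, moment_arm, moment_arm_norm`.
#' @seealso [classify_function()], [summarize_groups()], [diff_modes()],
#'   [save_records()]
#' @export
#' @examples
#' toy <- make_hinge_toy()
#' rec <- run_sweep(toy, sweep_protocol(abd_offset = 0, dofs = "FE"))
#' head(rec)
run_sweep <- function(model, protocol = sweep_protocol(),
                      method = c("excursion", "geometric"), h_deg = 0.25) {
  method <- match.arg(method)
  if (method == "excursion") .check_h(h_deg)
  cache <- .compile_model(model)
  if (length(cache$muscles) == 0) {
    stop("model has no muscles to sweep", call. = FALSE)
  }
  fe <- seq(protocol$fe_min, protocol$fe_max, by = protocol$fe_step)
  nmu <- length(cache$muscles)
  ndof <- length(protocol$dofs)
  rows <- vector("list", length(fe) * length(protocol$modes))
  k <- 0L
  for (mode in protocol$modes) {
    for (f in fe) {
      q <- posture(f, protocol$abd_deg, protocol$lar_deg)
      arms <- if (method == "excursion") {
        .arms_excursion(cache, q, mode, h_deg, protocol$dofs)
      } else {
        .arms_geometric(cache, q, mode, protocol$dofs)
      }
      k <- k + 1L
      rows[[k]] <- tibble(
        model = model$name,
        muscle = rep(cache$muscles, times = ndof),
        dof = rep(protocol$dofs, each = nmu),
        fe_deg = f, abd_deg = q[[2]], lar_deg = q[[3]], mode = mode,
        moment_arm = as.numeric(arms[, protocol$dofs]),
        moment_arm_norm = as.numeric(arms[, protocol$dofs]) /
          cache$femur_length)
    }
  }
  out <- .arrange_records(dplyr::bind_rows(rows))
  new_marm_records(out, protocol = protocol, method = method, h_deg = h_deg)
}
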