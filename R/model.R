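#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

DOFS <- c("FE", "ABD", "LAR")
SEGMENTS <- c("pelvis", "femur")
MODEL_SCHEMA_VERSION <- 1L

#' Define a three-degree-of-freedom hip joint
#'
#' The hip is modelled as a pure ball joint with a fixed rotation order:
#' flexion-extension (FE) about the pelvis-fixed mediolateral axis, then
#' abduction-adduction (ABD) about the FE-rotated craniocaudal axis, then
#' long-axis rotation (LAR) about the FE- and ABD-rotated proximodistal axis.
#' Anatomical angle conventions (positive = extension / adduction / lateral
#' rotation) are mapped onto right-handed rotations about the stored axis
#' directions by the per-degree-of-freedom sense flags, so left- and
#' right-limb models can share one sign vocabulary.
#'
#' @param center Numeric length 3, joint centre in the global (= pelvis)
#'   frame.
#' @param dof_senses Named numeric vector with entries `FE`, `ABD`, `LAR`,
#'   each +1 or -1. The default `(+1, +1, +1)` is the canonical synthetic
#'   right-hindlimb convention.
#' @return An object of class `hip_joint`.
#' @export
#' @examples
#' hip_joint()
hip_joint <- function(center = c(0, 0, 0),
                      dof_senses = c(FE = 1, ABD = 1, LAR = 1)) {
  center <- as.numeric(center)
  if (length(center) != 3 || any(!is.finite(center))) {
    stop("joint `center` must be 3 finite numbers", call. = FALSE)
  }
  dof_senses <- dof_senses[DOFS]
  if (length(dof_senses) != 3 || any(is.na(dof_senses)) ||
      !all(dof_senses %in% c(-1, 1))) {
    stop("`dof_senses` must be a named vector with FE, ABD, LAR in {+1, -1}",
         call. = FALSE)
  }
  names(dof_senses) <- DOFS
  structure(list(center = center, dof_senses = dof_senses),
            class = "hip_joint")
}

#' Specify a hip posture
#'
#' Angles are in degrees with anatomical sign semantics: positive
#' flexion-extension is extension (femoral retraction), positive
#' abduction-adduction is adduction (toward the midline), positive long-axis
#' rotation is lateral rotation. The neutral posture is `(0, 0, 0)`. Note the
#' common starting posture of 10 degrees of *abduction* is therefore
#' `abd_deg = -10`.
#'
#' @param fe_deg,abd_deg,lar_deg Finite angles in degrees.
#' @return Named numeric vector `c(fe_deg, abd_deg, lar_deg)`.
#' @export
#' @examples
#' posture(fe_deg = -45, abd_deg = -10, lar_deg = 25)
posture <- function(fe_deg = 0, abd_deg = 0, lar_deg = 0) {
  p <- c(fe_deg = as.numeric(fe_deg), abd_deg = as.numeric(abd_deg),
         lar_deg = as.numeric(lar_deg))
  if (length(p) != 3 || any(!is.finite(p))) {
    stop("posture angles must be single finite numbers", call. = FALSE)
  }
  p
}

.as_posture <- function(q) {
  q <- as.numeric(q)
  if (length(q) != 3 || any(!is.finite(q))) {
    stop("a posture must be 3 finite angles (fe_deg, abd_deg, lar_deg)",
         call. = FALSE)
  }
  names(q) <- c("fe_deg", "abd_deg", "lar_deg")
  q
}

#' Assemble a two-segment limb model
#'
#' A limb model is the complete geometric input of the analysis: the hip
#' joint, the femur length used for normalization, and one or more muscle
#' paths given as ordered polylines of attachment / via points, each owned by
#' either the static pelvis or the mobile femur.
#'
#' Coordinates are stored in segment-local neutral-posture frames. The pelvis
#' frame coincides with the global frame (the pelvis never moves); femur
#' coordinates are expressed relative to the joint centre at neutral, so that
#' posture changes act on femur points as pure rotations about the joint
#' centre.
#'
#' @param name Model identifier.
#' @param muscles Data frame of path points with columns `muscle`, `segment`
#'   (`"pelvis"` or `"femur"`), `x`, `y`, `z`. Rows are ordered along each
#'   path; the first point of every muscle must be pelvis-owned and the last
#'   femur-owned.
#' @param femur_length Positive femur length in model units (the
#'   normalization constant).
#' @param joint A [hip_joint()].
#' @param metadata Free-form named list (e.g. `taxon`, `posture_class`).
#' @return A validated object of class `limb_model`.
#' @seealso [read_limb_model()], [write_limb_model()], [validate_limb_model()]
#' @export
#' @examples
#' m <- limb_model(
#'   "toy",
#'   muscles = tibble::tribble(
#'     ~muscle, ~segment, ~x, ~y, ~z,
#'     "M1", "pelvis", 0, 1, 0,
#'     "M1", "femur",  0, -1, 0
#'   ),
#'   femur_length = 1
#' )
#' muscle_length(m, "M1", posture())
limb_model <- function(name, muscles, femur_length, joint = hip_joint(),
                       metadata = list()) {
  muscles <- as_tibble(muscles)
  model <- structure(
    list(name = as.character(name), joint = joint,
         femur_length = as.numeric(femur_length),
         muscles = muscles[, c("muscle", "segment", "x", "y", "z")],
         metadata = metadata),
    class = "limb_model")
  validate_limb_model(model)
}

#' Validate a limb model
#'
#' Checks every structural invariant: a finite joint centre, valid senses,
#' positive femur length, unique muscle names, at least two path points per
#' muscle, pelvis-owned first and femur-owned last points, known segment
#' owners, and no coincident consecutive path points.
#'
#' @param model A `limb_model`.
#' @return The model, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_limb_model <- function(model) {
  if (!inherits(model, "limb_model")) stop("not a limb_model", call. = FALSE)
  if (is.null(model$joint) || is.null(model$joint$center)) {
    stop("model is missing the joint center", call. = FALSE)
  }
  jc <- model$joint$center
  if (length(jc) != 3 || any(!is.finite(jc))) {
    stop("joint center must be 3 finite numbers", call. = FALSE)
  }
  fl <- model$femur_length
  if (length(fl) != 1 || !is.finite(fl) || fl <= 0) {
    stop("femur_length must be a single positive number", call. = FALSE)
  }
  m <- model$muscles
  need <- c("muscle", "segment", "x", "y", "z")
  if (!all(need %in% names(m))) {
    stop("muscles table must have columns muscle, segment, x, y, z",
         call. = FALSE)
  }
  if (nrow(m) == 0) stop("model has no muscles", call. = FALSE)
  if (!all(m$segment %in% SEGMENTS)) {
    bad <- unique(setdiff(m$segment, SEGMENTS))
    stop("unknown segment owner: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(as.matrix(m[, c("x", "y", "z")])))) {
    stop("muscle path coordinates must all be finite", call. = FALSE)
  }
  # muscle blocks must be contiguous so row order defines the path order
  runs <- rle(m$muscle)$values
  if (anyDuplicated(runs)) {
    stop("non-unique or non-contiguous muscle name: ",
         runs[duplicated(runs)][1], call. = FALSE)
  }
  for (mu in runs) {
    rows <- m[m$muscle == mu, ]
    if (nrow(rows) < 2) {
      stop("muscle ", mu, " has fewer than 2 path points", call. = FALSE)
    }
    if (rows$segment[1] != "pelvis") {
      stop("muscle ", mu, ": first path point must be pelvis-owned",
           call. = FALSE)
    }
    if (rows$segment[nrow(rows)] != "femur") {
      stop("muscle ", mu, ": last path point must be femur-owned",
           call. = FALSE)
    }
    xyz <- as.matrix(rows[, c("x", "y", "z")])
    # femur coordinates are joint-centre-relative; compare neutral-posture
    # global positions so the coincidence check is frame-consistent
    fem <- rows$segment == "femur"
    xyz[fem, ] <- xyz[fem, , drop = FALSE] + rep(jc, each = sum(fem))
    d <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                       xyz[-nrow(xyz), , drop = FALSE])^2))
    if (any(d == 0)) {
      stop("muscle ", mu, ": consecutive path points are coincident",
           call. = FALSE)
    }
  }
  invisible(model)
}

#' @export
print.limb_model <- function(x, ...) {
  cat("<limb_model> ", x$name, "\n", sep = "")
  cat("  femur length: ", format(x$femur_length), "\n", sep = "")
  cat("  joint center: [", paste(format(x$joint$center), collapse = ", "),
      "]  senses: ", paste(sprintf("%s=%+d", DOFS,
                                   as.integer(x$joint$dof_senses)),
                           collapse = " "), "\n", sep = "")
  cat("  muscles (", length(unique(x$muscles$muscle)), "): ",
      paste(unique(x$muscles$muscle), collapse = ", "), "\n", sep = "")
  if (length(x$metadata)) {
    cat("  metadata: ",
        paste(names(x$metadata),
              vapply(x$metadata, function(v) paste(format(v), collapse = ","),
                     ""), sep = "=", collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

.model_known_keys <- c("schema_version", "name", "femur_length", "joint",
                       "muscles", "metadata")

#' Write a limb model to a JSON or YAML file
#'
#' The file carries an explicit `schema_version` field. JSON is the default;
#' files ending in `.yaml` / `.yml` are written as YAML.
#'
#' @param model A validated `limb_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_limb_model <- function(model, path) {
  validate_limb_model(model)
  mus <- split(model$muscles, factor(model$muscles$muscle,
                                     levels = unique(model$muscles$muscle)))
  obj <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    name = model$name,
    femur_length = model$femur_length,
    joint = list(center = model$joint$center,
                 dof_senses = as.list(model$joint$dof_senses)),
    muscles = lapply(mus, function(rows) {
      list(name = rows$muscle[1],
           points = lapply(seq_len(nrow(rows)), function(i) {
             list(segment = rows$segment[i],
                  xyz = c(rows$x[i], rows$y[i], rows$z[i]))
           }))
    }),
    metadata = model$metadata
  )
  names(obj$muscles) <- NULL
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path, precision = 15L)
  } else {
    json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    writeLines(json, path)
  }
  invisible(path)
}

#' Read a limb model from a JSON or YAML file
#'
#' Parses and validates a model file written in the schema of
#' [write_limb_model()]. Unknown top-level keys produce a warning, not an
#' error; structural violations (missing joint centre, non-positive femur
#' length, bad segment owners, duplicate muscle names, paths with fewer than
#' two points) are errors naming the offending field.
#'
#' @param path Model file path (`.json`, `.yaml` or `.yml`).
#' @return A validated `limb_model`.
#' @export
read_limb_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  unknown <- setdiff(names(obj), .model_known_keys)
  if (length(unknown)) {
    warning("ignoring unknown model file keys: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (key in c("name", "femur_length", "joint", "muscles")) {
    if (is.null(obj[[key]])) {
      stop("model file is missing required field `", key, "`", call. = FALSE)
    }
  }
  if (is.null(obj$joint$center)) {
    stop("model file is missing required field `joint.center`",
         call. = FALSE)
  }
  senses <- obj$joint$dof_senses
  senses <- if (is.null(senses)) c(FE = 1, ABD = 1, LAR = 1) else
    unlist(senses)
  joint <- hip_joint(center = unlist(obj$joint$center), dof_senses = senses)
  rows <- lapply(obj$muscles, function(mu) {
    if (is.null(mu$name) || is.null(mu$points)) {
      stop("each muscle needs `name` and `points`", call. = FALSE)
    }
    pts <- lapply(mu$points, function(p) {
      xyz <- as.numeric(unlist(p$xyz))
      if (length(xyz) != 3) {
        stop("muscle ", mu$name, ": each point needs 3 coordinates",
             call. = FALSE)
      }
      tibble(muscle = mu$name, segment = as.character(p$segment),
             x = xyz[1], y = xyz[2], z = xyz[3])
    })
    dplyr::bind_rows(pts)
  })
  muscles <- dplyr::bind_rows(rows)
  meta <- obj$metadata
  limb_model(name = obj$name, muscles = muscles,
             femur_length = as.numeric(obj$femur_length), joint = joint,
             metadata = if (is.null(meta)) list() else meta)
}

RECORD_COLUMNS <- c("model", "muscle", "dof", "fe_deg", "abd_deg", "lar_deg",
                    "mode", "moment_arm", "moment_arm_norm")

.arrange_records <- function(records) {
  dplyr::arrange(records, .data$model, .data$muscle,
                 match(.data$dof, DOFS), .data$fe_deg, .data$abd_deg,
                 .data$lar_deg, .data$mode)
}

#' Write moment-arm records to CSV
#'
#' One row per record with columns `model, muscle, dof, fe_deg, abd_deg,
#' lar_deg, mode, moment_arm, moment_arm_norm`, sorted by
#' (model, muscle, dof, fe_deg). Numeric values round-trip at full double
#' precision.
#'
#' @param records A non-empty data frame of moment-arm records, e.g. from
#'   [run_sweep()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_records <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("`records` must be a non-empty data frame", call. = FALSE)
  }
  if (!all(RECORD_COLUMNS %in% names(records))) {
    stop("records are missing columns: ",
         paste(setdiff(RECORD_COLUMNS, names(records)), collapse = ", "),
         call. = FALSE)
  }
  out <- .arrange_records(as_tibble(records)[, RECORD_COLUMNS])
  readr::write_csv(out, path)
  invisible(path)
}

#' Read moment-arm records from CSV
#'
#' @param path CSV written by [save_records()].
#' @return A tibble of class `marm_records`.
#' @export
load_records <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      model = readr::col_character(), muscle = readr::col_character(),
      dof = readr::col_character(), fe_deg = readr::col_double(),
      abd_deg = readr::col_double(), lar_deg = readr::col_double(),
      mode = readr::col_character(), moment_arm = readr::col_double(),
      moment_arm_norm = readr::col_double()))
  new_marm_records(out)
}

new_marm_records <- function(x, ...) {
  attrs <- list(...)
  x <- as_tibble(x)
  class(x) <- c("marm_records", class(x))
  for (nm in names(attrs)) attr(x, nm) <- attrs[[nm]]
  x
}
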