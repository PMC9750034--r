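#' Movement specification registry
#'
#' For each of the five voluntary movements, the registry lists the animation
#' units that the movement engages, per facial side plus units shared by both
#' sides, together with the expected direction of change relative to rest
#' (`+1` value increases during the movement, `-1` value decreases). The
#' eyebrow lowerers decrease when the brows are raised; in whistling the lip
#' pucker rises while both cheek puff units fall below their resting level.
#'
#' @param movement One of the five voluntary movement labels
#'   (see [movement_labels()]), or `NULL` for the whole registry.
#' @return A list with elements `movement`, `left`, `right`, `shared`; each
#'   side entry is a data.frame with columns `descriptor` and `direction`.
#' @export
movement_spec <- function(movement = NULL) {
  unit <- function(descriptor, direction) {
    data.frame(descriptor = descriptor, direction = direction,
               stringsAsFactors = FALSE)
  }
  none <- unit(character(0), numeric(0))
  registry <- list(
    smiling = list(
      left = unit("lip_corner_puller_left", +1),
      right = unit("lip_corner_puller_right", +1),
      shared = none
    ),
    eye_closure = list(
      left = unit("left_eye_closed", +1),
      right = unit("right_eye_closed", +1),
      shared = none
    ),
    raising_eyebrows = list(
      left = unit("left_eyebrow_lowerer", -1),
      right = unit("right_eyebrow_lowerer", -1),
      shared = none
    ),
    blowing_cheeks = list(
      left = unit("left_cheek_puff", +1),
      right = unit("right_cheek_puff", +1),
      shared = none
    ),
    whistling = list(
      left = unit("left_cheek_puff", -1),
      right = unit("right_cheek_puff", -1),
      shared = unit("lip_pucker", +1)
    )
  )
  registry <- lapply(names(registry), function(m) {
    c(list(movement = m), registry[[m]])
  })
  names(registry) <- movement_labels(voluntary_only = TRUE)
  if (is.null(movement)) return(registry)
  movement <- match.arg(movement, names(registry))
  registry[[movement]]
}

#' Direction-folded movement-minus-rest change of one unit
#'
#' Returns `direction * (movement value - rest value)`: positive when the
#' unit moved in the direction the movement is expected to drive it.
#'
#' @param movement_frame FAU frame at the evaluated (peak) moment.
#' @param rest Resting baseline frame.
#' @param descriptor Animation unit name.
#' @param direction `+1` or `-1`.
#' @return Signed effective delta.
#' @export
effective_delta <- function(movement_frame, rest, descriptor, direction = +1) {
  if (!all(descriptor %in% fau_descriptors())) {
    stop("unknown descriptor: ",
         paste(setdiff(descriptor, fau_descriptors()), collapse = ", "))
  }
  direction * (as.numeric(movement_frame[descriptor]) -
                 as.numeric(rest[descriptor]))
}

#' Grade from an effective delta
#'
#' One grade point per completed 0.1 of effective movement-minus-rest change,
#' capped at 10 (reached exactly when the delta attains its maximum value
#' of 1). Negative deltas — paradoxical movement — score 0 rather than
#' erroring. A `1e-9` epsilon guards floating-point representations of
#' multiples of 0.1.
#'
#' @param delta Effective delta (finite numeric, vectorised).
#' @return Integer grade(s) in `0:10`.
#' @export
#' @examples
#' score_from_delta(c(-0.2, 0.34, 1.0))  # 0 3 10
score_from_delta <- function(delta) {
  if (any(!is.finite(delta))) stop("delta must be finite")
  as.integer(pmin(floor((pmax(delta, 0) + 1e-9) * 10), 10))
}

#' Peak-frame selection
#'
#' Picks the frame of a voluntary-movement session at which the movement is
#' most fully expressed: the frame maximising the mean effective delta over
#' all units the movement engages (both sides plus shared units). Ties go to
#' the earliest frame.
#'
#' @param session A voluntary-movement [fau_session()].
#' @param rest Resting baseline frame.
#' @param spec Movement spec from [movement_spec()]; defaults to the
#'   session's movement.
#' @return Frame index (1-based).
#' @export
select_peak_frame <- function(session, rest, spec = NULL) {
  stopifnot(inherits(session, "fau_session"))
  if (session$movement == "rest") stop("peak selection applies to voluntary movements")
  if (nrow(session$frames) < 1) stop("session has no frames")
  if (is.null(spec)) spec <- movement_spec(session$movement)
  units <- rbind(spec$left, spec$right, spec$shared)
  deltas <- sapply(seq_len(nrow(units)), function(i) {
    units$direction[i] * (session$frames[, units$descriptor[i]] -
                            as.numeric(rest[units$descriptor[i]]))
  })
  if (is.null(dim(deltas))) deltas <- matrix(deltas, nrow = 1)
  which.max(rowMeans(deltas))  # which.max takes the first maximum
}

#' Grade one voluntary movement per facial side
#'
#' Evaluates the movement at its peak frame and grades each side from its
#' effective deltas. For the four lateralised movements the per-side delta is
#' the side's engaged unit delta; for whistling it is the unweighted mean of
#' the shared lip-pucker rise and that side's cheek-puff decrease.
#'
#' @param session A voluntary-movement [fau_session()].
#' @param rest Resting baseline frame (from [rest_baseline()]).
#' @return List with `movement`, `left_grade`, `right_grade`, `left_delta`,
#'   `right_delta`, `peak_frame_index`.
#' @export
grade_movement <- function(session, rest) {
  stopifnot(inherits(session, "fau_session"))
  if (!session$movement %in% movement_labels(voluntary_only = TRUE)) {
    stop("grade_movement applies to the five voluntary movements, got '",
         session$movement, "'")
  }
  if (is.null(rest)) stop("a resting baseline frame is required for grading")
  spec <- movement_spec(session$movement)
  peak_idx <- select_peak_frame(session, rest, spec)
  peak <- fau_frame(session$frames[peak_idx, ])
  side_delta <- function(side_units) {
    units <- rbind(side_units, spec$shared)
    mean(vapply(seq_len(nrow(units)), function(i) {
      effective_delta(peak, rest, units$descriptor[i], units$direction[i])
    }, numeric(1)))
  }
  left_delta <- side_delta(spec$left)
  right_delta <- side_delta(spec$right)
  list(
    movement = session$movement,
    left_grade = score_from_delta(left_delta),
    right_grade = score_from_delta(right_delta),
    left_delta = left_delta,
    right_delta = right_delta,
    peak_frame_index = peak_idx
  )
}

#' Per-patient grading report
#'
#' Grades every voluntary movement present among `sessions` against the
#' patient's resting baseline: up to 10 grades (5 movements x 2 sides).
#'
#' @param sessions List of [fau_session()] objects for one patient,
#'   including a rest session.
#' @return Object of class `grade_report`: named list movement ->
#'   [grade_movement()] result, with attribute `patient_id`.
#' @export
grade_report <- function(sessions) {
  stopifnot(all(vapply(sessions, inherits, logical(1), "fau_session")))
  moves <- vapply(sessions, function(s) s$movement, character(1))
  rest_idx <- which(moves == "rest")
  if (length(rest_idx) < 1) {
    stop("grading requires a rest session to establish the resting baseline")
  }
  rest <- rest_baseline(sessions[[rest_idx[1]]])
  voluntary <- sessions[moves != "rest"]
  out <- lapply(voluntary, grade_movement, rest = rest)
  names(out) <- vapply(out, function(g) g$movement, character(1))
  pid <- unique(vapply(sessions, function(s) s$patient_id, character(1)))
  structure(out, class = "grade_report", patient_id = pid[1])
}

#' @export
print.grade_report <- function(x, ...) {
  cat("<grade_report> patient", attr(x, "patient_id"), "\n")
  for (g in x) {
    cat(sprintf("  %-18s left %2d (d=%+.3f)   right %2d (d=%+.3f)\n",
                g$movement, g$left_grade, g$left_delta,
                g$right_grade, g$right_delta))
  }
  invisible(x)
}
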