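#' Animation symmetry index of one left/right unit pair
#'
#' The animation symmetry index (ASI) of a mirrored pair of facial animation
#' units is `(1 - |left - right|) * 100`, the percent agreement between the
#' two sides. Signed units (the eyebrow lowerers) can make `|left - right|`
#' exceed 1, so the result is clamped to `[0, 100]` to stay interpretable as
#' a percentage.
#'
#' @param left_value,right_value Activations of the left and right unit.
#' @return Percent symmetry in `[0, 100]`.
#' @export
#' @examples
#' asi_pair(0.2, 0.7)  # 50
asi_pair <- function(left_value, right_value) {
  if (!all(is.finite(left_value)) || !all(is.finite(right_value))) {
    stop("asi_pair requires finite activations")
  }
  pmin(pmax((1 - abs(left_value - right_value)) * 100, 0), 100)
}

#' @rdname facial_area_asi
#' @export
asi_eyes <- function(frame) {
  frame <- fau_frame(frame)
  asi_pair(frame[["left_eye_closed"]], frame[["right_eye_closed"]])
}

#' Animation symmetry indices of the three facial areas
#'
#' `asi_eyes()` compares the left/right eye-closed units, `asi_eyebrows()`
#' the left/right eyebrow lowerers, and `asi_mouth()` averages four mouth
#' pair symmetries: lip corner puller, lip stretcher, lip corner depressor
#' and cheek puff.
#'
#' @param frame A 17-unit FAU frame (see [fau_frame()]).
#' @return `asi_eyes()` and `asi_eyebrows()` return a percent in `[0, 100]`.
#'   `asi_mouth()` returns a list with `mouth` (the mean percent) and
#'   `components` (named vector `lip_puller`, `lip_stretcher`,
#'   `lip_depressor`, `cheeks`).
#' @name facial_area_asi
#' @export
asi_eyebrows <- function(frame) {
  frame <- fau_frame(frame)
  asi_pair(frame[["left_eyebrow_lowerer"]], frame[["right_eyebrow_lowerer"]])
}

#' @rdname facial_area_asi
#' @export
asi_mouth <- function(frame) {
  frame <- fau_frame(frame)
  comp <- c(
    lip_puller = asi_pair(frame[["lip_corner_puller_left"]],
                          frame[["lip_corner_puller_right"]]),
    lip_stretcher = asi_pair(frame[["lip_stretcher_left"]],
                             frame[["lip_stretcher_right"]]),
    lip_depressor = asi_pair(frame[["lip_corner_depressor_left"]],
                             frame[["lip_corner_depressor_right"]]),
    cheeks = asi_pair(frame[["left_cheek_puff"]], frame[["right_cheek_puff"]])
  )
  list(mouth = mean(comp), components = comp)
}

#' Total ASI of a movement
#'
#' The per-movement total is the arithmetic mean of the three facial-area
#' symmetries (eyes, eyebrows, mouth).
#'
#' @param eyes,eyebrows,mouth Area ASIs in percent.
#' @return Percent in `[0, 100]`.
#' @export
total_asi <- function(eyes, eyebrows, mouth) {
  mean(c(eyes, eyebrows, mouth))
}

#' Per-patient symmetry report
#'
#' Computes the three facial-area ASIs, their per-movement total, and the
#' four mouth components for every movement present in `sessions`. Static
#' symmetry (rest) is evaluated on the median rest baseline; dynamic
#' symmetry for each voluntary movement is evaluated at that movement's peak
#' frame (see [select_peak_frame()]). With all six movements present the
#' report holds the full 18 area values (3 areas x 6 movements).
#'
#' @param sessions List of [fau_session()] objects sharing one `patient_id`,
#'   at most one session per movement.
#' @return An object of class `asi_report`: a list with `patient_id`,
#'   `per_area` (named list movement -> c(eyes, eyebrows, mouth)),
#'   `total` (named numeric, movement -> percent) and `mouth_components`
#'   (named list movement -> 4-vector).
#' @export
asi_report <- function(sessions) {
  stopifnot(all(vapply(sessions, inherits, logical(1), "fau_session")))
  pid <- unique(vapply(sessions, function(s) s$patient_id, character(1)))
  if (length(pid) > 1) {
    stop("asi_report expects sessions from a single patient, got: ",
         paste(pid, collapse = ", "))
  }
  moves <- vapply(sessions, function(s) s$movement, character(1))
  if (anyDuplicated(moves)) {
    stop("duplicate sessions for movement(s): ",
         paste(unique(moves[duplicated(moves)]), collapse = ", "),
         " — disambiguate by sample_id and pass one session per movement")
  }
  rest <- NULL
  rest_idx <- which(moves == "rest")
  if (length(rest_idx) == 1) rest <- rest_baseline(sessions[[rest_idx]])

  per_area <- list()
  total <- numeric(0)
  mouth_components <- list()
  for (s in sessions) {
    frame <- if (s$movement == "rest") {
      rest
    } else {
      spec <- movement_spec(s$movement)
      base <- if (is.null(rest)) fau_frame(s$frames[1, ]) else rest
      fau_frame(s$frames[select_peak_frame(s, base, spec), ])
    }
    eyes <- asi_eyes(frame)
    brows <- asi_eyebrows(frame)
    mouth <- asi_mouth(frame)
    per_area[[s$movement]] <- c(eyes = eyes, eyebrows = brows,
                                mouth = mouth$mouth)
    total[s$movement] <- total_asi(eyes, brows, mouth$mouth)
    mouth_components[[s$movement]] <- mouth$components
  }
  structure(
    list(patient_id = pid, per_area = per_area, total = total,
         mouth_components = mouth_components),
    class = "asi_report"
  )
}

#' @export
print.asi_report <- function(x, ...) {
  cat("<asi_report> patient", x$patient_id, "\n")
  for (m in names(x$per_area)) {
    v <- x$per_area[[m]]
    cat(sprintf("  %-18s eyes %3.0f  eyebrows %3.0f  mouth %3.0f  | total %3.0f\n",
                m, v[["eyes"]], v[["eyebrows"]], v[["mouth"]], x$total[[m]]))
  }
  invisible(x)
}
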