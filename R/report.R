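#' Full per-patient assessment report
#'
#' Assembles the three assessment stages into one report: the 18 animation
#' symmetry indices (3 facial areas x 6 movements), the five Yes/No/May-be
#' ability decisions, and the ten per-side movement grades. Partial inputs
#' (e.g. rest only) yield partial reports with explicit `NULL`/missing
#' blocks rather than errors; a rest session is always required because both
#' grading and the symmetry baseline depend on it.
#'
#' @param sessions Sessions for one patient; must include rest, at most one
#'   session per movement.
#' @param model Optional trained `movement_classifier`; when `NULL` the
#'   ability block is marked missing.
#' @param margin Confidence margin for the ability decision.
#' @return Object of class `patient_report`: list with `patient_id`, `asi`,
#'   `ability`, `grades`, `missing` (character vector of absent blocks or
#'   movements) and `metadata`.
#' @export
assess_patient <- function(sessions, model = NULL, margin = 0.07) {
  stopifnot(length(sessions) >= 1,
            all(vapply(sessions, inherits, logical(1), "fau_session")))
  pid <- unique(vapply(sessions, function(s) s$patient_id, character(1)))
  if (length(pid) > 1) {
    stop("sessions mix patient ids (", paste(pid, collapse = ", "),
         "); assess one patient at a time")
  }
  moves <- vapply(sessions, function(s) s$movement, character(1))
  if (!"rest" %in% moves) {
    stop("a rest session is required to establish the resting baseline")
  }
  if (anyDuplicated(moves)) {
    stop("duplicate sessions for movement(s): ",
         paste(unique(moves[duplicated(moves)]), collapse = ", "))
  }
  missing_movements <- setdiff(movement_labels(), moves)
  have_voluntary <- length(setdiff(moves, "rest")) > 0

  asi <- asi_report(sessions)
  grades <- if (have_voluntary) grade_report(sessions) else NULL
  ability <- if (have_voluntary && !is.null(model)) {
    ability_report(sessions, model, margin = margin)
  } else NULL

  missing <- character(0)
  if (length(missing_movements) > 0) {
    missing <- c(missing, paste0("movement:", missing_movements))
  }
  if (is.null(grades)) missing <- c(missing, "block:grades")
  if (is.null(ability)) {
    missing <- c(missing,
                 if (is.null(model) && have_voluntary) "block:ability (no model)"
                 else "block:ability")
  }
  structure(
    list(
      patient_id = pid,
      asi = asi,
      ability = ability,
      grades = grades,
      missing = missing,
      metadata = list(
        schema_version = "1.0",
        model_version = if (is.null(model)) NULL else model$schema_version,
        model_features = if (is.null(model)) NULL else model$features,
        margin = margin,
        n_sessions = length(sessions)
      )
    ),
    class = "patient_report"
  )
}

#' Render an assessment report
#'
#' `format = "json"` produces a schema-stable JSON document with full
#' numeric precision; `format = "text"` mirrors the three-block clinical
#' report layout (symmetry, ability, grades) with ASIs and grades rounded to
#' integers for display and missing entries shown as an em dash.
#'
#' @param report A `patient_report` from [assess_patient()].
#' @param format `"json"` or `"text"`.
#' @return A character scalar holding the rendered document.
#' @export
render_report <- function(report, format = c("json", "text")) {
  stopifnot(inherits(report, "patient_report"))
  format <- match.arg(format)
  if (format == "json") render_report_json(report) else render_report_text(report)
}

report_to_list <- function(report) {
  asi_block <- lapply(names(report$asi$per_area), function(m) {
    v <- report$asi$per_area[[m]]
    c(as.list(v),
      list(total = unname(report$asi$total[[m]]),
           mouth_components = as.list(report$asi$mouth_components[[m]])))
  })
  names(asi_block) <- names(report$asi$per_area)
  ability_block <- if (is.null(report$ability)) NULL else {
    lapply(unclass(report$ability), function(a) {
      list(decision = a$decision, predicted = a$predicted,
           confidence = as.list(a$confidence))
    })
  }
  grade_block <- if (is.null(report$grades)) NULL else {
    lapply(unclass(report$grades), function(g) {
      list(left = g$left_grade, right = g$right_grade,
           left_delta = g$left_delta, right_delta = g$right_delta,
           peak_frame_index = g$peak_frame_index)
    })
  }
  list(
    patient_id = report$patient_id,
    asi = asi_block,
    ability = ability_block,
    grades = grade_block,
    missing = as.list(report$missing),
    metadata = report$metadata
  )
}

render_report_json <- function(report) {
  as.character(jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                                digits = NA, null = "null", pretty = TRUE))
}

render_report_text <- function(report) {
  dash <- "—"
  fmt <- function(x) if (is.null(x) || length(x) == 0 || is.na(x)) dash
    else sprintf("%d", as.integer(round(x)))
  lines <- c(
    sprintf("FP assessment report — patient %s", report$patient_id),
    "",
    "Symmetry (ASI %, by movement)",
    sprintf("  %-18s %5s %9s %6s %6s", "movement", "eyes", "eyebrows",
            "mouth", "total")
  )
  for (m in movement_labels()) {
    v <- report$asi$per_area[[m]]
    tot <- if (m %in% names(report$asi$total)) report$asi$total[[m]] else NULL
    lines <- c(lines, sprintf(
      "  %-18s %5s %9s %6s %6s", m,
      fmt(v[["eyes"]]), fmt(v[["eyebrows"]]), fmt(v[["mouth"]]), fmt(tot)
    ))
  }
  lines <- c(lines, "", "Ability of performing the facial movements")
  for (m in movement_labels(voluntary_only = TRUE)) {
    a <- report$ability[[m]]
    lines <- c(lines, sprintf("  %-18s %s", m,
                              if (is.null(a)) dash else a$decision))
  }
  lines <- c(lines, "", "Movement grades (0-10, left / right)")
  for (m in movement_labels(voluntary_only = TRUE)) {
    g <- report$grades[[m]]
    lines <- c(lines, sprintf(
      "  %-18s %s / %s", m,
      if (is.null(g)) dash else fmt(g$left_grade),
      if (is.null(g)) dash else fmt(g$right_grade)
    ))
  }
  paste(lines, collapse = "\n")
}

#' @export
print.patient_report <- function(x, ...) {
  cat(render_report_text(x), "\n")
  invisible(x)
}
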