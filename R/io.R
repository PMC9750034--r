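#' Read FAU sessions from disk
#'
#' Reads per-frame FAU recordings from either a frame-per-row CSV or a
#' session-structured JSON file and returns validated sessions.
#'
#' The CSV schema has columns `patient_id`, `movement`, `sample_id`,
#' `frame_index`, `timestamp`, then the 17 descriptor columns in canonical
#' order (see [fau_descriptors()]); optional columns `affected_side` and
#' `tracking_ok` are honoured when present. Frames are grouped into sessions
#' by (`patient_id`, `movement`, `sample_id`) and ordered by `frame_index`.
#'
#' The JSON schema is a list of objects
#' `{"patient_id", "movement", "affected_side", "sample_id",
#' "frames": [{"timestamp", "tracking_ok", "values": {descriptor: value}}]}`.
#'
#' @param path File to read.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @return List of [fau_session()] objects.
#' @seealso [write_sessions()]
#' @export
read_sessions <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") read_sessions_csv(path) else read_sessions_json(path)
}

read_sessions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  desc <- fau_descriptors()
  required <- c("patient_id", "movement", "sample_id", "frame_index",
                "timestamp", desc)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("CSV schema error: missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) return(list())
  for (d in desc) {
    rng <- fau_range(d)
    bad <- which(!is.finite(df[[d]]) | df[[d]] < rng[1, "lower"] - 1e-12 |
                   df[[d]] > rng[1, "upper"] + 1e-12)
    if (length(bad) > 0) {
      stop(sprintf("validation error: activation out of range for '%s' at row %d",
                   d, bad[1]))
    }
  }
  key <- interaction(df$patient_id, df$movement, df$sample_id, drop = TRUE)
  groups <- split(seq_len(nrow(df)), key)
  # stable session order: first appearance in the file
  groups <- groups[order(vapply(groups, min, integer(1)))]
  lapply(groups, function(idx) {
    g <- df[idx[order(df$frame_index[idx])], , drop = FALSE]
    ts <- g$timestamp
    if (all(is.na(ts))) ts <- NULL
    trk <- if ("tracking_ok" %in% names(g) && !all(is.na(g$tracking_ok))) {
      as.logical(g$tracking_ok)
    } else NULL
    side <- if ("affected_side" %in% names(g)) g$affected_side[1] else "unknown"
    if (is.na(side) || !nzchar(side)) side <- "unknown"
    frames <- as.matrix(g[, desc, drop = FALSE])
    rownames(frames) <- NULL
    fau_session(
      patient_id = g$patient_id[1], movement = g$movement[1],
      frames = frames,
      affected_side = side, sample_id = g$sample_id[1],
      timestamp = ts, tracking_ok = trk
    )
  })
}

read_sessions_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(s) {
    frames <- lapply(s$frames, function(fr) unlist(fr$values))
    ts <- vapply(s$frames, function(fr) {
      if (is.null(fr$timestamp)) NA_real_ else as.numeric(fr$timestamp)
    }, numeric(1))
    if (all(is.na(ts))) ts <- NULL
    trk <- vapply(s$frames, function(fr) {
      if (is.null(fr$tracking_ok)) NA else as.logical(fr$tracking_ok)
    }, logical(1))
    if (all(is.na(trk))) trk <- NULL
    fau_session(
      patient_id = s$patient_id, movement = s$movement, frames = frames,
      affected_side = if (is.null(s$affected_side)) "unknown" else s$affected_side,
      sample_id = if (is.null(s$sample_id)) 1L else s$sample_id,
      timestamp = ts, tracking_ok = trk
    )
  })
}

#' Write FAU sessions to disk
#'
#' Writes sessions in a format losslessly re-readable by [read_sessions()].
#'
#' @param sessions List of [fau_session()] objects (may be empty).
#' @param path Output file.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @export
write_sessions <- function(sessions, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  stopifnot(all(vapply(sessions, inherits, logical(1), "fau_session")))
  if (format == "csv") write_sessions_csv(sessions, path)
  else write_sessions_json(sessions, path)
  invisible(NULL)
}

write_sessions_csv <- function(sessions, path) {
  desc <- fau_descriptors()
  header <- c("patient_id", "movement", "sample_id", "frame_index",
              "timestamp", "affected_side", "tracking_ok", desc)
  rows <- lapply(sessions, function(s) {
    n <- nrow(s$frames)
    data.frame(
      patient_id = s$patient_id, movement = s$movement,
      sample_id = s$sample_id, frame_index = seq_len(n) - 1L,
      timestamp = if (is.null(s$timestamp)) NA_real_ else s$timestamp,
      affected_side = s$affected_side,
      tracking_ok = if (is.null(s$tracking_ok)) NA else s$tracking_ok,
      s$frames, check.names = FALSE, stringsAsFactors = FALSE
    )
  })
  df <- if (length(rows) > 0) do.call(rbind, rows) else {
    as.data.frame(setNames(rep(list(numeric(0)), length(header)), header),
                  check.names = FALSE)
  }
  # full double precision so timestamps and activations round-trip
  for (col in c("timestamp", desc)) {
    df[[col]] <- vapply(df[[col]], function(x) {
      if (is.na(x)) NA_character_ else format(x, digits = 17, scientific = FALSE)
    }, character(1))
  }
  utils::write.csv(df[, header], path, row.names = FALSE, quote = FALSE, na = "")
}

write_sessions_json <- function(sessions, path) {
  out <- lapply(sessions, function(s) {
    frames <- lapply(seq_len(nrow(s$frames)), function(i) {
      fr <- list(values = as.list(s$frames[i, ]))
      if (!is.null(s$timestamp)) fr$timestamp <- s$timestamp[i]
      if (!is.null(s$tracking_ok)) fr$tracking_ok <- s$tracking_ok[i]
      fr
    })
    list(
      patient_id = s$patient_id, movement = s$movement,
      affected_side = s$affected_side, sample_id = s$sample_id,
      frames = frames
    )
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
}
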