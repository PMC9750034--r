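#' Canonical facial animation unit descriptors
#'
#' The 17 facial animation units (FAUs) tracked by Kinect-style face SDKs,
#' identified by descriptor string. Descriptor strings — not "FAU<n>" numbers —
#' are the canonical identifiers throughout the package, because published
#' FAU numberings are not consistent between sources while the descriptors
#' are unambiguous.
#'
#' @return Character vector of the 17 descriptor names, in canonical order.
#' @export
#' @examples
#' fau_descriptors()
fau_descriptors <- function() {
  c(
    "jaw_open",
    "lip_pucker",
    "jaw_slide_right",
    "lip_stretcher_right",
    "lip_stretcher_left",
    "lip_corner_puller_left",
    "lip_corner_puller_right",
    "lip_corner_depressor_left",
    "lip_corner_depressor_right",
    "left_cheek_puff",
    "right_cheek_puff",
    "left_eye_closed",
    "right_eye_closed",
    "right_eyebrow_lowerer",
    "left_eyebrow_lowerer",
    "lower_lip_depressor_left",
    "lower_lip_depressor_right"
  )
}

#' Left/right mirror pairs used in symmetry analysis
#'
#' Six of the seventeen units come in left/right pairs (12 units total):
#' eyes, eyebrows, lip corner puller, lip stretcher, lip corner depressor
#' and cheek puff. These pairs drive the animation symmetry indices.
#'
#' @return A data.frame with columns `pair` (pair name), `left` and `right`
#'   (descriptor names).
#' @export
fau_mirror_pairs <- function() {
  data.frame(
    pair = c("eyes", "eyebrows", "lip_puller", "lip_stretcher",
             "lip_depressor", "cheeks"),
    left = c("left_eye_closed", "left_eyebrow_lowerer",
             "lip_corner_puller_left", "lip_stretcher_left",
             "lip_corner_depressor_left", "left_cheek_puff"),
    right = c("right_eye_closed", "right_eyebrow_lowerer",
              "lip_corner_puller_right", "lip_stretcher_right",
              "lip_corner_depressor_right", "right_cheek_puff"),
    stringsAsFactors = FALSE
  )
}

# Per-descriptor activation bounds. Most units are one-sided [0, 1];
# jaw slide and the eyebrow lowerers are signed [-1, 1] (lowerer goes
# negative when the brow is raised).
fau_range <- function(descriptor) {
  signed <- c("jaw_slide_right", "right_eyebrow_lowerer", "left_eyebrow_lowerer")
  lo <- ifelse(descriptor %in% signed, -1, 0)
  cbind(lower = lo, upper = rep(1, length(descriptor)))
}

#' Movement labels
#'
#' The six recorded facial movements: the rest state plus five voluntary
#' movements (smiling, eye closure, raising eyebrows, blowing cheeks,
#' whistling).
#'
#' @param voluntary_only If `TRUE`, return only the five voluntary movements.
#' @return Character vector of movement labels.
#' @export
movement_labels <- function(voluntary_only = FALSE) {
  voluntary <- c("smiling", "eye_closure", "raising_eyebrows",
                 "blowing_cheeks", "whistling")
  if (voluntary_only) voluntary else c("rest", voluntary)
}

#' Construct a validated FAU frame
#'
#' A frame is one time-sample of the 17 animation units, represented as a
#' named numeric vector in canonical descriptor order.
#'
#' @param values Named numeric vector covering all 17 descriptors (any order;
#'   reordered canonically).
#' @return Named numeric vector of length 17 with class `fau_frame`.
#' @export
#' @examples
#' f <- fau_frame(setNames(rep(0, 17), fau_descriptors()))
fau_frame <- function(values) {
  desc <- fau_descriptors()
  if (is.null(names(values))) {
    stop("frame values must be named by FAU descriptor")
  }
  missing <- setdiff(desc, names(values))
  if (length(missing) > 0) {
    stop("frame is missing descriptor(s): ", paste(missing, collapse = ", "))
  }
  v <- as.numeric(values[desc])
  names(v) <- desc
  validate_frame_values(v)
  structure(v, class = "fau_frame")
}

# Validates a 17-vector (or each row of an n x 17 matrix) against the
# per-descriptor activation bounds. `where` labels error messages.
validate_frame_values <- function(v, where = NULL) {
  m <- if (is.matrix(v)) v else matrix(v, nrow = 1, dimnames = list(NULL, names(v)))
  desc <- fau_descriptors()
  rng <- fau_range(desc)
  label <- if (is.null(where)) "" else paste0(" in ", where)
  if (any(!is.finite(m))) {
    stop("non-finite FAU activation", label)
  }
  for (j in seq_along(desc)) {
    x <- m[, desc[j]]
    bad <- which(x < rng[j, "lower"] - 1e-12 | x > rng[j, "upper"] + 1e-12)
    if (length(bad) > 0) {
      stop(sprintf(
        "activation out of range for '%s'%s: value %.4f at row %d (allowed [%g, %g])",
        desc[j], label, x[bad[1]], bad[1], rng[j, "lower"], rng[j, "upper"]
      ))
    }
  }
  invisible(TRUE)
}

#' Construct a validated session
#'
#' A session is an ordered sequence of FAU frames for one patient performing
#' one movement (or at rest). Frames are stored as an `n x 17` matrix with
#' descriptor column names; timestamps and per-frame tracking flags are
#' optional.
#'
#' @param patient_id Patient identifier string.
#' @param movement One of [movement_labels()].
#' @param frames Numeric matrix (`n x 17`, descriptor colnames) or a list of
#'   frames acceptable to [fau_frame()].
#' @param affected_side `"left"`, `"right"`, `"none"` or `"unknown"`.
#' @param sample_id Integer sample index when several sessions of the same
#'   movement exist for a patient.
#' @param timestamp Optional numeric vector of frame times in seconds,
#'   non-decreasing.
#' @param tracking_ok Optional logical vector flagging frames with good
#'   face tracking.
#' @return An object of class `fau_session`.
#' @export
fau_session <- function(patient_id, movement, frames,
                        affected_side = "unknown", sample_id = 1L,
                        timestamp = NULL, tracking_ok = NULL) {
  movement <- match.arg(movement, movement_labels())
  affected_side <- match.arg(affected_side, c("left", "right", "none", "unknown"))
  desc <- fau_descriptors()
  if (is.list(frames)) {
    frames <- do.call(rbind, lapply(frames, function(f) as.numeric(fau_frame(f))))
    colnames(frames) <- desc
  }
  if (!is.matrix(frames) || nrow(frames) < 1) {
    stop("a session needs at least one frame")
  }
  if (is.null(colnames(frames))) {
    if (ncol(frames) != length(desc)) stop("frame matrix must have 17 columns")
    colnames(frames) <- desc
  }
  missing <- setdiff(desc, colnames(frames))
  if (length(missing) > 0) {
    stop("frames are missing descriptor(s): ", paste(missing, collapse = ", "))
  }
  frames <- frames[, desc, drop = FALSE]
  validate_frame_values(frames, where = paste0(patient_id, "/", movement))
  if (!is.null(timestamp)) {
    if (length(timestamp) != nrow(frames)) {
      stop("timestamp length must match the number of frames")
    }
    if (any(diff(timestamp) < 0)) stop("timestamps must be non-decreasing")
  }
  if (!is.null(tracking_ok) && length(tracking_ok) != nrow(frames)) {
    stop("tracking_ok length must match the number of frames")
  }
  structure(
    list(
      patient_id = as.character(patient_id),
      movement = movement,
      affected_side = affected_side,
      sample_id = as.integer(sample_id),
      frames = frames,
      timestamp = timestamp,
      tracking_ok = tracking_ok
    ),
    class = "fau_session"
  )
}

#' @export
print.fau_session <- function(x, ...) {
  cat(sprintf(
    "<fau_session> patient %s, %s (sample %d): %d frame(s), affected side %s\n",
    x$patient_id, x$movement, x$sample_id, nrow(x$frames), x$affected_side
  ))
  invisible(x)
}

#' Resting baseline frame of a rest session
#'
#' Aggregates a rest-state session into a single baseline frame by taking the
#' per-unit median over frames, restricted to frames flagged as well tracked
#' when a `tracking_ok` flag is present. The median is robust to transient
#' tracking glitches, which dominate the error budget of consumer depth
#' sensors at rest.
#'
#' @param rest_session A `fau_session` with `movement == "rest"`.
#' @return A `fau_frame` (named numeric vector of 17 medians).
#' @export
rest_baseline <- function(rest_session) {
  stopifnot(inherits(rest_session, "fau_session"))
  if (rest_session$movement != "rest") {
    stop("rest_baseline requires a session with movement 'rest', got '",
         rest_session$movement, "'")
  }
  frames <- rest_session$frames
  if (!is.null(rest_session$tracking_ok)) {
    keep <- which(rest_session$tracking_ok)
    if (length(keep) > 0) frames <- frames[keep, , drop = FALSE]
  }
  if (nrow(frames) < 1) stop("rest session has no usable frames")
  fau_frame(apply(frames, 2, stats::median))
}
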