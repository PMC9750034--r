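# Fixture builders shared across the suite. Frames are built in code; no
# stored data files.

# A frame with every unit at `fill`, overridden by named values.
make_frame <- function(..., fill = 0) {
  v <- setNames(rep(fill, 17), fau_descriptors())
  over <- c(...)
  if (length(over) > 0) v[names(over)] <- over
  fau_frame(v)
}

# A single-movement session whose frames are built from a list of named
# override vectors (one per frame).
make_session <- function(movement, frame_overrides = list(numeric(0)),
                         patient_id = "p1", fill = 0, ...) {
  frames <- lapply(frame_overrides, function(ov) {
    do.call(make_frame, c(as.list(ov), list(fill = fill)))
  })
  fau_session(patient_id, movement, frames, ...)
}

# A minimal all-zero rest session.
make_rest <- function(patient_id = "p1", n = 1, fill = 0) {
  make_session("rest", rep(list(numeric(0)), n),
               patient_id = patient_id, fill = fill)
}

# A valid confidence vector with the given named probabilities; the
# remaining mass is split evenly over the unnamed movements.
make_confidence <- function(...) {
  given <- c(...)
  labels <- movement_labels()
  p <- setNames(rep(0, 6), labels)
  p[names(given)] <- given
  others <- setdiff(labels, names(given))
  p[others] <- (1 - sum(given)) / length(others)
  p
}

# Random valid frame under a fixed-seed RNG stream (uniform within each
# unit's legal range).
random_frame <- function() {
  desc <- fau_descriptors()
  signed <- c("jaw_slide_right", "right_eyebrow_lowerer", "left_eyebrow_lowerer")
  v <- setNames(stats::runif(17), desc)
  v[signed] <- stats::runif(3, -1, 1)
  fau_frame(v)
}
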