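#' Default resting activation levels
#'
#' Resting FAU levels the generator builds sessions around. Most units idle
#' near zero; the cheek-puff units idle at a clearly non-zero level so that
#' whistling — which deflates the cheeks below rest — remains observable.
#' The signed units (jaw slide, eyebrow lowerers) rest at 0.
#'
#' @return Named numeric vector over the 17 descriptors.
#' @export
default_rest_levels <- function() {
  v <- setNames(rep(0.05, 17), fau_descriptors())
  v[c("left_cheek_puff", "right_cheek_puff")] <- 0.35
  v[c("jaw_slide_right", "right_eyebrow_lowerer", "left_eyebrow_lowerer")] <- 0
  v
}

#' Default per-movement activation profiles
#'
#' Peak movement-minus-rest deltas of the units each voluntary movement
#' engages; unengaged units stay at their resting level. Engaged units reach
#' a peak |delta| of 0.8 in the direction given by [movement_spec()] (the
#' eyebrow lowerers fall when the brows are raised; whistling raises the lip
#' pucker while deflating both cheeks).
#'
#' @param peak Peak absolute delta of engaged units.
#' @return Named list movement -> named numeric delta vector.
#' @export
default_activation_profiles <- function(peak = 0.8) {
  registry <- movement_spec()
  profiles <- lapply(registry, function(spec) {
    units <- rbind(spec$left, spec$right, spec$shared)
    setNames(units$direction * peak, units$descriptor)
  })
  c(list(rest = setNames(numeric(0), character(0))), profiles)
}

#' Generator configuration
#'
#' Bundles every knob of the synthetic FAU-session generator. Defaults
#' emulate a short depth-camera acquisition: 30 frames at 30 fps, Gaussian
#' frame noise of 0.02 activation units, engaged-unit peak deltas of 0.8,
#' and (for palsy patients) unilateral attenuation of movement deltas by
#' `1 - severity` plus a static per-patient resting asymmetry whose scale
#' grows with severity.
#'
#' @param seed Integer master seed; every derived random draw is a pure
#'   function of it (plus patient/movement/sample identity).
#' @param n_frames Frames per session.
#' @param fps Frame rate used for timestamps (Hz).
#' @param noise_sd Standard deviation of per-frame Gaussian activation noise.
#' @param severity Palsy severity in `[0, 1]`: affected-side (and shared)
#'   movement deltas are scaled by `1 - severity`.
#' @param affected_side `"left"`, `"right"` or `"none"`.
#' @param rest_asymmetry_scale Scale of the static per-patient resting
#'   offset applied to affected-side units; the effective scale is
#'   `rest_asymmetry_scale * severity`.
#' @param mirrored_blow If `TRUE`, blowing cheeks follows the clinical
#'   observation that some palsy patients can puff the affected cheek but
#'   not the healthy one: the attenuation of the two cheek units is swapped
#'   for that movement.
#' @param k_samples Sessions generated per movement by [generate_patient()].
#' @param activation_profiles Per-movement engaged-unit peak deltas
#'   (see [default_activation_profiles()]).
#' @param rest_levels Resting activation levels (see [default_rest_levels()]).
#' @return Object of class `generator_config` (a validated list).
#' @export
generator_config <- function(seed = 1L, n_frames = 30L, fps = 30,
                             noise_sd = 0.02, severity = 0,
                             affected_side = c("none", "left", "right"),
                             rest_asymmetry_scale = 0.05,
                             mirrored_blow = FALSE, k_samples = 1L,
                             activation_profiles = default_activation_profiles(),
                             rest_levels = default_rest_levels()) {
  affected_side <- match.arg(affected_side)
  stopifnot(severity >= 0, severity <= 1, noise_sd >= 0, n_frames >= 1,
            k_samples >= 1, rest_asymmetry_scale >= 0)
  structure(
    list(seed = as.integer(seed), n_frames = as.integer(n_frames), fps = fps,
         noise_sd = noise_sd, severity = severity,
         affected_side = affected_side,
         rest_asymmetry_scale = rest_asymmetry_scale,
         mirrored_blow = mirrored_blow, k_samples = as.integer(k_samples),
         activation_profiles = activation_profiles,
         rest_levels = rest_levels),
    class = "generator_config"
  )
}

# Deterministic 31-bit sub-seed from the master seed and identity strings.
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (c in utf8ToInt(parts)) h <- (h * 31 + c) %% 2147483629
  as.integer(h)
}

# Which side a descriptor belongs to: "left", "right" or "center".
descriptor_side <- function(descriptor) {
  ifelse(grepl("left", descriptor), "left",
         ifelse(grepl("right", descriptor), "right", "center"))
}

# Static per-patient resting asymmetry: a fixed offset on the affected-side
# members of the mirror pairs, drawn once per patient, scale growing
# linearly with severity so severity sweeps under a fixed patient identity
# stay monotone.
patient_rest_offsets <- function(config, patient_id) {
  offsets <- setNames(rep(0, 17), fau_descriptors())
  if (config$affected_side == "none" || config$rest_asymmetry_scale == 0 ||
      config$severity == 0) {
    return(offsets)
  }
  pairs <- fau_mirror_pairs()
  units <- pairs[[config$affected_side]]
  set.seed(derive_seed(config$seed, "rest-offset", patient_id))
  draw <- stats::rnorm(length(units))
  offsets[units] <- config$rest_asymmetry_scale * config$severity * draw
  offsets
}

# Smooth 0 -> 1 activation ramp reaching its plateau at the final third of
# the session (smoothstep in normalised time).
rise_profile <- function(n_frames) {
  x <- seq_len(n_frames) / n_frames
  u <- pmin(x / (2 / 3), 1)
  3 * u^2 - 2 * u^3
}

# Per-descriptor delta attenuation for a movement under the config's
# severity and affected side. Affected-side lateral units and shared
# (midline) units are scaled by 1 - severity; mirrored_blow swaps the two
# cheek attenuations for blowing_cheeks.
delta_attenuation <- function(config, movement, descriptors) {
  att <- rep(1, length(descriptors))
  if (config$affected_side == "none" || config$severity == 0) return(att)
  side <- descriptor_side(descriptors)
  affected <- side == config$affected_side | side == "center"
  if (config$mirrored_blow && movement == "blowing_cheeks") {
    cheek <- descriptors %in% c("left_cheek_puff", "right_cheek_puff")
    healthy_side <- setdiff(c("left", "right"), config$affected_side)
    affected[cheek] <- side[cheek] == healthy_side
  }
  att[affected] <- 1 - config$severity
  att
}

#' Generate one synthetic FAU session
#'
#' Frames follow `rest level (+ static asymmetry offset) + profile x rise(t)
#' + Gaussian noise`, clamped to each unit's legal range. The rise is a
#' smooth 0 to 1 ramp reaching its plateau at the final third of the session.
#' For palsy configurations, affected-side and midline engaged-unit deltas
#' are scaled by `1 - severity`. Fully reproducible: the same config, patient
#' id, movement and sample index always yield a bit-identical session.
#'
#' @param config A [generator_config()].
#' @param movement One of [movement_labels()].
#' @param patient_id Patient identifier.
#' @param sample_id Sample index (varies the noise draw).
#' @return A [fau_session()].
#' @export
generate_session <- function(config, movement, patient_id = "sim01",
                             sample_id = 1L) {
  stopifnot(inherits(config, "generator_config"))
  movement <- match.arg(movement, movement_labels())
  desc <- fau_descriptors()
  profile <- config$activation_profiles[[movement]]
  if (is.null(profile)) stop("no activation profile for movement '", movement, "'")
  base <- config$rest_levels[desc] + patient_rest_offsets(config, patient_id)
  n <- config$n_frames
  values <- matrix(rep(base, each = n), nrow = n, dimnames = list(NULL, desc))
  if (length(profile) > 0) {
    att <- delta_attenuation(config, movement, names(profile))
    rise <- rise_profile(n)
    for (i in seq_along(profile)) {
      values[, names(profile)[i]] <- values[, names(profile)[i]] +
        profile[i] * att[i] * rise
    }
  }
  if (config$noise_sd > 0) {
    set.seed(derive_seed(config$seed, "noise", patient_id, movement, sample_id))
    values <- values + matrix(stats::rnorm(n * 17, sd = config$noise_sd),
                              nrow = n)
  }
  rng <- fau_range(desc)
  for (j in seq_along(desc)) {
    values[, j] <- pmin(pmax(values[, j], rng[j, "lower"]), rng[j, "upper"])
  }
  fau_session(
    patient_id = patient_id, movement = movement, frames = values,
    affected_side = config$affected_side, sample_id = sample_id,
    timestamp = (seq_len(n) - 1) / config$fps
  )
}

#' Generate a full patient recording
#'
#' One rest session plus the five voluntary movements, `k_samples` sessions
#' of each (6 x k sessions in total).
#'
#' @inheritParams generate_session
#' @return List of [fau_session()] objects.
#' @export
generate_patient <- function(config, patient_id = "sim01") {
  sessions <- list()
  for (movement in movement_labels()) {
    for (k in seq_len(config$k_samples)) {
      sessions[[length(sessions) + 1]] <-
        generate_session(config, movement, patient_id, sample_id = k)
    }
  }
  sessions
}

#' Generate a cohort of synthetic palsy patients
#'
#' Emulates a clinical acquisition campaign: `n_patients` unilateral-palsy
#' patients, each recorded for all six movements with `config$k_samples`
#' samples per movement (so `n_patients * 6 * k_samples` session records).
#' Per-patient severity and affected side are drawn reproducibly from the
#' master seed unless given explicitly.
#'
#' @param config A [generator_config()]; its `severity`/`affected_side` are
#'   overridden per patient.
#' @param n_patients Number of patients.
#' @param severities Optional numeric vector (recycled) of per-patient
#'   severities; default drawn uniformly from `[0.2, 1]`.
#' @param affected_sides Optional character vector (recycled); default drawn
#'   uniformly from left/right.
#' @return List of [fau_session()] objects.
#' @export
generate_cohort <- function(config, n_patients = 13, severities = NULL,
                            affected_sides = NULL) {
  set.seed(derive_seed(config$seed, "cohort"))
  if (is.null(severities)) severities <- stats::runif(n_patients, 0.2, 1)
  if (is.null(affected_sides)) {
    affected_sides <- sample(c("left", "right"), n_patients, replace = TRUE)
  }
  severities <- rep_len(severities, n_patients)
  affected_sides <- rep_len(affected_sides, n_patients)
  sessions <- list()
  for (i in seq_len(n_patients)) {
    pconf <- config
    pconf$severity <- severities[i]
    pconf$affected_side <- affected_sides[i]
    sessions <- c(sessions,
                  generate_patient(pconf, sprintf("sim%02d", i)))
  }
  sessions
}

#' Generate a labelled training dataset of difference vectors
#'
#' Simulates `n_per_class` healthy (severity 0) subjects, each performing all
#' six movements once, and converts every session into its 17-unit
#' movement-minus-rest difference vector — the feature space of the movement
#' classifier. The result is balanced: `n_per_class` instances per class for
#' all six classes.
#'
#' @param n_per_class Instances per movement class.
#' @param seed Master seed.
#' @param config Optional [generator_config()] template (severity and
#'   affected side are forced to healthy).
#' @return List with `x` (matrix, `6 * n_per_class` rows x 17 columns) and
#'   `label` (character vector).
#' @export
generate_training_dataset <- function(n_per_class = 60, seed = 1L,
                                      config = NULL) {
  if (is.null(config)) config <- generator_config(seed = seed)
  config$seed <- as.integer(seed)
  config$severity <- 0
  config$affected_side <- "none"
  xs <- vector("list", n_per_class)
  labels <- vector("list", n_per_class)
  for (i in seq_len(n_per_class)) {
    sessions <- generate_patient(config, sprintf("train%04d", i))
    dv <- difference_vectors(sessions)
    xs[[i]] <- dv$x
    labels[[i]] <- dv$label
  }
  list(x = do.call(rbind, xs), label = unlist(labels))
}
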