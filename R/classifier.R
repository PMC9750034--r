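#' Default classifier feature set
#'
#' The nine movement-minus-rest FAU differences the movement classifier uses
#' by default: the union of all units engaged by at least one voluntary
#' movement (lip corner pullers, eye-closed units, eyebrow lowerers, cheek
#' puffs and the lip pucker), in canonical order. Users can override this
#' list when training.
#'
#' @return Character vector of 9 descriptors.
#' @export
default_feature_set <- function() {
  engaged <- unique(unlist(lapply(movement_spec(), function(spec) {
    rbind(spec$left, spec$right, spec$shared)$descriptor
  })))
  intersect(fau_descriptors(), engaged)
}

#' Feature vector of one session
#'
#' The selected movement-minus-rest FAU differences, evaluated at the
#' session's peak frame (or, for a rest session, at its median baseline
#' frame), in the fixed order of `selected`.
#'
#' @param movement_session A [fau_session()].
#' @param rest Resting baseline frame.
#' @param selected Descriptor list (default [default_feature_set()]).
#' @return Named numeric vector of differences, `length(selected)`.
#' @export
build_feature_vector <- function(movement_session, rest,
                                 selected = default_feature_set()) {
  unknown <- setdiff(selected, fau_descriptors())
  if (length(unknown) > 0) {
    stop("unknown descriptor(s) in feature set: ", paste(unknown, collapse = ", "))
  }
  frame <- if (movement_session$movement == "rest") {
    rest_baseline(movement_session)
  } else {
    fau_frame(movement_session$frames[
      select_peak_frame(movement_session, rest), ])
  }
  setNames(as.numeric(frame[selected]) - as.numeric(rest[selected]), selected)
}

#' Train the probabilistic movement classifier
#'
#' Fits a radial-kernel support vector machine with per-class probability
#' estimates (Platt-style pairwise calibration, as implemented in libsvm via
#' \pkg{e1071}) on labelled difference vectors covering all six movement
#' classes. Training is deterministic given `seed`, and the fitted model
#' serializes/reloads bit-identically via [save_model()]/[load_model()].
#'
#' @param x Numeric matrix of difference vectors (descriptor columns), or a
#'   list with `x` and `label` as from [generate_training_dataset()].
#' @param label Class label per row (one of [movement_labels()]).
#' @param seed Integer seed controlling the internal calibration folds.
#' @param features Descriptors used as inputs (default
#'   [default_feature_set()]).
#' @return Object of class `movement_classifier`.
#' @export
train_movement_classifier <- function(x, label = NULL, seed = 1L,
                                      features = default_feature_set()) {
  if (is.list(x) && !is.matrix(x)) {
    label <- x$label
    x <- x$x
  }
  stopifnot(is.matrix(x), length(label) == nrow(x))
  absent <- setdiff(movement_labels(), unique(label))
  if (length(absent) > 0) {
    stop("training data is missing class(es): ", paste(absent, collapse = ", "))
  }
  if (min(table(label)) < 2) stop("each class needs at least 2 samples")
  missing_feat <- setdiff(features, colnames(x))
  if (length(missing_feat) > 0) {
    stop("training matrix lacks feature column(s): ",
         paste(missing_feat, collapse = ", "))
  }
  y <- factor(label, levels = movement_labels())
  set.seed(as.integer(seed) %% 2147483647L)
  fit <- e1071::svm(x[, features, drop = FALSE], y, kernel = "radial",
                    probability = TRUE)
  structure(
    list(svm = fit, features = features, levels = movement_labels(),
         seed = as.integer(seed), schema_version = "1.0",
         n_train = nrow(x)),
    class = "movement_classifier"
  )
}

#' @export
print.movement_classifier <- function(x, ...) {
  cat(sprintf(
    "<movement_classifier> 6-class SVM on %d features, trained on %d samples (seed %d)\n",
    length(x$features), x$n_train, x$seed))
  invisible(x)
}

#' Class-confidence vector for one feature vector
#'
#' @param model A `movement_classifier`.
#' @param feature_vector Named numeric vector (or one-row matrix) over the
#'   model's feature set.
#' @return Named probability vector over the six movements (sums to 1).
#' @export
predict_confidence <- function(model, feature_vector) {
  stopifnot(inherits(model, "movement_classifier"))
  m <- if (is.matrix(feature_vector)) feature_vector else
    matrix(feature_vector, nrow = 1, dimnames = list(NULL, names(feature_vector)))
  m <- m[, model$features, drop = FALSE]
  pred <- stats::predict(model$svm, m, probability = TRUE)
  probs <- attr(pred, "probabilities")[1, model$levels]
  probs / sum(probs)
}

#' Three-valued ability decision from class confidences
#'
#' Implements the confidence-margin rule for deciding whether the intended
#' movement was performed. Let `p1 >= p2` be the top-two class confidences
#' with movements `m1`, `m2` (ties broken by canonical movement order). If
#' `p1 - p2` is strictly less than `margin` and the intended movement is one
#' of `m1`, `m2`, the classifier cannot separate the two and the decision is
#' `"maybe"`. Otherwise it is `"yes"` when `m1` is the intended movement and
#' `"no"` when it is not. The default margin of 0.07 (7 percentage points of
#' absolute confidence) makes e.g. confidences of 0.46 vs 0.40 inconclusive.
#'
#' @param confidence Named probability vector over the six movements
#'   (entries in `[0,1]`, summing to 1 within `1e-9`).
#' @param intended The movement the patient was asked to perform.
#' @param margin Confidence-difference threshold (fraction, default 0.07).
#' @return `"yes"`, `"no"` or `"maybe"`.
#' @export
#' @examples
#' p <- c(rest = 0.035, smiling = 0.40, eye_closure = 0.46,
#'        raising_eyebrows = 0.035, blowing_cheeks = 0.035, whistling = 0.035)
#' ability_decision(p, "smiling")          # "maybe"
#' ability_decision(p, "raising_eyebrows") # "no"
ability_decision <- function(confidence, intended, margin = 0.07) {
  labels <- movement_labels()
  if (!intended %in% labels) {
    stop("intended movement must be one of: ", paste(labels, collapse = ", "))
  }
  if (is.null(names(confidence)) || !setequal(names(confidence), labels)) {
    stop("confidence must be named by the six movement labels")
  }
  p <- as.numeric(confidence[labels])
  if (any(p < -1e-9) || any(p > 1 + 1e-9) || abs(sum(p) - 1) > 1e-9) {
    stop("confidence must be a probability vector over the six movements")
  }
  ord <- order(-p, seq_along(labels))
  m1 <- labels[ord[1]]
  m2 <- labels[ord[2]]
  gap <- p[ord[1]] - p[ord[2]]
  if (gap < margin && intended %in% c(m1, m2)) return("maybe")
  if (m1 == intended) "yes" else "no"
}

#' Ability-of-movement report
#'
#' Runs the movement classifier on each voluntary-movement session and
#' applies the margin rule with the session's own movement as the intended
#' one: five Yes/No/May-be decisions.
#'
#' @param sessions Sessions for one patient, including rest (used for the
#'   baseline) unless `rest` is supplied.
#' @param model A trained `movement_classifier`.
#' @param rest Optional resting baseline frame; computed from the rest
#'   session when `NULL`.
#' @param margin Margin passed to [ability_decision()].
#' @return Object of class `ability_report`: named list movement ->
#'   list(decision, predicted, confidence).
#' @export
ability_report <- function(sessions, model, rest = NULL, margin = 0.07) {
  if (is.null(model)) stop("a trained movement classifier is required")
  stopifnot(inherits(model, "movement_classifier"))
  moves <- vapply(sessions, function(s) s$movement, character(1))
  if (is.null(rest)) {
    rest_idx <- which(moves == "rest")
    if (length(rest_idx) < 1) {
      stop("ability assessment needs a rest session (or an explicit baseline)")
    }
    rest <- rest_baseline(sessions[[rest_idx[1]]])
  }
  voluntary <- sessions[moves != "rest"]
  out <- lapply(voluntary, function(s) {
    fv <- build_feature_vector(s, rest, model$features)
    conf <- predict_confidence(model, fv)
    list(
      decision = ability_decision(conf, s$movement, margin),
      predicted = names(conf)[which.max(conf)],
      confidence = conf
    )
  })
  names(out) <- vapply(voluntary, function(s) s$movement, character(1))
  structure(out, class = "ability_report")
}

#' @export
print.ability_report <- function(x, ...) {
  cat("<ability_report>\n")
  for (m in names(x)) {
    cat(sprintf("  %-18s %-6s (classified %s, confidence %.2f)\n",
                m, x[[m]]$decision, x[[m]]$predicted,
                max(x[[m]]$confidence)))
  }
  invisible(x)
}

#' Save / load a trained movement classifier
#'
#' The model artifact embeds its schema version and selected-feature list;
#' a reloaded model reproduces the original's confidence vectors exactly.
#'
#' @param model A `movement_classifier`.
#' @param path File path for the model artifact (RDS).
#' @return `load_model()` returns the `movement_classifier`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "movement_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "movement_classifier")) {
    stop("file does not contain a movement_classifier artifact")
  }
  model
}
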