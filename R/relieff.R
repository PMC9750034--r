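#' FAU difference matrix from sessions
#'
#' Builds labelled movement-minus-rest difference vectors, the feature space
#' used for feature ranking and movement classification: for each session the
#' 17 peak-frame (or, for rest, baseline-frame) activations minus the
#' patient's resting baseline.
#'
#' @param sessions List of [fau_session()] objects for one subject,
#'   including a rest session.
#' @return A list with `x` (numeric matrix, one row per session, 17
#'   descriptor columns) and `label` (character vector of movements).
#' @export
difference_vectors <- function(sessions) {
  moves <- vapply(sessions, function(s) s$movement, character(1))
  rest_idx <- which(moves == "rest")
  if (length(rest_idx) < 1) stop("difference vectors need a rest session")
  rest <- rest_baseline(sessions[[rest_idx[1]]])
  rows <- lapply(sessions, function(s) {
    frame <- if (s$movement == "rest") {
      rest_baseline(s)
    } else {
      fau_frame(s$frames[select_peak_frame(s, rest), ])
    }
    as.numeric(frame) - as.numeric(rest)
  })
  x <- do.call(rbind, rows)
  colnames(x) <- fau_descriptors()
  list(x = x, label = moves)
}

#' ReliefF feature weights for one movement versus rest
#'
#' Binary ReliefF over difference-vector features: for every instance, the
#' `k` nearest same-class neighbours (hits) and `k` nearest other-class
#' neighbours (misses) are found by Manhattan distance on range-normalised
#' features, and each feature is credited with the mean normalised separation
#' it provides across misses minus the mean across hits:
#' `W[f] = sum_miss diff(f) / (m*k) - sum_hit diff(f) / (m*k)`,
#' where `diff(f, a, b) = |a_f - b_f| / range(f)` and `m` is the number of
#' instances (every instance is used once — no subsampling, which removes a
#' randomness source on small clinical datasets). A zero-range (constant)
#' feature has `diff = 0` and hence weight 0. Weights lie in `[-1, 1]`.
#'
#' @param x Numeric matrix of difference vectors (rows = instances, named
#'   feature columns), or a list as returned by [difference_vectors()].
#' @param label Class label per row (ignored when `x` carries its own).
#' @param target_movement The movement contrasted against `"rest"`; rows with
#'   other labels are dropped.
#' @param k Number of nearest hits/misses (default 10).
#' @return Object of class `relieff_weights`: named numeric weight vector
#'   with attributes `movement`, `k_neighbors`, `n_samples_used`.
#' @export
relieff <- function(x, label = NULL, target_movement, k = 10) {
  if (is.list(x) && !is.matrix(x)) {
    label <- x$label
    x <- x$x
  }
  stopifnot(is.matrix(x), length(label) == nrow(x))
  keep <- label %in% c(target_movement, "rest")
  x <- x[keep, , drop = FALSE]
  y <- label[keep]
  counts <- table(y)
  if (length(counts) < 2 || any(counts < k + 1)) {
    stop("each class needs at least k+1 = ", k + 1, " samples; got ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  rng <- apply(x, 2, function(col) diff(range(col)))
  xn <- x
  for (j in seq_len(ncol(x))) {
    xn[, j] <- if (rng[j] > 0) x[, j] / rng[j] else 0
  }
  m <- nrow(xn)
  d <- as.matrix(stats::dist(xn, method = "manhattan"))
  w <- numeric(ncol(xn))
  for (i in seq_len(m)) {
    same <- setdiff(which(y == y[i]), i)
    other <- which(y != y[i])
    # deterministic neighbour choice: distance, then row index
    hits <- same[order(d[i, same], same)][seq_len(k)]
    misses <- other[order(d[i, other], other)][seq_len(k)]
    diff_hit <- abs(sweep(xn[hits, , drop = FALSE], 2, xn[i, ]))
    diff_miss <- abs(sweep(xn[misses, , drop = FALSE], 2, xn[i, ]))
    w <- w + colSums(diff_miss) / (m * k) - colSums(diff_hit) / (m * k)
  }
  names(w) <- colnames(x)
  structure(w, class = "relieff_weights", movement = target_movement,
            k_neighbors = k, n_samples_used = m)
}

#' Top-ranked features
#'
#' @param weights A `relieff_weights` vector (or any named weight vector over
#'   the 17 descriptors).
#' @param n Number of descriptors to return.
#' @return Character vector of descriptors sorted by weight, descending;
#'   ties broken by canonical descriptor order.
#' @export
top_features <- function(weights, n = length(weights)) {
  stopifnot(n <= length(weights))
  canon <- match(names(weights), fau_descriptors())
  ord <- order(-as.numeric(weights), canon)
  names(weights)[ord][seq_len(n)]
}

#' Aggregate feature ranking across movements
#'
#' Combines per-movement ReliefF weights into one consensus list:
#' descriptors are sorted by their maximum weight across movements, with
#' mean weight as the secondary key and canonical order as the final
#' tie-break. ReliefF weights are computed on range-normalised features, so
#' they are commensurable across movements; taking the maximum means a unit
#' that dominates a single movement (the eye-closed units only matter for
#' eye closure) out-ranks units that are merely unremarkable everywhere —
#' which a mean- or rank-based pooling does not guarantee. With the default
#' generator profiles the top nine are exactly the nine units engaged by at
#' least one movement.
#'
#' @param per_movement_weights List of `relieff_weights`, one per voluntary
#'   movement.
#' @param n Number of descriptors to return (default 9, the classifier's
#'   default feature count).
#' @return Character vector of `n` descriptors.
#' @export
aggregate_ranking <- function(per_movement_weights, n = 9) {
  stopifnot(length(per_movement_weights) >= 1)
  desc <- names(per_movement_weights[[1]])
  w <- vapply(per_movement_weights, function(w) as.numeric(w[desc]),
              numeric(length(desc)))
  w <- matrix(w, nrow = length(desc))
  canon <- match(desc, fau_descriptors())
  desc[order(-apply(w, 1, max), -rowMeans(w), canon)][seq_len(n)]
}
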