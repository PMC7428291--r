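# The five grasp penalty functions, evaluated over every ordered
# (thumb-candidate, index-candidate) pair, their per-object [0,1]
# normalization, and the combined overall penalty.
#
# A penalty map is a square matrix indexed by the shared candidate ordering:
# rows are thumb contacts, columns index contacts. The diagonal (both digits
# on the same triangle) is masked as physically impossible.

#' Model configuration
#'
#' Bundles the fixed model parameters: the natural grasp axis (the
#' empirically preferred orientation of the thumb-to-index axis, taken from
#' a published regression of preferred hand postures and unit-normalized on
#' load), the precision-grip aperture threshold below which no aperture
#' penalty accrues, gravitational acceleration (acting along -z), and the
#' hand start location used to decide which side of a grasp the hand
#' occludes.
#'
#' @param nga length-3 natural grasp axis direction; default
#'   \code{c(0.49, 0.87, 0)}.
#' @param aperture_threshold mm; default 25 (precision grips are preferred
#'   for object spans under 2.5 cm).
#' @param gravity m/s^2; default 9.81.
#' @param hand_reference_point length-3, mm; the start location of the hand
#'   in the participant frame (default 280 mm right, 95 mm forward, on the
#'   table).
#' @return An object of class \code{model_config}.
#' @export
model_config <- function(nga = c(0.49, 0.87, 0), aperture_threshold = 25,
                         gravity = 9.81,
                         hand_reference_point = c(280, 95, 0)) {
  nga <- as.numeric(nga)
  stopifnot(length(nga) == 3, sum(nga^2) > 0,
            aperture_threshold > 0, gravity > 0,
            length(hand_reference_point) == 3)
  structure(list(nga = nga / sqrt(sum(nga^2)),
                 aperture_threshold = aperture_threshold,
                 gravity = gravity,
                 hand_reference_point = as.numeric(hand_reference_point)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(paste0("model config: NGA [%s], aperture threshold %g mm, ",
                     "g %g m/s^2, hand at [%s] mm\n"),
              paste(format(round(x$nga, 4)), collapse = ", "),
              x$aperture_threshold, x$gravity,
              paste(format(x$hand_reference_point), collapse = ", ")))
  invisible(x)
}

new_penalty_map <- function(values, label, normalized = FALSE, mask = NULL) {
  dimnames(values) <- NULL
  n <- nrow(values)
  if (is.null(mask)) {
    mask <- matrix(FALSE, n, n)
    diag(mask) <- TRUE
  }
  values[mask] <- NA_real_
  structure(list(values = values, mask = mask, normalized = normalized,
                 label = label, n = n), class = "penalty_map")
}

#' @export
print.penalty_map <- function(x, ...) {
  v <- x$values[!x$mask]
  cat(sprintf("penalty map %s: %d x %d candidates%s, range [%.4g, %.4g]\n",
              x$label, x$n, x$n,
              if (x$normalized) " (normalized)" else "", min(v), max(v)))
  invisible(x)
}

#' Force closure penalty
#'
#' A two-digit grasp achieves force closure when the grasp axis (the segment
#' from thumb to index contact) is aligned with the directions along which
#' the gripping forces act, i.e. the inward surface normals. The penalty is
#' the sum of the angular deviations (via atan2) of the grasp axis from both
#' force vectors, in radians, range [0, 2*pi]. Symmetric under digit swap.
#'
#' @param cands \code{candidate_set}.
#' @return Raw \code{penalty_map}, label "FC".
#' @export
penalty_force_closure <- function(cands) {
  p <- cands$positions
  f <- -cands$normals                      # gripping force directions
  dx <- outer(p[, 1], p[, 1], function(a, b) b - a)   # dx[i,j] = x_j - x_i
  dy <- outer(p[, 2], p[, 2], function(a, b) b - a)
  dz <- outer(p[, 3], p[, 3], function(a, b) b - a)
  # A[i,j] = angle between F_i and (CP_j - CP_i); total = A + t(A)
  dot <- f[, 1] * dx + f[, 2] * dy + f[, 3] * dz
  cx <- f[, 2] * dz - f[, 3] * dy
  cy <- f[, 3] * dx - f[, 1] * dz
  cz <- f[, 1] * dy - f[, 2] * dx
  A <- atan2(sqrt(cx^2 + cy^2 + cz^2), dot)
  new_penalty_map(A + t(A), "FC")
}

#' Torque penalty
#'
#' Magnitude of the net gravitational torque about the contact points when
#' each digit applies a force countering gravity: with lever arms from each
#' contact to the center of mass, the two cross products with the
#' counteracting force sum and their norm is the penalty, in N m (lever arms
#' in m, |F| = mass * g). Zero whenever the thumb-index midpoint lies on the
#' vertical line through the CoM. Symmetric under digit swap.
#'
#' @param cands \code{candidate_set}.
#' @param obj \code{rigid_object} providing mass and center of mass.
#' @param cfg \code{model_config} providing g.
#' @return Raw \code{penalty_map}, label "T".
#' @export
penalty_torque <- function(cands, obj, cfg = model_config()) {
  p <- cands$positions
  com <- object_com(obj)
  # total torque = (2 CoM - CP_T - CP_I) x (0, 0, m g); only the horizontal
  # offset of the contact midpoint from the CoM contributes
  ux <- outer(com[1] - p[, 1], com[1] - p[, 1], "+")   # mm
  uy <- outer(com[2] - p[, 2], com[2] - p[, 2], "+")
  fmag <- (obj$mass / 1000) * cfg$gravity              # N
  new_penalty_map(fmag * sqrt(ux^2 + uy^2) / 1000, "T")
}

#' Natural grasp axis penalty
#'
#' Angular deviation (radians, [0, pi]) of the thumb-to-index grasp axis
#' from the natural grasp axis. The only asymmetric penalty: swapping the
#' digits reverses the grasp axis, so P(i,j) + P(j,i) = pi.
#'
#' @param cands \code{candidate_set}.
#' @param cfg \code{model_config} providing the NGA direction.
#' @return Raw \code{penalty_map}, label "NGA".
#' @export
penalty_nga <- function(cands, cfg = model_config()) {
  p <- cands$positions
  a <- cfg$nga
  dx <- outer(p[, 1], p[, 1], function(x, y) y - x)
  dy <- outer(p[, 2], p[, 2], function(x, y) y - x)
  dz <- outer(p[, 3], p[, 3], function(x, y) y - x)
  dot <- a[1] * dx + a[2] * dy + a[3] * dz
  cx <- a[2] * dz - a[3] * dy
  cy <- a[3] * dx - a[1] * dz
  cz <- a[1] * dy - a[2] * dx
  new_penalty_map(atan2(sqrt(cx^2 + cy^2 + cz^2), dot), "NGA")
}

#' Optimal grasp aperture penalty
#'
#' Zero for grasp apertures (thumb-index distance) up to the threshold, then
#' growing linearly with the excess, in mm. Symmetric under digit swap.
#'
#' @param cands \code{candidate_set}.
#' @param cfg \code{model_config} providing the aperture threshold.
#' @return Raw \code{penalty_map}, label "OGA".
#' @export
penalty_aperture <- function(cands, cfg = model_config()) {
  d <- as.matrix(stats::dist(cands$positions))
  new_penalty_map(pmax(d - cfg$aperture_threshold, 0), "OGA")
}

#' Object visibility penalty
#'
#' Fraction of the object's surface points occluded by the grasping hand:
#' contacts and candidate positions are projected onto the horizontal plane,
#' and every surface point strictly on the same side of the 2D grasp line as
#' the hand start location counts as occluded. Range [0, 1]. Symmetric under
#' digit swap.
#'
#' When both contacts project to the same 2D point the grasp line is
#' undefined; that pair falls back to the line through the point
#' perpendicular to its direction toward the hand.
#'
#' @param cands \code{candidate_set}.
#' @param cfg \code{model_config} providing the hand reference point.
#' @return Raw \code{penalty_map}, label "VIS".
#' @export
penalty_visibility <- function(cands, cfg = model_config()) {
  p <- cands$positions[, 1:2, drop = FALSE]    # project to table plane
  h <- cfg$hand_reference_point[1:2]
  n <- nrow(p)
  # signed side of point s wrt the directed line i -> j:
  #   c(s) = a*x_s + b*y_s + d with a = -(y_j - y_i), b = x_j - x_i
  dxm <- outer(p[, 1], p[, 1], function(x, y) y - x)
  dym <- outer(p[, 2], p[, 2], function(x, y) y - x)
  A <- -dym
  B <- dxm
  D <- dym * p[, 1] - dxm * p[, 2]             # row-recycled: uses x_i, y_i
  degen <- abs(A) + abs(B) < 1e-12
  if (any(degen[upper.tri(degen) | lower.tri(degen)])) {
    # replace the undefined line by the perpendicular to the hand direction
    idx <- which(degen, arr.ind = TRUE)
    idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
    if (nrow(idx)) {
      message(nrow(idx), " coincident contact pair(s): visibility line ",
              "replaced by the perpendicular to the hand direction")
      hd <- cbind(h[1] - p[idx[, 1], 1], h[2] - p[idx[, 1], 2])
      A[idx] <- hd[, 1]; B[idx] <- hd[, 2]
      D[idx] <- -(hd[, 1] * p[idx[, 1], 1] + hd[, 2] * p[idx[, 1], 2])
    }
  }
  hand_side <- A * h[1] + B * h[2] + D
  occluded <- matrix(0, n, n)
  for (s in seq_len(n)) {
    cs <- A * p[s, 1] + B * p[s, 2] + D
    occluded <- occluded + ((cs > 0) == (hand_side > 0) & abs(cs) > 1e-12)
  }
  new_penalty_map(occluded / n, "VIS")
}

#' Normalize a penalty map to [0, 1]
#'
#' Min-max rescaling over the unmasked entries, per object (each object's
#' map is normalized independently). A constant map carries no information
#' and normalizes to all zeros. Idempotent.
#'
#' @param m \code{penalty_map}.
#' @return Normalized \code{penalty_map}.
#' @export
normalize_map <- function(m) {
  v <- m$values[!m$mask]
  if (!length(v)) stop("penalty map has no unmasked entries")
  lo <- min(v); hi <- max(v)
  vals <- if (hi - lo < 1e-15) {
    m$values * 0
  } else {
    (m$values - lo) / (hi - lo)
  }
  new_penalty_map(vals, m$label, normalized = TRUE, mask = m$mask)
}

#' Compute all five penalty maps
#'
#' @param cands \code{candidate_set}.
#' @param obj \code{rigid_object}.
#' @param cfg \code{model_config}.
#' @param normalized normalize each map to [0, 1] (the form entering the
#'   overall penalty).
#' @return Named list of \code{penalty_map}s: FC, T, NGA, OGA, VIS.
#' @export
penalty_stack <- function(cands, obj, cfg = model_config(), normalized = TRUE) {
  maps <- list(FC = penalty_force_closure(cands),
               T = penalty_torque(cands, obj, cfg),
               NGA = penalty_nga(cands, cfg),
               OGA = penalty_aperture(cands, cfg),
               VIS = penalty_visibility(cands, cfg))
  if (normalized) maps <- lapply(maps, normalize_map)
  maps
}

#' Combine penalty maps into the overall grasp penalty
#'
#' Unweighted mode sums the five normalized maps and rescales the sum to
#' [0, 1]; its minima are the grasps that best satisfy all constraints at
#' once. Weighted mode computes the fitted-model form, the weighted sum of
#' squared penalties \code{sum_i w_i P_i^2} (set \code{squared = FALSE} for
#' the unsquared variant), returned unnormalized.
#'
#' @param maps named list of five normalized \code{penalty_map}s over the
#'   same candidate set.
#' @param weights \code{NULL} for the unweighted sum, or a numeric vector of
#'   five nonnegative weights named/ordered FC, T, NGA, OGA, VIS.
#' @param squared square each penalty in weighted mode (the fitted form).
#' @return \code{penalty_map} labelled "OVERALL".
#' @export
combine_maps <- function(maps, weights = NULL, squared = TRUE) {
  stopifnot(length(maps) == 5)
  n <- maps[[1]]$n
  for (m in maps) {
    if (m$n != n) stop("penalty maps cover different candidate sets")
    if (!m$normalized) stop("combine_maps expects normalized maps")
  }
  mask <- Reduce(`|`, lapply(maps, `[[`, "mask"))
  if (is.null(weights)) {
    total <- Reduce(`+`, lapply(maps, `[[`, "values"))
    return(normalize_map(new_penalty_map(total, "OVERALL", mask = mask)))
  }
  w <- as.numeric(weights)
  stopifnot(length(w) == 5, all(w >= 0))
  e <- if (squared) 2 else 1
  total <- Reduce(`+`, Map(function(m, wi) wi * m$values^e, maps, w))
  new_penalty_map(total, "OVERALL", mask = mask)
}

#' Write / read a penalty map as delimited text with a JSON sidecar
#'
#' The matrix goes to \code{path} (tab-separated, \code{NA} for masked
#' pairs) and the metadata (candidate count, label, normalized flag) to
#' \code{paste0(path, ".json")}.
#' @param m \code{penalty_map}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_penalty_map <- function(m, path) {
  utils::write.table(m$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(n = m$n, label = m$label,
                            normalized = m$normalized),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_penalty_map
#' @export
read_penalty_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(vals) <- NULL
  new_penalty_map(vals, meta$label, normalized = meta$normalized,
                  mask = is.na(vals))
}
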