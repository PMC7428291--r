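# Rigid transforms (rotation + translation) between the object frame and the
# participant frame. Coordinate convention used throughout the package:
# x rightward, y away from the participant, z up; the table plane is z = 0;
# all lengths in mm.

#' Create a rigid transform
#'
#' A rigid transform maps object-frame coordinates into the participant frame
#' as \code{x_participant = R x_object + t}. Rotations must be proper
#' (orthonormal, determinant +1); reflections are rejected.
#'
#' @param rotation 3x3 orthonormal rotation matrix with determinant +1.
#' @param translation length-3 numeric translation, mm.
#' @return An object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal")
  if (det(rotation) < 0)
    stop("rotation must be proper (det = +1), reflections are not rigid poses")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation (mm):", format(round(x$translation, 3)), "\n")
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param tf \code{rigid_transform}.
#' @param points n x 3 matrix (or length-3 vector) of coordinates, mm.
#' @param vector logical; if TRUE transform as directions (rotation only).
#' @return Matrix of transformed coordinates with the input shape.
#' @export
transform_points <- function(tf, points, vector = FALSE) {
  p <- rbind3(points)
  out <- p %*% t(tf$rotation)
  if (!vector) out <- sweep(out, 2, tf$translation, "+")
  if (is.null(dim(points))) out[1, ] else out
}

#' Invert a rigid transform
#' @param tf \code{rigid_transform}.
#' @return The inverse \code{rigid_transform}.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), -drop(t(tf$rotation) %*% tf$translation))
}

#' Compose two rigid transforms
#' @param a,b \code{rigid_transform}s; the result applies \code{b} first.
#' @return \code{rigid_transform} equal to \code{a %after% b}.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Rotation matrix about a coordinate axis or arbitrary axis
#'
#' @param axis "x", "y", "z" or a length-3 direction vector.
#' @param angle_deg rotation angle in degrees, counterclockwise looking down
#'   the axis toward the origin (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  if (is.character(axis))
    axis <- switch(match.arg(axis, c("x", "y", "z")),
                   x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigid Procrustes alignment of matched point sets
#'
#' Finds the rotation and translation (no scaling, no reflection) minimizing
#' the sum of squared distances between \code{transform_points(tf, model)}
#' and \code{measured}. Used to pose mesh models in the participant frame
#' from a handful of measured landmark points.
#'
#' @param model n x 3 matrix of model-frame landmarks, n >= 4, non-coplanar.
#' @param measured n x 3 matrix of the same landmarks measured in the
#'   participant frame.
#' @return \code{rigid_transform} mapping model coordinates to measured ones.
#' @export
align_procrustes <- function(model, measured) {
  model <- rbind3(model); measured <- rbind3(measured)
  if (nrow(model) < 4) stop("need at least 4 point correspondences")
  if (nrow(model) != nrow(measured)) stop("point sets must be matched 1:1")
  cm <- colMeans(model); cs <- colMeans(measured)
  A <- sweep(model, 2, cm); B <- sweep(measured, 2, cs)
  sv <- svd(A)
  # coplanar (or worse) configurations leave a rotation dof unconstrained
  if (sv$d[3] < 1e-8 * max(sv$d[1], 1))
    stop("landmarks are coplanar or degenerate; rotation is not identifiable")
  s <- svd(crossprod(B, A))  # maximizes tr(R * t(B) %*% A)... see Kabsch
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  rigid_transform(R, cs - drop(R %*% cm))
}

# stack points as an n x 3 double matrix
rbind3 <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3)
  points
}
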