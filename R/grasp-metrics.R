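# Grasp similarity and behavioral statistics. Similarity between two grasps
# is 100 * (1 - d6 / D_max): the Euclidean distance between their 6D contact
# vectors, normalized by the object's largest pairwise 3D extent. Because
# the 6D distance can exceed the 3D D_max, similarity is reported unclamped
# (optionally floored at 0).

#' Similarity between two grasps
#'
#' @param g1,g2 length-6 grasp vectors \code{[xT,yT,zT,xI,yI,zI]} (or
#'   single-row grasp data frames), mm, in a common frame.
#' @param d_max object's largest pairwise vertex distance, mm (see
#'   \code{rigid_object$d_max}).
#' @param clamp floor the similarity at 0 (default FALSE: values below 0
#'   indicate 6D distances beyond the 3D object extent).
#' @return List with \code{value} (percent), \code{d6}, \code{d_max}.
#' @export
grasp_similarity <- function(g1, g2, d_max, clamp = FALSE) {
  stopifnot(d_max > 0)
  v1 <- as_grasp_vector(g1); v2 <- as_grasp_vector(g2)
  d6 <- sqrt(sum((v1 - v2)^2))
  s <- 100 * (1 - d6 / d_max)
  if (clamp) s <- max(s, 0)
  list(value = s, d6 = d6, d_max = d_max)
}

as_grasp_vector <- function(g) {
  if (is.data.frame(g)) {
    stopifnot(nrow(g) == 1)
    return(as.numeric(grasp_matrix(g)))
  }
  stopifnot(length(g) == 6)
  as.numeric(g)
}

# pairwise 6D distance matrix of a grasp set
grasp_dist <- function(grasps) {
  as.matrix(stats::dist(grasp_matrix(grasps)))
}

#' Medoid grasp of a set
#'
#' The member minimizing the summed 6D distance to all other members; ties
#' break to the lowest row index.
#' @param grasps grasp data frame, >= 1 row.
#' @return One-row grasp data frame (the medoid member).
#' @export
medoid_grasp <- function(grasps) {
  stopifnot(nrow(grasps) >= 1)
  if (nrow(grasps) == 1) return(grasps)
  tot <- rowSums(grasp_dist(grasps))
  grasps[which.min(tot), , drop = FALSE]
}

#' Within- and between-subject grasp similarity
#'
#' Within-subject similarity is the mean similarity of each subject's grasps
#' to that subject's own medoid grasp. Between-subject similarity is the
#' similarity of each subject's medoid to the medoid of all other subjects'
#' grasps pooled.
#'
#' @param grasps grasp data frame with a \code{subject} column.
#' @param d_max normalizing distance, mm.
#' @param clamp passed to \code{\link{grasp_similarity}}.
#' @return Data frame: subject, within, between (percent; between is NA
#'   with a single subject).
#' @export
within_between_similarity <- function(grasps, d_max, clamp = FALSE) {
  stopifnot(!is.null(grasps$subject))
  subjects <- unique(grasps$subject)
  res <- lapply(subjects, function(s) {
    own <- grasps[grasps$subject == s, , drop = FALSE]
    med <- medoid_grasp(own)
    within <- mean(vapply(seq_len(nrow(own)), function(i)
      grasp_similarity(own[i, ], med, d_max, clamp)$value, 0))
    others <- grasps[grasps$subject != s, , drop = FALSE]
    between <- if (nrow(others)) {
      grasp_similarity(med, medoid_grasp(others), d_max, clamp)$value
    } else NA_real_
    data.frame(subject = s, within = within, between = between)
  })
  do.call(rbind, res)
}

#' Chance-level grasp similarity from random surface grasps
#'
#' Samples uniform random (thumb, index) candidate pairs (the diagonal
#' excluded) — grasps randomly attemptable on the object — and reports the
#' mean similarity of the sample to its own medoid, with a seeded bootstrap
#' confidence interval. This estimates the similarity floor imposed by
#' object geometry alone.
#'
#' @param cands \code{candidate_set}.
#' @param d_max normalizing distance, mm.
#' @param n number of random grasps.
#' @param seed integer seed.
#' @param n_boot bootstrap resamples for the CI (default 10000).
#' @param clamp passed to \code{\link{grasp_similarity}}.
#' @return List: \code{value} (percent), \code{ci} (2.5/97.5 percentiles),
#'   \code{grasps} (the sample).
#' @export
random_grasp_baseline <- function(cands, d_max, n, seed = NULL,
                                  n_boot = 10000, clamp = FALSE) {
  stopifnot(n >= 2)
  g <- random_grasps(cands, n, seed)
  med <- medoid_grasp(g)
  sims <- vapply(seq_len(n), function(i)
    grasp_similarity(g[i, ], med, d_max, clamp)$value, 0)
  ci <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
    means <- vapply(seq_len(n_boot), function(b)
      mean(sims[sample.int(n, n, replace = TRUE)]), 0)
    stats::quantile(means, c(0.025, 0.975), names = FALSE)
  })
  list(value = mean(sims), ci = ci, grasps = g)
}

#' Uniform random grasps on the candidate set
#' @param cands \code{candidate_set}.
#' @param n number of grasps.
#' @param seed integer seed.
#' @return Grasp data frame.
#' @export
random_grasps <- function(cands, n, seed = NULL) {
  with_seed(seed, {
    ti <- cbind(sample.int(cands$n, n, replace = TRUE),
                sample.int(cands$n, n, replace = TRUE))
    same <- ti[, 1] == ti[, 2]
    while (any(same)) {         # resample diagonal picks
      ti[same, 2] <- sample.int(cands$n, sum(same), replace = TRUE)
      same <- ti[, 1] == ti[, 2]
    }
    grasp_table(cands$positions[ti[, 1], , drop = FALSE],
                cands$positions[ti[, 2], , drop = FALSE],
                thumb_cand = ti[, 1], index_cand = ti[, 2])
  })
}

# distance of each grasp's thumb-index midpoint to a reference point
midpoint_distances <- function(grasps, ref) {
  gm <- grasp_matrix(grasps)
  mid <- (gm[, 1:3, drop = FALSE] + gm[, 4:6, drop = FALSE]) / 2
  sqrt(rowSums(sweep(mid, 2, ref)^2))
}

#' Attraction of grasps toward the center of mass
#'
#' Mean CoM distance of random surface grasps minus mean CoM distance of
#' the observed grasps, where a grasp's CoM distance is measured from its
#' thumb-index midpoint. Positive values mean the observed grasps lie
#' closer to the CoM than geometry alone predicts.
#'
#' @param grasps observed grasp data frame.
#' @param obj \code{rigid_object} (for the posed CoM).
#' @param cands \code{candidate_set} for the random baseline.
#' @param baseline_n number of random grasps.
#' @param seed integer seed.
#' @return List: \code{attraction} (mm), \code{observed_mean},
#'   \code{random_mean}.
#' @export
com_attraction <- function(grasps, obj, cands, baseline_n = 1000,
                           seed = NULL) {
  com <- object_com(obj)
  obs <- mean(midpoint_distances(grasps, com))
  rnd <- mean(midpoint_distances(random_grasps(cands, baseline_n, seed), com))
  list(attraction = rnd - obs, observed_mean = obs, random_mean = rnd)
}

#' Spatial bias of grasps toward the hand start location
#'
#' Distance from the start location to the object centroid minus the mean
#' distance from the start location to the grasp midpoints. Positive values
#' mean grasps land nearer the start location than the object centroid does.
#'
#' @param grasps grasp data frame.
#' @param obj \code{rigid_object}.
#' @param start_point length-3 start location, mm (e.g. the configured hand
#'   reference point).
#' @param planar measure in the horizontal (x, y) plane only.
#' @return Bias in mm.
#' @export
spatial_bias <- function(grasps, obj, start_point, planar = FALSE) {
  centroid <- object_centroid(obj)
  start_point <- as.numeric(start_point)
  if (planar) {
    centroid[3] <- 0
    start_point[3] <- 0
    gm <- grasp_matrix(grasps)
    gm[, c(3, 6)] <- 0
    grasps <- grasp_table(gm[, 1:3, drop = FALSE], gm[, 4:6, drop = FALSE])
  }
  ref <- sqrt(sum((centroid - start_point)^2))
  ref - mean(midpoint_distances(grasps, start_point))
}

#' Re-express grasps in egocentric or allocentric coordinates
#'
#' Egocentric encoding keeps the participant-frame coordinates unchanged;
#' allocentric encoding maps the contacts through the inverse object pose
#' into the object frame, so grasps on the same object at different
#' orientations become directly comparable.
#'
#' @param grasps grasp data frame in the participant frame.
#' @param pose the object's \code{rigid_transform} for those trials.
#' @param mode "egocentric" or "allocentric".
#' @return Grasp data frame in the requested frame.
#' @export
encode_frame <- function(grasps, pose, mode = c("egocentric", "allocentric")) {
  mode <- match.arg(mode)
  if (mode == "egocentric") return(grasps)
  inv <- invert_transform(pose)
  gm <- grasp_matrix(grasps)
  out <- grasps
  out[, grasp_columns] <- cbind(transform_points(inv, gm[, 1:3, drop = FALSE]),
                                transform_points(inv, gm[, 4:6, drop = FALSE]))
  out
}

#' Synthetic clustered grasp sets
#'
#' Generates per-subject grasp clusters for exercising the similarity
#' metrics, mimicking the hierarchical structure of human grasping data: a
#' population anchor grasp is drawn from the candidate pairs, each subject's
#' cluster center scatters around it with Gaussian jitter of
#' \code{sigma_between} mm, and individual trials scatter around the
#' subject center with \code{sigma_within} mm (both on each contact). With
#' \code{sigma_within < sigma_between} much smaller than the object extent,
#' within-subject similarity exceeds between-subject similarity, which in
#' turn exceeds the geometry-only chance level.
#'
#' @param cands \code{candidate_set}.
#' @param n_subjects number of subjects.
#' @param n_trials trials per subject.
#' @param sigma_within within-subject jitter SD, mm (default 5, the scale of
#'   human repeat-grasp scatter).
#' @param sigma_between between-subject cluster spread SD, mm (default 15).
#' @param seed integer seed.
#' @return Grasp data frame with a \code{subject} column.
#' @export
simulate_clustered_grasps <- function(cands, n_subjects, n_trials,
                                      sigma_within = 5, sigma_between = 15,
                                      seed = NULL) {
  with_seed(seed, {
    ti <- sample.int(cands$n, 2)
    anchor <- c(cands$positions[ti[1], ], cands$positions[ti[2], ])
    out <- lapply(seq_len(n_subjects), function(s) {
      center <- anchor + stats::rnorm(6, 0, sigma_between)
      scatter <- matrix(stats::rnorm(n_trials * 6, 0, sigma_within),
                        n_trials, 6)
      gm <- sweep(scatter, 2, center, "+")
      g <- grasp_table(gm[, 1:3, drop = FALSE], gm[, 4:6, drop = FALSE])
      g$subject <- s
      g
    })
    do.call(rbind, out)
  })
}
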