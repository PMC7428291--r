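# End-to-end orchestration: object -> candidate contacts -> penalty stack ->
# overall penalty -> sampled predictions (-> weight fit and similarity
# metrics when observations are supplied), plus the model perturbation
# experiments (candidate subsampling, aperture-threshold relaxation, natural
# grasp axis rotation).

#' Run the full grasp-prediction pipeline
#'
#' @param obj \code{rigid_object}.
#' @param cfg \code{model_config}.
#' @param observed optional grasp data frame of observed trials (fingertip
#'   positions in the participant frame); when given, contacts are snapped
#'   to the candidate set, constraint weights are fitted, and
#'   model-vs-observed medoid similarity is reported.
#' @param n_predict number of predicted grasps to sample (defaults to the
#'   observed trial count, or 10).
#' @param weights optional five weights: use the weighted (fitted-form)
#'   combination instead of the unweighted sum.
#' @param percentile survivor percentile for sampling.
#' @param subsample_pct candidate subsampling percentage.
#' @param seed integer seed controlling subsampling and sampling.
#' @param table_z table plane height, mm.
#' @return List: \code{candidates}, \code{maps}, \code{overall},
#'   \code{predictions}, and with observations \code{observed_snapped},
#'   \code{fit}, \code{similarity_to_observed}; plus a \code{log} record
#'   (seed, config hash, package version).
#' @export
run_pipeline <- function(obj, cfg = model_config(), observed = NULL,
                         n_predict = NULL, weights = NULL, percentile = 0.1,
                         subsample_pct = 100, seed = 1, table_z = 0) {
  cands <- candidate_contacts(obj, table_z = table_z,
                              subsample_pct = subsample_pct, seed = seed)
  maps <- penalty_stack(cands, obj, cfg)
  overall <- if (is.null(weights)) {
    combine_maps(maps)
  } else {
    normalize_map(combine_maps(maps, weights = weights))
  }
  if (is.null(n_predict))
    n_predict <- if (!is.null(observed)) nrow(observed) else 10L
  predictions <- sample_optimal_grasps(overall, cands, n_predict,
                                       percentile = percentile,
                                       seed = seed + 1L)
  out <- list(candidates = cands, maps = maps, overall = overall,
              predictions = predictions,
              log = pipeline_log(cfg, seed,
                                 subsample_pct = subsample_pct,
                                 percentile = percentile))
  if (!is.null(observed)) {
    snapped <- project_contacts(cands, grasp_matrix(observed)[, 1:3, drop = FALSE],
                                grasp_matrix(observed)[, 4:6, drop = FALSE],
                                trial = observed$trial)
    out$observed_snapped <- snapped
    out$fit <- fit_weights(build_fit_problem(maps, snapped))
    out$similarity_to_observed <- grasp_similarity(
      medoid_grasp(predictions), medoid_grasp(snapped), obj$d_max)$value
  }
  out
}

pipeline_log <- function(cfg, seed, ...) {
  cfg_string <- paste(utils::capture.output(utils::str(c(unclass(cfg),
                                                         list(...)))),
                      collapse = "\n")
  list(seed = seed,
       config_hash = sprintf("%08x", sum(utf8ToInt(cfg_string) *
                                           seq_along(utf8ToInt(cfg_string))) %%
                               .Machine$integer.max),
       package_version = as.character(utils::packageVersion("graspsel")),
       r_version = R.version.string,
       timestamp = format(Sys.time(), tz = "UTC"))
}

#' Rotate the natural grasp axis within an anatomical plane
#'
#' Transverse-plane rotations are about the z (vertical) axis; sagittal
#' about the x (left-right) axis. Positive angles are counterclockwise
#' looking down the rotation axis; for sagittal rotations positive angles
#' tilt the thumb below the index finger.
#'
#' @param cfg \code{model_config}.
#' @param angle_deg signed rotation angle, degrees.
#' @param plane "transverse" or "sagittal".
#' @return New \code{model_config} with the rotated NGA.
#' @export
rotate_nga <- function(cfg, angle_deg, plane = c("transverse", "sagittal")) {
  plane <- match.arg(plane)
  axis <- if (plane == "transverse") "z" else "x"
  # mutate in place: rotation preserves unit length, and a 0-degree
  # rotation must reproduce the baseline configuration bit-exactly
  cfg$nga <- drop(rotation_about(axis, angle_deg) %*% cfg$nga)
  cfg
}

#' Model perturbation experiment
#'
#' Re-runs the prediction pipeline with one model component perturbed over a
#' set of levels and reports, per level and seed, the similarity between the
#' medoid predicted grasp and the medoid of the observed grasps:
#' \describe{
#'   \item{subsample}{levels = percentages of candidate contacts retained}
#'   \item{aperture}{levels = aperture thresholds, mm}
#'   \item{nga_rotation}{levels = signed rotation angles, degrees, in
#'     \code{plane}}
#' }
#' The identity level (100 / the configured threshold / 0) reproduces the
#' unperturbed pipeline exactly.
#'
#' @param kind one of "subsample", "aperture", "nga_rotation".
#' @param levels numeric perturbation levels.
#' @param obj \code{rigid_object}.
#' @param observed grasp data frame of observed trials.
#' @param cfg \code{model_config}.
#' @param plane rotation plane, required for \code{nga_rotation}.
#' @param seeds integer seeds; stochastic perturbations (subsampling, and
#'   the prediction sampling itself) are repeated per seed.
#' @param ... further arguments to \code{\link{run_pipeline}}.
#' @return Tidy data frame: kind, level, seed, similarity (NA with a reason
#'   column if a level is infeasible).
#' @export
run_perturbation <- function(kind = c("subsample", "aperture", "nga_rotation"),
                             levels, obj, observed, cfg = model_config(),
                             plane = c("transverse", "sagittal"),
                             seeds = 1L, ...) {
  kind <- match.arg(kind)
  if (kind == "nga_rotation") plane <- match.arg(plane)
  stopifnot(length(levels) >= 1)
  rows <- list()
  for (lv in levels) {
    for (sd in seeds) {
      res <- tryCatch({
        pl <- switch(kind,
          subsample = run_pipeline(obj, cfg, observed = observed,
                                   subsample_pct = lv, seed = sd, ...),
          aperture = {
            stopifnot(lv > 0)
            cfg2 <- cfg
            cfg2$aperture_threshold <- lv
            run_pipeline(obj, cfg2, observed = observed, seed = sd, ...)
          },
          nga_rotation = run_pipeline(obj, rotate_nga(cfg, lv, plane),
                                      observed = observed, seed = sd, ...))
        list(sim = pl$similarity_to_observed, reason = NA_character_)
      }, error = function(e) list(sim = NA_real_, reason = conditionMessage(e)))
      rows[[length(rows) + 1L]] <-
        data.frame(kind = kind,
                   plane = if (kind == "nga_rotation") plane else NA_character_,
                   level = lv, seed = sd, similarity = res$sim,
                   reason = res$reason)
    }
  }
  do.call(rbind, rows)
}
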