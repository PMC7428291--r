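# Fitting per-participant constraint weights. Observed grasps define a
# binary human penalty function P_H over the grasp manifold (0 where the
# participant grasped, 1 everywhere else); the fitted model
#   P_fit = sum_i w_i * P_i^2
# approximates P_H in least squares, with a regularization table R giving
# the few selected grasps the same total influence as the vast non-selected
# region. Weights are box-constrained to [0, 1].

#' Build a weight-fitting problem from observed grasps
#'
#' Selected pairs (those the participant grasped, after snapping to the
#' candidate set) get human penalty 0 and regularization weight equal to
#' their selection count; every other unmasked pair gets penalty 1 and
#' regularization weight N_selected / N_nonselected. Both regions then sum
#' to N_selected, balancing their influence on the fit.
#'
#' @param maps named list of five normalized \code{penalty_map}s (FC, T,
#'   NGA, OGA, VIS).
#' @param observed grasp data frame carrying \code{thumb_cand} and
#'   \code{index_cand} columns (see \code{\link{project_contacts}}).
#' @return A \code{fit_problem}.
#' @export
build_fit_problem <- function(maps, observed) {
  stopifnot(length(maps) == 5)
  n <- maps[[1]]$n
  if (is.null(observed$thumb_cand) || is.null(observed$index_cand))
    stop("observed grasps must carry candidate indices ",
         "(snap them with project_contacts)")
  if (!nrow(observed)) stop("no observed grasps")
  mask <- Reduce(`|`, lapply(maps, `[[`, "mask"))
  sel <- indices_to_pair(observed$thumb_cand, observed$index_cand, n)
  if (any(mask[sel])) stop("observed grasps fall on masked pairs")
  counts <- table(sel)
  n_selected <- nrow(observed)
  n_nonselected <- sum(!mask) - length(counts)
  if (n_nonselected < 1) stop("no non-selected pairs left in the manifold")

  p_h <- matrix(1, n, n)
  r <- matrix(n_selected / n_nonselected, n, n)
  sel_idx <- as.integer(names(counts))
  p_h[sel_idx] <- 0
  r[sel_idx] <- as.numeric(counts)
  p_h[mask] <- NA; r[mask] <- NA
  structure(list(maps = maps, p_h = p_h, r = r, mask = mask,
                 n_selected = n_selected, n_nonselected = n_nonselected,
                 selection_counts = counts), class = "fit_problem")
}

#' @export
print.fit_problem <- function(x, ...) {
  cat(sprintf(paste0("fit problem: %d selected grasps on %d distinct pairs, ",
                     "%d non-selected pairs\n"),
              x$n_selected, length(x$selection_counts), x$n_nonselected))
  invisible(x)
}

#' Fit constraint weights by bounded least squares
#'
#' Minimizes the regularized squared misfit between the weighted penalty
#' combination \code{sum_i w_i P_i^e} and the binary human penalty function
#' \code{P_H} over the unmasked grasp manifold, with each weight bounded in
#' \code{bounds} and started at \code{start}. The exponent is 2 (squared
#' penalties, the fitted-model form) unless \code{squared = FALSE}.
#'
#' \code{residual_weighting} controls where the regularization table R
#' enters. \code{"balance"} (default) minimizes
#' \code{sum R * (sum_i w_i P_i^e - P_H)^2}: R weights the squared
#' residuals, so the selected and non-selected regions — over each of which
#' R sums to N_selected — carry exactly equal total influence, which is the
#' purpose R was designed for. \code{"literal"} squares the weighted
#' residual \code{R * (...)} itself, which re-unbalances the regions toward
#' the few selected pairs (documented in the methods vignette; kept for
#' sensitivity analysis).
#'
#' Because the residual is linear in the weights this is a box-constrained
#' convex quadratic program, solved with a projected quasi-Newton method
#' and analytic gradient; the bounded optimum it reaches is global.
#'
#' @param problem \code{fit_problem}.
#' @param start starting value for every weight; default 0.2.
#' @param bounds lower/upper weight bounds; default c(0, 1).
#' @param squared use squared penalties (default) or the unsquared variant.
#' @param residual_weighting "balance" (default) or "literal"; see Details.
#' @return A \code{weight_fit}: \code{weights} (named), \code{relative}
#'   (weights / sum), \code{residual} (weighted sum of squares at the
#'   solution), \code{converged}, \code{solver}.
#' @export
fit_weights <- function(problem, start = 0.2, bounds = c(0, 1),
                        squared = TRUE,
                        residual_weighting = c("balance", "literal")) {
  stopifnot(inherits(problem, "fit_problem"),
            bounds[1] <= start, start <= bounds[2])
  residual_weighting <- match.arg(residual_weighting)
  open <- !problem$mask
  e <- if (squared) 2 else 1
  X <- vapply(problem$maps, function(m) (m$values[open])^e,
              numeric(sum(open)))
  rr <- problem$r[open]
  sw <- if (residual_weighting == "balance") sqrt(rr) else rr
  X <- X * sw
  # minimize || sw * (sum_i w_i P_i^e - P_H) ||^2 = || X w - sw * P_H ||^2
  y <- sw * problem$p_h[open]
  obj <- function(w) { r <- drop(X %*% w) - y; sum(r * r) }
  grad <- function(w) { r <- drop(X %*% w) - y; drop(2 * crossprod(X, r)) }
  w0 <- rep(start, 5)
  fit <- stats::nlminb(w0, obj, grad, lower = bounds[1], upper = bounds[2],
                       control = list(rel.tol = 1e-10, x.tol = 1e-10,
                                      iter.max = 500))
  if (fit$objective > obj(w0) + 1e-12)
    warning("solver did not improve on the starting point")
  w <- stats::setNames(fit$par, names(problem$maps))
  structure(list(weights = w,
                 relative = relative_weights(w),
                 residual = fit$objective,
                 start_residual = obj(w0),
                 converged = fit$convergence == 0,
                 squared = squared,
                 solver = list(algorithm = "nlminb (bounded quasi-Newton)",
                               message = fit$message,
                               iterations = fit$iterations)),
            class = "weight_fit")
}

#' @export
print.weight_fit <- function(x, ...) {
  cat("fitted constraint weights", if (!x$squared) "(unsquared penalties)",
      "\n")
  print(round(rbind(weight = x$weights, relative = x$relative), 4))
  cat(sprintf("  residual %.6g (start %.6g), converged: %s\n",
              x$residual, x$start_residual, x$converged))
  invisible(x)
}

#' Relative constraint weights
#'
#' Each weight divided by the sum of all weights; sums to one.
#' @param w numeric vector of five nonnegative weights, or a
#'   \code{weight_fit}.
#' @return Named numeric vector of fractions.
#' @export
relative_weights <- function(w) {
  if (inherits(w, "weight_fit")) w <- w$weights
  stopifnot(is.numeric(w), all(w >= 0))
  if (sum(w) <= 0) stop("relative weights undefined: all weights are zero")
  w / sum(w)
}

#' Simulate a synthetic grasping observer
#'
#' Draws grasps from the weighted overall penalty built with known true
#' weights, via the same percentile truncation and probability-weighted
#' resampling used for model predictions. This is the generator behind the
#' parameter-recovery checks: fitted weights can be compared against
#' \code{w_true}. Optional candidate jitter resamples each chosen contact
#' uniformly among its \code{jitter_k} nearest candidates (itself included),
#' emulating motor/measurement noise at the discretization scale.
#'
#' @param maps named list of five normalized \code{penalty_map}s.
#' @param cands the matching \code{candidate_set}.
#' @param w_true numeric vector of five true weights in [0, 1].
#' @param n_trials number of grasps to simulate.
#' @param jitter_k 1 for no jitter (default), else the nearest-neighbour
#'   pool size.
#' @param percentile survivor percentile passed to the sampler.
#' @param seed integer seed.
#' @return Grasp data frame with candidate indices.
#' @export
simulate_observer <- function(maps, cands, w_true, n_trials, jitter_k = 1,
                              percentile = 0.1, seed = NULL) {
  overall <- normalize_map(combine_maps(maps, weights = w_true))
  g <- sample_optimal_grasps(overall, cands, n_trials,
                             percentile = percentile, seed = seed)
  if (jitter_k > 1) {
    nn <- nearest_candidates(cands, jitter_k)
    g <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
      jt <- nn[cbind(g$thumb_cand,
                     sample.int(jitter_k, nrow(g), replace = TRUE))]
      ji <- nn[cbind(g$index_cand,
                     sample.int(jitter_k, nrow(g), replace = TRUE))]
      # avoid collapsing a grasp onto a single triangle
      same <- jt == ji
      ji[same] <- g$index_cand[same]
      grasp_table(cands$positions[jt, , drop = FALSE],
                  cands$positions[ji, , drop = FALSE],
                  thumb_cand = jt, index_cand = ji, trial = g$trial)
    })
  }
  g
}

# row i: indices of the k nearest candidates to candidate i (self first)
nearest_candidates <- function(cands, k) {
  d <- as.matrix(stats::dist(cands$positions))
  t(apply(d, 1, function(row) order(row)[seq_len(k)]))
}

#' Serialize a weight fit as JSON
#' @param fit \code{weight_fit}.
#' @param path output path.
#' @export
write_weight_fit <- function(fit, path) {
  jsonlite::write_json(list(weights = as.list(fit$weights),
                            relative_weights = as.list(fit$relative),
                            residual = fit$residual,
                            converged = fit$converged,
                            solver_meta = fit$solver),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
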