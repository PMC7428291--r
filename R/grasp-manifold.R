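# The 2D grasp manifold: all ordered (thumb, index) candidate pairs under a
# shared deterministic candidate ordering (mesh face order). Grasps travel
# as data frames with one row per trial and columns
#   xT yT zT xI yI zI [thumb_cand index_cand trial ...]
# so they serialize directly as delimited text.

grasp_columns <- c("xT", "yT", "zT", "xI", "yI", "zI")

#' Assemble a grasp table from thumb and index contact positions
#'
#' @param thumb,index n x 3 matrices (or length-3 vectors), mm.
#' @param thumb_cand,index_cand optional candidate indices.
#' @param trial optional trial identifiers.
#' @return Grasp data frame (one 6D grasp vector per row).
#' @export
grasp_table <- function(thumb, index, thumb_cand = NULL, index_cand = NULL,
                        trial = NULL) {
  thumb <- rbind3(thumb); index <- rbind3(index)
  stopifnot(nrow(thumb) == nrow(index))
  g <- as.data.frame(cbind(thumb, index))
  names(g) <- grasp_columns
  g$trial <- if (is.null(trial)) seq_len(nrow(g)) else trial
  if (!is.null(thumb_cand)) g$thumb_cand <- thumb_cand
  if (!is.null(index_cand)) g$index_cand <- index_cand
  g
}

#' 6D grasp vectors as a matrix
#' @param grasps grasp data frame.
#' @return n x 6 matrix [xT, yT, zT, xI, yI, zI].
#' @export
grasp_matrix <- function(grasps) {
  as.matrix(grasps[, grasp_columns, drop = FALSE])
}

#' Convert between linear pair index and (thumb, index) candidate indices
#'
#' Pairs are stored column-major in the n x n map: linear index
#' \code{k = (index - 1) * n + thumb}.
#' @param k linear pair index.
#' @param n candidate count.
#' @return \code{pair_to_indices}: 2-column matrix (thumb, index);
#'   \code{indices_to_pair}: linear indices.
#' @export
pair_to_indices <- function(k, n) {
  cbind(thumb = (k - 1L) %% n + 1L, index = (k - 1L) %/% n + 1L)
}

#' @rdname pair_to_indices
#' @param thumb,index candidate indices.
#' @export
indices_to_pair <- function(thumb, index, n) {
  (index - 1L) * n + thumb
}

#' Sample predicted optimal grasps from an overall penalty map
#'
#' Grasps with penalty above the lower \code{percentile}-th percentile of
#' the map are discarded, leaving only optimal and near-optimal grasps
#' (0.1 covers roughly the proportion of grasp space human grasps occupy).
#' From the survivors, \code{n} grasps are drawn with replacement with
#' probability proportional to 1 minus the grasp penalty (renormalized over
#' the survivors), so zero-penalty grasps are the most likely picks.
#'
#' @param overall normalized \code{penalty_map} (label OVERALL or any
#'   normalized map).
#' @param cands the \code{candidate_set} the map was computed on.
#' @param n number of grasps to draw (e.g. the observed trial count).
#' @param percentile lower percentile retained, in percent; default 0.1.
#' @param seed integer seed.
#' @return Grasp data frame with candidate indices and penalties.
#' @export
sample_optimal_grasps <- function(overall, cands, n, percentile = 0.1,
                                  seed = NULL) {
  stopifnot(n >= 1)
  if (!overall$normalized)
    stop("overall map must be normalized before sampling")
  if (overall$n != cands$n)
    stop("penalty map and candidate set sizes differ")
  open <- which(!overall$mask)
  v <- overall$values[open]
  thr <- stats::quantile(v, percentile / 100, names = FALSE)
  keep <- open[v <= thr]
  if (!length(keep)) {      # cannot happen for percentile > 0; guard anyway
    warning("empty survivor set; widening to the map minimum")
    keep <- open[v == min(v)]
  }
  w <- pmax(1 - overall$values[keep], 0)
  if (sum(w) == 0) w <- rep(1, length(keep))
  pick <- with_seed(seed,
                    keep[sample.int(length(keep), n, replace = TRUE,
                                    prob = w / sum(w))])
  ti <- pair_to_indices(pick, overall$n)
  g <- grasp_table(cands$positions[ti[, "thumb"], , drop = FALSE],
                   cands$positions[ti[, "index"], , drop = FALSE],
                   thumb_cand = ti[, "thumb"], index_cand = ti[, "index"])
  g$penalty <- overall$values[pick]
  g
}

#' Project measured fingertip contacts onto the candidate set
#'
#' Each fingertip position snaps to its nearest accessible candidate contact
#' (Euclidean distance to triangle centers, consistent with the manifold
#' discretization). Records snapping further than \code{suspect_mm} are
#' flagged as suspect (likely tracking error).
#'
#' @param cands \code{candidate_set}.
#' @param thumb,index n x 3 matrices of fingertip positions at contact, mm,
#'   participant frame.
#' @param trial optional trial identifiers.
#' @param suspect_mm snap-distance threshold for flagging, mm.
#' @return Grasp data frame with candidate indices, snap distances, and a
#'   \code{suspect} flag.
#' @export
project_contacts <- function(cands, thumb, index, trial = NULL,
                             suspect_mm = 20) {
  thumb <- rbind3(thumb); index <- rbind3(index)
  snap <- function(pts) {
    d2 <- outer(rowSums(pts^2), rowSums(cands$positions^2), "+") -
      2 * tcrossprod(pts, cands$positions)
    idx <- max.col(-d2, ties.method = "first")
    list(idx = idx, dist = sqrt(pmax(d2[cbind(seq_len(nrow(pts)), idx)], 0)))
  }
  st <- snap(thumb); si <- snap(index)
  g <- grasp_table(cands$positions[st$idx, , drop = FALSE],
                   cands$positions[si$idx, , drop = FALSE],
                   thumb_cand = st$idx, index_cand = si$idx, trial = trial)
  g$snap_thumb <- st$dist
  g$snap_index <- si$dist
  g$suspect <- st$dist > suspect_mm | si$dist > suspect_mm
  if (any(g$suspect))
    warning(sum(g$suspect), " contact record(s) snapped further than ",
            suspect_mm, " mm; flagged as suspect")
  g
}

#' Read / write grasp tables as delimited text
#'
#' Tab-separated with a header row; at minimum the six coordinate columns
#' \code{xT yT zT xI yI zI} (mm), plus any extra columns (trial, subject,
#' object, ...).
#' @param path file path.
#' @return \code{read_grasp_table}: grasp data frame.
#' @export
read_grasp_table <- function(path) {
  g <- utils::read.delim(path, check.names = FALSE)
  missing <- setdiff(grasp_columns, names(g))
  if (length(missing))
    stop("grasp table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  g
}

#' @rdname read_grasp_table
#' @param grasps grasp data frame.
#' @export
write_grasp_table <- function(grasps, path) {
  utils::write.table(grasps, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
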